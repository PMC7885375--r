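# Recording I/O: minimal EDF / EDF+C and delimited-matrix formats.
#
# The EDF implementation covers what this package needs: 16-bit signals
# with a common sampling rate, one data record spanning the recording,
# and (when annotations are present) an EDF+C "EDF Annotations" signal
# carrying time-stamped annotation lists.

.padField <- function(s, width) {
  s <- as.character(s)
  if (nchar(s, type = "bytes") > width)
    stop("EDF header field too wide: ", s)
  formatC(s, width = -width, flag = " ")
}

.numField <- function(x, width = 8L) {
  s <- formatC(x, format = "fg", width = 1L, digits = 7L)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 4L), 1L, width)
  .padField(s, width)
}

#' Construct a Recording
#'
#' @param samples numeric channel x time matrix in microvolts; rows named
#'   by channel (or supply `channels`).
#' @param rate sampling frequency, Hz.
#' @param annotations data.frame with columns `onset` (s) and `label`.
#' @param channels optional channel labels if `samples` is unnamed.
#' @return a [Recording-class].
#' @export
newRecording <- function(samples, rate,
                         annotations = data.frame(onset = numeric(0),
                                                  label = character(0)),
                         channels = NULL) {
  samples <- as.matrix(samples)
  if (!is.null(channels)) rownames(samples) <- channels
  new("Recording", samples = samples, rate = rate,
      annotations = as.data.frame(annotations))
}

#' Read a multichannel recording
#'
#' Supports European Data Format (plain EDF and EDF+C with an annotation
#' signal) and a delimited numeric matrix (channels x samples, tab
#' separated) accompanied by a JSON sidecar `<path>.json` holding
#' `{rate, channel_names, annotations}`. When a montage is supplied, every
#' file channel must belong to it (an unknown label is a named error) and
#' channels are reordered to montage order.
#'
#' @param path input file.
#' @param montage optional [Montage-class] for label checking/ordering.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @return a [Recording-class] in microvolts.
#' @export
readRecording <- function(path, montage = NULL,
                          format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  rec <- if (format == "edf") .readEDF(path) else .readDelimited(path)
  if (!is.null(montage)) {
    unknown <- setdiff(rownames(rec@samples), montage@channels)
    if (length(unknown))
      stop("channel(s) not in montage: ", paste(unknown, collapse = ", "))
    ord <- intersect(montage@channels, rownames(rec@samples))
    rec@samples <- rec@samples[ord, , drop = FALSE]
  }
  validObject(rec)
  rec
}

#' Write a multichannel recording
#'
#' EDF signals are quantized to 16 bits over integer physical bounds
#' enclosing each channel's range; `readRecording(writeRecording(rec))`
#' reproduces the samples within one quantization step
#' `(physMax - physMin) / 65535`. The delimited writer stores full-precision
#' text plus the JSON sidecar.
#'
#' @param rec a [Recording-class].
#' @param path output file.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @return invisibly, `path`.
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "delimited")) {
  stopifnot(is(rec, "Recording"))
  if (nrow(rec@samples) == 0L) stop("cannot write a recording with 0 channels")
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") .writeEDF(rec, path) else .writeDelimited(rec, path)
  invisible(path)
}

.writeDelimited <- function(rec, path) {
  utils::write.table(rec@samples, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  side <- list(rate = rec@rate, channel_names = rownames(rec@samples),
               annotations = rec@annotations)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
}

.readDelimited <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- list(side$channel_names, NULL)
  ann <- side$annotations
  if (is.null(ann) || length(ann) == 0L)
    ann <- data.frame(onset = numeric(0), label = character(0))
  newRecording(x, rate = side$rate, annotations = as.data.frame(ann))
}

.writeEDF <- function(rec, path) {
  x <- rec@samples
  n <- nrow(x); nsamp <- ncol(x)
  dur <- nsamp / rec@rate
  hasAnn <- nrow(rec@annotations) > 0L
  pmn <- floor(apply(x, 1L, min)); pmx <- ceiling(apply(x, 1L, max))
  flat <- pmx - pmn < 1e-12
  pmn[flat] <- pmn[flat] - 1; pmx[flat] <- pmx[flat] + 1
  dig <- round(sweep(sweep(x, 1L, pmn, "-"), 1L, (pmx - pmn) / 65535, "/")) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)

  tal <- raw(0)
  if (hasAnn) {
    # TALs separated by NUL: record timestamp first, then one TAL per event
    pieces <- c("+0\x14\x14",
                sprintf("+%.6g\x14%s\x14", rec@annotations$onset,
                        rec@annotations$label))
    tal <- unlist(lapply(pieces, function(p) c(charToRaw(p), as.raw(0L))))
    if (length(tal) %% 2L) tal <- c(tal, as.raw(0L))
  }
  ns <- n + as.integer(hasAnn)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.padField(s, w), con, nchars = w, eos = NULL)
  wr("0", 8L); wr("X X X X", 80L); wr("Startdate 01-JAN-2000 X X X", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(as.character(256L * (ns + 1L)), 8L)
  wr(if (hasAnn) "EDF+C" else "", 44L)
  wr("1", 8L)                       # one data record
  wr(format(dur, digits = 8), 8L)
  wr(as.character(ns), 4L)
  labs <- c(rownames(x), if (hasAnn) "EDF Annotations")
  for (l in labs) wr(l, 16L)
  for (i in seq_len(ns)) wr("", 80L)                   # transducer
  for (i in seq_len(ns)) wr(if (i <= n) "uV" else "", 8L)
  for (i in seq_len(ns)) wr(if (i <= n) .numField(pmn[i]) else "-1", 8L)
  for (i in seq_len(ns)) wr(if (i <= n) .numField(pmx[i]) else "1", 8L)
  for (i in seq_len(ns)) wr("-32768", 8L)
  for (i in seq_len(ns)) wr("32767", 8L)
  for (i in seq_len(ns)) wr("", 80L)                   # prefiltering
  spr <- c(rep(nsamp, n), if (hasAnn) length(tal) / 2L)
  for (v in spr) wr(as.character(v), 8L)
  for (i in seq_len(ns)) wr("", 32L)
  for (i in seq_len(n))
    writeBin(as.integer(dig[i, ]), con, size = 2L, endian = "little")
  if (hasAnn) writeBin(tal, con)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    sub("[ ]+$", "", s)
  }
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L); rd(8L)
  reserved <- rd(44L)
  nRec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  for (i in seq_len(ns)) rd(80L)
  for (i in seq_len(ns)) rd(8L)   # physical dimension
  pmn <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  pmx <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  dmn <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  dmx <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  for (i in seq_len(ns)) rd(80L)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1))
  for (i in seq_len(ns)) rd(32L)

  isAnn <- labels == "EDF Annotations"
  dataIdx <- which(!isAnn)
  if (length(unique(spr[dataIdx])) > 1L)
    stop("rate mismatch across channels in ", path)
  sig <- vector("list", ns)
  for (i in dataIdx) sig[[i]] <- numeric(0)
  annRaw <- raw(0)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        annRaw <- c(annRaw, readBin(con, "raw", n = 2L * spr[i]))
      } else {
        d <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
        sig[[i]] <- c(sig[[i]],
                      pmn[i] + (d - dmn[i]) * (pmx[i] - pmn[i]) / (dmx[i] - dmn[i]))
      }
    }
  }
  x <- do.call(rbind, sig[dataIdx])
  rownames(x) <- labels[dataIdx]
  ann <- .parseTALs(annRaw)
  newRecording(x, rate = spr[dataIdx[1L]] / dur, annotations = ann)
}

.parseTALs <- function(annRaw) {
  out <- data.frame(onset = numeric(0), label = character(0))
  if (!length(annRaw)) return(out)
  nul <- which(annRaw == as.raw(0L))
  starts <- c(1L, nul + 1L)
  ends <- c(nul - 1L, length(annRaw))
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k]) next
    tal <- rawToChar(annRaw[starts[k]:ends[k]])
    fields <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) next
    onset <- as.numeric(sub("\x15.*$", "", fields[1L]))
    labels <- fields[-1L][nzchar(fields[-1L])]
    for (l in labels)
      out <- rbind(out, data.frame(onset = onset, label = l))
  }
  out
}
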