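# Montage construction, JSON I/O, neighbour relations, mid-sagittal flip.

#' All unordered channel pairs
#'
#' Enumerates the n(n-1)/2 unordered channel pairs in the canonical order
#' used throughout the package (column-major upper triangle: (1,2), (1,3),
#' (2,3), (1,4), ...). A 62-channel montage yields 1891 pairs.
#'
#' @param x a [Montage-class], a character vector of channel labels, or a
#'   single integer channel count.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @examples
#' nrow(channelPairs(62))  # 1891
#' @export
channelPairs <- function(x) {
  n <- if (is(x, "Montage")) length(x@channels)
       else if (is.character(x)) length(x)
       else as.integer(x)
  if (n < 2L) stop("need at least two channels")
  m <- matrix(FALSE, n, n)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j")
  rownames(idx) <- NULL
  idx
}

#' Construct a Montage
#'
#' Hemisphere labels are derived from the sign of the x coordinate
#' (head-centered frame, x positive toward the right ear; |x| below
#' `tol` is midline). The homologue map, when not supplied, is derived
#' from 10-20 nomenclature: trailing odd digits pair with the next even
#' digit (1-2, 3-4, 5-6, 7-8, 9-10) and z-line channels are fixed points.
#'
#' @param channels character vector of channel labels.
#' @param positions numeric n x 2 matrix of 2-D scalp positions.
#' @param flipMap optional named character homologue map; `NULL` derives it
#'   from the labels, `NA` leaves it undefined.
#' @param neighbors optional logical adjacency matrix (see
#'   [neighborsFromPositions()]).
#' @param tol midline tolerance on |x|.
#' @return a [Montage-class] object.
#' @export
newMontage <- function(channels, positions, flipMap = NULL, neighbors = NULL,
                       tol = .MIDLINE_TOL) {
  positions <- as.matrix(positions)
  rownames(positions) <- channels
  colnames(positions) <- c("x", "y")
  x <- positions[, 1L]
  hemisphere <- ifelse(abs(x) <= tol, "midline", ifelse(x > 0, "right", "left"))
  if (is.null(flipMap)) flipMap <- .deriveFlipMap(channels, hemisphere)
  if (length(flipMap) == 1L && is.na(flipMap)) flipMap <- character(0)
  if (is.null(neighbors)) neighbors <- matrix(logical(0), 0L, 0L)
  new("Montage", channels = channels, positions = positions,
      hemisphere = unname(hemisphere), neighbors = neighbors,
      flipMap = flipMap)
}

# Homologue labels by 10-20 digit parity; errors on a lateral channel
# without a homologue in the montage.
.deriveFlipMap <- function(channels, hemisphere) {
  target <- vapply(channels, function(ch) {
    m <- regmatches(ch, regexec("^([A-Za-z]+?)(z|[0-9]+)$", ch))[[1L]]
    if (length(m) == 0L) return(NA_character_)
    if (m[3L] == "z") return(ch)
    k <- as.integer(m[3L])
    paste0(m[2L], if (k %% 2L == 1L) k + 1L else k - 1L)
  }, character(1))
  bad <- channels[is.na(target) | !(target %in% channels)]
  bad <- setdiff(bad, channels[hemisphere == "midline"])
  if (length(bad))
    stop("no homologue in montage for channel(s): ", paste(bad, collapse = ", "))
  target[is.na(target)] <- channels[is.na(target)]  # midline without z suffix
  target[!(target %in% channels)] <- channels[!(target %in% channels)]
  structure(unname(target), names = channels)
}

#' Left/right hemisphere channel sets
#'
#' Midline (z-line) channels belong to neither set; the equal-size left and
#' right sets are the S_Lhemi / S_Rhemi node sets of the intermediate- and
#' small-scale network indices.
#'
#' @param montage a [Montage-class].
#' @return list with character vectors `left`, `right`, `midline`.
#' @export
hemisphereSets <- function(montage) {
  split(montage@channels,
        factor(montage@hemisphere, c("left", "right", "midline")))
}

#' Read / write a montage as versioned JSON
#'
#' The JSON schema is `{name, version, channels: [{label, x, y, hemisphere,
#' homologue}], neighbors: [[label, label], ...]}`.
#'
#' @param path file path.
#' @return `readMontage` returns a [Montage-class]; `writeMontage`
#'   (invisibly) the path.
#' @export
readMontage <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- doc$channels
  nb <- matrix(FALSE, nrow(ch), nrow(ch), dimnames = list(ch$label, ch$label))
  if (!is.null(doc$neighbors) && length(doc$neighbors)) {
    e <- if (is.matrix(doc$neighbors)) doc$neighbors else do.call(rbind, doc$neighbors)
    nb[cbind(e[, 1L], e[, 2L])] <- TRUE
    nb <- nb | t(nb)
  }
  fm <- if (all(is.na(ch$homologue))) NA else
    structure(ch$homologue, names = ch$label)
  m <- newMontage(ch$label, cbind(ch$x, ch$y), flipMap = fm,
                  neighbors = if (any(nb)) nb else NULL)
  if (!identical(unname(m@hemisphere), unname(ch$hemisphere)))
    stop("stored hemisphere labels inconsistent with coordinates in ", path)
  m
}

#' @rdname readMontage
#' @param montage a [Montage-class] to serialize.
#' @param name,version metadata stored in the file.
#' @export
writeMontage <- function(montage, path, name = "montage", version = "1") {
  ch <- data.frame(label = montage@channels,
                   x = montage@positions[, 1L], y = montage@positions[, 2L],
                   hemisphere = montage@hemisphere,
                   homologue = if (length(montage@flipMap))
                     unname(montage@flipMap[montage@channels]) else NA_character_)
  nbl <- list()
  if (length(montage@neighbors)) {
    idx <- which(montage@neighbors & upper.tri(montage@neighbors), arr.ind = TRUE)
    nbl <- lapply(seq_len(nrow(idx)), function(k)
      c(montage@channels[idx[k, 1L]], montage@channels[idx[k, 2L]]))
  }
  jsonlite::write_json(
    list(name = name, version = version, channels = ch, neighbors = nbl),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The shipped 62-channel analysis montage
#'
#' A 10-20/10-10 layout of 62 analysis channels (a 64-channel cap with
#' ground and reference removed): 28 left, 28 right and 6 midline channels
#' (Fz, Cz, CPz, Pz, POz, Oz), with positions on the azimuthal scalp
#' projection, the digit-parity homologue map, and Delaunay-derived
#' neighbour structure precomputed at asset-build time.
#'
#' @return a [Montage-class] with 62 channels and 1891 unordered pairs.
#' @examples
#' m <- defaultMontage()
#' length(channelNames(m))       # 62
#' nrow(channelPairs(m))         # 1891
#' @export
defaultMontage <- function() {
  readMontage(system.file("extdata", "montage62.json", package = "imcohnet",
                          mustWork = TRUE))
}

# Programmatic construction of the shipped layout (used to build the JSON
# asset; exported for reproducibility of the asset itself).
#' @rdname defaultMontage
#' @param neighbors logical; also compute the Delaunay neighbour relation.
#' @export
standardMontage62 <- function(neighbors = TRUE) {
  rows <- list(Fp = 0.1, AF = 0.2, F = 0.3, FT = 0.4, FC = 0.4,
               T = 0.5, C = 0.5, TP = 0.6, CP = 0.6, P = 0.7,
               PO = 0.8, O = 0.9)
  midline <- c("Fz", "Cz", "CPz", "Pz", "POz", "Oz")
  leftNums <- list(Fp = 1L, AF = c(7L, 3L), F = c(7L, 5L, 3L, 1L),
                   FT = c(9L, 7L), FC = c(5L, 3L, 1L), T = 7L,
                   C = c(5L, 3L, 1L), TP = c(9L, 7L), CP = c(5L, 3L, 1L),
                   P = c(7L, 5L, 3L, 1L), PO = c(7L, 3L), O = 1L)
  lab <- character(0); px <- numeric(0); py <- numeric(0)
  posOf <- function(t, u, side) {
    # Row arc through the midline point (0, yt) and the preauricular
    # points (+-1, 0); 9/10 channels sit 15% beyond the rim along the
    # direction of the row's u = 0.4 channel.
    yt <- (0.5 - t) * 1.6
    if (u >= 0.5 - 1e-9) {
      p <- c(side * sin(0.4 * pi), yt * cos(0.4 * pi))
      p * 1.15 / sqrt(sum(p^2))
    } else c(side * sin(u * pi), yt * cos(u * pi))
  }
  for (row in names(rows)) {
    t <- rows[[row]]
    for (k in leftNums[[row]]) {
      u <- c(`1` = 0.1, `3` = 0.2, `5` = 0.3, `7` = 0.4, `9` = 0.5)[[as.character(k)]]
      # T row's lateral extreme is labelled T7/T8 (u = 0.4)
      u <- if (row == "T") 0.4 else u
      for (side in c(-1, 1)) {
        num <- if (side < 0) k else k + 1L
        lab <- c(lab, paste0(row, num))
        p <- posOf(t, u, side)
        px <- c(px, p[1L]); py <- c(py, p[2L])
      }
    }
  }
  for (ch in midline) {
    row <- sub("z$", "", ch)
    t <- rows[[row]]
    lab <- c(lab, ch); px <- c(px, 0); py <- c(py, (0.5 - t) * 1.6)
  }
  m <- newMontage(lab, cbind(px, py))
  if (neighbors) m@neighbors <- neighborsFromPositions(m)
  validObject(m)
  m
}

#' Subset a montage to a balanced channel set
#'
#' Keeps the given channels (hemisphere balance and flip-map closure are
#' required) and recomputes the neighbour relation on the remaining
#' positions. Used for reduced-scale analyses where the full 1891-pair
#' edge set is not wanted.
#'
#' @param montage a [Montage-class].
#' @param channels channel labels to keep.
#' @param rule,param neighbour rule, see [neighborsFromPositions()].
#' @return a [Montage-class] over `channels` (in montage order).
#' @export
subsetMontage <- function(montage, channels, rule = "delaunay", param = NULL) {
  keep <- intersect(montage@channels, channels)
  missing <- setdiff(channels, montage@channels)
  if (length(missing))
    stop("channel(s) not in montage: ", paste(missing, collapse = ", "))
  fm <- NULL
  if (length(montage@flipMap)) {
    fm <- montage@flipMap[keep]
    if (!all(fm %in% keep))
      stop("subset is not closed under the flip map; missing homologue(s): ",
           paste(setdiff(fm, keep), collapse = ", "))
  }
  m <- newMontage(keep, montage@positions[keep, , drop = FALSE], flipMap = fm)
  m@neighbors <- neighborsFromPositions(m, rule, param)
  validObject(m)
  m
}

#' Channel-neighbour relation from 2-D positions
#'
#' Default rule: Delaunay triangulation of the scalp positions with edges
#' longer than `param` times the median Delaunay edge length removed
#' (standard sensor-space practice). The alternative `"distance"` rule
#' connects channels closer than the absolute threshold `param`. Under
#' either rule the result is symmetric and irreflexive, and under the
#' default rule a channel stripped of all edges by pruning keeps its
#' shortest Delaunay edge so every channel has at least one neighbour.
#'
#' @param montage a [Montage-class] (or n x 2 position matrix).
#' @param rule `"delaunay"` or `"distance"`.
#' @param param prune factor (delaunay, default 1.5) or absolute distance
#'   threshold (distance).
#' @return logical n x n adjacency matrix.
#' @examples
#' sq <- newMontage(c("a1","a2","b1","b2"),
#'                  cbind(c(-.5,.5,-.5,.5), c(0,0,1,1)))
#' sum(neighborsFromPositions(sq, "distance", 1.1)) / 2  # 4 edges: sides
#' @export
neighborsFromPositions <- function(montage, rule = c("delaunay", "distance"),
                                   param = NULL) {
  rule <- match.arg(rule)
  P <- if (is(montage, "Montage")) montage@positions else as.matrix(montage)
  n <- nrow(P)
  if (n < 2L) stop("need at least 2 channel positions")
  D <- as.matrix(stats::dist(P))
  nb <- matrix(FALSE, n, n, dimnames = list(rownames(P), rownames(P)))
  if (rule == "distance") {
    if (is.null(param)) stop("distance rule requires a threshold")
    nb <- D > 0 & D <= param
  } else {
    if (n < 3L) stop("delaunay rule needs at least 3 positions")
    if (any(D[upper.tri(D)] < 1e-12)) stop("duplicate positions under delaunay rule")
    tri <- .delaunayTriangles(P)
    if (nrow(tri) == 0L) stop("positions are collinear; no triangulation exists")
    for (k in seq_len(nrow(tri))) {
      v <- tri[k, ]
      nb[v[1L], v[2L]] <- nb[v[2L], v[3L]] <- nb[v[1L], v[3L]] <- TRUE
    }
    nb <- nb | t(nb)
    prune <- if (is.null(param)) 1.5 else param
    lens <- D[nb & upper.tri(nb)]
    cut <- prune * stats::median(lens)
    keep <- nb & D <= cut
    # guarantee degree >= 1: restore the shortest incident edge
    for (i in which(rowSums(keep) == 0L)) {
      j <- which(nb[i, ])
      j <- j[which.min(D[i, j])]
      keep[i, j] <- keep[j, i] <- TRUE
    }
    nb <- keep
  }
  diag(nb) <- FALSE
  nb
}

# Brute-force Delaunay: a triple is a Delaunay triangle iff no other point
# lies strictly inside its circumcircle. O(n^3) triples x O(n) test; fine
# for sensor counts.
.delaunayTriangles <- function(P) {
  n <- nrow(P)
  out <- matrix(integer(0), 0L, 3L)
  x <- P[, 1L]; y <- P[, 2L]
  for (i in seq_len(n - 2L)) for (j in seq((i + 1L), n - 1L)) for (k in seq((j + 1L), n)) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear triple
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (x - ux)^2 + (y - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 >= r2 * (1 - 1e-9))) out <- rbind(out, c(i, j, k))
  }
  out
}

#' Mid-sagittal flip of a TrialSet
#'
#' Moves each channel's signal to its left/right homologue (midline
#' channels unchanged), as used to pool subjects with left- and
#' right-hemisphere lesions into one group. Applying the flip twice
#' restores the input exactly.
#'
#' @param trials a [TrialSet-class].
#' @param montage a [Montage-class] whose `flipMap` covers all channels.
#' @return a [TrialSet-class] with permuted channel data; condition and
#'   limb labels untouched.
#' @export
flipMidSagittal <- function(trials, montage) {
  if (!length(montage@flipMap))
    stop("montage has no flip map; cannot flip")
  ch <- channelNames(trials)
  missing <- setdiff(ch, names(montage@flipMap))
  if (length(missing))
    stop("channel(s) without homologue and not midline: ",
         paste(missing, collapse = ", "))
  target <- montage@flipMap[ch]
  if (!all(target %in% ch))
    stop("homologue(s) absent from TrialSet: ",
         paste(setdiff(target, ch), collapse = ", "))
  perm <- match(target, ch)   # data of channel i moves to position perm[i]
  out <- trials@data
  out[, perm, ] <- trials@data
  dimnames(out) <- dimnames(trials@data)
  initialize(trials, data = out)
}
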