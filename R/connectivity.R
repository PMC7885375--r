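# Welch cross-spectra and imaginary-coherence connectivity.

#' Define a frequency band (inclusive edges)
#'
#' @param name band name.
#' @param loHz,hiHz inclusive band edges in Hz.
#' @return a [BandDefinition-class].
#' @export
bandDefinition <- function(name, loHz, hiHz) {
  new("BandDefinition", name = name, loHz = loHz, hiHz = hiHz)
}

#' The beta sub-bands used for tactile connectivity
#'
#' Beta 1 = 15-19 Hz, beta 2 = 20-25 Hz, beta 3 = 26-30 Hz; beta 2 is the
#' band of interest for stimulation-induced connectivity.
#'
#' @return named list of [BandDefinition-class] objects.
#' @export
betaBands <- function() {
  list(beta1 = bandDefinition("beta1", 15, 19),
       beta2 = bandDefinition("beta2", 20, 25),
       beta3 = bandDefinition("beta3", 26, 30))
}

#' Welch-averaged cross-spectral matrix of one trial
#'
#' Partitions the trial into Hann-tapered segments of `windowS` seconds
#' with fractional `overlap` (defaults 2 s, 50%), demeans each segment,
#' and averages the segment cross-periodograms, giving a frequency grid
#' with spacing `1/windowS` (0.5 Hz at defaults: a 4-s trial yields 3
#' averaged segments). The result is Hermitian with a real non-negative
#' diagonal.
#'
#' @param trial numeric channel x sample matrix (one trial), rows named by
#'   channel, or a [TrialSet-class] trial slice.
#' @param rate sampling frequency, Hz.
#' @param windowS segment length in seconds.
#' @param overlap overlap fraction in [0, 1).
#' @param freqRange optional `c(lo, hi)` in Hz; restricts the stored grid
#'   (the full FFT is still computed).
#' @return a [CrossSpectrum-class].
#' @export
crossSpectrum <- function(trial, rate, windowS = 2, overlap = 0.5,
                          freqRange = NULL) {
  x <- as.matrix(trial)
  nCh <- nrow(x); N <- ncol(x)
  nper <- as.integer(round(windowS * rate))
  if (N < nper)
    stop("trial (", N, " samples) shorter than one ", windowS, "-s window")
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, N - nper + 1L, by = step)
  K <- length(starts)
  w <- 0.5 * (1 - cos(2 * pi * seq(0L, nper - 1L) / (nper - 1L)))  # Hann
  U <- sum(w^2)
  nF <- nper %/% 2L + 1L
  freqs <- (seq_len(nF) - 1L) / windowS
  keep <- seq_len(nF)
  if (!is.null(freqRange))
    keep <- which(freqs >= freqRange[1L] - 1e-9 & freqs <= freqRange[2L] + 1e-9)
  # X[ch, kept freq, seg]
  X <- array(0 + 0i, c(nCh, length(keep), K))
  for (k in seq_len(K)) {
    seg <- x[, starts[k]:(starts[k] + nper - 1L), drop = FALSE]
    seg <- sweep(seg, 1L, rowMeans(seg)) * rep(w, each = nCh)
    F <- stats::mvfft(t(seg))             # nper x nCh
    X[, , k] <- t(F[keep, , drop = FALSE])
  }
  S <- array(0 + 0i, c(nCh, nCh, length(keep)),
             dimnames = list(rownames(x), rownames(x), NULL))
  scale <- 1 / (K * U * rate)
  for (m in seq_along(keep)) {
    Xf <- X[, m, , drop = TRUE]
    if (is.null(dim(Xf))) Xf <- matrix(Xf, nCh, K)
    S[, , m] <- (Xf %*% Conj(t(Xf))) * scale
  }
  new("CrossSpectrum", values = S, freqs = freqs[keep],
      windowS = windowS, overlap = overlap, nSegments = K)
}

#' Imaginary coherence from a cross-spectrum
#'
#' Coherency is the normalized cross-spectrum
#' C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f)); the connectivity value is
#' |Im C_ij(f)|, in [0, 1]. Zero-lag common signals (volume conduction)
#' have real coherency and therefore vanish. The signed imaginary part is
#' kept in the `signedIm` slot.
#'
#' @param cs a [CrossSpectrum-class] with strictly positive auto-spectra
#'   at every evaluated frequency.
#' @return a [SpectralConnectivity-class].
#' @export
imaginaryCoherence <- function(cs) {
  S <- cs@values
  nCh <- dim(S)[1L]; nF <- dim(S)[3L]
  ch <- dimnames(S)[[1L]]
  auto <- matrix(NA_real_, nCh, nF)
  for (m in seq_len(nF)) auto[, m] <- Re(diag(S[, , m, drop = TRUE]))
  bad <- which(auto <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("zero auto-spectrum for channel %s at %g Hz",
                 if (is.null(ch)) bad[1L, 1L] else ch[bad[1L, 1L]],
                 cs@freqs[bad[1L, 2L]]))
  im <- array(NA_real_, dim(S), dimnames = dimnames(S))
  for (m in seq_len(nF)) {
    denom <- sqrt(outer(auto[, m], auto[, m]))
    im[, , m] <- Im(S[, , m] / denom)
    diag(im[, , m]) <- 0
  }
  a <- abs(im)
  a[a > 1] <- 1   # guard against rounding just above 1
  new("SpectralConnectivity", imcoh = a, signedIm = im, freqs = cs@freqs)
}

#' Band-aggregated connectivity matrix
#'
#' Per channel pair, the mean (or peak) imaginary coherence over the
#' frequency bins with `loHz <= f <= hiHz` (edges inclusive on the 0.5-Hz
#' grid, so beta 2 = 20-25 Hz spans 11 bins).
#'
#' @param sc a [SpectralConnectivity-class].
#' @param band a [BandDefinition-class].
#' @param mode `"mean"` or `"peak"`.
#' @return symmetric channel x channel matrix with zero diagonal.
#' @export
bandSummary <- function(sc, band, mode = c("mean", "peak")) {
  mode <- match.arg(mode)
  idx <- which(sc@freqs >= band@loHz - 1e-9 & sc@freqs <= band@hiHz + 1e-9)
  if (!length(idx))
    stop("band ", band@name, " (", band@loHz, "-", band@hiHz,
         " Hz) outside the frequency grid")
  v <- sc@imcoh[, , idx, drop = FALSE]
  if (mode == "mean") apply(v, c(1L, 2L), mean) else apply(v, c(1L, 2L), max)
}

#' Per-trial band connectivity matrices of a TrialSet
#'
#' Convenience wrapper: Welch cross-spectrum, imaginary coherence and band
#' aggregation for every trial. Cross-spectra are averaged across the
#' segments of each trial; condition-level connectivity should average
#' the per-trial ImCoh matrices (the values entering trial-wise t-tests),
#' not the cross-spectra.
#'
#' @param trials a [TrialSet-class].
#' @param band a [BandDefinition-class] (default beta 2).
#' @param windowS,overlap Welch parameters.
#' @param mode band aggregation mode.
#' @return channel x channel x trial array.
#' @export
trialConnectivity <- function(trials, band = betaBands()$beta2,
                              windowS = 2, overlap = 0.5,
                              mode = c("mean", "peak")) {
  mode <- match.arg(mode)
  d <- dim(trials@data)
  ch <- channelNames(trials)
  out <- array(NA_real_, c(d[2L], d[2L], d[1L]),
               dimnames = list(ch, ch, NULL))
  pad <- 1 / windowS  # keep one guard bin each side of the band
  for (tr in seq_len(d[1L])) {
    cs <- crossSpectrum(trials@data[tr, , ], trials@rate, windowS, overlap,
                        freqRange = c(band@loHz - pad, band@hiHz + pad))
    out[, , tr] <- bandSummary(imaginaryCoherence(cs), band, mode)
  }
  out
}

#' Condition-averaged connectivity of a TrialSet
#'
#' Averages per-trial band ImCoh matrices within each condition (and,
#' optionally, a single limb).
#'
#' @inheritParams trialConnectivity
#' @param limb optional limb filter (`"left"`/`"right"`).
#' @return named list of channel x channel matrices, one per condition,
#'   plus the per-trial array in `$trials` and labels in `$condition`.
#' @export
conditionConnectivity <- function(trials, band = betaBands()$beta2,
                                  limb = NULL, windowS = 2, overlap = 0.5) {
  keep <- if (is.null(limb)) seq_len(nTrials(trials)) else which(trials@limb == limb)
  sub <- subsetTrials(trials, keep)
  fc <- trialConnectivity(sub, band, windowS, overlap)
  conds <- unique(sub@condition)
  means <- lapply(conds, function(cd)
    apply(fc[, , sub@condition == cd, drop = FALSE], c(1L, 2L), mean))
  names(means) <- conds
  c(means, list(trials = fc, condition = sub@condition))
}
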