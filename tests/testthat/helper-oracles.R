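# Shared fixtures and independent brute-force oracles.

# Balanced rectangular grid montage (nx columns straddle the midline so
# left/right counts are equal); 4-neighbour adjacency by distance.
gridMontage <- function(nx = 4, ny = 4, spacing = 1) {
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing
  g <- expand.grid(x = xs, y = ys)
  lab <- sprintf("g%02d", seq_len(nrow(g)))
  # homologue = mirror image across the mid-sagittal (x = 0) line
  fm <- vapply(seq_len(nrow(g)), function(i)
    lab[which(abs(g$x + g$x[i]) < 1e-9 & abs(g$y - g$y[i]) < 1e-9)],
    character(1))
  m <- newMontage(lab, as.matrix(g), flipMap = structure(fm, names = lab))
  m@neighbors <- neighborsFromPositions(m, "distance", spacing * 1.01)
  m
}

# --- graph oracles: explicit path enumeration via boolean matrix powers ---

bruteDistances <- function(A) {
  A <- (as.matrix(A) != 0) * 1
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n)
  P <- diag(n)
  for (k in seq_len(n - 1)) {
    P <- (P %*% A > 0) * 1
    newly <- P > 0 & reach == 0
    D[newly] <- k
    reach <- reach | P
  }
  D
}

bruteGlobalEff <- function(A) {
  n <- nrow(A)
  D <- bruteDistances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

bruteLocalEff <- function(A) {
  A <- (as.matrix(A) != 0) * 1
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    bruteGlobalEff(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

bruteInterIntra <- function(A, L, R) {
  A <- (as.matrix(A) != 0) * 1
  Ns <- length(L)
  inter <- 0
  for (i in L) for (j in R) inter <- inter + A[i, j]
  intraCount <- function(S) {
    s <- 0
    for (i in S) for (j in S) if (i < j) s <- s + A[i, j]
    s
  }
  dInter <- numeric(nrow(A)); dIntra <- numeric(nrow(A))
  for (i in L) { for (j in R) dInter[i] <- dInter[i] + A[i, j]
                 for (j in setdiff(L, i)) dIntra[i] <- dIntra[i] + A[i, j] }
  for (i in R) { for (j in L) dInter[i] <- dInter[i] + A[i, j]
                 for (j in setdiff(R, i)) dIntra[i] <- dIntra[i] + A[i, j] }
  list(kInter = inter / Ns^2,
       kIntraL = intraCount(L) / (Ns * (Ns - 1) / 2),
       kIntraR = intraCount(R) / (Ns * (Ns - 1) / 2),
       dInter = dInter, dIntra = dIntra)
}

randomAdjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# symmetric zero-diagonal FC stack with channel names from a montage
randomFCStack <- function(montage, nObs, mean = 0.3, sd = 0.05) {
  n <- length(channelNames(montage))
  out <- array(0, c(n, n, nObs),
               dimnames = list(channelNames(montage), channelNames(montage), NULL))
  for (s in seq_len(nObs)) {
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- stats::rnorm(n * (n - 1) / 2, mean, sd)
    out[, , s] <- M + t(M)
  }
  out
}

# small reduced-rate config for fast signal-level tests
fastConfig <- function(...) {
  cohortConfig(nChannels = 16L, rate = 250, trialS = 4, noiseSD = 1, ...)
}

# an SFCResult with a prescribed topography: nContra channels on the
# hemisphere contralateral to `side`, the rest ipsilateral
syntheticSFC <- function(montage, nContra, nTotal, side = "left") {
  ch <- channelNames(montage)
  hemi <- hemisphereOf(montage)
  contraHemi <- if (side == "left") "right" else "left"
  ipsiHemi <- setdiff(c("left", "right"), contraHemi)
  ns <- structure(numeric(length(ch)), names = ch)
  ns[ch[hemi == contraHemi][seq_len(nContra)]] <- -1
  if (nTotal > nContra)
    ns[ch[hemi == ipsiHemi][seq_len(nTotal - nContra)]] <- 1
  new("SFCResult", channels = ch,
      clusters = list(new("EdgeCluster", edges = matrix(1:2, 1), t = 1,
                          clusterStat = 1, permP = 0.01)),
      edges = matrix(1:2, 1), t = 1, normalizedT = 1, clusterId = 1L,
      permP = 0.01, nodeSum = ns, nPermutations = 256L, exhaustive = TRUE,
      alpha = 0.05, seed = 1L)
}
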