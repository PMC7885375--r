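# Stimulation-induced functional connectivity: paired edge statistics,
# sign-homogeneous edge clusters on adjacent channels, max-statistic
# permutation correction, and topography summaries.

# Canonical pair layout: columns of channelPairs(n). Converts a stack of
# symmetric channel x channel matrices (3rd dim = subject/trial) into an
# observation x pair matrix.
.pairMatrix <- function(fc) {
  if (is.list(fc)) fc <- simplify2array(fc)
  if (length(dim(fc)) == 2L) fc <- array(fc, c(dim(fc), 1L))
  n <- dim(fc)[1L]
  pr <- channelPairs(n)
  out <- matrix(NA_real_, dim(fc)[3L], nrow(pr))
  for (s in seq_len(dim(fc)[3L]))
    out[s, ] <- fc[, , s][pr]
  out
}

# Vectorized paired t over columns of difference matrix D (obs x pairs).
.pairedT <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  list(t = m / sqrt(v / n), df = n - 1)
}

#' Paired edge statistics between two conditions
#'
#' Per unordered channel pair, the paired t statistic of the subject-wise
#' (or trial-wise) differences `condA - condB`, with two-sided p-values.
#'
#' @param condA,condB channel x channel x subject arrays (or lists of
#'   symmetric matrices) of band connectivity, same subjects in the same
#'   order.
#' @param channels channel labels (defaults to dimnames of `condA`).
#' @return an [EdgeStatMap-class] over all n(n-1)/2 pairs.
#' @export
edgeStats <- function(condA, condB, channels = NULL) {
  A <- .pairMatrix(condA); B <- .pairMatrix(condB)
  if (!identical(dim(A), dim(B)))
    stop("condition arrays must have identical dimensions")
  if (nrow(A) < 2L) stop("paired statistics need at least 2 subjects")
  if (is.null(channels)) {
    if (is.list(condA)) condA <- simplify2array(condA)
    channels <- dimnames(condA)[[1L]]
  }
  n <- if (!is.null(channels)) length(channels) else
    as.integer((1 + sqrt(1 + 8 * ncol(A))) / 2)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(n))
  D <- A - B
  sdD <- apply(D, 2L, stats::sd)
  mD <- colMeans(D)
  # identical conditions give 0/0: defined as t = 0 (p = 1); a non-zero
  # mean with zero variance would be t = +-Inf, which is disallowed
  if (any(sdD == 0 & mD != 0)) {
    pr <- channelPairs(n)
    k <- which(sdD == 0 & mD != 0)[1L]
    stop(sprintf("zero variance of paired differences for pair %s-%s",
                 channels[pr[k, 1L]], channels[pr[k, 2L]]))
  }
  ts <- .pairedT(D)
  tt <- ifelse(is.finite(ts$t), ts$t, 0)
  p <- 2 * stats::pt(-abs(tt), ts$df)
  new("EdgeStatMap", channels = channels, pairs = channelPairs(n),
      t = tt, p = p, df = ts$df)
}

# Closed-neighbourhood matrix: channel adjacency plus identity. Two edges
# are cluster-adjacent iff some endpoint of one is identical to, or a
# montage neighbour of, an endpoint of the other.
.closedNeighbors <- function(montage, n, sharedEndpointOnly = FALSE) {
  if (sharedEndpointOnly || is.null(montage) || !length(montage@neighbors)) {
    nb <- matrix(FALSE, n, n)
  } else nb <- montage@neighbors
  diag(nb) <- TRUE
  nb
}

# Core cluster scorer used both by the exported builder and by the
# permutation null loop: groups suprathreshold edges (split by t sign)
# into connected components under edge adjacency, discards singletons,
# returns member lists and summed statistics.
.edgeClusters <- function(pairs, tvals, supra, nbClosed) {
  idx <- which(supra)
  m <- length(idx)
  if (m == 0L) return(list(members = list(), stats = numeric(0)))
  a <- pairs[idx, 1L]; b <- pairs[idx, 2L]
  sgn <- sign(tvals[idx])
  adj <- (nbClosed[cbind(rep(a, each = m), rep(a, m))] |
          nbClosed[cbind(rep(a, each = m), rep(b, m))] |
          nbClosed[cbind(rep(b, each = m), rep(a, m))] |
          nbClosed[cbind(rep(b, each = m), rep(b, m))])
  dim(adj) <- c(m, m)
  adj <- adj & outer(sgn, sgn, "==")
  diag(adj) <- FALSE
  # label connected components (iterative flood fill)
  comp <- integer(m); cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nxt <- which(adj[v, ] & comp == 0L)
      comp[nxt] <- cur
      queue <- c(queue, nxt)
    }
  }
  members <- split(idx, comp)
  keep <- lengths(members) > 1L           # reject isolated significant edges
  members <- members[keep]
  list(members = members,
       stats = vapply(members, function(ix) sum(tvals[ix]), numeric(1)))
}

#' Build sign-homogeneous edge clusters (unscored)
#'
#' Thresholds the edge map at `edgeAlpha`, splits suprathreshold edges by
#' t sign, and groups them into connected components where two edges are
#' adjacent iff they share an endpoint channel or have endpoints that are
#' montage neighbours (`adjacency = "shared"` restricts to shared
#' endpoints only). Isolated suprathreshold edges are discarded.
#'
#' @param stats an [EdgeStatMap-class].
#' @param montage a [Montage-class] providing the neighbour relation.
#' @param edgeAlpha edge-inclusion threshold on the uncorrected p.
#' @param adjacency `"neighbor"` (default) or `"shared"`.
#' @return list of [EdgeCluster-class] (with `permP = NA`).
#' @export
buildEdgeClusters <- function(stats, montage, edgeAlpha = 0.05,
                              adjacency = c("neighbor", "shared")) {
  adjacency <- match.arg(adjacency)
  n <- length(stats@channels)
  nb <- .closedNeighbors(montage, n, adjacency == "shared")
  cl <- .edgeClusters(stats@pairs, stats@t, stats@p < edgeAlpha, nb)
  lapply(seq_along(cl$members), function(k)
    new("EdgeCluster", edges = stats@pairs[cl$members[[k]], , drop = FALSE],
        t = stats@t[cl$members[[k]]], clusterStat = cl$stats[[k]],
        permP = NA_real_))
}

#' Cluster-based permutation test for stimulation-induced connectivity
#'
#' Scores every observed sign-homogeneous edge cluster against the null
#' distribution of the maximum absolute cluster statistic under
#' within-subject condition-label exchange. When `nPerm` meets or exceeds
#' the 2^n exhaustive count the full enumeration is used (logged via a
#' message); otherwise sign flips are sampled and the Monte-Carlo p uses
#' the +1 correction. Clusters with `permP < alpha` are retained; their
#' edges get normalized t-values (t / max|t| over retained edges) and
#' every channel the sum of normalized t over its retained incident
#' edges.
#'
#' @param condA,condB per-subject band connectivity (channel x channel x
#'   subject arrays or lists of matrices); `condA` is the stimulation
#'   condition in the usual call.
#' @param montage a [Montage-class] with a neighbour relation.
#' @param nPerm requested number of permutations (>= 100).
#' @param alpha cluster significance level.
#' @param edgeAlpha edge-inclusion threshold.
#' @param seed RNG seed (ignored under exhaustive enumeration).
#' @param adjacency edge-adjacency rule, see [buildEdgeClusters()].
#' @return an [SFCResult-class].
#' @export
sfcPermutationTest <- function(condA, condB, montage, nPerm = 1000L,
                               alpha = 0.05, edgeAlpha = 0.05, seed = 1L,
                               adjacency = c("neighbor", "shared")) {
  adjacency <- match.arg(adjacency)
  if (nPerm < 100L) stop("nPerm must be at least 100")
  A <- .pairMatrix(condA); B <- .pairMatrix(condB)
  if (!identical(dim(A), dim(B)))
    stop("condition arrays must have identical dimensions")
  nSub <- nrow(A)
  if (nSub < 2L) stop("paired design needs at least 2 subjects")
  if (is.list(condA)) condA <- simplify2array(condA)
  channels <- dimnames(condA)[[1L]]
  n <- length(channels)
  if (n == 0L) {
    n <- as.integer((1 + sqrt(1 + 8 * ncol(A))) / 2)
    channels <- sprintf("ch%02d", seq_len(n))
  }
  pairs <- channelPairs(n)
  nb <- .closedNeighbors(montage, n, adjacency == "shared")
  D <- A - B
  df <- nSub - 1L
  tcrit <- stats::qt(1 - edgeAlpha / 2, df)
  SS <- colSums(D^2)

  tFromSigns <- function(s) {
    m <- as.vector(s %*% D) / nSub
    v <- (SS - nSub * m^2) / df
    v[v <= 0] <- NA_real_        # degenerate under flip: no finite t
    m / sqrt(v / nSub)
  }

  tObs <- tFromSigns(rep(1, nSub))
  degenerate <- !is.finite(tObs)
  if (any(degenerate & colMeans(D) != 0)) {
    k <- which(degenerate & colMeans(D) != 0)[1L]
    stop(sprintf("zero variance of paired differences for pair %s-%s",
                 channels[pairs[k, 1L]], channels[pairs[k, 2L]]))
  }
  tObs[degenerate] <- 0
  obs <- .edgeClusters(pairs, tObs, abs(tObs) > tcrit, nb)

  exhaustive <- nPerm >= 2^nSub
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), nSub)))
    message(sprintf(
      "requested %d permutations >= 2^%d; using exhaustive enumeration (%d sign flips)",
      nPerm, nSub, nrow(signs)))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), nPerm * nSub, replace = TRUE), nPerm, nSub)
  }
  nullMax <- apply(signs, 1L, function(s) {
    tp <- tFromSigns(s)
    supra <- !is.na(tp) & abs(tp) > tcrit
    cl <- .edgeClusters(pairs, tp, supra, nb)
    if (length(cl$stats)) max(abs(cl$stats)) else 0
  })

  permP <- if (length(obs$stats) == 0L) numeric(0)
    else if (exhaustive)
      vapply(obs$stats, function(cs) mean(nullMax >= abs(cs)), numeric(1))
    else
      vapply(obs$stats, function(cs)
        (1 + sum(nullMax >= abs(cs))) / (1 + nPerm), numeric(1))

  keep <- which(permP < alpha)
  clusters <- lapply(keep, function(k)
    new("EdgeCluster", edges = pairs[obs$members[[k]], , drop = FALSE],
        t = tObs[obs$members[[k]]], clusterStat = obs$stats[[k]],
        permP = permP[[k]]))

  edgeIdx <- unlist(obs$members[keep], use.names = FALSE)
  clusterId <- rep(seq_along(keep), lengths(obs$members[keep]))
  tRet <- tObs[edgeIdx]
  normT <- if (length(tRet)) tRet / max(abs(tRet)) else numeric(0)
  nodeSum <- structure(numeric(n), names = channels)
  for (k in seq_along(edgeIdx)) {
    e <- pairs[edgeIdx[k], ]
    nodeSum[e[1L]] <- nodeSum[e[1L]] + normT[k]
    nodeSum[e[2L]] <- nodeSum[e[2L]] + normT[k]
  }
  new("SFCResult", channels = channels, clusters = clusters,
      edges = pairs[edgeIdx, , drop = FALSE], t = tRet,
      normalizedT = normT, clusterId = as.integer(clusterId),
      permP = if (length(edgeIdx)) permP[clusterId] else numeric(0),
      nodeSum = nodeSum,
      nPermutations = if (exhaustive) nrow(signs) else as.integer(nPerm),
      exhaustive = exhaustive, alpha = alpha, seed = as.integer(seed))
}

#' Hemispheric-lateralization degree
#'
#' `100 * nContra / nTotal`, the percentage of SFC-topography channels
#' lying contralateral to the stimulated forearm. The return value is the
#' exact float; displays round half away from zero (9/13 -> 69%,
#' 4/28 -> 14%).
#'
#' @param nContra contralateral channel count.
#' @param nTotal total channels on the SFC topography.
#' @return HL degree in percent (float).
#' @export
hlDegree <- function(nContra, nTotal) {
  if (nTotal <= 0) stop("HL degree undefined for an empty topography")
  100 * nContra / nTotal
}

# round half away from zero (display convention for HL percentages)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Topography summary of an SFC result
#'
#' Counts the channels carrying retained edges (`nodeSum != 0`), splits
#' them by hemisphere relative to the stimulated forearm, and reports the
#' hemispheric-lateralization degree plus the mean node intensity
#' (sum of normalized t) per hemisphere. Midline channels count toward
#' the total but toward neither hemisphere.
#'
#' @param sfc an [SFCResult-class] with at least one retained cluster.
#' @param montage a [Montage-class].
#' @param stimulatedSide `"left"` or `"right"` forearm.
#' @return list with `hlDegree` (percent, float), `hlDegreeDisplay`
#'   (rounded half away from zero), `nContra`, `nTotal`,
#'   `meanIntensityContra`, `meanIntensityIpsi`.
#' @export
topographySummary <- function(sfc, montage, stimulatedSide = c("left", "right")) {
  stimulatedSide <- match.arg(stimulatedSide)
  if (!length(sfc@clusters) || all(sfc@nodeSum == 0))
    stop("empty SFC: no retained clusters to summarize")
  hemi <- hemisphereOf(montage)[sfc@channels]
  on <- sfc@nodeSum != 0
  contraHemi <- if (stimulatedSide == "left") "right" else "left"
  ipsiHemi <- if (stimulatedSide == "left") "left" else "right"
  nTotal <- sum(on)
  nContra <- sum(on & hemi == contraHemi)
  mInt <- function(h) {
    v <- sfc@nodeSum[on & hemi == h]
    if (length(v)) mean(v) else NA_real_
  }
  hl <- hlDegree(nContra, nTotal)
  list(hlDegree = hl, hlDegreeDisplay = .roundHalfAway(hl),
       nContra = nContra, nTotal = nTotal,
       meanIntensityContra = mInt(contraHemi),
       meanIntensityIpsi = mInt(ipsiHemi))
}
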