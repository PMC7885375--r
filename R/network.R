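# Binary functional brain networks and multiscale graph indices:
# global/local efficiency, smallworldness against G(n, m) references,
# inter-/intra-hemispheric density and per-node degree.

#' Construct a BinaryNetwork
#'
#' @param adjacency symmetric 0/1 matrix (dimnames become channel labels).
#' @param hemisphere per-channel hemisphere labels (`NULL` derives them
#'   from a montage).
#' @param montage optional [Montage-class] supplying hemisphere labels.
#' @return a [BinaryNetwork-class].
#' @export
binaryNetwork <- function(adjacency, hemisphere = NULL, montage = NULL) {
  A <- as.matrix(adjacency)
  storage.mode(A) <- "numeric"
  if (is.null(rownames(A)))
    dimnames(A) <- list(sprintf("ch%02d", seq_len(nrow(A))),
                        sprintf("ch%02d", seq_len(nrow(A))))
  if (is.null(hemisphere)) {
    hemisphere <- if (!is.null(montage))
      unname(hemisphereOf(montage)[rownames(A)])
    else rep("midline", nrow(A))
  }
  new("BinaryNetwork", adjacency = A, hemisphere = hemisphere)
}

#' Per-subject binary functional brain network
#'
#' Pairs the k-th stimulation trial with the k-th baseline trial, runs a
#' paired t-test per channel pair across trials, applies
#' Benjamini-Hochberg FDR over all pairs, and encodes the surviving pairs
#' as 1 in the adjacency matrix (step-up decision: adjusted p <= alpha).
#'
#' @param stimFC,baseFC channel x channel x trial arrays of band
#'   connectivity for the stimulation and baseline trials of one subject;
#'   equal trial counts (trial k is paired with trial k).
#' @param alpha FDR level.
#' @param montage optional [Montage-class] for hemisphere labels.
#' @return a [BinaryNetwork-class].
#' @export
binarizeNetwork <- function(stimFC, baseFC, alpha = 0.05, montage = NULL) {
  S <- .pairMatrix(stimFC); B <- .pairMatrix(baseFC)
  if (nrow(S) != nrow(B))
    stop("unequal trial counts: ", nrow(S), " stimulation vs ", nrow(B),
         " baseline (paired per-trial test requires equal counts)")
  if (is.list(stimFC)) stimFC <- simplify2array(stimFC)
  ch <- dimnames(stimFC)[[1L]]
  n <- if (!is.null(ch)) length(ch) else
    as.integer((1 + sqrt(1 + 8 * ncol(S))) / 2)
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_len(n))
  D <- S - B
  ts <- .pairedT(D)
  p <- 2 * stats::pt(-abs(ts$t), ts$df)
  p[!is.finite(ts$t)] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  A <- matrix(0, n, n, dimnames = list(ch, ch))
  pr <- channelPairs(n)
  sig <- padj <= alpha
  A[pr[sig, , drop = FALSE]] <- 1
  A <- A + t(A)
  binaryNetwork(A, montage = montage)
}

.adjOf <- function(net) if (is(net, "BinaryNetwork")) net@adjacency else as.matrix(net)

# BFS shortest-path lengths via igraph (unweighted); Inf for disconnected.
.shortestPaths <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  igraph::distances(g)
}

#' Global efficiency of a binary network
#'
#' The mean inverse shortest-path length over all ordered node pairs,
#' `E = (1/(N(N-1))) * sum_{i != j} 1/d_ij`, with disconnected pairs
#' contributing 0. Equals 1 for a complete graph and 0 for an empty one.
#'
#' @param net a [BinaryNetwork-class] or adjacency matrix with N >= 2.
#' @return efficiency in [0, 1].
#' @export
globalEfficiency <- function(net) {
  A <- .adjOf(net)
  N <- nrow(A)
  if (N < 2L) stop("global efficiency needs at least 2 nodes")
  d <- .shortestPaths(A)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (N * (N - 1))
}

#' Local efficiency of a binary network
#'
#' The average, over nodes, of the global efficiency of the subgraph
#' induced on each node's neighbours (the node itself excluded); nodes
#' with fewer than 2 neighbours contribute 0. A measure of segregation:
#' 1 for a complete graph, 0 for a star.
#'
#' @param net a [BinaryNetwork-class] or adjacency matrix.
#' @return efficiency in [0, 1].
#' @export
localEfficiency <- function(net) {
  A <- .adjOf(net)
  N <- nrow(A)
  if (N < 1L) stop("empty network")
  contrib <- vapply(seq_len(N), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2L) return(0)
    globalEfficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(contrib)
}

#' Smallworldness against random-graph references
#'
#' `SW = (Eloc / ElocR) / (Eglo / EgloR)` where the reference efficiencies
#' are means over `nRefs` uniform random graphs G(n, m) with the same node
#' and link counts. SW > 1 indicates simultaneous segregation and
#' integration. When the random references have zero local efficiency
#' (too sparse for any connected neighbourhood) SW is NaN with a warning.
#'
#' @param net a [BinaryNetwork-class] or adjacency matrix with >= 1 link.
#' @param nRefs number of reference graphs.
#' @param seed RNG seed (results deterministic given the seed).
#' @return list with `sw`, `eGloR`, `eLocR`.
#' @export
smallworldness <- function(net, nRefs = 100L, seed = 1L) {
  A <- .adjOf(net)
  N <- nrow(A)
  m <- sum(A != 0) / 2
  if (m < 1) stop("smallworldness needs at least one link")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eg <- numeric(nRefs); el <- numeric(nRefs)
  for (r in seq_len(nRefs)) {
    gr <- igraph::sample_gnm(N, m)
    Ar <- as.matrix(igraph::as_adjacency_matrix(gr))
    eg[r] <- globalEfficiency(Ar)
    el[r] <- localEfficiency(Ar)
  }
  eGloR <- mean(eg); eLocR <- mean(el)
  sw <- if (eLocR == 0 || eGloR == 0) {
    warning("random references have zero efficiency; SW undefined (NaN)")
    NaN
  } else (localEfficiency(A) / eLocR) / (globalEfficiency(A) / eGloR)
  list(sw = sw, eGloR = eGloR, eLocR = eLocR)
}

.hemisphereIdx <- function(net) {
  h <- net@hemisphere
  L <- which(h == "left"); R <- which(h == "right")
  if (length(L) != length(R))
    stop("unequal hemisphere sizes (", length(L), " left vs ", length(R),
         " right); the 1/Ns^2 interdensity normalization is undefined")
  list(L = L, R = R, Ns = length(L))
}

#' Inter- and intra-hemispheric link density
#'
#' `Kinter` is the number of links between the two hemispheres over the
#' Ns^2 possible ones; `Kintra(S)` the number of links within hemisphere
#' S over the Ns(Ns-1)/2 possible unordered pairs. Both lie in [0, 1];
#' midline channels are excluded. Requires equal hemisphere sizes.
#'
#' @param net a [BinaryNetwork-class] with hemisphere labels.
#' @return list with `kInter`, `kIntraLeft`, `kIntraRight`.
#' @export
interIntraDensity <- function(net) {
  A <- net@adjacency
  hi <- .hemisphereIdx(net)
  Ns <- hi$Ns
  kInter <- sum(A[hi$L, hi$R]) / Ns^2
  intra <- function(S) sum(A[S, S]) / 2 / (Ns * (Ns - 1) / 2)
  list(kInter = kInter, kIntraLeft = intra(hi$L), kIntraRight = intra(hi$R))
}

#' Inter- and intra-hemispheric node degree
#'
#' Per node, the number of its links crossing to the opposite hemisphere
#' (`dInter`, range 0..N) and the number staying within its own
#' hemisphere (`dIntra`, range 0..N-1). Midline nodes are reported with
#' both degrees 0 by convention. Summing `dInter` over all nodes gives
#' twice the inter-hemispheric link count; summing `dIntra` within a
#' hemisphere gives twice its intra-hemispheric link count.
#'
#' @param net a [BinaryNetwork-class] with hemisphere labels.
#' @return list with named numeric vectors `dInter`, `dIntra`.
#' @export
interIntraDegree <- function(net) {
  A <- net@adjacency
  hi <- .hemisphereIdx(net)
  n <- nrow(A)
  ch <- rownames(A)
  dInter <- structure(numeric(n), names = ch)
  dIntra <- structure(numeric(n), names = ch)
  dInter[hi$L] <- rowSums(A[hi$L, hi$R, drop = FALSE])
  dInter[hi$R] <- rowSums(A[hi$R, hi$L, drop = FALSE])
  dIntra[hi$L] <- rowSums(A[hi$L, hi$L, drop = FALSE])
  dIntra[hi$R] <- rowSums(A[hi$R, hi$R, drop = FALSE])
  list(dInter = dInter, dIntra = dIntra)
}

#' All multiscale indices of a binary network
#'
#' Convenience wrapper computing the large-scale (global efficiency,
#' local efficiency, smallworldness), intermediate-scale (inter/intra
#' density) and small-scale (inter/intra degree) indices in one pass.
#'
#' @param net a [BinaryNetwork-class] with hemisphere labels.
#' @param nRefs,seed smallworldness reference parameters.
#' @return a [NetworkIndices-class].
#' @export
networkIndices <- function(net, nRefs = 100L, seed = 1L) {
  eGlo <- globalEfficiency(net)
  eLoc <- localEfficiency(net)
  swr <- if (sum(net@adjacency) > 0)
    smallworldness(net, nRefs, seed)
  else list(sw = NaN, eGloR = NaN, eLocR = NaN)
  dens <- interIntraDensity(net)
  deg <- interIntraDegree(net)
  new("NetworkIndices", eGlo = eGlo, eLoc = eLoc, sw = swr$sw,
      eGloR = swr$eGloR, eLocR = swr$eLocR,
      kInter = dens$kInter, kIntraLeft = dens$kIntraLeft,
      kIntraRight = dens$kIntraRight,
      dInter = deg$dInter, dIntra = deg$dIntra,
      nRandomRefs = as.integer(nRefs), seed = as.integer(seed))
}

#' Read / write a binary network as a delimited 0/1 matrix
#'
#' Tab-separated adjacency with a header row of channel labels.
#'
#' @param net a [BinaryNetwork-class].
#' @param path file path.
#' @return `writeNetwork` invisibly returns `path`; `readNetwork` a
#'   [BinaryNetwork-class] (hemisphere labels from `montage` if given).
#' @export
writeNetwork <- function(net, path) {
  utils::write.table(net@adjacency, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeNetwork
#' @param montage optional [Montage-class].
#' @export
readNetwork <- function(path, montage = NULL) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(x) <- colnames(x)
  binaryNetwork(x, montage = montage)
}
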