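test_that("efficiency fixtures match hand-derived values", {
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  expect_equal(globalEfficiency(path4), 13 / 18)   # distances 1,2,3,1,2,1
  expect_equal(bruteGlobalEff(path4), 13 / 18)     # oracle agrees
  triPend <- matrix(0, 4, 4)
  triPend[1, 2] <- triPend[2, 3] <- triPend[1, 3] <- triPend[1, 4] <- 1
  triPend <- triPend + t(triPend)
  expect_equal(localEfficiency(triPend), 7 / 12)   # per node: 1/3, 1, 1, 0
  expect_equal(bruteLocalEff(triPend), 7 / 12)
  n <- 6
  complete <- matrix(1, n, n) - diag(n)
  expect_equal(globalEfficiency(complete), 1)
  expect_equal(localEfficiency(complete), 1)
  expect_equal(globalEfficiency(matrix(0, 5, 5)), 0)   # empty graph
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(localEfficiency(star), 0)
})

test_that("all indices equal the brute-force oracle on random small graphs", {
  set.seed(61)
  for (r in 1:60) {
    n <- sample(4:8, 1)
    n <- n - n %% 2                       # even for hemisphere balance
    A <- randomAdjacency(n, runif(1, 0.2, 0.8))
    dimnames(A) <- list(sprintf("c%d", 1:n), sprintf("c%d", 1:n))
    expect_equal(globalEfficiency(A), bruteGlobalEff(A))
    expect_equal(localEfficiency(A), bruteLocalEff(A))
    L <- seq_len(n / 2); R <- seq(n / 2 + 1, n)
    net <- binaryNetwork(A, hemisphere = rep(c("left", "right"), each = n / 2))
    o <- bruteInterIntra(A, L, R)
    dens <- interIntraDensity(net)
    deg <- interIntraDegree(net)
    expect_equal(dens$kInter, o$kInter)
    expect_equal(dens$kIntraLeft, o$kIntraL)
    expect_equal(dens$kIntraRight, o$kIntraR)
    expect_equal(unname(deg$dInter), o$dInter)
    expect_equal(unname(deg$dIntra), o$dIntra)
    # consistency identities between densities and degree sums
    Ns <- n / 2
    expect_equal(dens$kInter, sum(deg$dInter) / (2 * Ns^2))
    expect_equal(dens$kIntraLeft, sum(deg$dIntra[L]) / (Ns * (Ns - 1)))
  }
})

test_that("our efficiency agrees with igraph's as an independent cross-check", {
  set.seed(71)
  for (r in 1:10) {
    A <- randomAdjacency(10, 0.3)
    g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
    expect_equal(globalEfficiency(A), igraph::global_efficiency(g),
                 tolerance = 1e-12)
  }
})

test_that("adding a link never decreases efficiency or incident degrees", {
  set.seed(81)
  for (r in 1:20) {
    A <- randomAdjacency(8, 0.3)
    zero <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    B <- A; B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
    expect_gte(globalEfficiency(B), globalEfficiency(A))
    hem <- rep(c("left", "right"), each = 4)
    dA <- interIntraDegree(binaryNetwork(A, hemisphere = hem))
    dB <- interIntraDegree(binaryNetwork(B, hemisphere = hem))
    expect_true(all(dB$dInter >= dA$dInter))
    expect_true(all(dB$dIntra >= dA$dIntra))
  }
})

test_that("index ranges hold on many random graphs", {
  set.seed(91)
  for (r in 1:100) {
    n <- 8
    A <- randomAdjacency(n, runif(1, 0.1, 0.9))
    net <- binaryNetwork(A, hemisphere = rep(c("left", "right"), each = 4))
    eg <- globalEfficiency(net); el <- localEfficiency(net)
    dens <- interIntraDensity(net); deg <- interIntraDegree(net)
    expect_true(eg >= 0 && eg <= 1)
    expect_true(el >= 0 && el <= 1)
    expect_true(all(unlist(dens) >= 0 & unlist(dens) <= 1))
    expect_true(all(deg$dInter >= 0 & deg$dInter <= n))
    expect_true(all(deg$dIntra >= 0 & deg$dIntra <= n - 1))
  }
})

test_that("hemisphere-partition fixtures behave as defined", {
  hem6 <- rep(c("left", "right"), each = 3)
  bip <- matrix(0, 6, 6)
  bip[1:3, 4:6] <- 1; bip <- bip + t(bip) - diag(diag(bip + t(bip)))
  diag(bip) <- 0
  net <- binaryNetwork(bip, hemisphere = hem6)
  dens <- interIntraDensity(net)
  expect_equal(dens$kInter, 1)                      # complete bipartite
  expect_equal(dens$kIntraLeft, 0)
  expect_equal(dens$kIntraRight, 0)
  two <- matrix(0, 6, 6); two[1, 4] <- two[2, 5] <- 1; two <- two + t(two)
  expect_equal(interIntraDensity(binaryNetwork(two, hemisphere = hem6))$kInter,
               2 / 9)
  leftComplete <- matrix(0, 6, 6)
  leftComplete[1:3, 1:3] <- 1; diag(leftComplete) <- 0
  d3 <- interIntraDensity(binaryNetwork(leftComplete, hemisphere = hem6))
  expect_equal(d3$kIntraLeft, 1)
  expect_equal(d3$kIntraRight, 0)
  expect_equal(d3$kInter, 0)
  # single inter link, triangle degrees, midline convention
  one <- matrix(0, 6, 6); one[1, 4] <- 1; one <- one + t(one)
  dg <- interIntraDegree(binaryNetwork(one, hemisphere = hem6))
  expect_equal(unname(dg$dInter[c(1, 4)]), c(1, 1))
  expect_true(all(dg$dIntra == 0))
  hemMid <- c("left", "left", "midline", "right", "right", "midline")
  tri <- matrix(0, 6, 6); tri[1, 2] <- tri[1, 3] <- tri[2, 3] <- 1
  tri <- tri + t(tri)
  dgm <- interIntraDegree(binaryNetwork(tri, hemisphere = hemMid))
  expect_equal(unname(dgm$dIntra[1:2]), c(1, 1))    # link to midline not counted
  expect_equal(unname(dgm$dInter[3]), 0)            # midline: 0 by convention
  expect_equal(unname(dgm$dIntra[3]), 0)
  uneven <- binaryNetwork(matrix(0, 4, 4),
                          hemisphere = c("left", "left", "left", "right"))
  expect_error(interIntraDensity(uneven), "unequal hemisphere")
})

test_that("smallworldness is deterministic, ~1 for random graphs, >1 for lattices", {
  set.seed(101)
  A <- randomAdjacency(20, 0.3)
  s1 <- smallworldness(A, nRefs = 30, seed = 7)
  s2 <- smallworldness(A, nRefs = 30, seed = 7)
  expect_identical(s1, s2)
  # an Erdos-Renyi-like graph brackets SW = 1
  draws <- replicate(20, {
    B <- randomAdjacency(24, 0.3)
    smallworldness(B, nRefs = 15, seed = 11)$sw
  })
  expect_lt(min(draws), 1)
  expect_gt(max(draws), 1)
  expect_lt(abs(mean(draws) - 1), 0.2)
  # classic small-world construction: ring lattice, few rewired links
  g <- igraph::sample_smallworld(1, 62, 3, 0.05, loops = FALSE)
  L <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g)))
  expect_gt(smallworldness(L, nRefs = 20, seed = 13)$sw, 1)
  # too sparse for any neighbourhood: SW undefined with a warning
  single <- matrix(0, 6, 6); single[1, 2] <- single[2, 1] <- 1
  expect_warning(sw0 <- smallworldness(single, nRefs = 10, seed = 1), "undefined")
  expect_true(is.nan(sw0$sw))
  expect_error(smallworldness(matrix(0, 4, 4)), "at least one link")
})

test_that("binarization applies the paired t + BH step-up rule", {
  m <- gridMontage()
  set.seed(111)
  base <- randomFCStack(m, 9)
  # identical conditions: empty network
  net0 <- binarizeNetwork(base, base, montage = m)
  expect_equal(sum(adjacency(net0)), 0)
  # planted strong single edge over 9 trial pairs is recovered
  stim <- base
  stim[2, 3, ] <- stim[3, 2, ] <- base[2, 3, ] + 0.3 + rnorm(9, 0, 0.01)
  net1 <- binarizeNetwork(stim, base, montage = m)
  expect_equal(adjacency(net1)[2, 3], 1)
  expect_lte(sum(adjacency(net1)) / 2, 3)   # essentially only the planted edge
  expect_error(binarizeNetwork(base[, , 1:8], base, montage = m),
               "unequal trial counts")
})

test_that("network adjacency round-trips through the delimited format", {
  m <- gridMontage()
  set.seed(121)
  A <- randomAdjacency(16, 0.2)
  dimnames(A) <- list(channelNames(m), channelNames(m))
  net <- binaryNetwork(A, montage = m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, f)
  net2 <- readNetwork(f, montage = m)
  expect_equal(adjacency(net2), adjacency(net))
  expect_identical(net2@hemisphere, net@hemisphere)
})

test_that("networkIndices bundles all scales consistently", {
  m <- gridMontage()
  set.seed(131)
  A <- randomAdjacency(16, 0.3)
  dimnames(A) <- list(channelNames(m), channelNames(m))
  net <- binaryNetwork(A, montage = m)
  idx <- networkIndices(net, nRefs = 10, seed = 3)
  expect_equal(idx@eGlo, globalEfficiency(net))
  expect_equal(idx@eLoc, localEfficiency(net))
  expect_equal(idx@kInter, interIntraDensity(net)$kInter)
  expect_equal(idx@dInter, interIntraDegree(net)$dInter)
})
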