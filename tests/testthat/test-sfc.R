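# helper: FC stack with a planted mean difference on listed pairs
shiftPairs <- function(fc, montage, pairs, delta) {
  ch <- channelNames(montage)
  for (p in pairs) {
    i <- match(p[1], ch); j <- match(p[2], ch)
    fc[i, j, ] <- fc[i, j, ] + delta
    fc[j, i, ] <- fc[j, i, ] + delta
  }
  fc
}

test_that("edge statistics match the textbook paired-t formula", {
  m <- gridMontage()
  set.seed(21)
  a <- randomFCStack(m, 8)
  b <- randomFCStack(m, 8)
  es <- edgeStats(a, b)
  expect_equal(nrow(es@pairs), 16 * 15 / 2)
  expect_equal(es@df, 7)
  # explicit mean/sd oracle on one pair, plus stats::t.test agreement
  i <- 3; j <- 7
  d <- a[i, j, ] - b[i, j, ]
  tOracle <- mean(d) / (sd(d) / sqrt(8))
  k <- which(es@pairs[, 1] == i & es@pairs[, 2] == j)
  expect_equal(es@t[k], tOracle, tolerance = 1e-10)
  expect_equal(es@p[k], t.test(d)$p.value, tolerance = 1e-10)
  # identical conditions: t = 0, p = 1 everywhere
  es0 <- edgeStats(a, a)
  expect_true(all(es0@t == 0))
  expect_true(all(es0@p == 1))
  # consistent positive differences give large positive t
  aUp <- a; aUp[2, 5, ] <- aUp[5, 2, ] <- b[2, 5, ] + 0.1 + rnorm(8, 0, 1e-4)
  esUp <- edgeStats(aUp, b)
  kk <- which(esUp@pairs[, 1] == 2 & esUp@pairs[, 2] == 5)
  expect_gt(esUp@t[kk], 50)
  expect_error(edgeStats(a[, , 1, drop = FALSE], b[, , 1, drop = FALSE]),
               "at least 2")
})

test_that("cluster building groups by endpoint adjacency, sign, and drops isolates", {
  m <- gridMontage()
  ch <- channelNames(m)
  n <- 16
  mkStats <- function(sig, tval) {
    tv <- rep(0.1, n * (n - 1) / 2)
    p <- rep(0.9, n * (n - 1) / 2)
    pr <- channelPairs(n)
    for (k in seq_along(sig)) {
      i <- match(sig[[k]][1], ch); j <- match(sig[[k]][2], ch)
      r <- which(pr[, 1] == min(i, j) & pr[, 2] == max(i, j))
      tv[r] <- tval[k]; p[r] <- 0.001
    }
    new("EdgeStatMap", channels = ch, pairs = pr, t = tv, p = p, df = 7)
  }
  # shared endpoint: (g01-g02) and (g02-g03) -> one cluster of 2
  cl <- buildEdgeClusters(mkStats(list(c("g01", "g02"), c("g02", "g03")),
                                  c(3, 3)), m)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]@edges), 2L)
  expect_equal(cl[[1]]@clusterStat, 6)
  # two remote edges: both isolated -> both discarded
  cl2 <- buildEdgeClusters(mkStats(list(c("g01", "g02"), c("g15", "g16")),
                                   c(3, 3)), m)
  expect_length(cl2, 0L)
  # opposite signs on touching edges -> sign-homogeneous split -> isolates
  cl3 <- buildEdgeClusters(mkStats(list(c("g01", "g02"), c("g02", "g03")),
                                   c(3, -3)), m)
  expect_length(cl3, 0L)
  # neighbouring endpoints (not shared): g01-g05 and g02-g06 with g01~g02
  cl4 <- buildEdgeClusters(mkStats(list(c("g01", "g05"), c("g02", "g06")),
                                   c(3, 3)), m)
  expect_length(cl4, 1L)
  # shared-endpoint-only rule separates them
  cl5 <- buildEdgeClusters(mkStats(list(c("g01", "g05"), c("g02", "g06")),
                                   c(3, 3)), m, adjacency = "shared")
  expect_length(cl5, 0L)
})

test_that("the permutation test retains a planted cluster and nothing under the null", {
  m <- gridMontage()
  set.seed(31)
  base <- randomFCStack(m, 8)
  planted <- shiftPairs(randomFCStack(m, 8), m,
                        list(c("g06", "g07"), c("g07", "g08"), c("g06", "g10")),
                        0.25)
  res <- sfcPermutationTest(planted, base, m, nPerm = 500, seed = 3)
  expect_s4_class(res, "SFCResult")
  expect_gte(length(res@clusters), 1L)
  got <- apply(res@edges, 1, function(e)
    paste(sort(channelNames(m)[e]), collapse = "-"))
  expect_true(all(c("g06-g07", "g07-g08") %in% got))
  expect_true(all(res@permP < res@alpha))
  expect_equal(max(abs(res@normalizedT)), 1)
  # node sums live only on channels incident to retained edges
  onEdges <- unique(channelNames(m)[as.vector(res@edges)])
  expect_setequal(names(res@nodeSum)[res@nodeSum != 0], onEdges)
  # identical conditions: nothing retained
  res0 <- sfcPermutationTest(base, base, m, nPerm = 500, seed = 3)
  expect_length(res0@clusters, 0L)
})

test_that("the permutation test is seed-deterministic and exhaustive when possible", {
  m <- gridMontage()
  set.seed(41)
  a <- randomFCStack(m, 5)
  b <- shiftPairs(randomFCStack(m, 5), m,
                  list(c("g01", "g02"), c("g02", "g03")), 0.3)
  r1 <- sfcPermutationTest(a, b, m, nPerm = 200, seed = 9)
  r2 <- sfcPermutationTest(a, b, m, nPerm = 200, seed = 9)
  expect_identical(r1@permP, r2@permP)
  expect_identical(r1@edges, r2@edges)
  # 2^5 = 32 < 200: exhaustive enumeration, logged
  expect_message(r3 <- sfcPermutationTest(a, b, m, nPerm = 200, seed = 9),
                 "exhaustive")
  expect_true(r3@exhaustive)
  expect_equal(r3@nPermutations, 32L)
  expect_error(sfcPermutationTest(a, b, m, nPerm = 50), "at least 100")
})

test_that("retained edges are invariant to channel reordering", {
  m <- gridMontage()
  set.seed(51)
  base <- randomFCStack(m, 8)
  stim <- shiftPairs(randomFCStack(m, 8), m,
                     list(c("g05", "g06"), c("g06", "g07")), 0.3)
  res <- sfcPermutationTest(stim, base, m, nPerm = 300, seed = 2)
  perm <- sample(16)
  ch <- channelNames(m)[perm]
  m2 <- newMontage(ch, m@positions[perm, ], flipMap = NA,
                   neighbors = m@neighbors[perm, perm])
  res2 <- sfcPermutationTest(stim[perm, perm, ], base[perm, perm, ], m2,
                             nPerm = 300, seed = 2)
  lab <- function(r, mm) sort(apply(r@edges, 1, function(e)
    paste(sort(channelNames(mm)[e]), collapse = "-")))
  expect_identical(lab(res, m), lab(res2, m2))
})

test_that("topography summary reproduces the printed HL arithmetic", {
  # montage with 28/28/6 split as shipped
  m <- defaultMontage()
  ch <- channelNames(m)
  hemi <- hemisphereOf(m)
  mkSFC <- function(nContra, nTotal, side = "left") {
    contraHemi <- if (side == "left") "right" else "left"
    onContra <- ch[hemi == contraHemi][seq_len(nContra)]
    onIpsi <- ch[hemi == ifelse(contraHemi == "right", "left", "right")
                 ][seq_len(nTotal - nContra)]
    ns <- structure(numeric(62), names = ch)
    ns[onContra] <- -1; ns[onIpsi] <- 0.5
    new("SFCResult", channels = ch,
        clusters = list(new("EdgeCluster", edges = matrix(1:2, 1),
                            t = 1, clusterStat = 1, permP = 0.01)),
        edges = matrix(1:2, 1), t = 1, normalizedT = 1, clusterId = 1L,
        permP = 0.01, nodeSum = ns, nPermutations = 256L,
        exhaustive = TRUE, alpha = 0.05, seed = 1L)
  }
  s1 <- topographySummary(mkSFC(9, 13), m, "left")
  expect_equal(s1$hlDegree, 100 * 9 / 13)
  expect_equal(s1$hlDegreeDisplay, 69)
  expect_equal(s1$meanIntensityContra, -1)
  expect_equal(s1$meanIntensityIpsi, 0.5)
  s2 <- topographySummary(mkSFC(4, 28), m, "left")
  expect_equal(s2$hlDegreeDisplay, 14)
  s3 <- topographySummary(mkSFC(13, 13), m, "left")
  expect_equal(s3$hlDegree, 100)                    # all contralateral
  expect_error(hlDegree(0, 0), "empty")
  empty <- mkSFC(1, 1)
  empty@clusters <- list()
  expect_error(topographySummary(empty, m, "left"), "empty SFC")
})
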