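test_that("the Shapiro screen is calibrated on normal and skewed samples", {
  set.seed(141)
  pNorm <- replicate(200, shapiroScreen(rnorm(8)))
  expect_gte(mean(pNorm > 0.05), 0.9)
  pSkew <- replicate(200, shapiroScreen(rexp(50)))
  expect_gte(mean(pSkew < 0.05), 0.9)
  expect_error(shapiroScreen(c(1, 2)), "n >= 3")
  expect_error(shapiroScreen(rep(1, 8)), "constant")
})

test_that("paired comparison matches the explicit formula oracle", {
  a <- c(0.64, 0.61, 0.67, 0.59, 0.66, 0.62, 0.65, 0.63)
  b <- c(0.59, 0.57, 0.62, 0.55, 0.60, 0.61, 0.58, 0.57)
  cmp <- pairedCompare(a, b)
  d <- a - b
  n <- 8
  tOracle <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(cmp$t, tOracle, tolerance = 1e-6)
  expect_equal(cmp$df, n - 1)
  expect_equal(cmp$p, 2 * pt(-abs(tOracle), n - 1), tolerance = 1e-6)
  expect_equal(cmp$effectSize, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(cmp$commonLanguageES, pnorm(mean(d) / sd(d)))
  ciOracle <- mean(a) + c(-1, 1) * qt(0.975, n - 1) * sd(a) / sqrt(n)
  expect_equal(cmp$ciA, ciOracle, tolerance = 1e-12)
  # identical inputs: defined as no effect
  same <- pairedCompare(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$effectSize, 0)
  # consistent direction with tiny jitter
  set.seed(151)
  up <- pairedCompare(b + 1 + rnorm(8, 0, 1e-3), b)
  expect_lt(up$p, 1e-6)
  expect_gt(up$t, 0)
  expect_error(pairedCompare(a, a + 1), "zero-variance")
  expect_error(pairedCompare(a[1:3], b), "equal length")
})

test_that("a non-normal screen triggers the Wilcoxon fallback with a warning", {
  set.seed(161)
  a <- c(rep(0.1, 7), 50)    # heavy outlier: Shapiro rejects
  b <- rep(0, 8) + rnorm(8, 0, 1e-4)
  expect_warning(cmp <- pairedCompare(a, b), "normality screen")
  expect_false(is.na(cmp$wilcoxP))
})

test_that("node-level FDR follows the BH step-up decision", {
  allOne <- nodeLevelFdr(structure(rep(0.1, 10), names = paste0("c", 1:10)),
                         p = rep(1, 10))
  expect_false(any(allOne$significant))
  t62 <- structure(c(rep(5, 5), rep(0.1, 57)), names = sprintf("c%02d", 1:62))
  p62 <- c(rep(0.001, 5), rep(0.9, 57))
  res <- nodeLevelFdr(t62, p62)
  expect_equal(sum(res$significant), 5L)
  expect_identical(res$channel[res$significant], sprintf("c%02d", 1:5))
  expect_true(all(res$sign[res$significant] == 1))
  single <- nodeLevelFdr(structure(2.5, names = "Cz"), p = 0.03)
  expect_true(single$significant)
  # the hand BH example: sorted p .01,.02,.03,.04,.2 at q = .05 -> 4 flags
  bh <- nodeLevelFdr(structure(rep(3, 5), names = paste0("e", 1:5)),
                     p = c(0.01, 0.02, 0.03, 0.04, 0.2))
  expect_equal(sum(bh$significant), 4L)
  # never flags a channel whose raw p exceeds the level
  set.seed(171)
  for (r in 1:20) {
    p <- runif(30)
    res <- nodeLevelFdr(structure(rnorm(30), names = paste0("x", 1:30)), p = p)
    expect_false(any(res$significant & res$p > 0.05))
  }
})

test_that("the HL report assembles rows per group and limb", {
  m <- defaultMontage()
  ch <- channelNames(m)
  hemi <- hemisphereOf(m)
  mkSFC <- function(nContra, nTotal, side) {
    contraHemi <- if (side == "left") "right" else "left"
    ns <- structure(numeric(62), names = ch)
    ns[ch[hemi == contraHemi][seq_len(nContra)]] <- -1
    if (nTotal > nContra)
      ns[ch[hemi == setdiff(c("left", "right"), contraHemi)
            ][seq_len(nTotal - nContra)]] <- 1
    new("SFCResult", channels = ch,
        clusters = list(new("EdgeCluster", edges = matrix(1:2, 1), t = 1,
                            clusterStat = 1, permP = 0.01)),
        edges = matrix(1:2, 1), t = 1, normalizedT = 1, clusterId = 1L,
        permP = 0.01, nodeSum = ns, nPermutations = 256L, exhaustive = TRUE,
        alpha = 0.05, seed = 1L)
  }
  res <- list(control = list(left = mkSFC(9, 13, "left"),
                             right = mkSFC(4, 28, "right")),
              stroke = list(left = mkSFC(13, 13, "left")))
  tab <- hlReport(res, m)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$hlDegreeDisplay[tab$group == "control" & tab$limb == "left"], 69)
  expect_equal(tab$hlDegreeDisplay[tab$group == "control" & tab$limb == "right"], 14)
  expect_equal(tab$hlDegree[tab$group == "stroke"], 100)
  # missing cell: NA row with a warning
  res$stroke$right <- NULL
  res$stroke$left@clusters <- list()
  res$stroke$left@nodeSum[] <- 0
  expect_warning(tab2 <- hlReport(res, m), "NA row")
  expect_true(is.na(tab2$hlDegree[tab2$group == "stroke"]))
})

test_that("type-I error of the index comparison is nominal under the null", {
  # per-subject efficiency values drawn from one distribution for both
  # limbs: the paired t on e_glo should reject at ~5%
  set.seed(181)
  rej <- replicate(400, {
    a <- rnorm(8, 0.6, 0.05)
    b <- rnorm(8, 0.6, 0.05)
    suppressWarnings(pairedCompare(a, b)$p < 0.05)
  })
  ciHalf <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gt(mean(rej), 0.05 - ciHalf)
  expect_lt(mean(rej), 0.05 + ciHalf)
})

test_that("compareIndices assembles the comparison table", {
  mkIdx <- function(eg) new("NetworkIndices", eGlo = eg, eLoc = eg * 0.9,
                            sw = 1.3, eGloR = 0.5, eLocR = 0.4,
                            kInter = 0.3, kIntraLeft = 0.1, kIntraRight = 0.12,
                            dInter = numeric(4), dIntra = numeric(4),
                            nRandomRefs = 10L, seed = 1L)
  set.seed(191)
  A <- lapply(rnorm(8, 0.65, 0.02), mkIdx)
  B <- lapply(rnorm(8, 0.58, 0.02), mkIdx)
  tab <- compareIndices(A, B, group = "stroke")
  expect_true(all(c("sw", "eGlo", "eLoc", "kInter") %in% tab$index))
  eg <- tab[tab$index == "eGlo", ]
  expect_lt(eg$p, 0.01)
  expect_equal(eg$meanA, mean(vapply(A, function(x) x@eGlo, numeric(1))))
  expect_true(is.na(tab[tab$index == "sw", ]$p))   # constant: no variance
})
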