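test_that("the default design yields 288 trials per group", {
  d <- cohortDesign(cohortConfig())
  expect_equal(nrow(d), 288L)                      # 2 x 9 x 2 x 8
  expect_equal(nrow(unique(d[c("subject")])), 8L)
  expect_equal(table(d$condition)[["baseline"]], 144L)
  d2 <- cohortDesign(cohortConfig(nSubjects = 1L, nTrials = 1L))
  expect_equal(nrow(d2), 4L)                       # 2 x 1 x 2 x 1
})

test_that("cohort generation is deterministic and matches its design", {
  m <- gridMontage()
  cfg <- fastConfig(nSubjects = 2L, nTrials = 2L, seed = 42L)
  spec <- couplingSpec(data.frame(from = "g01", to = "g02", loHz = 20,
                                  hiHz = 25, lagMs = 12, strength = 0.5))
  specs <- list(g1 = list(spec), g2 = list(spec))
  a <- simulateCohort(cfg, m, specs)
  b <- simulateCohort(cfg, m, specs)
  expect_identical(a, b)                            # bit-identical
  des <- cohortDesign(cfg)
  expect_equal(sum(vapply(a$g1, nTrials, integer(1))), nrow(des))
  ts <- a$g1[[1]]
  expect_identical(ts@condition, des$condition[des$subject == "s01"])
  expect_identical(ts@limb, des$limb[des$subject == "s01"])
  c2 <- simulateCohort(fastConfig(nSubjects = 2L, nTrials = 2L, seed = 43L),
                       m, specs)
  expect_false(identical(a$g1[[1]]@data, c2$g1[[1]]@data))
})

test_that("a planted lagged edge carries ImCoh far above unplanted pairs", {
  m <- defaultMontage()
  cfg <- cohortConfig(seed = 7L)
  spec <- couplingSpec(data.frame(from = "C4", to = "CP2", loHz = 20,
                                  hiHz = 25, lagMs = 12.5, strength = 0.9))
  b2 <- betaBands()$beta2
  nTr <- 40
  acc <- 0
  for (k in seq_len(nTr)) {
    tr <- simulateTrial(spec, cfg, m, seed = 1000 + k)
    acc <- acc + bandSummary(imaginaryCoherence(
      crossSpectrum(tr, cfg@rate, freqRange = c(19, 26))), b2) / nTr
  }
  pr <- channelPairs(m)
  vals <- acc[pr]
  planted <- acc["C4", "CP2"]
  others <- vals[!(pr[, 1] == match("C4", channelNames(m)) &
                   pr[, 2] == match("CP2", channelNames(m))) &
                 !(pr[, 2] == match("C4", channelNames(m)) &
                   pr[, 1] == match("CP2", channelNames(m)))]
  expect_gt(planted, quantile(others, 0.99))
})

test_that("zero-lag mixing alone leaves band ImCoh at the unplanted level", {
  m <- gridMontage()
  cfg <- fastConfig(seed = 5L)
  spec <- couplingSpec(
    condition = "stimulation",
    zeroLagMixing = list(list(channels = c("g01", "g02"),
                              weights = c(1, 0.8))))
  b2 <- betaBands()$beta2
  nTr <- 30
  acc <- 0
  for (k in seq_len(nTr)) {
    tr <- simulateTrial(spec, cfg, m, seed = 500 + k)
    acc <- acc + bandSummary(imaginaryCoherence(
      crossSpectrum(tr, cfg@rate, freqRange = c(19, 26))), b2) / nTr
  }
  mixed <- acc["g01", "g02"]
  pr <- channelPairs(m)
  others <- acc[pr][-1]   # pair (1,2) is the mixed one
  expect_lt(mixed, quantile(others, 0.99))
  expect_lt(abs(mixed - mean(others)), 3 * sd(others))
})

test_that("strength 0 gives pure-noise connectivity everywhere", {
  m <- gridMontage()
  cfg <- fastConfig(seed = 6L)
  spec <- couplingSpec(data.frame(from = "g01", to = "g02", loHz = 20,
                                  hiHz = 25, lagMs = 12, strength = 0))
  tr <- simulateTrial(spec, cfg, m, seed = 11)
  noise <- simulateTrial(couplingSpec(condition = "baseline"), cfg, m,
                         condition = "stimulation", seed = 11)
  expect_equal(dim(tr), dim(noise))
  b2 <- betaBands()$beta2
  fc <- bandSummary(imaginaryCoherence(
    crossSpectrum(tr, cfg@rate, freqRange = c(19, 26))), b2)
  # planted pair indistinguishable from the rest at strength 0
  pr <- channelPairs(m)
  expect_lt(fc["g01", "g02"], quantile(fc[pr], 0.99))
})

test_that("simulator rejects impossible specs", {
  m <- gridMontage()
  cfg <- fastConfig()
  badLag <- couplingSpec(data.frame(from = "g01", to = "g02", loHz = 20,
                                    hiHz = 25, lagMs = 5000, strength = 0.5))
  expect_error(simulateTrial(badLag, cfg, m), "lag")
  badCh <- couplingSpec(data.frame(from = "nope", to = "g02", loHz = 20,
                                   hiHz = 25, lagMs = 12, strength = 0.5))
  expect_error(simulateTrial(badCh, cfg, m), "nope")
  expect_error(couplingSpec(data.frame(from = "a", to = "b", loHz = 20,
                                       hiHz = 25, lagMs = 12, strength = 2)),
               "strength")
})

test_that("right-limb trials mirror the planted pattern through the flip map", {
  m <- defaultMontage()
  cfg <- cohortConfig(seed = 9L, noiseSD = 0.1)
  spec <- couplingSpec(data.frame(from = "C4", to = "CP4", loHz = 20,
                                  hiHz = 25, lagMs = 12.5, strength = 0.9))
  b2 <- betaBands()$beta2
  accL <- 0; accR <- 0
  for (k in 1:8) {
    fcL <- bandSummary(imaginaryCoherence(crossSpectrum(
      simulateTrial(spec, cfg, m, limb = "left", seed = 70 + k),
      cfg@rate, freqRange = c(19, 26))), b2)
    fcR <- bandSummary(imaginaryCoherence(crossSpectrum(
      simulateTrial(spec, cfg, m, limb = "right", seed = 170 + k),
      cfg@rate, freqRange = c(19, 26))), b2)
    accL <- accL + fcL / 8; accR <- accR + fcR / 8
  }
  expect_gt(accL["C4", "CP4"], 0.8)
  expect_gt(accR["C3", "CP3"], 0.8)     # mirrored homologues
  expect_lt(accR["C4", "CP4"], accR["C3", "CP3"])
})
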