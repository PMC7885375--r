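# Self-contained validation experiments: parameter recovery and
# calibration runs on synthetic cohorts. These are the package's own
# checks that the pipeline recovers what the generator plants.

#' Balanced sensorimotor montage subset
#'
#' The 28 FC/C/CP/P-row and temporal channels (14 per hemisphere) of the
#' shipped layout, used for reduced-scale recovery experiments: at 378
#' channel pairs, chance suprathreshold edges are sparse enough not to
#' percolate into planted clusters, which they do at the full 1891-pair
#' scale when pair noise is independent across pairs.
#'
#' @param montage the full montage to subset (default: shipped layout).
#' @return a [Montage-class] with 28 channels.
#' @export
sensorimotorMontage <- function(montage = defaultMontage()) {
  subsetMontage(montage,
                c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
                  "C5", "C3", "C1", "C2", "C4", "C6",
                  "CP5", "CP3", "CP1", "CP2", "CP4", "CP6",
                  "P5", "P3", "P1", "P2", "P4", "P6",
                  "T7", "T8", "TP7", "TP8"))
}

#' Hemispheric-lateralization recovery experiment
#'
#' Simulates one group of subjects stimulated on the left forearm with a
#' chain of beta-2 couplings of which `fraction` run through the
#' contralateral hemisphere, runs the full connectivity + cluster
#' permutation analysis, and reports the recovered HL degree. The
#' analysis uses shared-endpoint edge adjacency and a 0.005
#' cluster-forming threshold so the recovered topography reflects the
#' planted pattern rather than chance-edge percolation.
#'
#' @param fraction contralateral fraction of planted stimulation edges.
#' @param seed integer seed driving both simulation and permutations.
#' @param montage analysis montage (default [sensorimotorMontage()]).
#' @param nSubjects,nTrials design size (defaults 8 subjects, 9 trials
#'   per condition: a 144-trial run).
#' @param nEdges,strength planted chain size and in-band coherence.
#' @return list with `hlDegree`, `nContra`, `nTotal`, `sfc`.
#' @export
hlRecoveryExperiment <- function(fraction, seed, montage = sensorimotorMontage(),
                                 nSubjects = 8L, nTrials = 9L,
                                 nEdges = 14L, strength = 0.6) {
  cfg <- cohortConfig(nSubjects = nSubjects, nTrials = nTrials,
                      nChannels = length(montage@channels),
                      lateralization = fraction, seed = seed)
  cfg@limbs <- "left"
  validObject(cfg)
  pool <- montage@channels[hemisphereOf(montage) == "right"]
  stim <- lateralizedSpec(montage, fraction = fraction, nEdges = nEdges,
                          strength = strength, pool = pool)
  specs <- list(grp = list(stim, couplingSpec(condition = "baseline")))
  cohort <- simulateCohort(cfg, montage, specs)$grp
  b2 <- betaBands()$beta2
  stimM <- list(); baseM <- list()
  for (s in names(cohort)) {
    cx <- conditionConnectivity(cohort[[s]], b2, limb = "left")
    stimM[[s]] <- cx$stimulation
    baseM[[s]] <- cx$baseline
  }
  sfc <- suppressMessages(
    sfcPermutationTest(stimM, baseM, montage, nPerm = 1000L,
                       edgeAlpha = 0.005, seed = seed,
                       adjacency = "shared"))
  ts <- topographySummary(sfc, montage, "left")
  list(hlDegree = ts$hlDegree, nContra = ts$nContra, nTotal = ts$nTotal,
       sfc = sfc)
}

#' Family-wise error calibration of the cluster permutation test
#'
#' Draws both conditions from one null distribution of band-connectivity
#' matrices (16-channel grid, 8 subjects) and measures how often the
#' permutation test retains any cluster at `alpha`.
#'
#' @param nSims number of simulated null datasets.
#' @param seed integer seed.
#' @param nSubjects subjects per dataset.
#' @param nPerm permutations per test.
#' @param alpha cluster significance level.
#' @return list with `rate`, `nSims`, and the binomial 95% half-width
#'   `ciHalf` around `alpha`.
#' @export
fwerExperiment <- function(nSims = 500L, seed = 1L, nSubjects = 8L,
                           nPerm = 200L, alpha = 0.05) {
  xs <- (1:4 - 2.5); ys <- (1:4 - 2.5)
  g <- expand.grid(x = xs, y = ys)
  m <- newMontage(sprintf("g%02d", 1:16), as.matrix(g), flipMap = NA)
  m@neighbors <- neighborsFromPositions(m, "distance", 1.01)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nullStack <- function() {
    out <- array(0, c(16, 16, nSubjects),
                 dimnames = list(m@channels, m@channels, NULL))
    for (s in seq_len(nSubjects)) {
      M <- matrix(0, 16, 16)
      M[upper.tri(M)] <- stats::rnorm(120, 0.3, 0.05)
      out[, , s] <- M + t(M)
    }
    out
  }
  permSeeds <- sample.int(2^30, nSims)
  rej <- vapply(seq_len(nSims), function(s) {
    res <- sfcPermutationTest(nullStack(), nullStack(), m, nPerm = nPerm,
                              alpha = alpha, seed = permSeeds[s])
    length(res@clusters) > 0
  }, logical(1))
  list(rate = mean(rej), nSims = nSims,
       ciHalf = 1.96 * sqrt(alpha * (1 - alpha) / nSims))
}

#' Volume-conduction suppression experiment
#'
#' Simulates trials carrying one quarter-cycle-lagged beta-2 coupling
#' (C4-CP2, coherence 0.9) and one zero-lag mixed source (F3/F4), and
#' compares trial-averaged band ImCoh of the planted, mixed, and
#' remaining pairs.
#'
#' @param nTrialsSim number of simulated trials averaged.
#' @param seed integer seed.
#' @param montage analysis montage (default: shipped 62-channel layout).
#' @return list with `planted`, `mixed`, `q99` (99th percentile of the
#'   other pairs), and `meanOthers`.
#' @export
vcSuppressionExperiment <- function(nTrialsSim = 100L, seed = 1L,
                                    montage = defaultMontage()) {
  cfg <- cohortConfig(nChannels = length(montage@channels), seed = seed)
  spec <- couplingSpec(
    data.frame(from = "C4", to = "CP2", loHz = 20, hiHz = 25,
               lagMs = 12.5, strength = 0.9),
    zeroLagMixing = list(list(channels = c("F3", "F4"),
                              weights = c(1, 0.9))))
  b2 <- betaBands()$beta2
  acc <- 0
  for (k in seq_len(nTrialsSim)) {
    tr <- simulateTrial(spec, cfg, montage,
                        seed = .substream(seed, 90000 + k))
    acc <- acc + bandSummary(imaginaryCoherence(
      crossSpectrum(tr, cfg@rate, freqRange = c(19, 26))), b2) / nTrialsSim
  }
  ch <- montage@channels
  pr <- channelPairs(montage)
  nm <- paste(ch[pr[, 1]], ch[pr[, 2]], sep = "-")
  vals <- structure(acc[pr], names = nm)
  plantedName <- nm[grepl("^(C4-CP2|CP2-C4)$", nm)]
  mixedName <- nm[grepl("^(F3-F4|F4-F3)$", nm)]
  others <- vals[!names(vals) %in% c(plantedName, mixedName)]
  list(planted = unname(vals[plantedName]), mixed = unname(vals[mixedName]),
       q99 = unname(stats::quantile(others, 0.99)),
       meanOthers = mean(others))
}
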