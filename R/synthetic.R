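# Synthetic cohort generator: epoched multichannel trials with planted
# band-limited, phase-lagged coupling (carrying imaginary coherence) and
# optional zero-lag "volume-conduction" mixing as a nuisance.

#' Construct a CouplingSpec
#'
#' @param edges data.frame with columns `from`, `to`, `loHz`, `hiHz`,
#'   `lagMs`, `strength` (target in-band coherence in [0, 1]).
#' @param condition condition the spec applies to.
#' @param zeroLagMixing list of entries `list(channels =, weights =)`
#'   adding one shared instantaneous broadband source per entry.
#' @return a [CouplingSpec-class].
#' @export
couplingSpec <- function(edges = data.frame(from = character(0), to = character(0),
                                            loHz = numeric(0), hiHz = numeric(0),
                                            lagMs = numeric(0), strength = numeric(0)),
                         condition = "stimulation", zeroLagMixing = list()) {
  new("CouplingSpec", edges = as.data.frame(edges), condition = condition,
      zeroLagMixing = zeroLagMixing)
}

#' Construct a CohortConfig
#'
#' Defaults are the emulated study design: 8 subjects per group, 62
#' channels at 1000 Hz, 4-s trials, 9 trials per condition per forearm,
#' 2 conditions x 2 forearms, pink background noise of unit SD, and 90%
#' of planted stimulation couplings contralateral to the stimulated limb.
#'
#' @param nSubjects,nChannels,rate,trialS,nTrials design parameters.
#' @param conditions,limbs design factor levels.
#' @param noiseModel `"pink"` (1/f) or `"white"`.
#' @param noiseSD background noise SD in microvolts.
#' @param lateralization fraction of stimulation edges contralateral.
#' @param seed master seed, expanded to per-trial substreams.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nSubjects = 8L, nChannels = 62L, rate = 1000,
                         trialS = 4, nTrials = 9L,
                         conditions = c("baseline", "stimulation"),
                         limbs = c("left", "right"),
                         noiseModel = c("pink", "white"), noiseSD = 1,
                         lateralization = 0.9, seed = 1L) {
  new("CohortConfig", nSubjects = as.integer(nSubjects),
      nChannels = as.integer(nChannels), rate = rate, trialS = trialS,
      nTrials = as.integer(nTrials), conditions = conditions, limbs = limbs,
      noiseModel = match.arg(noiseModel), noiseSD = noiseSD,
      lateralization = lateralization, seed = as.integer(seed))
}

# Counter-based substream: one master seed expands to reproducible
# per-trial seeds independent of generation order (Lehmer step + offset,
# kept below 2^31).
.substream <- function(seed, counter) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + counter * 9973) %% 2147483647)
}

# Spectral shaping vector over the N FFT bins (two-sided), normalized so
# filtering unit-variance white noise yields unit variance.
.noiseShape <- function(N, rate, model) {
  k <- seq_len(N) - 1L
  f <- pmin(k, N - k) * rate / N
  H <- if (model == "pink") ifelse(f > 0, 1 / sqrt(f), 0) else rep(1, N)
  H[1L] <- 0  # no DC
  H / sqrt(mean(H^2))
}

.bandShape <- function(N, rate, loHz, hiHz) {
  k <- seq_len(N) - 1L
  f <- pmin(k, N - k) * rate / N
  H <- as.numeric(f >= loHz - 1e-9 & f <= hiHz + 1e-9 & f > 0)
  if (!any(H > 0)) stop("coupling band contains no FFT bins")
  H / sqrt(mean(H^2))
}

.shapedNoise <- function(nCh, N, H) {
  W <- matrix(stats::rnorm(nCh * N), N, nCh)
  Re(stats::mvfft(stats::mvfft(W) * H, inverse = TRUE) / N)  # N x nCh
}

#' Cohort design table
#'
#' Enumerates the trials of one group under a [CohortConfig-class] without
#' simulating any signals: one row per trial with subject, limb, condition
#' and trial number. The default design has
#' 2 x 9 x 2 x 8 = 288 rows (trials per group).
#'
#' @param config a [CohortConfig-class].
#' @return data.frame with columns `subject`, `limb`, `condition`,
#'   `trial`.
#' @examples
#' nrow(cohortDesign(cohortConfig()))  # 288
#' @export
cohortDesign <- function(config) {
  g <- expand.grid(trial = seq_len(config@nTrials),
                   condition = config@conditions,
                   limb = config@limbs,
                   subject = sprintf("s%02d", seq_len(config@nSubjects)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("subject", "limb", "condition", "trial")]
}

#' Simulate one epoched trial
#'
#' Background noise (pink or white) per channel, plus, for every planted
#' edge of a spec matching the trial's condition, a band-limited latent
#' source injected into `from` and a lag-delayed copy into `to` with
#' amplitude calibrated so the planted in-band coherence approximates
#' `strength`; zero-lag mixing entries add one shared instantaneous
#' broadband source across their channels. Edges are defined relative to
#' left-forearm stimulation; for `limb = "right"` they are mirrored
#' through the montage homologue map so planted couplings stay
#' contralateral to the stimulated limb.
#'
#' @param specs a [CouplingSpec-class] or list of them.
#' @param config a [CohortConfig-class].
#' @param montage a [Montage-class]; its channel count must match the
#'   config.
#' @param condition,limb trial labels.
#' @param seed integer seed for this trial.
#' @return numeric channel x sample matrix (microvolts).
#' @export
simulateTrial <- function(specs, config, montage,
                          condition = "stimulation", limb = "left",
                          seed = 1L) {
  if (is(specs, "CouplingSpec")) specs <- list(specs)
  ch <- montage@channels
  if (length(ch) != config@nChannels)
    stop("montage has ", length(ch), " channels; config expects ", config@nChannels)
  N <- as.integer(round(config@trialS * config@rate))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  Hn <- .noiseShape(N, config@rate, config@noiseModel)
  x <- t(.shapedNoise(length(ch), N, Hn)) * config@noiseSD  # ch x N
  rownames(x) <- ch

  for (spec in specs) {
    if (spec@condition != condition) next
    e <- spec@edges
    if (nrow(e)) {
      bad <- setdiff(unique(c(e$from, e$to)), ch)
      if (length(bad))
        stop("spec channel(s) outside montage: ", paste(bad, collapse = ", "))
      if (limb == "right") {
        if (!length(montage@flipMap))
          stop("right-limb trials need a montage flip map to mirror couplings")
        e$from <- unname(montage@flipMap[e$from])
        e$to <- unname(montage@flipMap[e$to])
      }
      # Power-neutral injection: within each coupling band a channel's
      # intrinsic noise is attenuated by exactly the total source power
      # fraction planted on it, and each shared source is scaled to its
      # own fraction of the nominal in-band noise power. Auto-spectra are
      # unchanged, so planted edges neither bias the coherence of other
      # pairs incident to the same channels nor alter channel power, and
      # a planted pair's in-band coherence approximates `strength`
      # (slightly less where chained edges share an endpoint and the
      # per-channel fractions are rescaled to keep their sum below 1).
      bandKey <- paste(e$loHz, e$hiHz)
      contrib <- list()   # per channel x band: summed source fractions
      for (k in seq_len(nrow(e))) for (ch_k in c(e$from[k], e$to[k])) {
        key <- paste(ch_k, bandKey[k])
        contrib[[key]] <- (if (is.null(contrib[[key]])) 0 else contrib[[key]]) +
          e$strength[k]
      }
      capFactor <- function(ch_k, k) {
        tot <- contrib[[paste(ch_k, bandKey[k])]]
        if (tot > 0.95) 0.95 / tot else 1
      }
      srcs <- vector("list", nrow(e))
      for (k in seq_len(nrow(e))) {
        lagSamp <- as.integer(round(e$lagMs[k] / 1000 * config@rate))
        if (abs(lagSamp) >= N)
          stop("edge lag (", e$lagMs[k], " ms) is not shorter than the trial")
        Hs <- .bandShape(N, config@rate, e$loHz[k], e$hiHz[k])
        srcs[[k]] <- list(s = .shapedNoise(1L, N, Hs)[, 1L], band = Hs > 0,
                          lag = ((lagSamp %% N) + N) %% N)
      }
      # attenuate each channel's intrinsic noise once per band
      for (key in names(contrib)) {
        parts <- strsplit(key, " ", fixed = TRUE)[[1L]]
        ch_k <- parts[1L]
        tot <- min(contrib[[key]], 0.95)
        band <- .bandShape(N, config@rate, as.numeric(parts[2L]),
                           as.numeric(parts[3L])) > 0
        V <- stats::fft(x[ch_k, ])
        V[band] <- V[band] * sqrt(1 - tot)
        x[ch_k, ] <- Re(stats::fft(V, inverse = TRUE) / N)
      }
      for (k in seq_len(nrow(e))) {
        band <- srcs[[k]]$band
        pn <- config@noiseSD^2 * mean(Hn[band]^2)
        ps <- mean(.bandShape(N, config@rate, e$loHz[k], e$hiHz[k])[band]^2)
        s <- srcs[[k]]$s
        sh <- srcs[[k]]$lag
        sLag <- if (sh == 0L) s else
          c(s[(N - sh + 1L):N], s[1L:(N - sh)])  # circular delay
        aFrom <- sqrt(e$strength[k] * capFactor(e$from[k], k) * pn / ps)
        aTo <- sqrt(e$strength[k] * capFactor(e$to[k], k) * pn / ps)
        x[e$from[k], ] <- x[e$from[k], ] + aFrom * s
        x[e$to[k], ]   <- x[e$to[k], ]   + aTo * sLag
      }
    }
    for (mx in spec@zeroLagMixing) {
      bad <- setdiff(mx$channels, ch)
      if (length(bad))
        stop("mixing channel(s) outside montage: ", paste(bad, collapse = ", "))
      u <- stats::rnorm(N)
      for (j in seq_along(mx$channels))
        x[mx$channels[j], ] <- x[mx$channels[j], ] + mx$weights[j] * u
    }
  }
  x
}

#' Simulate a full cohort
#'
#' Generates, per group, `nConditions x nTrials x nLimbs x nSubjects`
#' labelled trials (288 per group at defaults). Generation is
#' deterministic given the config seed: every trial draws from its own
#' counter-derived substream, so per-subject results are reproducible
#' independently of generation order.
#'
#' @param config a [CohortConfig-class].
#' @param montage a [Montage-class].
#' @param groupSpecs named list mapping each group name to a list of
#'   [CouplingSpec-class] objects (see [defaultCouplingSpecs()]).
#' @return named list: per group, a list of [TrialSet-class] (one per
#'   subject).
#' @export
simulateCohort <- function(config, montage,
                           groupSpecs = list(
                             stroke = defaultCouplingSpecs(montage, "stroke", config),
                             control = defaultCouplingSpecs(montage, "control", config))) {
  design <- cohortDesign(config)
  subjects <- unique(design$subject)
  nL <- length(config@limbs); nC <- length(config@conditions)
  nT <- config@nTrials
  N <- as.integer(round(config@trialS * config@rate))
  out <- vector("list", length(groupSpecs))
  names(out) <- names(groupSpecs)
  for (g in seq_along(groupSpecs)) {
    specs <- groupSpecs[[g]]
    grpName <- names(groupSpecs)[g]
    subjList <- vector("list", length(subjects))
    for (s in seq_along(subjects)) {
      rows <- design[design$subject == subjects[s], ]
      dat <- array(NA_real_, c(nrow(rows), length(montage@channels), N),
                   dimnames = list(NULL, montage@channels, NULL))
      for (r in seq_len(nrow(rows))) {
        lIdx <- match(rows$limb[r], config@limbs)
        cIdx <- match(rows$condition[r], config@conditions)
        counter <- ((((g - 1L) * length(subjects) + (s - 1L)) * nL +
                       (lIdx - 1L)) * nC + (cIdx - 1L)) * nT + rows$trial[r]
        dat[r, , ] <- simulateTrial(specs, config, montage,
                                    condition = rows$condition[r],
                                    limb = rows$limb[r],
                                    seed = .substream(config@seed, counter))
      }
      subjList[[s]] <- new("TrialSet", data = dat, rate = config@rate,
                           condition = rows$condition, limb = rows$limb,
                           subject = subjects[s], group = grpName)
    }
    names(subjList) <- subjects
    out[[g]] <- subjList
  }
  out
}

#' Lateralized stimulation coupling spec
#'
#' Builds `nEdges` stimulation-condition couplings of which
#' `round(fraction * nEdges)` chain through contralateral (right, for
#' left-forearm stimulation) somatosensory-area channels and the rest
#' chain through their ipsilateral homologues. Chaining edges over shared
#' endpoints makes the planted pattern a spatial cluster, as required for
#' it to survive cluster-based retention.
#'
#' @param montage a [Montage-class] containing the standard somatosensory
#'   labels (FC2/FC4, C2-C6, CP2-CP6, P2/P4 and homologues).
#' @param fraction contralateral fraction in [0, 1].
#' @param nEdges number of planted couplings (at most 9 per side).
#' @param strength target in-band coherence.
#' @param loHz,hiHz coupling band (default beta 2).
#' @param lagMs transmission lag (12.5 ms = a quarter cycle at 20 Hz).
#' @param pool contralateral (right-hemisphere) channels the edge chain
#'   runs through; defaults to the somatosensory-area labels.
#' @return a [CouplingSpec-class] with `condition = "stimulation"`.
#' @export
lateralizedSpec <- function(montage, fraction = 0.9, nEdges = 10L,
                            strength = 0.6, loHz = 20, hiHz = 25,
                            lagMs = 12.5,
                            pool = c("FC2", "FC4", "C2", "C4", "C6",
                                     "CP2", "CP4", "CP6", "P2", "P4")) {
  pool <- pool[pool %in% montage@channels]
  if (length(pool) < 2L) stop("montage lacks the somatosensory channel pool")
  if (!length(montage@flipMap)) stop("montage needs a flip map")
  poolIpsi <- unname(montage@flipMap[pool])
  nContra <- round(fraction * nEdges)
  nIpsi <- nEdges - nContra
  if (nContra > length(pool) - 1L || nIpsi > length(pool) - 1L)
    stop("nEdges too large for the channel pool")
  chain <- function(p, m) if (m > 0L)
    data.frame(from = p[seq_len(m)], to = p[seq_len(m) + 1L]) else
    data.frame(from = character(0), to = character(0))
  e <- rbind(chain(pool, nContra), chain(poolIpsi, nIpsi))
  e$loHz <- loHz; e$hiHz <- hiHz; e$lagMs <- lagMs; e$strength <- strength
  couplingSpec(e, condition = "stimulation")
}

#' Default coupling specs for a simulated group
#'
#' The emulated study conditions: beta-2 (20-25 Hz) stimulation couplings
#' with a 12.5-ms lag and in-band coherence 0.6, strongly contralateral
#' for the control group (`lateralization` from the config, default 0.9)
#' and weakly lateralized, more widespread for the stroke group (fraction
#' 0.2, 12 edges); plus, in both conditions, one shared zero-lag broadband
#' source mixed into five frontal channels with weight 0.5 as the
#' volume-conduction nuisance.
#'
#' @param montage a [Montage-class].
#' @param group `"control"` or `"stroke"`.
#' @param config a [CohortConfig-class] supplying the lateralization
#'   fraction for the control group.
#' @return list of [CouplingSpec-class] objects.
#' @export
defaultCouplingSpecs <- function(montage, group = c("control", "stroke"),
                                 config = cohortConfig()) {
  group <- match.arg(group)
  mixChannels <- intersect(c("Fz", "F1", "F2", "AF3", "AF4"), montage@channels)
  mixing <- if (length(mixChannels))
    list(list(channels = mixChannels, weights = rep(0.5, length(mixChannels))))
  else list()
  stim <- if (group == "control")
    lateralizedSpec(montage, fraction = config@lateralization)
  else
    lateralizedSpec(montage, fraction = 0.2, nEdges = 10L)
  stim@zeroLagMixing <- mixing
  list(stim, couplingSpec(condition = "baseline", zeroLagMixing = mixing))
}
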