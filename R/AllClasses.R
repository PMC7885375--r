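#' @import methods
NULL

.MIDLINE_TOL <- 1e-6

#' Montage: channel geometry, hemisphere partition and homologue map
#'
#' A `Montage` describes the sensor layout an analysis runs on: channel
#' labels in 10-20 nomenclature, 2-D head-centered scalp positions
#' (x positive toward the right ear, y toward the nasion), the
#' left/right/midline partition, a symmetric channel-neighbour relation
#' used for cluster formation, and the involutive homologue map
#' (C3 <-> C4, ...) used by the mid-sagittal flip.
#'
#' @slot channels ordered character vector of channel labels.
#' @slot positions numeric matrix (n x 2) of scalp coordinates, rows named
#'   by channel.
#' @slot hemisphere character vector in `c("left","right","midline")`,
#'   consistent with the sign of the x coordinate.
#' @slot neighbors symmetric, irreflexive logical matrix (n x n); may be
#'   empty (0 x 0) until computed with [neighborsFromPositions()].
#' @slot flipMap named character vector mapping each channel to its
#'   homologue (midline channels map to themselves); may be empty.
#'
#' @seealso [newMontage()], [defaultMontage()], [flipMidSagittal()]
#' @export
setClass("Montage", representation(
  channels   = "character",
  positions  = "matrix",
  hemisphere = "character",
  neighbors  = "matrix",
  flipMap    = "character"
))

setValidity("Montage", function(object) {
  ch <- object@channels
  n  <- length(ch)
  msg <- character(0)
  if (anyDuplicated(ch)) msg <- c(msg, "duplicated channel labels")
  if (!is.numeric(object@positions) || nrow(object@positions) != n ||
      ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be a numeric n x 2 matrix")
  if (length(object@hemisphere) != n ||
      !all(object@hemisphere %in% c("left", "right", "midline")))
    msg <- c(msg, "hemisphere must be left/right/midline per channel")
  if (length(msg) == 0L) {
    x <- object@positions[, 1L]
    hem <- ifelse(abs(x) <= .MIDLINE_TOL, "midline",
                  ifelse(x > 0, "right", "left"))
    if (!all(hem == object@hemisphere))
      msg <- c(msg, "hemisphere labels inconsistent with sign of x coordinate")
    if (sum(object@hemisphere == "left") != sum(object@hemisphere == "right"))
      msg <- c(msg, "left and right hemisphere channel counts must be equal")
  }
  if (length(object@flipMap)) {
    if (is.null(names(object@flipMap)) || !setequal(names(object@flipMap), ch))
      msg <- c(msg, "flipMap must be named by every channel")
    else {
      fm <- object@flipMap
      if (!all(fm %in% ch)) msg <- c(msg, "flipMap targets outside montage")
      else {
        if (!identical(unname(fm[unname(fm)]), names(fm)))
          msg <- c(msg, "flipMap must be an involution")
        mid <- ch[object@hemisphere == "midline"]
        if (!all(fm[mid] == mid))
          msg <- c(msg, "flipMap must fix midline channels")
      }
    }
  }
  if (length(object@neighbors) > 0L) {
    nb <- object@neighbors
    if (!is.logical(nb) || nrow(nb) != n || ncol(nb) != n)
      msg <- c(msg, "neighbors must be a logical n x n matrix")
    else {
      if (!isTRUE(all(nb == t(nb)))) msg <- c(msg, "neighbor relation must be symmetric")
      if (any(diag(nb))) msg <- c(msg, "neighbor relation must be irreflexive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Recording: continuous multichannel signals with condition markers
#'
#' @slot samples numeric matrix (channel x time), in microvolts, rows named
#'   by channel.
#' @slot rate sampling frequency in Hz.
#' @slot annotations data.frame with columns `onset` (seconds) and `label`
#'   (condition markers, optionally `"condition:limb"`).
#'
#' @seealso [readRecording()], [writeRecording()], [epochRecording()]
#' @export
setClass("Recording", representation(
  samples     = "matrix",
  rate        = "numeric",
  annotations = "data.frame"
))

setValidity("Recording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (nrow(object@samples) > 0L && is.null(rownames(object@samples)))
    msg <- c(msg, "samples rows must be named by channel")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  ann <- object@annotations
  if (!all(c("onset", "label") %in% names(ann)))
    msg <- c(msg, "annotations need columns onset, label")
  else if (nrow(ann) && length(msg) == 0L) {
    dur <- ncol(object@samples) / object@rate
    if (any(ann$onset < 0 | ann$onset > dur))
      msg <- c(msg, "annotation onsets outside record duration")
  }
  if (length(msg)) msg else TRUE
})

#' TrialSet: epoched signals with condition/limb/subject labels
#'
#' @slot data numeric array, trial x channel x sample; channel dimension
#'   named.
#' @slot rate sampling frequency in Hz.
#' @slot condition per-trial label, `"baseline"` or `"stimulation"`.
#' @slot limb per-trial stimulated-forearm label, `"left"` or `"right"`.
#' @slot subject subject identifier.
#' @slot group group label, e.g. `"stroke"` or `"control"`.
#'
#' @export
setClass("TrialSet", representation(
  data      = "array",
  rate      = "numeric",
  condition = "character",
  limb      = "character",
  subject   = "character",
  group     = "character"
))

setValidity("TrialSet", function(object) {
  d <- dim(object@data)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "data must be trial x channel x sample")
  if (is.null(dimnames(object@data)[[2L]]))
    msg <- c(msg, "channel dimension must be named")
  if (length(msg) == 0L) {
    if (length(object@condition) != d[1L] || length(object@limb) != d[1L])
      msg <- c(msg, "condition and limb must label every trial")
    if (!all(object@condition %in% c("baseline", "stimulation")))
      msg <- c(msg, "condition labels must be baseline/stimulation")
    if (!all(object@limb %in% c("left", "right")))
      msg <- c(msg, "limb labels must be left/right")
  }
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' CrossSpectrum: Welch-averaged channel-pair cross-spectra
#'
#' Houses the complex cross-spectral matrix S_ij(f) of one trial:
#' Hermitian in (i, j) at each frequency, real non-negative diagonal,
#' frequency spacing `1/windowS`.
#'
#' @slot values complex array, channel x channel x frequency.
#' @slot freqs frequency grid in Hz.
#' @slot windowS Welch segment length in seconds.
#' @slot overlap segment overlap fraction.
#' @slot nSegments number of segments averaged.
#' @export
setClass("CrossSpectrum", representation(
  values    = "array",
  freqs     = "numeric",
  windowS   = "numeric",
  overlap   = "numeric",
  nSegments = "integer"
))

setValidity("CrossSpectrum", function(object) {
  d <- dim(object@values)
  msg <- character(0)
  if (length(d) != 3L || d[1L] != d[2L])
    msg <- c(msg, "values must be channel x channel x frequency")
  else if (d[3L] != length(object@freqs))
    msg <- c(msg, "frequency dimension must match freqs")
  if (length(msg)) msg else TRUE
})

#' SpectralConnectivity: imaginary-coherence connectivity
#'
#' `imcoh` holds |Im(coherency)| per channel pair and frequency: symmetric,
#' zero diagonal, values in [0, 1]. The signed imaginary part is retained
#' in `signedIm` for diagnostic use.
#'
#' @slot imcoh numeric array, channel x channel x frequency, in [0, 1].
#' @slot signedIm numeric array of the signed imaginary part of coherency.
#' @slot freqs frequency grid in Hz.
#' @export
setClass("SpectralConnectivity", representation(
  imcoh    = "array",
  signedIm = "array",
  freqs    = "numeric"
))

setValidity("SpectralConnectivity", function(object) {
  d <- dim(object@imcoh)
  msg <- character(0)
  if (length(d) != 3L || d[1L] != d[2L] || d[3L] != length(object@freqs))
    msg <- c(msg, "imcoh must be channel x channel x frequency matching freqs")
  else {
    v <- object@imcoh
    if (any(v < -1e-9 | v > 1 + 1e-9)) msg <- c(msg, "imcoh values outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' BandDefinition: a named frequency band with inclusive edges
#'
#' @slot name band name.
#' @slot loHz,hiHz inclusive band edges in Hz.
#' @export
setClass("BandDefinition", representation(
  name = "character", loHz = "numeric", hiHz = "numeric"
))

setValidity("BandDefinition", function(object) {
  if (object@loHz >= object@hiHz) "band must have loHz < hiHz" else TRUE
})

#' EdgeStatMap: paired statistics per unordered channel pair
#'
#' @slot channels channel labels.
#' @slot pairs integer matrix (P x 2) of channel indices, i < j, covering
#'   all n(n-1)/2 unordered pairs.
#' @slot t paired t statistic per pair.
#' @slot p two-sided uncorrected p-value per pair.
#' @slot df degrees of freedom.
#' @export
setClass("EdgeStatMap", representation(
  channels = "character",
  pairs    = "matrix",
  t        = "numeric",
  p        = "numeric",
  df       = "numeric"
))

setValidity("EdgeStatMap", function(object) {
  n <- length(object@channels)
  msg <- character(0)
  if (nrow(object@pairs) != n * (n - 1L) / 2L)
    msg <- c(msg, "pairs must enumerate all n(n-1)/2 unordered pairs")
  if (length(object@t) != nrow(object@pairs) || length(object@p) != nrow(object@pairs))
    msg <- c(msg, "t and p must be defined per pair")
  if (length(object@t) && !all(is.finite(object@t)))
    msg <- c(msg, "t must be finite")
  if (length(msg)) msg else TRUE
})

#' EdgeCluster: a sign-homogeneous connected set of suprathreshold edges
#'
#' @slot edges integer matrix (m x 2) of channel indices.
#' @slot t member edge t-values (all of one sign).
#' @slot clusterStat sum of member t-values.
#' @slot permP Monte-Carlo permutation p-value (NA before scoring).
#' @export
setClass("EdgeCluster", representation(
  edges = "matrix", t = "numeric", clusterStat = "numeric", permP = "numeric"
))

#' SFCResult: stimulation-induced functional connectivity
#'
#' Edges surviving the cluster-based permutation test, with normalized
#' t-values (t / max|t| over retained edges) and per-channel sums of the
#' normalized t over incident retained edges (the node intensities drawn
#' on SFC topographies).
#'
#' @slot channels channel labels.
#' @slot clusters list of retained [EdgeCluster-class] objects.
#' @slot edges integer matrix of retained edges (m x 2).
#' @slot t raw t per retained edge.
#' @slot normalizedT t / max|t| per retained edge.
#' @slot clusterId cluster membership per retained edge.
#' @slot permP permutation p per retained edge's cluster.
#' @slot nodeSum named per-channel sum of normalized t over incident edges.
#' @slot nPermutations number of permutations used (exhaustive count if
#'   enumeration was exhaustive).
#' @slot exhaustive TRUE when all sign flips were enumerated.
#' @slot alpha cluster significance level.
#' @slot seed RNG seed used.
#' @export
setClass("SFCResult", representation(
  channels      = "character",
  clusters      = "list",
  edges         = "matrix",
  t             = "numeric",
  normalizedT   = "numeric",
  clusterId     = "integer",
  permP         = "numeric",
  nodeSum       = "numeric",
  nPermutations = "integer",
  exhaustive    = "logical",
  alpha         = "numeric",
  seed          = "integer"
))

setValidity("SFCResult", function(object) {
  msg <- character(0)
  if (length(object@nodeSum) != length(object@channels))
    msg <- c(msg, "nodeSum must be defined per channel")
  if (nrow(object@edges) != length(object@t) ||
      nrow(object@edges) != length(object@normalizedT))
    msg <- c(msg, "edge annotation lengths disagree")
  if (length(msg)) msg else TRUE
})

#' BinaryNetwork: per-subject 0/1 functional brain network
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal, dimnames set to
#'   channel labels.
#' @slot hemisphere per-channel label in `c("left","right","midline")`.
#' @export
setClass("BinaryNetwork", representation(
  adjacency = "matrix", hemisphere = "character"
))

setValidity("BinaryNetwork", function(object) {
  A <- object@adjacency
  msg <- character(0)
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  else {
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0/1")
    if (!isTRUE(all(A == t(A)))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (length(object@hemisphere) != nrow(A))
      msg <- c(msg, "hemisphere must label every channel")
  }
  if (length(msg)) msg else TRUE
})

#' NetworkIndices: multiscale graph indices of a binary brain network
#'
#' Large scale: global efficiency, local efficiency, smallworldness with
#' its random-graph references. Intermediate scale: inter-hemispheric and
#' per-hemisphere intra-hemispheric link densities. Small scale: per-node
#' inter- and intra-hemispheric degrees.
#'
#' @slot eGlo,eLoc global and local efficiency, in [0, 1].
#' @slot sw smallworldness (NaN when the random reference has zero local
#'   efficiency).
#' @slot eGloR,eLocR mean efficiencies of the G(n, m) random references.
#' @slot kInter inter-hemispheric link density.
#' @slot kIntraLeft,kIntraRight intra-hemispheric link densities.
#' @slot dInter,dIntra named per-node degrees (midline nodes 0 by
#'   convention).
#' @slot nRandomRefs number of random reference graphs.
#' @slot seed RNG seed for the references.
#' @export
setClass("NetworkIndices", representation(
  eGlo = "numeric", eLoc = "numeric", sw = "numeric",
  eGloR = "numeric", eLocR = "numeric",
  kInter = "numeric", kIntraLeft = "numeric", kIntraRight = "numeric",
  dInter = "numeric", dIntra = "numeric",
  nRandomRefs = "integer", seed = "integer"
))

#' CouplingSpec: planted phase-lagged coupling for the simulator
#'
#' @slot edges data.frame with columns `from`, `to` (channel labels),
#'   `loHz`, `hiHz` (coupling band), `lagMs` (transmission lag; must be
#'   non-zero for an edge meant to carry imaginary coherence) and
#'   `strength` (target in-band coherence, in [0, 1]).
#' @slot condition condition the coupling applies to (`"baseline"` or
#'   `"stimulation"`).
#' @slot zeroLagMixing list of instantaneous-mixing entries, each a list
#'   with `channels` (labels) and `weights` (per-channel gain of a shared
#'   broadband source); the volume-conduction nuisance.
#' @export
setClass("CouplingSpec", representation(
  edges = "data.frame", condition = "character", zeroLagMixing = "list"
))

setValidity("CouplingSpec", function(object) {
  e <- object@edges
  msg <- character(0)
  need <- c("from", "to", "loHz", "hiHz", "lagMs", "strength")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("edges needs columns", paste(need, collapse = ", ")))
  else if (nrow(e)) {
    if (any(e$strength < 0 | e$strength > 1))
      msg <- c(msg, "strength must lie in [0, 1]")
    if (any(e$loHz >= e$hiHz) || any(e$loHz <= 0))
      msg <- c(msg, "coupling band must satisfy 0 < loHz < hiHz")
  }
  if (!object@condition %in% c("baseline", "stimulation"))
    msg <- c(msg, "condition must be baseline or stimulation")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: design of a simulated cohort
#'
#' Defaults reproduce the study design the simulator emulates: 8 subjects
#' per group, 62 channels at 1000 Hz, 4-s trials, 9 trials per condition
#' and forearm, two conditions and two forearms, hence
#' 2 x 9 x 2 x 8 = 288 trials per group.
#'
#' @slot nSubjects subjects per group.
#' @slot nChannels channel count (must match the montage in use).
#' @slot rate sampling frequency, Hz.
#' @slot trialS trial length, seconds.
#' @slot nTrials trials per condition per forearm.
#' @slot conditions,limbs factor levels of the design.
#' @slot noiseModel `"pink"` or `"white"`.
#' @slot noiseSD background noise standard deviation (microvolts).
#' @slot lateralization fraction of planted stimulation-condition edges
#'   placed contralateral to the stimulated limb (used by
#'   [lateralizedSpec()] when building default coupling specs).
#' @slot seed integer master seed; expanded into per-trial substreams.
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer", nChannels = "integer", rate = "numeric",
  trialS = "numeric", nTrials = "integer",
  conditions = "character", limbs = "character",
  noiseModel = "character", noiseSD = "numeric",
  lateralization = "numeric", seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (object@nSubjects < 1L || object@nTrials < 1L || object@nChannels < 1L)
    msg <- c(msg, "all design counts must be >= 1")
  if (object@trialS <= 0 || object@rate <= 0)
    msg <- c(msg, "rate and trialS must be positive")
  if (!object@noiseModel %in% c("pink", "white"))
    msg <- c(msg, "noiseModel must be pink or white")
  if (object@lateralization < 0 || object@lateralization > 1)
    msg <- c(msg, "lateralization must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
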