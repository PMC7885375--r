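# End-to-end orchestration: simulate -> connectivity -> SFC -> networks ->
# group report, with explicit seeds, config validation and provenance.

#' Assemble a pipeline configuration
#'
#' A plain list (JSON-serializable, so it round-trips through
#' serialization unchanged) holding every tunable of the end-to-end run.
#' Every random stage carries an explicit seed.
#'
#' @param cohort named list of [cohortConfig()] arguments (defaults give
#'   the full 8 + 8 subject design).
#' @param bandName,bandLo,bandHi analysis band (default beta 2, 20-25 Hz).
#' @param windowS,overlap Welch parameters.
#' @param nPerm,alpha,edgeAlpha,permSeed cluster-permutation block.
#' @param fdr,swRefs,netSeed network block (binarization FDR level,
#'   smallworldness references and their seed).
#' @return a named list.
#' @export
pipelineConfig <- function(cohort = list(), bandName = "beta2",
                           bandLo = 20, bandHi = 25,
                           windowS = 2, overlap = 0.5,
                           nPerm = 1000L, alpha = 0.05, edgeAlpha = 0.05,
                           permSeed = 1L, fdr = 0.05, swRefs = 100L,
                           netSeed = 1L) {
  cohortDefaults <- list(nSubjects = 8L, nChannels = 62L, rate = 1000,
                         trialS = 4, nTrials = 9L, noiseModel = "pink",
                         noiseSD = 1, lateralization = 0.9, seed = 1L)
  cohortDefaults[names(cohort)] <- cohort
  list(cohort = cohortDefaults,
       band = list(name = bandName, lo = bandLo, hi = bandHi),
       welch = list(windowS = windowS, overlap = overlap),
       permutation = list(nPerm = as.integer(nPerm), alpha = alpha,
                          edgeAlpha = edgeAlpha, seed = as.integer(permSeed)),
       network = list(fdr = fdr, swRefs = as.integer(swRefs),
                      seed = as.integer(netSeed)))
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns findings instead of erroring so
#' callers can report all problems at once. An empty character vector
#' means the configuration is usable.
#'
#' @param config a [pipelineConfig()] list.
#' @param montage optional [Montage-class] to check hemisphere balance.
#' @param retainS,epochS optional retention/epoch lengths to check
#'   divisibility (the preprocessing block, when recordings rather than
#'   epochs are the input).
#' @return character vector of findings (possibly empty).
#' @export
validateConfig <- function(config, montage = NULL, retainS = NULL,
                           epochS = NULL) {
  f <- character(0)
  nyq <- config$cohort$rate / 2
  if (config$band$lo >= config$band$hi)
    f <- c(f, "band low edge must be below high edge")
  if (config$band$hi >= nyq)
    f <- c(f, sprintf("band edge %g Hz is not below Nyquist (%g Hz)",
                      config$band$hi, nyq))
  if (config$welch$windowS > config$cohort$trialS)
    f <- c(f, "Welch window longer than a trial")
  if (config$permutation$nPerm < 100L)
    f <- c(f, "nPerm below 100")
  for (nm in c("alpha", "edgeAlpha"))
    if (config$permutation[[nm]] <= 0 || config$permutation[[nm]] >= 1)
      f <- c(f, paste(nm, "outside (0, 1)"))
  if (!is.null(retainS) && !is.null(epochS) &&
      abs(retainS / epochS - round(retainS / epochS)) > 1e-9)
    f <- c(f, sprintf("retain (%g s) not divisible by epoch (%g s)",
                      retainS, epochS))
  if (!is.null(montage)) {
    h <- hemisphereOf(montage)
    if (sum(h == "left") != sum(h == "right"))
      f <- c(f, "unequal hemisphere sizes: interdensity normalization (1/Ns^2) undefined")
    if (length(montage@channels) != config$cohort$nChannels)
      f <- c(f, sprintf("montage has %d channels, config expects %d",
                        length(montage@channels), config$cohort$nChannels))
  }
  f
}

.asCohortConfig <- function(cc) {
  cohortConfig(nSubjects = cc$nSubjects, nChannels = cc$nChannels,
               rate = cc$rate, trialS = cc$trialS, nTrials = cc$nTrials,
               noiseModel = cc$noiseModel, noiseSD = cc$noiseSD,
               lateralization = cc$lateralization, seed = cc$seed)
}

# Polynomial rolling hash of the canonical config JSON (provenance id).
.configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(s))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%d", h)
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, compute per-trial beta-band imaginary
#' coherence, per-subject condition connectivity, group-level SFC by the
#' cluster permutation test (per group and stimulated limb), per-subject
#' binary networks and multiscale indices, limb comparisons with
#' node-level FDR, and the hemispheric-lateralization report. All stages
#' are deterministic given the seeds in `config`; two runs with identical
#' seeds write byte-identical reports.
#'
#' @param config a [pipelineConfig()] list.
#' @param montage a [Montage-class] (default: the shipped 62-channel
#'   layout).
#' @param cohort optional cohort as returned by [simulateCohort()]
#'   (named list of per-subject [TrialSet-class] lists); `NULL` simulates
#'   one from the config.
#' @param outDir optional directory; when given, writes `report.json`,
#'   `hl_report.tsv`, `index_comparison.tsv`, `node_fdr.tsv` and
#'   `provenance.json`.
#' @return (invisibly) the report list with elements `sfc`, `indices`,
#'   `hl`, `comparisons`, `nodeFdr`, `provenance`.
#' @export
runPipeline <- function(config = pipelineConfig(), montage = defaultMontage(),
                        cohort = NULL, outDir = NULL) {
  findings <- validateConfig(config, montage)
  if (length(findings))
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "))
  band <- bandDefinition(config$band$name, config$band$lo, config$band$hi)
  cc <- .asCohortConfig(config$cohort)
  if (is.null(cohort)) cohort <- simulateCohort(cc, montage)

  limbs <- cc@limbs
  sfc <- list(); indices <- list(); hl <- list()
  for (g in names(cohort)) {
    subjects <- cohort[[g]]
    sfc[[g]] <- list(); indices[[g]] <- list()
    for (l in limbs) {
      stimMeans <- list(); baseMeans <- list(); idxList <- list()
      for (s in names(subjects)) {
        cx <- conditionConnectivity(subjects[[s]], band, limb = l,
                                    windowS = config$welch$windowS,
                                    overlap = config$welch$overlap)
        stimMeans[[s]] <- cx$stimulation
        baseMeans[[s]] <- cx$baseline
        net <- binarizeNetwork(
          cx$trials[, , cx$condition == "stimulation", drop = FALSE],
          cx$trials[, , cx$condition == "baseline", drop = FALSE],
          alpha = config$network$fdr, montage = montage)
        idxList[[s]] <- networkIndices(net, nRefs = config$network$swRefs,
                                       seed = config$network$seed)
      }
      sfc[[g]][[l]] <- sfcPermutationTest(
        stimMeans, baseMeans, montage,
        nPerm = config$permutation$nPerm, alpha = config$permutation$alpha,
        edgeAlpha = config$permutation$edgeAlpha,
        seed = config$permutation$seed)
      indices[[g]][[l]] <- idxList
    }
  }

  hl <- suppressWarnings(hlReport(sfc, montage))
  comparisons <- do.call(rbind, lapply(names(indices), function(g)
    compareIndices(indices[[g]][[limbs[1L]]], indices[[g]][[limbs[2L]]],
                   group = g)))

  nodeFdr <- do.call(rbind, lapply(names(indices), function(g) {
    out <- lapply(c("dInter", "dIntra"), function(kind) {
      a <- t(vapply(indices[[g]][[limbs[1L]]],
                    function(x) methods::slot(x, kind),
                    numeric(length(montage@channels))))
      b <- t(vapply(indices[[g]][[limbs[2L]]],
                    function(x) methods::slot(x, kind),
                    numeric(length(montage@channels))))
      D <- a - b
      ts <- .pairedT(D)
      p <- 2 * stats::pt(-abs(ts$t), ts$df)
      bad <- !is.finite(ts$t)
      tt <- ts$t; tt[bad] <- 0; p[bad] <- 1
      res <- nodeLevelFdr(structure(tt, names = montage@channels), p)
      res$kind <- kind; res$group <- g
      res
    })
    do.call(rbind, out)
  }))

  provenance <- list(package = "imcohnet",
                     version = as.character(utils::packageVersion("imcohnet")),
                     configHash = .configHash(config), config = config)
  report <- list(sfc = sfc, indices = indices, hl = hl,
                 comparisons = comparisons, nodeFdr = nodeFdr,
                 provenance = provenance)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wj <- function(x, f) jsonlite::write_json(
      x, file.path(outDir, f), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", pretty = TRUE)
    sfcSummary <- lapply(sfc, function(gl) lapply(gl, function(r) list(
      nClusters = length(r@clusters), nEdges = nrow(r@edges),
      nChannels = sum(r@nodeSum != 0), permP = r@permP,
      nPermutations = r@nPermutations, exhaustive = r@exhaustive,
      nodeSum = as.list(r@nodeSum[r@nodeSum != 0]))))
    wj(list(hl = hl, comparisons = comparisons, sfc = sfcSummary), "report.json")
    utils::write.table(hl, file.path(outDir, "hl_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(comparisons, file.path(outDir, "index_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nodeFdr, file.path(outDir, "node_fdr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    wj(provenance, "provenance.json")
  }
  invisible(report)
}
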