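# Group-level statistics over network indices: normality screening,
# paired limb comparisons with effect sizes and 95% CIs, node-level FDR,
# and the hemispheric-lateralization report table.

#' Shapiro-Wilk normality screen of paired differences
#'
#' Downstream paired t-tests proceed when p > 0.05; otherwise callers
#' should also report the rank-based fallback (see [pairedCompare()]'s
#' `wilcoxP`).
#'
#' @param values numeric vector of per-subject paired differences,
#'   `3 <= n <= 5000`.
#' @return the Shapiro-Wilk p-value.
#' @export
shapiroScreen <- function(values) {
  if (length(values) < 3L) stop("Shapiro-Wilk screen needs n >= 3")
  if (stats::sd(values) == 0) stop("constant input: normality screen undefined")
  stats::shapiro.test(values)$p.value
}

#' Paired comparison of an index between two limbs
#'
#' Two-sided paired t-test with t-based 95% confidence intervals for each
#' limb's mean, Cohen's d_z (mean difference / SD of differences) as the
#' default effect size, the common-language effect size as a secondary
#' descriptor, the Shapiro-Wilk screen on the differences, and a Wilcoxon
#' signed-rank p reported alongside (with a warning) when the screen
#' rejects normality.
#'
#' @param a,b per-subject index values for the two limbs, same subjects
#'   in the same order, n >= 2.
#' @param conf CI level.
#' @return list with `t`, `df`, `p`, `effectSize` (d_z),
#'   `effectSizeType`, `commonLanguageES`, `meanA`, `meanB`, `ciA`, `ciB`,
#'   `shapiroP`, `wilcoxP` (NA unless the screen rejected).
#' @export
pairedCompare <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  n <- length(a)
  if (n < 2L) stop("paired comparison needs n >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    # identical inputs: the 0/0 statistic is defined as no effect
    if (all(d == 0)) {
      ci <- function(x) {
        se <- stats::sd(x) / sqrt(n)
        mean(x) + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, n - 1) * se
      }
      return(list(t = 0, df = n - 1, p = 1, effectSize = 0,
                  effectSizeType = "cohen_dz", commonLanguageES = 0.5,
                  meanA = mean(a), meanB = mean(b),
                  ciA = ci(a), ciB = ci(b),
                  shapiroP = NA_real_, wilcoxP = NA_real_))
    }
    stop("zero-variance differences: paired t undefined")
  }
  tt <- tryCatch(stats::t.test(a, b, paired = TRUE, conf.level = conf),
                 error = function(e)
                   stop("zero-variance differences: paired t undefined",
                        call. = FALSE))
  dz <- mean(d) / stats::sd(d)
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(n)
    mean(x) + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, n - 1) * se
  }
  shp <- if (n >= 3L) shapiroScreen(d) else NA_real_
  wp <- NA_real_
  if (!is.na(shp) && shp <= 0.05) {
    warning("paired differences fail the normality screen (Shapiro-Wilk p = ",
            signif(shp, 3), "); reporting Wilcoxon signed-rank p alongside")
    wp <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       effectSize = dz, effectSizeType = "cohen_dz",
       commonLanguageES = stats::pnorm(dz),
       meanA = mean(a), meanB = mean(b), ciA = ci(a), ciB = ci(b),
       shapiroP = shp, wilcoxP = wp)
}

#' Node-level FDR over per-channel paired statistics
#'
#' Benjamini-Hochberg step-up across channels; a channel is flagged when
#' its adjusted p is at most `alpha`. The signed t direction is retained
#' for topographic display. BH never adjusts a p below its raw value, so
#' no channel with raw p > alpha is ever flagged.
#'
#' @param t named per-channel t statistics.
#' @param p matching raw two-sided p-values (computed from `t` and `df`
#'   when omitted).
#' @param df degrees of freedom (needed when `p` is omitted).
#' @param alpha FDR level.
#' @return data.frame with columns `channel`, `t`, `p`, `pAdj`,
#'   `significant`, `sign`.
#' @export
nodeLevelFdr <- function(t, p = NULL, df = NULL, alpha = 0.05) {
  if (is.null(p)) {
    if (is.null(df)) stop("supply either p or df")
    p <- 2 * stats::pt(-abs(t), df)
  }
  if (length(t) != length(p)) stop("t and p must align")
  pAdj <- stats::p.adjust(p, method = "BH")
  data.frame(
    channel = if (is.null(names(t))) sprintf("ch%02d", seq_along(t)) else names(t),
    t = unname(t), p = unname(p), pAdj = unname(pAdj),
    significant = unname(pAdj <= alpha), sign = sign(unname(t)),
    row.names = NULL)
}

#' Hemispheric-lateralization report over groups and limbs
#'
#' One row per group x stimulated limb with the SFC channel counts, HL
#' degree and per-hemisphere mean intensities. A missing cell yields a
#' row of NAs with a warning.
#'
#' @param sfcResults nested list `sfcResults[[group]][[limb]]` of
#'   [SFCResult-class] objects (limb = stimulated forearm).
#' @param montage a [Montage-class].
#' @return data.frame with columns `group`, `limb`, `nTotal`, `nContra`,
#'   `hlDegree`, `hlDegreeDisplay`, `meanIntensityContra`,
#'   `meanIntensityIpsi`.
#' @export
hlReport <- function(sfcResults, montage) {
  rows <- list()
  for (g in names(sfcResults)) for (l in names(sfcResults[[g]])) {
    sfc <- sfcResults[[g]][[l]]
    row <- data.frame(group = g, limb = l, nTotal = NA_integer_,
                      nContra = NA_integer_, hlDegree = NA_real_,
                      hlDegreeDisplay = NA_real_,
                      meanIntensityContra = NA_real_,
                      meanIntensityIpsi = NA_real_)
    if (is.null(sfc) || !length(sfc@clusters) || all(sfc@nodeSum == 0)) {
      warning("no SFC for ", g, "/", l, "; emitting an NA row")
    } else {
      ts <- topographySummary(sfc, montage, stimulatedSide = l)
      row$nTotal <- ts$nTotal; row$nContra <- ts$nContra
      row$hlDegree <- ts$hlDegree; row$hlDegreeDisplay <- ts$hlDegreeDisplay
      row$meanIntensityContra <- ts$meanIntensityContra
      row$meanIntensityIpsi <- ts$meanIntensityIpsi
    }
    rows[[paste(g, l)]] <- row
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group comparison table over network indices
#'
#' Runs [pairedCompare()] for each index of per-subject
#' [NetworkIndices-class] lists for two limbs and assembles the report
#' table (index, means with 95% CIs per limb, p, effect size).
#'
#' @param indicesA,indicesB lists of [NetworkIndices-class], one per
#'   subject, for the two stimulated limbs (same subjects, same order).
#' @param group group label for the table.
#' @return data.frame, one row per large/intermediate-scale index.
#' @export
compareIndices <- function(indicesA, indicesB, group = "group") {
  pull <- function(lst, slot) vapply(lst, methods::slot, numeric(1), name = slot)
  idxNames <- c(sw = "sw", eGlo = "eGlo", eLoc = "eLoc", kInter = "kInter",
                kIntraLeft = "kIntraLeft", kIntraRight = "kIntraRight")
  rows <- lapply(names(idxNames), function(nm) {
    a <- pull(indicesA, idxNames[[nm]]); b <- pull(indicesB, idxNames[[nm]])
    if (any(!is.finite(a)) || any(!is.finite(b)) || stats::sd(a - b) == 0)
      return(data.frame(index = nm, group = group,
                        meanA = mean(a), ciLowA = NA_real_, ciHighA = NA_real_,
                        meanB = mean(b), ciLowB = NA_real_, ciHighB = NA_real_,
                        p = NA_real_, effectSize = NA_real_))
    cmp <- pairedCompare(a, b)
    data.frame(index = nm, group = group,
               meanA = cmp$meanA, ciLowA = cmp$ciA[1L], ciHighA = cmp$ciA[2L],
               meanB = cmp$meanB, ciLowB = cmp$ciB[1L], ciHighB = cmp$ciB[2L],
               p = cmp$p, effectSize = cmp$effectSize)
  })
  do.call(rbind, rows)
}
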