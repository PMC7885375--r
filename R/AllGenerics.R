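#' Channel labels of an object
#'
#' @param x a [Montage-class], [Recording-class], [TrialSet-class],
#'   [SpectralConnectivity-class], [SFCResult-class] or
#'   [BinaryNetwork-class] object.
#' @return character vector of channel labels, in analysis order.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Sampling rate of an object, in Hz
#' @param x a [Recording-class] or [TrialSet-class] object.
#' @return sampling frequency in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Number of trials in a TrialSet
#' @param x a [TrialSet-class].
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Hemisphere labels of an object
#' @param x a [Montage-class] or [BinaryNetwork-class] object.
#' @return character vector in `c("left","right","midline")`.
#' @export
setGeneric("hemisphereOf", function(x) standardGeneric("hemisphereOf"))

#' Adjacency matrix of a binary network
#' @param x a [BinaryNetwork-class].
#' @return symmetric 0/1 matrix with channel dimnames.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Per-channel node intensities of an SFC result
#'
#' The sum of normalized t-values over the retained edges incident to each
#' channel; non-zero exactly on the channels of the SFC topography.
#'
#' @param x an [SFCResult-class].
#' @return named numeric vector over all channels.
#' @export
setGeneric("nodeSum", function(x) standardGeneric("nodeSum"))

setMethod("channelNames", "Montage", function(x) x@channels)
setMethod("channelNames", "Recording", function(x) rownames(x@samples))
setMethod("channelNames", "TrialSet", function(x) dimnames(x@data)[[2L]])
setMethod("channelNames", "SpectralConnectivity", function(x) dimnames(x@imcoh)[[1L]])
setMethod("channelNames", "SFCResult", function(x) x@channels)
setMethod("channelNames", "BinaryNetwork", function(x) rownames(x@adjacency))

setMethod("sampleRate", "Recording", function(x) x@rate)
setMethod("sampleRate", "TrialSet", function(x) x@rate)

setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1L])

setMethod("hemisphereOf", "Montage", function(x) {
  structure(x@hemisphere, names = x@channels)
})
setMethod("hemisphereOf", "BinaryNetwork", function(x) {
  structure(x@hemisphere, names = rownames(x@adjacency))
})

setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)
setMethod("nodeSum", "SFCResult", function(x) x@nodeSum)

setMethod("show", "Montage", function(object) {
  h <- table(factor(object@hemisphere, c("left", "right", "midline")))
  cat(sprintf("Montage with %d channels (%d left / %d right / %d midline)\n",
              length(object@channels), h[["left"]], h[["right"]], h[["midline"]]))
  cat(sprintf("  neighbors: %s; flip map: %s\n",
              if (length(object@neighbors)) sprintf("%d edges", sum(object@neighbors) / 2L)
              else "not computed",
              if (length(object@flipMap)) "defined" else "undefined"))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              ncol(object@samples) / object@rate, nrow(object@annotations)))
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialSet '%s' (%s): %d trials x %d channels x %d samples @ %g Hz\n",
              object@subject, object@group, d[1L], d[2L], d[3L], object@rate))
  tab <- table(object@condition, object@limb)
  print(tab)
})

setMethod("show", "SpectralConnectivity", function(object) {
  cat(sprintf("SpectralConnectivity: %d channels, %d frequencies (%.1f-%.1f Hz)\n",
              dim(object@imcoh)[1L], length(object@freqs),
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "SFCResult", function(object) {
  cat(sprintf(
    "SFCResult: %d cluster(s), %d retained edge(s) on %d channel(s); alpha = %g, %d permutations%s\n",
    length(object@clusters), nrow(object@edges), sum(object@nodeSum != 0),
    object@alpha, object@nPermutations,
    if (isTRUE(object@exhaustive)) " (exhaustive)" else ""))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d nodes, %d links\n",
              nrow(object@adjacency), sum(object@adjacency) / 2L))
})

setMethod("show", "NetworkIndices", function(object) {
  cat(sprintf("NetworkIndices: Eglo = %.3f, Eloc = %.3f, SW = %.3f\n",
              object@eGlo, object@eLoc, object@sw))
  cat(sprintf("  Kinter = %.3f, Kintra(L) = %.3f, Kintra(R) = %.3f (%d random refs)\n",
              object@kInter, object@kIntraLeft, object@kIntraRight,
              object@nRandomRefs))
})
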