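# Accessor generics and show methods.

#' @rdname GenerationProfile-class
#' @param object a `GenerationProfile`.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname GenerationProfile-class
#' @export
setMethod("counts", "GenerationProfile", function(object) object@counts)

#' @rdname PeakModel-class
#' @param object a `PeakModel`.
#' @export
setGeneric("peakMu0", function(object) standardGeneric("peakMu0"))

#' @rdname PeakModel-class
#' @export
setMethod("peakMu0", "PeakModel", function(object) object@mu0)

#' @rdname PeakModel-class
#' @export
setGeneric("peakSigma", function(object) standardGeneric("peakSigma"))

#' @rdname PeakModel-class
#' @export
setMethod("peakSigma", "PeakModel", function(object) object@sigma)

#' @rdname PeakModel-class
#' @export
setGeneric("peakWeights", function(object) standardGeneric("peakWeights"))

#' @rdname PeakModel-class
#' @export
setMethod("peakWeights", "PeakModel", function(object) {
  stats::setNames(object@weights, paste0("g", seq_along(object@weights) - 1L))
})

#' @rdname PeakModel-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname PeakModel-class
#' @export
setMethod("isConverged", "PeakModel", function(object) object@converged)

#' @rdname PosteriorDraws-class
#' @param object a `PosteriorDraws`.
#' @export
setMethod("isConverged", "PosteriorDraws", function(object) object@converged)

#' @rdname PosteriorDraws-class
#' @export
setGeneric("drawsMatrix", function(object) standardGeneric("drawsMatrix"))

#' @rdname PosteriorDraws-class
#' @export
setMethod("drawsMatrix", "PosteriorDraws", function(object) object@draws)

#' @rdname PosteriorDraws-class
#' @export
setGeneric("splitRhat", function(object) standardGeneric("splitRhat"))

#' @rdname PosteriorDraws-class
#' @export
setMethod("splitRhat", "PosteriorDraws", function(object) object@rhat)

#' @rdname PosteriorSummary-class
#' @param object a `PosteriorSummary`.
#' @export
setGeneric("postMedian", function(object) standardGeneric("postMedian"))

#' @rdname PosteriorSummary-class
#' @export
setMethod("postMedian", "PosteriorSummary", function(object) object@median)

#' @rdname PosteriorSummary-class
#' @export
setGeneric("credInt", function(object) standardGeneric("credInt"))

#' @rdname PosteriorSummary-class
#' @export
setMethod("credInt", "PosteriorSummary", function(object) {
  c(lower = object@ciLow, upper = object@ciHigh)
})

#' @rdname PosteriorSummary-class
#' @export
setGeneric("fsr", function(object) standardGeneric("fsr"))

#' @rdname PosteriorSummary-class
#' @export
setMethod("fsr", "PosteriorSummary", function(object) object@fsr)

#' @rdname PosteriorSummary-class
#' @export
setGeneric("effectDraws", function(object) standardGeneric("effectDraws"))

#' @rdname PosteriorSummary-class
#' @export
setMethod("effectDraws", "PosteriorSummary", function(object) object@draws)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nDonors, "donors (",
      sum(object@dayAssignment == 2.5), "day-2.5 /",
      sum(object@dayAssignment == 3.5), "day-3.5 ),",
      object@cellsPerPopulation, "cells/population\n")
  cat("  dye: mu0 =", object@dyeMu0, ", sigma =", object@dyeSigma,
      "; donor/well logit SD =", object@donorSdLogit, "/", object@wellSdLogit, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "PeakModel", function(object) {
  cat(sprintf("PeakModel: gMax = %d, mu0 = %.4f, sigma = %.4f%s\n",
              object@gMax, object@mu0, object@sigma,
              if (object@converged) "" else " (NOT converged)"))
  print(round(peakWeights(object), 4))
})

setMethod("show", "GenerationProfile", function(object) {
  cat("GenerationProfile (", sum(object@counts), "cells ):\n")
  print(stats::setNames(object@counts, paste0("g", seq_along(object@counts) - 1L)))
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %d chains x %d kept (warmup %d), %d parameters\n",
              object@nChains, object@nKept, object@nWarmup, ncol(object@draws)))
  cat(sprintf("  kernel: %s; max split-Rhat = %.4f%s\n",
              paste(unique(object@kernel), collapse = "+"),
              suppressWarnings(max(object@rhat, na.rm = TRUE)),
              if (object@converged) "" else " (convergence warning)"))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("%s: median %.4g, 95%% CrI [%.4g, %.4g], FSR %.3g\n",
              object@label, object@median, object@ciLow, object@ciHigh, object@fsr))
})
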