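# Generics, accessors and show methods.

#' Number of source positions
#' @param x a [SourceSpace-class] or [LeadField-class].
#' @return integer count of source positions K.
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' @rdname nSources
setMethod("nSources", "SourceSpace", function(x) nrow(x@positions))

#' @rdname nSources
setMethod("nSources", "LeadField", function(x) ncol(x@matrix) %/% 3L)

#' Source or sensor coordinates in mm
#' @param x a [SourceSpace-class] or [SensorArray-class].
#' @return numeric n x 3 matrix of coordinates (mm).
#' @export
setGeneric("coordinatesMm", function(x) standardGeneric("coordinatesMm"))

#' @rdname coordinatesMm
setMethod("coordinatesMm", "SourceSpace", function(x) x@positions)

#' @rdname coordinatesMm
setMethod("coordinatesMm", "SensorArray", function(x) x@positions)

#' Lead field matrix accessor
#' @param x a [LeadField-class].
#' @return the m x 3K numeric matrix.
#' @export
setGeneric("leadMatrix", function(x) standardGeneric("leadMatrix"))

#' @rdname leadMatrix
setMethod("leadMatrix", "LeadField", function(x) x@matrix)

#' Measurement modality
#' @param x a [LeadField-class].
#' @return character modality tag.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname modality
setMethod("modality", "LeadField", function(x) x@modality)

#' Measurement vector accessor
#' @param x a [MeasurementSet-class].
#' @return numeric data vector.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname measurements
setMethod("measurements", "MeasurementSet", function(x) x@y)

#' Noise standard deviation on the normalized data scale
#' @param x a [MeasurementSet-class].
#' @return numeric scalar.
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))

#' @rdname noiseSigma
setMethod("noiseSigma", "MeasurementSet", function(x) x@sigma)

#' Final RAMUS estimate on the fine grid
#' @param x a [RamusResult-class] or [IASState-class].
#' @return numeric length-3K current-density vector.
#' @export
setGeneric("currentEstimate", function(x) standardGeneric("currentEstimate"))

#' @rdname currentEstimate
setMethod("currentEstimate", "RamusResult", function(x) x@xFinal)

#' @rdname currentEstimate
setMethod("currentEstimate", "IASState", function(x) x@x)

#' Per-decomposition normalized level means
#' @param x a [RamusResult-class].
#' @return numeric 3K x D matrix.
#' @export
setGeneric("decompositionEstimates",
           function(x) standardGeneric("decompositionEstimates"))

#' @rdname decompositionEstimates
setMethod("decompositionEstimates", "RamusResult",
          function(x) x@perDecomposition)

#' Objective history of an IAS run
#' @param x an [IASState-class].
#' @return numeric vector, joint negative log posterior after each
#'   half-step.
#' @export
setGeneric("objectiveHistory", function(x) standardGeneric("objectiveHistory"))

#' @rdname objectiveHistory
setMethod("objectiveHistory", "IASState", function(x) x@objective)

#' Resolution levels of a decomposition
#' @param x a [MultiresDecomposition-class].
#' @return list of [ResolutionLevel-class] objects, coarsest first.
#' @export
setGeneric("resolutionLevels",
           function(x) standardGeneric("resolutionLevels"))

#' @rdname resolutionLevels
setMethod("resolutionLevels", "MultiresDecomposition", function(x) x@levels)

setMethod("show", "HeadModel", function(object) {
  cat("HeadModel:", length(object@radii), "concentric layers\n")
  cat("  radii (mm):        ", paste(object@radii, collapse = ", "), "\n")
  cat("  conductivity (S/m):",
      paste(object@conductivities, collapse = ", "), "\n")
  cat("  series: degree <=", object@maxDegree,
      "| tail tol", object@seriesTol, "\n")
})

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d %ss at radius %.1f mm\n",
              nrow(object@positions), sub("_", " ", object@kind),
              object@radius))
})

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace: %d positions in shell [%.1f, %.1f] mm (3K = %d)\n",
              nrow(object@positions), object@rMin, object@rMax,
              3L * nrow(object@positions)))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField (%s, %s): %d sensors x %d components (%d positions)\n",
              object@modality, object@units, nrow(object@matrix),
              ncol(object@matrix), ncol(object@matrix) %/% 3L))
})

setMethod("show", "DipoleSource", function(object) {
  cat(sprintf(
    "DipoleSource: position (%.1f, %.1f, %.1f) mm, |q| = %g, dir (%.2f, %.2f, %.2f)\n",
    object@position[1], object@position[2], object@position[3],
    object@amplitude, object@direction[1], object@direction[2],
    object@direction[3]))
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet: m = %d, max|y| = %.3g, sigma = %.3g\n",
              length(object@y), max(abs(object@y)), object@sigma))
})

setMethod("show", "HyperpriorSpec", function(object) {
  cat(sprintf("HyperpriorSpec: %s(beta = %g, theta0 = %g)\n",
              object@family, object@beta, object@theta0))
})

setMethod("show", "IASState", function(object) {
  cat(sprintf(
    "IASState: 3K = %d, %d half-steps, final objective %.6g, max|x| = %.3g\n",
    length(object@x), length(object@objective),
    object@objective[length(object@objective)], max(abs(object@x))))
})

setMethod("show", "MultiresDecomposition", function(object) {
  kl <- vapply(object@levels, function(l) length(l@centers), integer(1))
  cat(sprintf("MultiresDecomposition: L = %d levels, s = %g, K_l = %s\n",
              length(object@levels), object@sparsity,
              paste(kl, collapse = " -> ")))
})

setMethod("show", "RamusConfig", function(object) {
  cat(sprintf(
    "RamusConfig: L = %d, s = %g, D = %d, %s(beta = %g, theta0 = %g), %d IAS iters%s\n",
    object@nLevels, object@sparsity, object@nDecompositions,
    object@hyperprior@family, object@hyperprior@beta,
    object@hyperprior@theta0, object@nIter,
    if (object@chain) "" else " [chaining off]"))
})

setMethod("show", "RamusResult", function(object) {
  cat(sprintf(
    "RamusResult: 3K = %d, D = %d decompositions, max|x| = %.3g\n",
    length(object@xFinal), ncol(object@perDecomposition),
    max(abs(object@xFinal))))
})

setMethod("show", "CaseConfig", function(object) {
  cat(sprintf(
    "Case (%s): %s, s = %g, D = %d, %s, amplitudes deep %g / superficial %g, %g%% noise, %d realizations%s\n",
    object@caseId, object@modality, object@sparsity,
    object@nDecompositions, object@hyperprior, object@deepAmplitude,
    object@superficialAmplitude, object@noisePct, object@nRealizations,
    if (object@scaleFactor < 1)
      sprintf(" [scaled x%g]", object@scaleFactor) else ""))
})
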