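#' @include AllClasses.R
NULL

#' Accessors for spectral containers
#'
#' `wavelengths()` returns the wavelength axis (nm); `spectra()` the
#' N x B intensity matrix of a SpectrumSet; `sampleIds()` the sample
#' identifiers; `perturbation()` the per-sample perturbation values (SOD
#' activity, U/mg); `modality()` the instrument tag; `cubeValues()` the
#' `[row, col, band]` array of a SpectralCube; `isCalibrated()` its
#' calibration flag.
#'
#' @param x a SpectrumSet, SpectralCube, DynamicSpectra or CorrelationMaps.
#' @return The slot contents; see Details per generic.
#' @name accessors
#' @aliases wavelengths spectra sampleIds perturbation modality cubeValues
#'   isCalibrated
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("perturbation", function(x) standardGeneric("perturbation"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' @rdname accessors
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' @rdname accessors
setMethod("wavelengths", "SpectrumSet", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "DynamicSpectra", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "PeakList", function(x) x@wavelengths)

#' @rdname accessors
setMethod("spectra", "SpectrumSet", function(x) x@X)

#' @rdname accessors
setMethod("sampleIds", "SpectrumSet", function(x) x@ids)
#' @rdname accessors
setMethod("sampleIds", "DynamicSpectra", function(x) x@ids)

#' @rdname accessors
setMethod("perturbation", "SpectrumSet", function(x) x@perturbation)
#' @rdname accessors
setMethod("perturbation", "DynamicSpectra", function(x) x@perturbation)

#' @rdname accessors
setMethod("modality", "SpectrumSet", function(x) x@modality)
#' @rdname accessors
setMethod("modality", "SpectralCube", function(x) x@modality)

#' @rdname accessors
setMethod("cubeValues", "SpectralCube", function(x) x@values)

#' @rdname accessors
setMethod("isCalibrated", "SpectralCube", function(x) x@calibrated)

#' Synchronous / asynchronous map accessors
#'
#' @param x a CorrelationMaps object.
#' @return `syncMatrix()` and `asyncMatrix()` return the B1 x B2 map; axis
#'   wavelengths via `mapAxes()` as a list `list(wl1, wl2)`.
#' @export
setGeneric("syncMatrix", function(x) standardGeneric("syncMatrix"))
#' @rdname syncMatrix
#' @export
setGeneric("asyncMatrix", function(x) standardGeneric("asyncMatrix"))
#' @rdname syncMatrix
#' @export
setGeneric("mapAxes", function(x) standardGeneric("mapAxes"))

#' @rdname syncMatrix
setMethod("syncMatrix", "CorrelationMaps", function(x) x@sync)
#' @rdname syncMatrix
setMethod("asyncMatrix", "CorrelationMaps", function(x) x@async)
#' @rdname syncMatrix
setMethod("mapAxes", "CorrelationMaps",
          function(x) list(wl1 = x@wl1, wl2 = x@wl2))

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet [%s]: %d samples x %d bands (%.4g-%.4g nm)\n",
              object@modality, nrow(object@X), ncol(object@X),
              min(object@wavelengths), max(object@wavelengths)))
  pp <- object@provenance$preprocess
  if (!is.null(pp)) cat("  preprocess:", pp, "\n")
  if (nrow(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "SpectralCube [%s]: %d x %d pixels, %d bands (%.4g-%.4g nm), %s\n",
    object@modality, d[1], d[2], d[3],
    min(object@wavelengths), max(object@wavelengths),
    if (object@calibrated) "calibrated" else "raw"))
})

setMethod("show", "DynamicSpectra", function(object) {
  cat(sprintf(
    "DynamicSpectra [%s]: %d perturbation points x %d bands\n",
    object@modality, nrow(object@Y), ncol(object@Y)))
})

setMethod("show", "CorrelationMaps", function(object) {
  cat(sprintf("CorrelationMaps (%s): %d x %d grid, n = %d\n",
              if (object@hetero) "heterogeneous" else "homogeneous",
              nrow(object@sync), ncol(object@sync), object@n))
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: %d sensitive peaks", length(object@wavelengths)))
  if (!is.na(object@sourceSlice))
    cat(sprintf(" (slice at %.4g nm)", object@sourceSlice))
  cat("\n")
  if (length(object@wavelengths))
    cat(" ", paste(round(object@wavelengths, 1), collapse = ", "), "nm\n")
})

setMethod("show", "TransferPlan", function(object) {
  cat(sprintf("TransferPlan: %s -> %s, %d band pairs, strategy %s\n",
              object@sourceModality, object@targetModality,
              length(object@sourceBands), object@strategy))
})

setMethod("show", "ActivityMap", function(object) {
  cat(sprintf("ActivityMap [%s]: %d x %d pixels, %.4g-%.4g U/mg\n",
              object@modality, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d treatments x %d stages x %d plants = %d samples\n",
    length(object@treatments), length(object@stages),
    object@nPlantsPerCell,
    length(object@treatments) * length(object@stages) *
      object@nPlantsPerCell))
  cat(sprintf("  micro: %d bands; macro: %d bands; seed %d\n",
              length(object@microGrid), length(object@macroGrid),
              object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d paired samples, %d micro / %d macro bands, %d+%d cubes\n",
    length(object@sod), ncol(object@micro@X), ncol(object@macro@X),
    length(object@microCubes), length(object@macroCubes)))
})

#' Coerce a PeakList to a data.frame
#'
#' @param x a PeakList.
#' @param ... ignored.
#' @return data.frame with columns `wavelength` and `intensity`.
#' @export
as.data.frame.PeakList <- function(x, ...) {
  data.frame(wavelength = x@wavelengths, intensity = x@intensities)
}
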