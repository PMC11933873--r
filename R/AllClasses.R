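#' @import methods
NULL

setClassUnion("numericOrArray", c("numeric", "matrix", "array"))

#' SpectrumSet: a set of per-sample spectra under one modality
#'
#' Container for N samples by B bands of reflectance (or a derived quantity
#' such as a first-derivative spectrum), together with the wavelength axis,
#' a per-sample perturbation value (SOD activity in U/mg, or a treatment
#' code) and optional sample metadata.
#'
#' @slot ids character, sample identifiers (length N, unique).
#' @slot X numeric matrix, N x B; row i is the spectrum of sample `ids[i]`.
#' @slot wavelengths numeric, length B, strictly increasing, nm.
#' @slot perturbation numeric, length N; the external disturbance variable
#'   ordering samples for correlation analysis (typically SOD activity).
#' @slot modality character, `"micro"` or `"macro"`.
#' @slot meta data.frame with N rows of optional sample covariates
#'   (e.g. `treatment`, `stage`); zero-row data.frame when absent.
#' @slot provenance list recording preprocessing applied and other history.
#' @export
setClass("SpectrumSet",
  slots = c(
    ids = "character",
    X = "matrix",
    wavelengths = "numeric",
    perturbation = "numeric",
    modality = "character",
    meta = "data.frame",
    provenance = "list"
  ),
  prototype = prototype(meta = data.frame(), provenance = list())
)

setValidity("SpectrumSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (nrow(object@X) != n)
    msg <- c(msg, "nrow(X) must equal length(ids)")
  if (length(object@perturbation) != n)
    msg <- c(msg, "length(perturbation) must equal length(ids)")
  if (ncol(object@X) != length(object@wavelengths))
    msg <- c(msg, "ncol(X) must equal length(wavelengths)")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "sample ids must be unique")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(object@modality) != 1)
    msg <- c(msg, "modality must be a single string")
  if (nrow(object@meta) && nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per sample (or zero rows)")
  if (length(msg)) msg else TRUE
})

#' SpectralCube: a hyperspectral image cube
#'
#' A 3-D reflectance (or raw counts) array indexed `[row, col, band]` with
#' its wavelength axis, modality tag and a calibration flag.
#'
#' @slot values numeric 3-D array, `[row, col, band]`, finite.
#' @slot wavelengths numeric, strictly increasing, length = band count, nm.
#' @slot modality character, `"micro"` or `"macro"`.
#' @slot calibrated logical; `TRUE` after black/white reflectance calibration.
#' @slot metadata list; free-form acquisition metadata (exposure, gain,
#'   scan speed, planted truth fields for synthetic cubes, ...).
#' @export
setClass("SpectralCube",
  slots = c(
    values = "array",
    wavelengths = "numeric",
    modality = "character",
    calibrated = "logical",
    metadata = "list"
  ),
  prototype = prototype(calibrated = FALSE, metadata = list())
)

setValidity("SpectralCube", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3)
    msg <- c(msg, "values must be a 3-D array [row, col, band]")
  else if (d[3] != length(object@wavelengths))
    msg <- c(msg, "third dimension of values must match length(wavelengths)")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' CalibrationFrames: dark and white reference frames
#'
#' Holds the dark-current (shutter closed) and white-reference frames used
#' for reflectance calibration, R = (R0 - D) / (W - D). Either frame may be
#' a full `[row, col, band]` array matching the target cube, or a per-band
#' vector (a row-averaged reference) that is broadcast across pixels.
#'
#' @slot dark numeric vector (per band) or array (full frame), counts.
#' @slot white numeric vector or array, counts; `white - dark` must be
#'   nonzero everywhere it is used as a divisor.
#' @export
setClass("CalibrationFrames",
  slots = c(dark = "numericOrArray", white = "numericOrArray"))

#' DynamicSpectra: perturbation-ordered, reference-subtracted spectra
#'
#' The dynamic spectrum of 2D-COS: samples sorted by the perturbation
#' variable and centred by a reference spectrum (by default the mean
#' spectrum), so each column traces one band's excursion along the
#' perturbation sequence.
#'
#' @slot Y numeric matrix, N x B, centred intensities.
#' @slot wavelengths numeric, nm.
#' @slot perturbation numeric, length N, sorted ascending.
#' @slot reference numeric, length B, the reference spectrum subtracted.
#' @slot ids character, sample ids in perturbation order.
#' @slot modality character.
#' @export
setClass("DynamicSpectra",
  slots = c(
    Y = "matrix",
    wavelengths = "numeric",
    perturbation = "numeric",
    reference = "numeric",
    ids = "character",
    modality = "character"
  )
)

setValidity("DynamicSpectra", function(object) {
  msg <- character()
  if (nrow(object@Y) < 3)
    msg <- c(msg, "at least 3 perturbation points are required")
  if (ncol(object@Y) != length(object@wavelengths))
    msg <- c(msg, "ncol(Y) must equal length(wavelengths)")
  if (length(object@perturbation) != nrow(object@Y))
    msg <- c(msg, "length(perturbation) must equal nrow(Y)")
  if (is.unsorted(object@perturbation))
    msg <- c(msg, "perturbation must be sorted ascending")
  if (length(object@reference) != ncol(object@Y))
    msg <- c(msg, "length(reference) must equal ncol(Y)")
  if (length(msg)) msg else TRUE
})

#' CorrelationMaps: synchronous and asynchronous 2D correlation maps
#'
#' The synchronous map Phi and asynchronous map Psi on a (v1, v2)
#' wavelength grid. For a homogeneous analysis both axes are the same
#' instrument and Phi is symmetric / Psi antisymmetric; for a heterogeneous
#' (cross-instrument) analysis the axes belong to the two modalities.
#'
#' @slot sync numeric matrix, B1 x B2, synchronous intensities.
#' @slot async numeric matrix, B1 x B2, asynchronous intensities.
#' @slot wl1 numeric, wavelength axis of the first (row) dimension, nm.
#' @slot wl2 numeric, wavelength axis of the second (column) dimension, nm.
#' @slot hetero logical; TRUE when the two axes are different instruments.
#' @slot n integer, number of perturbation points used.
#' @slot provenance list (modalities, preprocessing, reference convention).
#' @export
setClass("CorrelationMaps",
  slots = c(
    sync = "matrix",
    async = "matrix",
    wl1 = "numeric",
    wl2 = "numeric",
    hetero = "logical",
    n = "integer",
    provenance = "list"
  ),
  prototype = prototype(provenance = list())
)

setValidity("CorrelationMaps", function(object) {
  msg <- character()
  if (!all(dim(object@sync) == c(length(object@wl1), length(object@wl2))))
    msg <- c(msg, "dim(sync) must be length(wl1) x length(wl2)")
  if (!all(dim(object@async) == dim(object@sync)))
    msg <- c(msg, "sync and async must have identical dimensions")
  if (!object@hetero) {
    if (!isTRUE(all.equal(object@wl1, object@wl2)))
      msg <- c(msg, "homogeneous maps require wl1 == wl2")
    else {
      sc <- max(abs(object@sync), 1e-300)
      if (max(abs(object@sync - t(object@sync))) > 1e-8 * sc)
        msg <- c(msg, "homogeneous sync map must be symmetric")
      sa <- max(abs(object@async), sc * 1e-12)
      if (max(abs(object@async + t(object@async))) > 1e-8 * max(sa, sc))
        msg <- c(msg, "homogeneous async map must be antisymmetric")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PeakList: sensitive wavelengths extracted from a correlation slice
#'
#' @slot wavelengths numeric, sorted ascending, nm.
#' @slot intensities numeric, slice magnitudes at the peaks.
#' @slot sourceSlice numeric, the wavelength (nm) at which the slice was
#'   taken, or NA when not slice-derived.
#' @slot exclusions list with elements `edge_bands` and `max_wavelength`
#'   recording the masking applied during selection.
#' @export
setClass("PeakList",
  slots = c(
    wavelengths = "numeric",
    intensities = "numeric",
    sourceSlice = "numeric",
    exclusions = "list"
  ),
  prototype = prototype(sourceSlice = NA_real_, exclusions = list())
)

setValidity("PeakList", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@intensities))
    msg <- c(msg, "wavelengths and intensities must have equal length")
  if (is.unsorted(object@wavelengths, strictly = TRUE) &&
      length(object@wavelengths) > 1)
    msg <- c(msg, "peak wavelengths must be sorted strictly ascending")
  if (length(msg)) msg else TRUE
})

#' TransferPlan: sensitive-band pairing between modalities
#'
#' An ordered pairing of source-modality and target-modality sensitive
#' wavelengths, plus the transfer strategy used to carry a model trained
#' on the source bands over to the target bands.
#'
#' @slot sourceModality,targetModality character.
#' @slot sourceBands,targetBands numeric, nm, equal length; `sourceBands[i]`
#'   is paired with `targetBands[i]`.
#' @slot strategy character, one of `"feature_frozen_finetune"`,
#'   `"full_finetune"`, `"zero_shot"`.
#' @slot nTargetLabels integer, number of labelled target samples used for
#'   fine-tuning (ignored for zero-shot).
#' @slot dropped list of unmatched peaks dropped during greedy pairing.
#' @export
setClass("TransferPlan",
  slots = c(
    sourceModality = "character",
    targetModality = "character",
    sourceBands = "numeric",
    targetBands = "numeric",
    strategy = "character",
    nTargetLabels = "integer",
    dropped = "list"
  ),
  prototype = prototype(strategy = "feature_frozen_finetune",
                        nTargetLabels = NA_integer_, dropped = list())
)

setValidity("TransferPlan", function(object) {
  msg <- character()
  if (length(object@sourceBands) != length(object@targetBands))
    msg <- c(msg, "sourceBands and targetBands must have equal length")
  if (!object@strategy %in%
      c("feature_frozen_finetune", "full_finetune", "zero_shot"))
    msg <- c(msg, "unknown transfer strategy")
  if (length(msg)) msg else TRUE
})

#' ActivityMap: pixel-wise predicted SOD activity
#'
#' @slot values numeric matrix, predicted activity (U/mg) per pixel; shape
#'   equals the source cube's spatial shape.
#' @slot modality character.
#' @slot provenance list (model id, preprocessing, band selection).
#' @export
setClass("ActivityMap",
  slots = c(values = "matrix", modality = "character", provenance = "list"),
  prototype = prototype(provenance = list())
)

setValidity("ActivityMap", function(object) {
  if (!all(is.finite(object@values))) "values must be finite" else TRUE
})

#' GeneratorConfig: study design for the synthetic paired-modality generator
#'
#' Encodes the salt-stress experiment the generator emulates: four NaCl
#' treatments (0/1/2/3 g/L) crossed with three growth stages, SOD activity
#' increasing with both concentration and stage, and two instruments with
#' deliberately different wavelength grids carrying SOD-proportional
#' absorption features at their sensitive bands.
#'
#' @slot nPlantsPerCell integer, plants per treatment (each observed at all
#'   stages); the default 27 yields 27 x 4 x 3 = 324 spectra.
#' @slot treatments numeric, salt concentrations g/L.
#' @slot stages character, growth stage codes, ordinal.
#' @slot microGrid,macroGrid numeric, wavelength axes nm.
#' @slot sensitiveBandsMicro,sensitiveBandsMacro numeric, planted band
#'   centres nm.
#' @slot effectSizeMicro,effectSizeMacro numeric, signed reflectance change
#'   per U/mg at each planted band (recycled to the band count); negative
#'   values plant dips, positive plant bumps.
#' @slot sodBase,sodConcSlope,sodStageSlope numeric, U/mg and U/mg per unit.
#' @slot sodNoiseSd numeric, sd of the per-sample label noise, U/mg.
#' @slot noiseSd numeric, sd of i.i.d. reflectance noise.
#' @slot driftSd numeric, amplitude sd of per-sample smooth broad-band
#'   baseline clutter (illumination/scattering variation).
#' @slot nCubes integer, cubes generated per modality (first samples).
#' @slot cubeSize integer, cube spatial side length in pixels.
#' @slot seed integer.
#' @export
setClass("GeneratorConfig",
  slots = c(
    nPlantsPerCell = "integer",
    treatments = "numeric",
    stages = "character",
    microGrid = "numeric",
    macroGrid = "numeric",
    sensitiveBandsMicro = "numeric",
    sensitiveBandsMacro = "numeric",
    effectSizeMicro = "numeric",
    effectSizeMacro = "numeric",
    sodBase = "numeric",
    sodConcSlope = "numeric",
    sodStageSlope = "numeric",
    sodNoiseSd = "numeric",
    noiseSd = "numeric",
    driftSd = "numeric",
    nCubes = "integer",
    cubeSize = "integer",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  chkGrid <- function(g, nm) {
    if (length(g) < 2 || any(diff(g) <= 0))
      paste(nm, "must be strictly increasing with >= 2 bands")
    else character()
  }
  msg <- c(msg, chkGrid(object@microGrid, "microGrid"),
           chkGrid(object@macroGrid, "macroGrid"))
  if (any(object@treatments < 0))
    msg <- c(msg, "treatments (salt g/L) must be non-negative")
  if (object@noiseSd < 0 || object@sodNoiseSd < 0 || object@driftSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  chkBands <- function(b, g, nm) {
    if (length(b) < 1) return(paste(nm, "must contain at least one band"))
    if (any(b < min(g) | b > max(g)))
      return(paste(nm, "must lie inside its modality's grid range"))
    character()
  }
  msg <- c(msg,
    chkBands(object@sensitiveBandsMicro, object@microGrid,
             "sensitiveBandsMicro"),
    chkBands(object@sensitiveBandsMacro, object@macroGrid,
             "sensitiveBandsMacro"))
  if (object@nPlantsPerCell < 1) msg <- c(msg, "nPlantsPerCell must be >= 1")
  if (object@cubeSize < 2) msg <- c(msg, "cubeSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: a generated paired micro/macro dataset
#'
#' @slot micro,macro SpectrumSet with identical sample ids in identical
#'   order (one leaf, two instruments).
#' @slot microCubes,macroCubes list of SpectralCube for the first
#'   `nCubes` samples; each carries its planted pixel-level activity field
#'   in `metadata$sod_field`.
#' @slot sod numeric, per-sample activity U/mg.
#' @slot truth data.frame of planted bands: modality, wavelength, effect.
#' @slot config GeneratorConfig used.
#' @export
setClass("SyntheticDataset",
  slots = c(
    micro = "SpectrumSet",
    macro = "SpectrumSet",
    microCubes = "list",
    macroCubes = "list",
    sod = "numeric",
    truth = "data.frame",
    config = "GeneratorConfig"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (!identical(object@micro@ids, object@macro@ids))
    msg <- c(msg, "micro and macro must share identical sample ids in order")
  if (length(object@sod) != length(object@micro@ids))
    msg <- c(msg, "sod must have one value per sample")
  if (length(msg)) msg else TRUE
})
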