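#' @include regressor.R twodcos.R
NULL

#' Pair sensitive bands of two modalities
#'
#' When both peak lists have the same length the i-th source peak (in
#' ascending wavelength) is paired with the i-th target peak -- rank-order
#' pairing, since cross-instrument sensitive peaks need not be nearest
#' neighbours in wavelength. With unequal lengths, greedy
#' nearest-wavelength matching is used and unmatched peaks are dropped
#' with a message.
#'
#' @param sourcePeaks,targetPeaks [PeakList-class] objects (non-empty).
#' @param sourceModality,targetModality instrument tags recorded in the
#'   plan.
#' @param strategy transfer strategy; see [TransferPlan-class].
#' @param nTargetLabels labelled target samples for fine-tuning; `NA`
#'   defers to the default fraction in [transferModel()].
#' @return A [TransferPlan-class].
#' @export
pairBands <- function(sourcePeaks, targetPeaks,
                      sourceModality = "micro", targetModality = "macro",
                      strategy = "feature_frozen_finetune",
                      nTargetLabels = NA_integer_) {
  sw <- if (is(sourcePeaks, "PeakList")) sourcePeaks@wavelengths
        else as.numeric(sourcePeaks)
  tw <- if (is(targetPeaks, "PeakList")) targetPeaks@wavelengths
        else as.numeric(targetPeaks)
  if (!length(sw) || !length(tw))
    stop("both peak lists must be non-empty")
  sw <- sort(sw); tw <- sort(tw)
  dropped <- list()
  if (length(sw) == length(tw)) {
    src <- sw; tgt <- tw
  } else {
    k <- min(length(sw), length(tw))
    srcLeft <- sw; tgtLeft <- tw
    src <- tgt <- numeric(0)
    for (step in seq_len(k)) {
      dmat <- abs(outer(srcLeft, tgtLeft, "-"))
      hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      src <- c(src, srcLeft[hit[1]]); tgt <- c(tgt, tgtLeft[hit[2]])
      srcLeft <- srcLeft[-hit[1]]; tgtLeft <- tgtLeft[-hit[2]]
    }
    ord <- order(src)
    src <- src[ord]; tgt <- tgt[ord]
    dropped <- list(source = srcLeft, target = tgtLeft)
    nd <- length(srcLeft) + length(tgtLeft)
    message(sprintf("%d unmatched peak(s) dropped during greedy pairing",
                    nd))
  }
  new("TransferPlan", sourceModality = sourceModality,
      targetModality = targetModality,
      sourceBands = src, targetBands = tgt,
      strategy = strategy, nTargetLabels = as.integer(nTargetLabels),
      dropped = dropped)
}

#' Restrict a SpectrumSet to selected bands
#'
#' Each requested wavelength is snapped to the nearest grid band
#' (half-way ties snap downward); duplicates after snapping are collapsed
#' with a warning. The returned columns are in ascending wavelength order
#' (the container's invariant).
#'
#' @param set a [SpectrumSet-class].
#' @param bands numeric wavelengths, nm, within the grid range.
#' @return A SpectrumSet with `length(unique(snapped))` bands.
#' @export
subsetToBands <- function(set, bands) {
  stopifnot(is(set, "SpectrumSet"))
  grid <- set@wavelengths
  if (any(bands < min(grid) | bands > max(grid)))
    stop(sprintf("requested band(s) outside grid range [%.4g, %.4g] nm",
                 min(grid), max(grid)))
  idx <- vapply(bands, function(b) which(abs(grid - b) ==
                                           min(abs(grid - b)))[1],
                integer(1))
  if (anyDuplicated(idx)) {
    warning("duplicate bands after snapping collapsed")
    idx <- unique(idx)
  }
  set[, sort(idx)]
}

#' Transfer a trained model to another modality's sensitive bands
#'
#' Carries a CNN-LSTM trained on the source modality's sensitive bands
#' over to the paired target-modality bands.
#' Strategies: `"feature_frozen_finetune"` (default) copies all weights,
#' freezes the convolutional feature extractor and fine-tunes the LSTM
#' and dense layers on a small number of labelled target samples;
#' `"full_finetune"` fine-tunes everything; `"zero_shot"` copies the
#' model untouched (bitwise-identical predictions on identical input).
#' For the fine-tuning strategies the per-band input standardization is
#' re-estimated from the (unlabelled) target calibration spectra, since
#' the two instruments sit on different reflectance scales; the target
#' scale of the activity output is kept from the source model.
#'
#' @param sourceModel a trained `cnnLSTM` whose input width equals the
#'   number of band pairs in `plan`.
#' @param plan a [TransferPlan-class].
#' @param targetCal target-modality calibration [SpectrumSet-class];
#'   restricted to `plan@targetBands` automatically if wider.
#' @param cfg [trainConfig()] for fine-tuning (epochs, lr, seed).
#' @param fineTuneFraction fraction of `targetCal` used as labelled
#'   fine-tuning samples when `plan@nTargetLabels` is `NA` (default
#'   0.25, the small-label regime motivating transfer).
#' @return A `cnnLSTM` accepting target-modality sensitive-band input.
#' @export
transferModel <- function(sourceModel, plan, targetCal,
                          cfg = trainConfig(), fineTuneFraction = 0.25) {
  stopifnot(inherits(sourceModel, "cnnLSTM"), is(plan, "TransferPlan"),
            is(targetCal, "SpectrumSet"))
  width <- length(plan@targetBands)
  if (sourceModel$arch$inputBands != width)
    stop(sprintf(
      "plan has %d band pairs but the source model consumes %d bands",
      width, sourceModel$arch$inputBands))
  if (ncol(targetCal@X) != width)
    targetCal <- subsetToBands(targetCal, plan@targetBands)
  model <- sourceModel
  model$transfer <- list(plan = list(
    source = plan@sourceBands, target = plan@targetBands,
    strategy = plan@strategy))
  if (plan@strategy == "zero_shot")
    return(model)
  nLab <- plan@nTargetLabels
  if (is.na(nLab))
    nLab <- max(2L, round(fineTuneFraction * nrow(targetCal@X)))
  if (nLab == 0)
    stop("nTargetLabels = 0: no labelled target samples; use the ",
         "zero_shot strategy instead")
  # re-anchor the input standardization on the target instrument
  model$scaling$xMean <- colMeans(targetCal@X)
  pooled <- max(sqrt(mean(apply(targetCal@X, 2, stats::var))), 1e-12)
  model$scaling$xSd <- rep(pooled, ncol(targetCal@X))
  model$wavelengths <- targetCal@wavelengths
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  labIdx <- sort(sample.int(nrow(targetCal@X), min(nLab,
                                                   nrow(targetCal@X))))
  frozen <- if (plan@strategy == "feature_frozen_finetune") "conv"
            else character()
  trainModel(model, targetCal[labIdx, ], cfg, frozen = frozen)
}

#' Evaluate a transferred model on the target prediction set
#'
#' @param model a `cnnLSTM` returned by [transferModel()].
#' @param targetPred target-modality prediction [SpectrumSet-class]
#'   (restricted to the plan's target bands automatically if the model's
#'   transfer plan is attached and the set is wider).
#' @return An `evalMetrics` with split `"prediction/target-modality"`.
#' @export
evaluateTransfer <- function(model, targetPred) {
  stopifnot(inherits(model, "cnnLSTM"))
  if (ncol(targetPred@X) != model$arch$inputBands &&
      !is.null(model$transfer))
    targetPred <- subsetToBands(targetPred, model$transfer$plan$target)
  evaluateModel(model, targetPred, split = "prediction/target-modality")
}

#' Pixel-wise SOD activity map of a hyperspectral cube
#'
#' Every pixel spectrum is preprocessed, restricted to the model's bands
#' and fed through the model, yielding a per-pixel activity prediction.
#'
#' @param cube a calibrated [SpectralCube-class].
#' @param model a trained `cnnLSTM`.
#' @param method pretreatment applied to the pixel spectra before band
#'   selection (see [preprocessSpectra()]).
#' @param bands numeric wavelengths the model consumes, or `NULL` for the
#'   full grid.
#' @param window,polyorder,baselineOrder pretreatment parameters.
#' @return An [ActivityMap-class] with the cube's spatial shape.
#' @export
predictMap <- function(cube, model, method = "none", bands = NULL,
                       window = 7, polyorder = 2, baselineOrder = 2) {
  stopifnot(is(cube, "SpectralCube"), inherits(model, "cnnLSTM"))
  if (!cube@calibrated)
    stop("cube must be reflectance-calibrated before prediction")
  d <- dim(cube@values)
  flat <- matrix(cube@values, d[1] * d[2], d[3])
  px <- spectrumSet(flat, cube@wavelengths, modality = cube@modality)
  px <- preprocessSpectra(px, method, window = window,
                          polyorder = polyorder,
                          baselineOrder = baselineOrder)
  if (!is.null(bands)) px <- subsetToBands(px, bands)
  pred <- predictActivity(model, px)
  new("ActivityMap", values = matrix(pred, d[1], d[2]),
      modality = cube@modality,
      provenance = list(preprocess = method, bands = bands))
}

#' Render an activity map as a PNG
#'
#' Values are mapped onto a fixed blue-to-red colour ramp (low to high
#' activity). Passing the same `range` to several maps renders them on a
#' shared value scale so their colours are comparable across a figure
#' set.
#'
#' @param map an [ActivityMap-class].
#' @param path output PNG path.
#' @param range numeric length-2 value range anchoring the colour scale;
#'   defaults to the map's own range. Values outside are clipped.
#' @return `path`, invisibly.
#' @export
writeActivityMap <- function(map, path, range = NULL) {
  stopifnot(is(map, "ActivityMap"))
  v <- map@values
  if (is.null(range)) range <- base::range(v)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  u <- pmin(pmax((v - range[1]) / diff(range), 0), 1)
  ramp <- grDevices::colorRamp(c("#0000FF", "#00FFFF", "#FFFF00",
                                 "#FF0000"))
  rgb <- ramp(as.vector(u)) / 255
  img <- array(0, dim = c(nrow(v), ncol(v), 3))
  img[, , 1] <- matrix(rgb[, 1], nrow(v))
  img[, , 2] <- matrix(rgb[, 2], nrow(v))
  img[, , 3] <- matrix(rgb[, 3], nrow(v))
  png::writePNG(img, path)
  invisible(path)
}
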