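#' @include nn-core.R hsi-io.R
NULL

#' Subset samples / bands of a SpectrumSet
#'
#' @param x a [SpectrumSet-class].
#' @param i sample index (integer, logical or character ids).
#' @param j band index.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @return A SpectrumSet.
#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@X))
  if (is.character(i)) i <- match(i, x@ids)
  if (missing(j)) j <- seq_len(ncol(x@X))
  initialize(x,
    ids = x@ids[i],
    X = x@X[i, j, drop = FALSE],
    wavelengths = x@wavelengths[j],
    perturbation = x@perturbation[i],
    meta = if (nrow(x@meta)) x@meta[i, , drop = FALSE] else x@meta)
})

#' CNN-LSTM architecture specification
#'
#' The architecture: input spectra treated as 1 x B data matrices pass
#' through conv blocks (1x2 kernel, stride 2, ReLU, 1x2 max-pool) with
#' 32/64/128 filters by default, then the flattened conv output is read
#' by an LSTM as a sequence over the reduced band axis (filters as
#' features), whose final state feeds a ReLU dense layer and a single
#' linear regression output. Kernel size and stride are fixed at 1x2 / 2.
#'
#' @param convFilters integer vector of filter counts per block.
#' @param lstmUnits LSTM hidden width.
#' @param denseUnits dense layer width.
#' @param seed integer, parameter initialization seed.
#' @return list of class `modelSpec`.
#' @export
modelSpec <- function(convFilters = c(32L, 64L, 128L), lstmUnits = 64L,
                      denseUnits = 32L, seed = 1L) {
  stopifnot(length(convFilters) >= 1, all(convFilters >= 1),
            lstmUnits >= 1, denseUnits >= 1)
  structure(list(convFilters = as.integer(convFilters),
                 lstmUnits = as.integer(lstmUnits),
                 denseUnits = as.integer(denseUnits),
                 seed = as.integer(seed)),
            class = "modelSpec")
}

#' Training configuration
#'
#' @param epochs passes over the calibration set.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param splitFraction calibration fraction for [splitDataset()].
#' @param seed RNG seed for splitting and batch shuffling.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 300L, batchSize = 16L,
                        learningRate = 1e-3, optimizer = "adam",
                        splitFraction = 0.75, seed = 42L) {
  stopifnot(epochs >= 1, batchSize >= 1,
            splitFraction > 0, splitFraction < 1,
            identical(optimizer, "adam"))
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, optimizer = optimizer,
                 splitFraction = splitFraction, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Build an (untrained) CNN-LSTM model
#'
#' Blocks that the band axis cannot support are dropped automatically: a
#' block is applied only while at least 4 band positions remain (each
#' block divides the axis by four), and the realized depth is recorded in
#' the model summary. Fewer than 8 input bands cannot support the default
#' three-block specification and raise an error suggesting a reduced
#' `convFilters`.
#'
#' @param spec a [modelSpec()].
#' @param inputBands number of spectral bands the model consumes.
#' @return list of class `cnnLSTM` (untrained): parameters, architecture
#'   summary, and empty scaling/history slots.
#' @export
buildModel <- function(spec = modelSpec(), inputBands) {
  stopifnot(inherits(spec, "modelSpec"))
  inputBands <- as.integer(inputBands)
  if (inputBands < 8 && length(spec$convFilters) >= 3)
    stop("inputBands < 8 cannot support three conv blocks; ",
         "use modelSpec() with fewer convFilters")
  if (inputBands < 4)
    stop("at least 4 input bands are required for one conv block")
  lens <- .planBlocks(inputBands, spec$convFilters)
  nBlocks <- length(lens)
  if (nBlocks < length(spec$convFilters))
    message(sprintf(
      "band axis supports %d of %d conv blocks; depth auto-reduced",
      nBlocks, length(spec$convFilters)))
  arch <- list(nBlocks = nBlocks,
               filters = spec$convFilters[seq_len(nBlocks)],
               lens = lens,
               lstmUnits = spec$lstmUnits,
               denseUnits = spec$denseUnits,
               inputBands = inputBands)
  params <- .initParams(arch, spec$seed)
  structure(list(spec = spec, arch = arch, params = params,
                 scaling = NULL, wavelengths = NULL,
                 trained = FALSE, history = NULL),
            class = "cnnLSTM")
}

#' @export
print.cnnLSTM <- function(x, ...) {
  a <- x$arch
  seqLen <- if (a$nBlocks) a$lens[[a$nBlocks]][["pool"]] else a$inputBands
  cat(sprintf(
    "CNN-LSTM: %d bands -> %d conv block(s) [%s filters] -> LSTM(%d) over %d steps -> dense(%d) -> 1\n",
    a$inputBands, a$nBlocks, paste(a$filters, collapse = "/"),
    a$lstmUnits, seqLen, a$denseUnits))
  cat(if (x$trained) sprintf("  trained, final loss %.6g\n",
                             utils::tail(x$history$loss, 1))
      else "  untrained\n")
  invisible(x)
}

#' Stratified calibration / prediction split
#'
#' Splits samples into disjoint calibration and prediction sets,
#' stratified by treatment x stage when those metadata columns are
#' present (largest-remainder allocation per stratum, so a fraction of
#' 0.75 on 108 samples yields exactly 81/27); strata smaller than 2
#' trigger a warning and a plain random split. Reproducible from the
#' config seed.
#'
#' @param set a [SpectrumSet-class] with at least 8 samples.
#' @param cfg a [trainConfig()] (uses `splitFraction` and `seed`).
#' @return list with elements `calibration` and `prediction`.
#' @export
splitDataset <- function(set, cfg = trainConfig()) {
  stopifnot(is(set, "SpectrumSet"))
  n <- nrow(set@X)
  if (n < 8) stop("at least 8 samples are required to split")
  f <- cfg$splitFraction
  stratCols <- intersect(c("treatment", "stage"), names(set@meta))
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  strata <- if (length(stratCols))
    interaction(set@meta[stratCols], drop = TRUE)
  else factor(rep(1, n))
  if (length(stratCols) && min(table(strata)) < 2) {
    warning("a stratum has fewer than 2 samples; falling back to a ",
            "plain random split")
    strata <- factor(rep(1, n))
  }
  total <- round(n * f)
  sizes <- table(strata)
  exact <- as.numeric(sizes) * f
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(exact - base)[seq_len(-rem)]
    base[cut] <- pmax(base[cut] - 1, 0)
  }
  calIdx <- unlist(lapply(seq_along(levels(strata)), function(k) {
    idx <- which(strata == levels(strata)[k])
    sample(idx, min(base[k], length(idx)))
  }), use.names = FALSE)
  calIdx <- sort(calIdx)
  predIdx <- setdiff(seq_len(n), calIdx)
  list(calibration = set[calIdx, ], prediction = set[predIdx, ])
}

#' Train a CNN-LSTM on a calibration set
#'
#' Minimizes mean squared error with Adam on standardized inputs and
#' targets (per-band z-scores and target z-scores computed from the
#' calibration set and stored in the model; predictions are returned on
#' the original U/mg scale). Deterministic given the config seed under
#' single-threaded BLAS. Training diverging to NaN raises an error
#' reporting the last finite epoch.
#'
#' @param model an untrained (or to-be-continued) `cnnLSTM` from
#'   [buildModel()].
#' @param calibration a [SpectrumSet-class]; `perturbation` holds the
#'   targets (U/mg).
#' @param cfg a [trainConfig()].
#' @param frozen character vector of parameter-name prefixes excluded
#'   from updates (e.g. `"conv"` to freeze all conv blocks).
#' @return The trained `cnnLSTM` with per-epoch loss history.
#' @export
trainModel <- function(model, calibration, cfg = trainConfig(),
                       frozen = character()) {
  stopifnot(inherits(model, "cnnLSTM"), is(calibration, "SpectrumSet"))
  X <- calibration@X
  y <- calibration@perturbation
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("calibration spectra and targets must be finite")
  if (ncol(X) != model$arch$inputBands)
    stop(sprintf("model expects %d bands, calibration has %d",
                 model$arch$inputBands, ncol(X)))
  if (stats::sd(y) == 0)
    stop("zero-variance targets: refusing degenerate fit")
  if (is.null(model$scaling)) {
    # centre per band but scale by the pooled band standard deviation:
    # per-band z-scoring would inflate noise-only bands (most bands of a
    # derivative spectrum) to unit variance and invite overfitting
    xMean <- colMeans(X)
    pooled <- max(sqrt(mean(apply(X, 2, stats::var))), 1e-12)
    model$scaling <- list(xMean = xMean, xSd = rep(pooled, ncol(X)),
                          yMean = mean(y), ySd = stats::sd(y))
    model$wavelengths <- calibration@wavelengths
  }
  sc <- model$scaling
  Xs <- sweep(sweep(X, 2, sc$xMean), 2, sc$xSd, "/")
  ys <- (y - sc$yMean) / sc$ySd

  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  n <- nrow(Xs)
  params <- model$params
  state <- .adamInit(params)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ordr <- sample.int(n)
    epLoss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batchSize)) {
      idx <- ordr[start:min(start + cfg$batchSize - 1, n)]
      fw <- .nnForward(params, model$arch, Xs[idx, , drop = FALSE],
                       cache = TRUE)
      loss <- mean((fw$out - ys[idx])^2)
      if (!is.finite(loss))
        stop(sprintf(
          "training diverged (NaN loss) at epoch %d; last finite epoch %d",
          ep, ep - 1))
      grads <- .nnBackward(params, model$arch, fw, ys[idx])
      upd <- .adamStep(params, grads, state, cfg$learningRate,
                       frozen = frozen)
      params <- upd$params; state <- upd$state
      epLoss <- epLoss + loss; nb <- nb + 1
    }
    losses[ep] <- epLoss / nb
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- list(loss = losses, epochs = cfg$epochs,
                        frozen = frozen)
  model
}

#' Predict SOD activity for spectra
#'
#' @param model a trained `cnnLSTM`.
#' @param newdata a [SpectrumSet-class] or numeric matrix with the band
#'   count the model was built for.
#' @return Numeric vector of predicted activities, U/mg.
#' @export
predictActivity <- function(model, newdata) {
  stopifnot(inherits(model, "cnnLSTM"))
  if (!model$trained) stop("model is untrained")
  X <- if (is(newdata, "SpectrumSet")) newdata@X else as.matrix(newdata)
  if (ncol(X) != model$arch$inputBands)
    stop(sprintf("model expects %d bands, data has %d",
                 model$arch$inputBands, ncol(X)))
  sc <- model$scaling
  Xs <- sweep(sweep(X, 2, sc$xMean), 2, sc$xSd, "/")
  out <- .nnForward(model$params, model$arch, Xs)
  out * sc$ySd + sc$yMean
}

#' Evaluate a model on a spectrum set
#'
#' Reports the Pearson correlation coefficient R between predictions and
#' reference activities, and the root mean square error in U/mg -- the
#' R_C/RMSEC (calibration) and R_P/RMSEP (prediction) statistics of
#' spectral calibration modelling.
#'
#' @param model a trained `cnnLSTM`.
#' @param set a [SpectrumSet-class] with reference activities.
#' @param split label recorded in the result (`"calibration"`,
#'   `"prediction"`, ...).
#' @return list of class `evalMetrics`: `r`, `rmse` (U/mg), `n`, `split`,
#'   and `flag` (`"zero_variance_predictions"` with `r = NA` when the
#'   correlation is undefined).
#' @export
evaluateModel <- function(model, set, split = "prediction") {
  pred <- predictActivity(model, set)
  ref <- set@perturbation
  if (stats::sd(ref) == 0)
    stop("zero variance in reference activities: R is undefined")
  evalMetrics(pred, ref, split)
}

#' Metrics from prediction / reference vectors
#'
#' @param pred,ref numeric vectors of equal length.
#' @param split label recorded in the result.
#' @return list of class `evalMetrics`.
#' @export
evalMetrics <- function(pred, ref, split = "prediction") {
  stopifnot(length(pred) == length(ref), length(pred) >= 2)
  rmse <- sqrt(mean((pred - ref)^2))
  flag <- NULL
  r <- if (stats::sd(pred) == 0) {
    flag <- "zero_variance_predictions"
    NA_real_
  } else stats::cor(pred, ref)
  structure(list(r = r, rmse = rmse, n = length(pred), split = split,
                 flag = flag),
            class = "evalMetrics")
}

#' @export
print.evalMetrics <- function(x, ...) {
  cat(sprintf("%s set (n = %d): R = %s, RMSE = %.4g U/mg\n",
              x$split, x$n,
              if (is.na(x$r)) "NA" else sprintf("%.4f", x$r), x$rmse))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Save / load a CNN-LSTM model as JSON
#'
#' The checkpoint is a single JSON file holding the architecture summary,
#' scaling, history and all weight matrices (full double precision).
#'
#' @param model a `cnnLSTM`.
#' @param path output path.
#' @return `path` invisibly; `readModel` returns the model.
#' @export
writeModel <- function(model, path) {
  stopifnot(inherits(model, "cnnLSTM"))
  payload <- list(
    spec = unclass(model$spec),
    arch = model$arch,
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    scaling = model$scaling,
    wavelengths = model$wavelengths,
    trained = model$trained,
    history = model$history)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"),
             path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  pl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  params <- lapply(pl$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  arch <- pl$arch
  lensIn <- arch$lens  # a data.frame (conv, pool) after JSON simplification
  arch$lens <- lapply(seq_len(arch$nBlocks), function(k) {
    v <- if (is.matrix(lensIn)) lensIn[k, 1:2]  # columns conv, pool
         else if (is.data.frame(lensIn)) c(lensIn$conv[k], lensIn$pool[k])
         else unlist(lensIn[[k]])
    stats::setNames(as.integer(v), c("conv", "pool"))
  })
  structure(list(
    spec = structure(pl$spec, class = "modelSpec"),
    arch = arch,
    params = params,
    scaling = lapply(pl$scaling, as.numeric),
    wavelengths = as.numeric(pl$wavelengths),
    trained = isTRUE(pl$trained),
    history = pl$history), class = "cnnLSTM")
}
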