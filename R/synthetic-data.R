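#' @include hsi-io.R
NULL

.gauss <- function(x, mu, sd) exp(-((x - mu)^2) / (2 * sd^2))
.sigm <- function(x, mu, scale) 1 / (1 + exp(-(x - mu) / scale))

# modality baseline reflectance shapes: the micro curve has absorption
# peaks near 480/560 nm, valleys near 500/690 nm and levels off low past
# ~700 nm; the macro (Vis-NIR) curve has a green peak near 545 nm, a
# high-reflectance red-edge plateau over 755-900 nm and a small O-H
# overtone valley near 950 nm.
.baselineMicro <- function(wl) {
  0.25 + 0.10 * .gauss(wl, 480, 14) - 0.09 * .gauss(wl, 500, 9) +
    0.18 * .gauss(wl, 560, 30) - 0.12 * .sigm(wl, 660, 25) -
    0.04 * .gauss(wl, 690, 18)
}

.baselineMacro <- function(wl) {
  0.08 + 0.18 * .gauss(wl, 545, 22) + 0.45 * .sigm(wl, 715, 18) -
    0.06 * .gauss(wl, 950, 20)
}

.snapToGrid <- function(bands, grid) {
  vapply(bands, function(b) grid[which.min(abs(grid - b))], numeric(1))
}

# default planted sensitive bands: the slice-spectrum peak lists of the
# two instruments (macro includes the 948 nm band that survives the
# 750 nm cutoff by prominence)
.microPeaks <- c(426, 458, 481, 510, 527, 547, 607, 631, 641, 682)
.macroPeaks <- c(497, 511, 516, 540, 564, 607, 641, 694, 723, 948)

#' Study-design configuration for the synthetic generator
#'
#' Encodes the conditions the generator emulates: 4 NaCl treatments
#' (0/1/2/3 g/L) x 3 growth stages (A = seedling, B = flowering,
#' C = fruit-setting), 27 plants per treatment each observed at all three
#' stages (324 spectra), two instruments with deliberately different
#' wavelength grids, and SOD-proportional Gaussian absorption features
#' planted at each instrument's sensitive bands (alternating dips and
#' bumps). SOD activity increases linearly with both salt concentration
#' and stage.
#'
#' @param nPlantsPerCell plants per treatment (default 27).
#' @param treatments salt concentrations, g/L.
#' @param stages growth stage codes (ordinal).
#' @param microGrid,macroGrid wavelength axes, nm; the defaults differ in
#'   step (2 vs 2.35 nm) so downstream code must handle unequal axes.
#' @param sensitiveBandsMicro,sensitiveBandsMacro planted band centres,
#'   nm (snapped to the grid at generation time).
#' @param effectSizeMicro,effectSizeMacro signed reflectance change per
#'   U/mg at each planted band, recycled; defaults alternate -0.6/+0.6.
#' @param sodBase,sodConcSlope,sodStageSlope U/mg; per g/L; per stage step.
#' @param sodNoiseSd label noise sd, U/mg.
#' @param noiseSd i.i.d. reflectance noise sd.
#' @param driftSd amplitude sd of per-sample smooth broad-band baseline
#'   clutter (illumination/scattering variation between leaves).
#' @param nCubes cubes per modality (for the first samples).
#' @param cubeSize cube side length, pixels.
#' @param seed integer RNG seed.
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(nPlantsPerCell = 27L,
                            treatments = c(0, 1, 2, 3),
                            stages = c("A", "B", "C"),
                            microGrid = seq(400, 1000, by = 2),
                            macroGrid = seq(400, 1000, by = 2.35),
                            sensitiveBandsMicro = .microPeaks,
                            sensitiveBandsMacro = .macroPeaks,
                            effectSizeMicro = NULL,
                            effectSizeMacro = NULL,
                            sodBase = 0.05,
                            sodConcSlope = 0.02,
                            sodStageSlope = 0.03,
                            sodNoiseSd = 0.01,
                            noiseSd = 0.002,
                            driftSd = 0.05,
                            nCubes = 3L,
                            cubeSize = 32L,
                            seed = 1L) {
  altSign <- function(k) 0.6 * rep_len(c(-1, 1), k)
  if (is.null(effectSizeMicro))
    effectSizeMicro <- altSign(length(sensitiveBandsMicro))
  if (is.null(effectSizeMacro))
    effectSizeMacro <- altSign(length(sensitiveBandsMacro))
  new("GeneratorConfig",
      nPlantsPerCell = as.integer(nPlantsPerCell),
      treatments = as.numeric(treatments),
      stages = as.character(stages),
      microGrid = as.numeric(microGrid),
      macroGrid = as.numeric(macroGrid),
      sensitiveBandsMicro = as.numeric(sensitiveBandsMicro),
      sensitiveBandsMacro = as.numeric(sensitiveBandsMacro),
      effectSizeMicro = rep_len(as.numeric(effectSizeMicro),
                                length(sensitiveBandsMicro)),
      effectSizeMacro = rep_len(as.numeric(effectSizeMacro),
                                length(sensitiveBandsMacro)),
      sodBase = sodBase, sodConcSlope = sodConcSlope,
      sodStageSlope = sodStageSlope, sodNoiseSd = sodNoiseSd,
      noiseSd = noiseSd, driftSd = driftSd,
      nCubes = as.integer(nCubes), cubeSize = as.integer(cubeSize),
      seed = as.integer(seed))
}

# signed effect spectrum: sum of narrow Gaussians at the planted bands,
# in reflectance units per U/mg; sigma chosen narrow enough that
# neighbouring planted bands (down to ~5 nm apart) stay resolvable
.effectSpectrum <- function(wl, centres, effects, sigma = 3) {
  e <- numeric(length(wl))
  for (k in seq_along(centres))
    e <- e + effects[k] * .gauss(wl, centres[k], sigma)
  e
}

# per-sample baseline clutter emulating illumination/scattering
# variation between leaves: a dominant low-order polynomial component
# (the classic additive offset/slope/curvature scatter model that
# motivates polynomial baseline removal) plus weaker broad smooth
# residuals (suppressed only by derivative pretreatment)
.driftSpectrum <- function(wl, sd) {
  if (sd == 0) return(numeric(length(wl)))
  t0 <- (wl - mean(wl)) / (diff(range(wl)) / 2)
  a <- stats::rnorm(3, 0, sd)
  e <- a[1] + a[2] * t0 + a[3] * (1.5 * t0^2 - 0.5)
  k <- 4
  ctr <- stats::runif(k, min(wl), max(wl))
  wid <- stats::runif(k, 60, 120)
  amp <- stats::rnorm(k, 0, sd / 2)
  for (i in seq_len(k)) e <- e + amp[i] * .gauss(wl, ctr[i], wid[i])
  e
}

#' Generate a synthetic paired micro/macro dataset
#'
#' Draws SOD labels from the linear treatment x stage model
#' `sod = sodBase + sodConcSlope * conc + sodStageSlope * stageIndex +
#' noise` (truncated at 0), then builds for every sample one spectrum per
#' instrument: the modality's smooth baseline shape, plus SOD-proportional
#' Gaussian dips/bumps at the planted sensitive bands, plus per-sample
#' smooth baseline clutter, plus i.i.d. noise. Small hyperspectral cubes
#' are generated for the first `nCubes` samples per modality by
#' replicating that sample's noise-free spectrum per pixel, modulated by
#' a planted spatial activity gradient (stored in
#' `metadata$sod_field`), with pixel noise. Fully reproducible from the
#' config seed; the caller's RNG state is left untouched.
#'
#' @param config a [GeneratorConfig-class].
#' @return A [SyntheticDataset-class].
#' @export
generateDataset <- function(config = generatorConfig()) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(config@seed)

  design <- expand.grid(
    plant = seq_len(config@nPlantsPerCell),
    treatment = config@treatments,
    stage = config@stages,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$stage_index <- match(design$stage, config@stages) - 1L
  n <- nrow(design)
  ids <- sprintf("t%g_%s_p%02d", design$treatment, design$stage,
                 design$plant)
  ord <- order(ids)  # canonical order, stable across platforms
  design <- design[ord, , drop = FALSE]
  rownames(design) <- NULL
  ids <- ids[ord]

  sod <- config@sodBase + config@sodConcSlope * design$treatment +
    config@sodStageSlope * design$stage_index +
    stats::rnorm(n, 0, config@sodNoiseSd)
  sod <- pmax(sod, 0)

  bandsMic <- .snapToGrid(config@sensitiveBandsMicro, config@microGrid)
  bandsMac <- .snapToGrid(config@sensitiveBandsMacro, config@macroGrid)
  effMic <- .effectSpectrum(config@microGrid, bandsMic,
                            config@effectSizeMicro)
  effMac <- .effectSpectrum(config@macroGrid, bandsMac,
                            config@effectSizeMacro)
  baseMic <- .baselineMicro(config@microGrid)
  baseMac <- .baselineMacro(config@macroGrid)

  mkSet <- function(grid, base, eff, modality) {
    B <- length(grid)
    X <- matrix(rep(base, each = n), n, B) + outer(sod, eff)
    for (i in seq_len(n))
      X[i, ] <- X[i, ] + .driftSpectrum(grid, config@driftSd)
    X <- X + matrix(stats::rnorm(n * B, 0, config@noiseSd), n, B)
    spectrumSet(X, grid, ids, sod, modality,
                meta = design,
                provenance = list(origin = "synthetic",
                                  seed = config@seed))
  }
  micro <- mkSet(config@microGrid, baseMic, effMic, "micro")
  macro <- mkSet(config@macroGrid, baseMac, effMac, "macro")

  mkCubes <- function(set, grid, eff, modality) {
    nc <- min(config@nCubes, n)
    if (nc < 1) return(list())
    sz <- config@cubeSize
    # spread cube samples across the design so the maps span the
    # treatment range, as a visualization figure set would
    cubeIdx <- unique(round(seq(1, n, length.out = nc)))
    lapply(cubeIdx, function(i) {
      # planted activity field: column-wise gradient around the sample's
      # own activity, +-15%
      ramp <- 0.3 * (matrix(rep(seq_len(sz), each = sz), sz, sz) - 1) /
        (sz - 1) - 0.15
      field <- set@perturbation[i] * (1 + ramp)
      clean <- set@X[i, ]  # includes the sample's drift and noise draw
      cube <- array(rep(clean, each = sz * sz), dim = c(sz, sz, length(grid)))
      delta <- field - set@perturbation[i]
      cube <- cube + array(outer(as.vector(delta), eff),
                           dim = c(sz, sz, length(grid)))
      cube <- cube + array(stats::rnorm(sz * sz * length(grid), 0,
                                        config@noiseSd),
                           dim = c(sz, sz, length(grid)))
      spectralCube(cube, grid, modality, calibrated = TRUE,
                   metadata = list(sample_id = set@ids[i],
                                   sod = set@perturbation[i],
                                   sod_field = field))
    })
  }
  microCubes <- mkCubes(micro, config@microGrid, effMic, "micro")
  macroCubes <- mkCubes(macro, config@macroGrid, effMac, "macro")

  truth <- rbind(
    data.frame(modality = "micro", wavelength = bandsMic,
               requested = config@sensitiveBandsMicro,
               effect = config@effectSizeMicro),
    data.frame(modality = "macro", wavelength = bandsMac,
               requested = config@sensitiveBandsMacro,
               effect = config@effectSizeMacro))

  new("SyntheticDataset", micro = micro, macro = macro,
      microCubes = microCubes, macroCubes = macroCubes,
      sod = sod, truth = truth, config = config)
}

#' Planted-band truth table
#'
#' Returns the planted sensitive wavelengths of a synthetic dataset with
#' their signed effect sizes (reflectance per U/mg), for peak-recovery
#' checks. When every planted effect is zero the dataset carries no
#' SOD-related spectral signal and the table is flagged as a null model.
#'
#' @param ds a [SyntheticDataset-class].
#' @return data.frame with columns `modality`, `wavelength` (grid-snapped
#'   nm), `requested` (nm as configured) and `effect`; attribute
#'   `null_model` is TRUE when all effects are zero.
#' @export
truthReport <- function(ds) {
  stopifnot(is(ds, "SyntheticDataset"))
  out <- ds@truth
  nullModel <- all(out$effect == 0)
  if (nullModel)
    message("all planted effect sizes are zero: null-model dataset")
  attr(out, "null_model") <- nullModel
  out
}

#' Write a synthetic dataset to disk
#'
#' Spectra as CSV (via [writeSpectra()]), cubes as ENVI header/binary
#' pairs, the truth table as CSV and the configuration as JSON.
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSpectra(ds@micro, file.path(dir, "micro_spectra.csv"))
  writeSpectra(ds@macro, file.path(dir, "macro_spectra.csv"))
  for (i in seq_along(ds@microCubes))
    writeCube(ds@microCubes[[i]], file.path(dir, sprintf("micro_cube_%02d.bsq", i)))
  for (i in seq_along(ds@macroCubes))
    writeCube(ds@macroCubes[[i]], file.path(dir, sprintf("macro_cube_%02d.bsq", i)))
  utils::write.csv(ds@truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- ds@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  writeLines(jsonlite::toJSON(cfgList, digits = NA),
             file.path(dir, "config.json"))
  invisible(dir)
}
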