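test_that("the default architecture realizes three 32/64/128 conv blocks", {
  mod <- buildModel(modelSpec(), 300L)
  expect_equal(mod$arch$nBlocks, 3)
  expect_equal(mod$arch$filters, c(32L, 64L, 128L))
  # 300 -> conv 150 -> pool 75 -> conv 37 -> pool 18 -> conv 9 -> pool 4
  expect_equal(mod$arch$lens[[3]][["pool"]], 4)
  # identical seeds give identical initial weights
  m2 <- buildModel(modelSpec(), 300L)
  expect_identical(mod$params, m2$params)
  m3 <- buildModel(modelSpec(seed = 2L), 300L)
  expect_false(identical(mod$params, m3$params))
})

test_that("narrow inputs auto-reduce the conv depth or error out", {
  expect_message(mod <- buildModel(modelSpec(), 10L), "auto-reduced")
  expect_equal(mod$arch$nBlocks, 1)
  # 10 -> conv 5 -> pool 2
  expect_equal(mod$arch$lens[[1]], c(conv = 5L, pool = 2L))
  expect_error(buildModel(modelSpec(), 6L), "fewer convFilters")
  expect_silent(mod2 <- buildModel(modelSpec(convFilters = 8L), 6L))
  expect_equal(mod2$arch$nBlocks, 1)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(14)
  mod <- buildModel(modelSpec(convFilters = c(3L, 4L), lstmUnits = 5L,
                              denseUnits = 4L, seed = 2L), 40L)
  X <- matrix(rnorm(6 * 40), 6, 40)
  y <- rnorm(6)
  fw <- h2dcos:::.nnForward(mod$params, mod$arch, X, cache = TRUE)
  gr <- h2dcos:::.nnBackward(mod$params, mod$arch, fw, y)
  lossAt <- function(p) mean((h2dcos:::.nnForward(p, mod$arch, X) - y)^2)
  eps <- 1e-6
  for (nm in names(mod$params)) {
    pv <- mod$params[[nm]]
    for (ii in sample(length(pv), min(3, length(pv)))) {
      up <- dn <- mod$params
      up[[nm]][ii] <- up[[nm]][ii] + eps
      dn[[nm]][ii] <- dn[[nm]][ii] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-5, info = nm)
    }
  }
})

test_that("training is deterministic and overfits a tiny noiseless set", {
  ds <- generateDataset(tinyConfig(
    nPlantsPerCell = 4L, noiseSd = 0, driftSd = 0, nCubes = 0L,
    microGrid = seq(400, 700, by = 4)))
  cal <- ds@micro[seq_len(40), ]
  cfg <- trainConfig(epochs = 120L, seed = 3L)
  spec <- modelSpec(convFilters = c(8L, 16L), lstmUnits = 16L,
                    denseUnits = 8L, seed = 4L)
  m1 <- trainModel(buildModel(spec, ncol(spectra(cal))), cal, cfg)
  ev <- evaluateModel(m1, cal, split = "calibration")
  expect_gte(ev$r, 0.99)
  m2 <- trainModel(buildModel(spec, ncol(spectra(cal))), cal, cfg)
  expect_identical(tail(m1$history$loss, 1), tail(m2$history$loss, 1))
  expect_identical(predictActivity(m1, cal), predictActivity(m2, cal))
})

test_that("degenerate fits and divergence are refused loudly", {
  s <- toySet(n = 10, B = 16)
  s@perturbation <- rep(1, 10)
  mod <- buildModel(modelSpec(convFilters = 4L, lstmUnits = 4L,
                              denseUnits = 4L), 16L)
  expect_error(trainModel(mod, s, trainConfig(epochs = 2L)),
               "zero-variance")
  s2 <- toySet(n = 10, B = 16)
  # a NaN anywhere in the parameters poisons the loss and must be caught
  bad <- mod
  bad$params$dense.b2 <- NaN
  expect_error(trainModel(bad, s2, trainConfig(epochs = 2L)),
               "diverged.*last finite epoch 0")
  expect_error(predictActivity(mod, s2), "untrained")
})

test_that("the stratified split honours counts, disjointness and the seed", {
  ds <- generateDataset(tinyConfig(nPlantsPerCell = 9L, nCubes = 0L))
  s <- ds@micro  # 108 samples in 12 treatment x stage cells
  cfg <- trainConfig(splitFraction = 0.75, seed = 21L)
  sp <- splitDataset(s, cfg)
  expect_equal(nrow(spectra(sp$calibration)), 81)
  expect_equal(nrow(spectra(sp$prediction)), 27)
  expect_length(intersect(sampleIds(sp$calibration),
                          sampleIds(sp$prediction)), 0)
  expect_setequal(c(sampleIds(sp$calibration), sampleIds(sp$prediction)),
                  sampleIds(s))
  # every cell contributes to calibration proportionally (6 or 7 of 9)
  calMeta <- sp$calibration@meta
  cells <- table(interaction(calMeta$treatment, calMeta$stage))
  expect_true(all(cells %in% c(6, 7)))
  sp2 <- splitDataset(s, cfg)
  expect_identical(sampleIds(sp2$calibration), sampleIds(sp$calibration))
  sp3 <- splitDataset(s, trainConfig(splitFraction = 0.75, seed = 22L))
  expect_false(identical(sampleIds(sp3$calibration),
                         sampleIds(sp$calibration)))
  # tiny strata fall back to a random split with a warning
  tiny <- s[c(1, 2, 3, 4, 5, 6, 7, 28), ]
  expect_warning(splitDataset(tiny, cfg), "fewer than 2")
  expect_error(splitDataset(s[1:5, ], cfg), "at least 8")
})

test_that("evaluation metrics match their closed forms", {
  expect_equal(evalMetrics(c(1, 2, 3), c(1, 2, 3))$r, 1)
  expect_equal(evalMetrics(c(1, 2, 3), c(1, 2, 3))$rmse, 0)
  off <- evalMetrics(c(1, 2, 3) + 0.1, c(1, 2, 3))
  expect_equal(off$r, 1)
  expect_equal(off$rmse, 0.1, tolerance = 1e-12)
  rev <- evalMetrics(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev$r, -1)
  expect_equal(rev$rmse, sqrt(8 / 3), tolerance = 1e-10)
  cz <- evalMetrics(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(cz$r))
  expect_equal(cz$flag, "zero_variance_predictions")
  expect_equal(cz$rmse, sqrt(mean((2 - (1:5))^2)))
  # property: r is invariant under positive affine maps of predictions,
  # rmse scales with the spread
  set.seed(31)
  for (k in 1:5) {
    p <- rnorm(20); ref <- rnorm(20)
    a <- runif(1, 0.5, 2); b <- rnorm(1)
    expect_equal(evalMetrics(a * p + b, ref)$r, evalMetrics(p, ref)$r,
                 tolerance = 1e-12)
    expect_equal(evalMetrics(a * p, a * p * 0 + a * ref)$rmse,
                 a * evalMetrics(p, ref)$rmse, tolerance = 1e-12)
  }
})

test_that("models survive a JSON checkpoint round-trip", {
  ds <- generateDataset(tinyConfig(nCubes = 0L,
                                   microGrid = seq(400, 700, by = 10)))
  cal <- ds@micro[1:12, ]
  mod <- trainModel(buildModel(modelSpec(convFilters = 4L, lstmUnits = 4L,
                                         denseUnits = 3L),
                               ncol(spectra(cal))),
                    cal, trainConfig(epochs = 3L))
  path <- tempfile(fileext = ".json")
  writeModel(mod, path)
  back <- readModel(path)
  expect_equal(predictActivity(back, cal), predictActivity(mod, cal),
               tolerance = 1e-12)
})
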