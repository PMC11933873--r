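test_that("black/white calibration matches the closed form", {
  wl <- c(400, 500, 600)
  cube <- spectralCube(array(0.5, c(2, 2, 3)), wl)
  frames <- calibrationFrames(dark = rep(0.1, 3), white = rep(0.9, 3))
  cal <- calibrateCube(cube, frames)
  # (0.5 - 0.1) / (0.9 - 0.1) = 0.5
  expect_equal(as.vector(cubeValues(cal)), rep(0.5, 12))
  expect_true(isCalibrated(cal))
  expect_equal(wavelengths(cal), wl)

  # raw = white -> 1 everywhere; raw = dark -> 0 everywhere
  white <- spectralCube(array(rep(c(0.7, 0.8, 0.9), each = 4), c(2, 2, 3)), wl)
  dark <- spectralCube(array(rep(c(0.1, 0.15, 0.2), each = 4), c(2, 2, 3)), wl)
  fr <- calibrationFrames(dark = c(0.1, 0.15, 0.2), white = c(0.7, 0.8, 0.9))
  expect_equal(as.vector(cubeValues(calibrateCube(white, fr))), rep(1, 12))
  expect_equal(as.vector(cubeValues(calibrateCube(dark, fr))), rep(0, 12))
})

test_that("calibration recovers planted reflectance from synthetic raw counts", {
  set.seed(4)
  d <- c(3, 4, 5)
  R <- array(runif(prod(d)), d)
  D <- array(runif(prod(d), 0, 0.2), d)
  W <- D + array(runif(prod(d), 0.5, 1), d)
  raw <- spectralCube(D + R * (W - D), seq(400, 480, by = 20))
  cal <- calibrateCube(raw, calibrationFrames(dark = D, white = W))
  expect_equal(cubeValues(cal), R, tolerance = 1e-12)
})

test_that("calibration error paths name the offending band", {
  cube <- spectralCube(array(0.5, c(2, 2, 3)), c(400, 500, 600))
  frames <- calibrationFrames(dark = c(0.1, 0.5, 0.1), white = c(0.9, 0.5, 0.9))
  expect_error(calibrateCube(cube, frames), "500")
  expect_error(
    calibrateCube(cube, calibrationFrames(dark = rep(0.1, 4),
                                          white = rep(0.9, 4))),
    "band count")
  cal <- calibrateCube(cube, calibrationFrames(dark = rep(0, 3),
                                               white = rep(1, 3)))
  expect_error(calibrateCube(cal, frames), "already calibrated")
})

test_that("masked mean spectra average the selected pixels", {
  wl <- c(400, 500)
  vals <- array(0, c(2, 2, 2))
  vals[1, 1, ] <- c(1, 2); vals[2, 1, ] <- c(3, 4)
  vals[1, 2, ] <- c(5, 6); vals[2, 2, ] <- c(7, 8)
  cube <- spectralCube(vals, wl)
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(extractMeanSpectrum(cube, m1), c(1, 2))
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(extractMeanSpectrum(cube, m2), c(2, 3))  # (s1+s2)/2
  uni <- spectralCube(array(0.4, c(2, 2, 2)), wl)
  expect_equal(extractMeanSpectrum(uni, matrix(TRUE, 2, 2)), c(0.4, 0.4))
  expect_error(extractMeanSpectrum(cube, matrix(FALSE, 2, 2)), "no pixels")
  expect_error(extractMeanSpectrum(cube, matrix(TRUE, 3, 3)), "shape")
})

test_that("ENVI cube round-trip is lossless", {
  set.seed(2)
  cube <- spectralCube(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                       seq(400, 500, length.out = 6), modality = "macro",
                       calibrated = TRUE)
  path <- file.path(tempdir(), "cube_rt.bsq")
  writeCube(cube, path)
  back <- readCube(path)
  expect_equal(cubeValues(back), cubeValues(cube), tolerance = 1e-12)
  expect_equal(wavelengths(back), wavelengths(cube), tolerance = 1e-12)
  expect_equal(modality(back), "macro")
  expect_true(isCalibrated(back))
})

test_that("BIL and BIP interleaves read back to the same cube", {
  set.seed(3)
  vals <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  wl <- c(450, 550)
  path <- file.path(tempdir(), "cube_il")
  # write BSQ via the package, then rewrite the binary by hand in BIL/BIP
  writeCube(spectralCube(vals, wl), path)
  for (il in c("bil", "bip")) {
    hdr <- readLines(paste0(path, ".hdr"))
    hdr <- sub("interleave = bsq", paste("interleave =", il), hdr)
    p2 <- file.path(tempdir(), paste0("cube_", il))
    writeLines(hdr, paste0(p2, ".hdr"))
    con <- file(p2, "wb")
    if (il == "bil") {
      for (r in 1:3) for (b in 1:2)
        writeBin(as.vector(vals[r, , b]), con, size = 8, endian = "little")
    } else {
      for (r in 1:3) for (cc in 1:4)
        writeBin(as.vector(vals[r, cc, ]), con, size = 8, endian = "little")
    }
    close(con)
    expect_equal(cubeValues(readCube(p2)), vals, tolerance = 1e-12,
                 info = il)
  }
})

test_that("malformed ENVI headers are format errors", {
  cube <- spectralCube(array(1, c(2, 2, 3)), c(400, 500, 600))
  path <- file.path(tempdir(), "cube_bad.bsq")
  writeCube(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(sub("bands = 3", "bands = 5", hdr), paste0(path, ".hdr"))
  expect_error(readCube(path), "mismatch|match")
  writeLines(hdr[!grepl("samples", hdr)], paste0(path, ".hdr"))
  expect_error(readCube(path), "samples")
})

test_that("spectrum-table CSV round-trip preserves everything", {
  set.seed(5)
  meta <- data.frame(treatment = rep(c(0, 1), 3), stage = rep("A", 6))
  s <- spectrumSet(matrix(rnorm(6 * 4), 6, 4), c(400, 410, 420, 430),
                   ids = paste0("x", 1:6), perturbation = runif(6),
                   modality = "macro", meta = meta)
  path <- tempfile(fileext = ".csv")
  writeSpectra(s, path)
  back <- readSpectra(path, modality = "macro")
  expect_equal(spectra(back), spectra(s), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(wavelengths(back), wavelengths(s))
  expect_equal(sampleIds(back), sampleIds(s))
  expect_equal(perturbation(back), perturbation(s), tolerance = 1e-12)
  expect_equal(back@meta$treatment, meta$treatment)
})

test_that("shuffled wavelength columns are re-sorted ascending on read", {
  s <- spectrumSet(matrix(1:8, 2, 4), c(400, 410, 420, 430))
  path <- tempfile(fileext = ".csv")
  writeSpectra(s, path)
  df <- utils::read.csv(path, check.names = FALSE)
  wlCols <- grep("^wl_", names(df))
  df <- df[, c(setdiff(seq_along(df), wlCols), rev(wlCols))]
  utils::write.csv(df, path, row.names = FALSE)
  back <- readSpectra(path)
  expect_equal(wavelengths(back), c(400, 410, 420, 430))
  expect_equal(spectra(back), spectra(s), ignore_attr = TRUE)
})

test_that("construction invariants are enforced", {
  expect_error(spectrumSet(matrix(1:4, 2, 2), c(410, 410)), "duplicate")
  expect_error(new("SpectrumSet", ids = c("a", "b"),
                   X = matrix(1:4, 2, 2), wavelengths = c(420, 410),
                   perturbation = c(0, 0), modality = "micro",
                   meta = data.frame(), provenance = list()),
               "increasing")
  expect_error(spectralCube(array(c(1, NA), c(1, 1, 2)), c(400, 500)),
               "finite")
})
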