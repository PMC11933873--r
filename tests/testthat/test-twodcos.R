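test_that("dynamic spectra are perturbation-ordered and mean-centred", {
  wl <- c(500, 510, 520)
  X <- rbind(c(1, 4, 7), c(2, 5, 8), c(6, 9, 12))
  s <- spectrumSet(X, wl, ids = c("a", "b", "c"),
                   perturbation = c(0.3, 0.1, 0.2))
  d <- makeDynamic(s)
  expect_equal(sampleIds(d), c("b", "c", "a"))
  expect_equal(perturbation(d), c(0.1, 0.2, 0.3))
  expect_equal(colMeans(d@Y), c(0, 0, 0), tolerance = 1e-12)
  # hand-centred first column: sorted values 2, 6, 1; mean 3
  expect_equal(d@Y[, 1], c(-1, 3, -2))
  # identical rows centre to zero
  same <- spectrumSet(matrix(5, 4, 3), wl, perturbation = 1:4)
  expect_equal(makeDynamic(same)@Y, matrix(0, 4, 3), ignore_attr = TRUE)
})

test_that("row order of the input does not affect the dynamic spectra", {
  s <- toySet(n = 7, B = 12, seed = 5)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  shuffled <- s[perm, ]
  expect_equal(makeDynamic(shuffled)@Y, makeDynamic(s)@Y)
  # ties in perturbation broken stably by id, with a message
  tied <- spectrumSet(matrix(1:8, 4, 2), c(400, 410),
                      ids = c("d", "b", "c", "a"),
                      perturbation = c(1, 1, 2, 2))
  expect_message(dt <- makeDynamic(tied), "ties")
  expect_equal(sampleIds(dt), c("b", "d", "a", "c"))
})

test_that("the printed n-1 reference convention is available", {
  s <- toySet(n = 5, B = 6, seed = 2)
  d <- makeDynamic(s, referenceDivisor = "n-1")
  expect_equal(d@reference, colSums(spectra(s)) / 4, tolerance = 1e-12)
  expect_error(makeDynamic(toySet(n = 2, B = 4)), "at least 3")
})

test_that("the Hilbert-Noda matrix has the defining structure", {
  M <- hilbertNoda(3)
  expect_equal(diag(M), c(0, 0, 0))
  expect_equal(M[1, 3], 1 / (2 * pi), tolerance = 1e-15)
  expect_equal(M[1, 2], 1 / pi, tolerance = 1e-15)
  for (n in c(2, 5, 9)) {
    Mn <- hilbertNoda(n)
    expect_equal(Mn + t(Mn), matrix(0, n, n))
  }
  expect_error(hilbertNoda(1), ">= 2")
})

test_that("matrix-form maps agree with the explicit double-loop sums", {
  set.seed(21)
  s1 <- spectrumSet(matrix(rnorm(8 * 12), 8, 12),
                    seq(400, by = 2, length.out = 12),
                    perturbation = runif(8))
  s2 <- spectrumSet(matrix(rnorm(8 * 10), 8, 10),
                    seq(600, by = 3, length.out = 10),
                    perturbation = perturbation(s1))
  d1 <- makeDynamic(s1); d2 <- makeDynamic(s2)
  expect_equal(computeSyncMap(d1, d1), bruteSync(d1@Y, d1@Y),
               tolerance = 1e-10)
  expect_equal(computeAsyncMap(d1, d1), bruteAsync(d1@Y, d1@Y),
               tolerance = 1e-10)
  expect_equal(computeSyncMap(d1, d2), bruteSync(d1@Y, d2@Y),
               tolerance = 1e-10)
  expect_equal(computeAsyncMap(d1, d2), bruteAsync(d1@Y, d2@Y),
               tolerance = 1e-10)
})

test_that("homogeneous maps have the required structural identities", {
  s <- toySet(n = 9, B = 14, seed = 31)
  d <- makeDynamic(s)
  sync <- computeSyncMap(d, d)
  async <- computeAsyncMap(d, d)
  expect_equal(sync, t(sync), tolerance = 1e-12)
  expect_equal(diag(sync), apply(spectra(s), 2, var), tolerance = 1e-12)
  expect_true(all(diag(sync) >= 0))
  expect_equal(async, -t(async), tolerance = 1e-12)
  expect_equal(diag(async), rep(0, 14), tolerance = 1e-14)
  # proportional band trajectories: Phi(1,2) = c * Phi(1,1)
  c0 <- 2.5
  X <- cbind(d@Y[, 1], c0 * d@Y[, 1]) + mean(spectra(s))
  sp <- spectrumSet(X, c(500, 510), perturbation = perturbation(s))
  dp <- makeDynamic(sp)
  sc <- computeSyncMap(dp, dp)
  expect_equal(sc[1, 2], c0 * sc[1, 1], tolerance = 1e-10)
})

test_that("in-phase signals give an exactly vanishing asynchronous map", {
  # rank-1 intensity structure: every band follows one common trajectory
  f <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.7)
  g <- c(1, -2, 0.5, 3)
  s <- spectrumSet(outer(f, g), c(400, 410, 420, 430), perturbation = f)
  d <- makeDynamic(s)
  expect_equal(computeAsyncMap(d, d), matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("both maps scale linearly with either modality (bilinearity)", {
  s1 <- toySet(n = 6, B = 8, seed = 41)
  s2 <- toySet(n = 6, B = 5, seed = 42, modality = "macro")
  d1 <- makeDynamic(s1); d2 <- makeDynamic(s2)
  c0 <- -1.7
  d1s <- d1; d1s@Y <- c0 * d1@Y
  expect_equal(computeSyncMap(d1s, d2), c0 * computeSyncMap(d1, d2),
               tolerance = 1e-12)
  expect_equal(computeAsyncMap(d1s, d2), c0 * computeAsyncMap(d1, d2),
               tolerance = 1e-12)
})

test_that("quarter-period lag reproduces the sequential-order sign rule", {
  n <- 32
  j <- seq_len(n)
  lagging <- sin(2 * pi * j / n)
  leading <- sin(2 * pi * j / n + pi / 2)  # peaks earlier in the sequence
  s <- spectrumSet(cbind(lagging, leading), c(500, 600),
                   perturbation = j / n)
  d <- makeDynamic(s, sortBy = "given_order")
  async <- computeAsyncMap(d, d)
  sync <- computeSyncMap(d, d)
  # brute-force oracle values
  expect_equal(async, bruteAsync(d@Y, d@Y), tolerance = 1e-10)
  # orthogonal in phase: no synchronous cross-peak
  expect_lt(abs(sync[1, 2]), 1e-10)
  # Psi(v1, v2) < 0: the band at v2 varies before the band at v1
  expect_lt(async[1, 2], 0)
  expect_gt(async[2, 1], 0)
  expect_equal(async[2, 1], 0.43388, tolerance = 1e-4)
})

test_that("map construction checks pairing and records orientation", {
  s1 <- toySet(n = 6, B = 8, seed = 51)
  s2 <- toySet(n = 6, B = 5, seed = 52, modality = "macro")
  maps <- heteroCorr(s1, s2)
  expect_true(maps@hetero)
  expect_equal(dim(syncMatrix(maps)), c(8, 5))
  expect_equal(mapAxes(maps)$wl1, wavelengths(s1))
  # copy of the same set degenerates to a symmetric homogeneous map
  homo <- heteroCorr(s1, s1)
  expect_false(homo@hetero)
  expect_equal(syncMatrix(homo), t(syncMatrix(homo)), tolerance = 1e-12)
  # reversing the direction transposes sync and antitransposes async
  rev <- heteroCorr(s2, s1)
  expect_equal(syncMatrix(rev), t(syncMatrix(maps)), tolerance = 1e-12)
  expect_equal(asyncMatrix(rev), -t(asyncMatrix(maps)), tolerance = 1e-12)
  # unpaired or permuted samples are alignment errors
  s3 <- s2; s3@ids[2] <- "zz"
  expect_error(heteroCorr(s1, s3), "unpaired")
  expect_error(heteroCorr(s1, s2[c(2, 1, 3:6), ]), "order differs")
})

test_that("slices snap to the nearest band and respect symmetry", {
  s <- toySet(n = 6, B = 11, seed = 61)
  maps <- heteroCorr(s, s)
  wl <- wavelengths(s)
  sl <- sliceSpectrum(maps, "sync", axis = 1, at = wl[4])
  expect_equal(sl$values, syncMatrix(maps)[4, ])
  # homogeneous symmetry: row slice equals column slice
  sl2 <- sliceSpectrum(maps, "sync", axis = 2, at = wl[4])
  expect_equal(sl$values, sl2$values, tolerance = 1e-12)
  # snapping: halfway between bands snaps downward, with a message
  expect_message(sl3 <- sliceSpectrum(maps, "sync", 1, at = wl[4] + 1),
                 "snapped")
  expect_equal(sl3$at, wl[4])
  expect_error(sliceSpectrum(maps, "sync", 1, at = min(wl) - 5),
               "outside")
})

test_that("peak selection masks edges and the long-wave region", {
  wl <- seq(400, 1000, by = 5)
  B <- length(wl)
  mk <- function(centres, amps = 1) {
    v <- numeric(B)
    for (i in seq_along(centres))
      v <- v + rep_len(amps, length(centres))[i] *
        exp(-((wl - centres[i])^2) / 50)
    v
  }
  # flat slice: nothing to find
  expect_equal(length(wavelengths(findSensitivePeaks(
    structure(list(values = rep(1, B), wavelengths = wl, at = 500,
                   axis = 1, which = "sync"), class = "corrSlice")))), 0)
  centres <- c(450, 500, 560, 620, 700)
  pk <- findSensitivePeaks(mk(centres), wavelengths = wl)
  expect_equal(wavelengths(pk), centres)
  # a peak 2 bands from the edge is excluded at edgeBands = 5
  pkEdge <- findSensitivePeaks(mk(c(410, 500)), wavelengths = wl,
                               edgeBands = 5)
  expect_equal(wavelengths(pkEdge), 500)
  # above the 750 nm cutoff: dropped unless very strong
  v <- mk(c(500, 900), amps = c(1, 0.4))
  expect_equal(wavelengths(findSensitivePeaks(v, wavelengths = wl)), 500)
  v2 <- mk(c(500, 900), amps = c(1, 0.8))
  expect_equal(wavelengths(findSensitivePeaks(v2, wavelengths = wl)),
               c(500, 900))
  expect_equal(wavelengths(findSensitivePeaks(v2, wavelengths = wl,
                                              retainStrong = NULL)), 500)
  expect_equal(wavelengths(findSensitivePeaks(v2, wavelengths = wl,
                                              maxWavelength = NULL)),
               c(500, 900))
  # weak peaks fall below the prominence floor
  v3 <- mk(c(500, 600), amps = c(1, 0.03))
  expect_equal(wavelengths(findSensitivePeaks(v3, wavelengths = wl)), 500)
  # maxPeaks keeps the strongest
  v4 <- mk(c(450, 550, 650), amps = c(0.5, 1, 0.8))
  expect_equal(wavelengths(findSensitivePeaks(v4, wavelengths = wl,
                                              maxPeaks = 2)),
               c(550, 650))
  expect_error(findSensitivePeaks(rep(0, 12), wavelengths = seq_len(12),
                                  edgeBands = 5), "too short")
})

test_that("correlation maps survive a text round-trip", {
  s1 <- toySet(n = 5, B = 7, seed = 71)
  s2 <- toySet(n = 5, B = 6, seed = 72, modality = "macro")
  maps <- heteroCorr(s1, s2)
  path <- file.path(tempdir(), "maps_rt")
  writeMaps(maps, path)
  back <- readMaps(path)
  expect_equal(syncMatrix(back), syncMatrix(maps), tolerance = 1e-12)
  expect_equal(asyncMatrix(back), asyncMatrix(maps), tolerance = 1e-12)
  expect_equal(mapAxes(back), mapAxes(maps))
  expect_equal(back@n, maps@n)
})
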