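# small in-code fixtures shared across test files

# tiny paired-design config: 2 plants x 4 treatments x 3 stages = 24 samples
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nPlantsPerCell = 2L, nCubes = 1L, cubeSize = 6L,
                   seed = 101L)
  do.call(generatorConfig, utils::modifyList(defaults, args))
}

# deterministic little SpectrumSet with known structure
toySet <- function(n = 6, B = 20, seed = 1, modality = "micro") {
  set.seed(seed)
  wl <- seq(500, 500 + 2 * (B - 1), by = 2)
  X <- matrix(rnorm(n * B, mean = 0.3, sd = 0.05), n, B)
  spectrumSet(X, wl, ids = sprintf("s%02d", seq_len(n)),
              perturbation = seq_len(n) / 10, modality = modality)
}

# brute-force double-loop 2D-COS oracles, straight from the defining sums
bruteSync <- function(Y1, Y2) {
  n <- nrow(Y1)
  out <- matrix(0, ncol(Y1), ncol(Y2))
  for (a in seq_len(ncol(Y1)))
    for (b in seq_len(ncol(Y2)))
      for (j in seq_len(n))
        out[a, b] <- out[a, b] + Y1[j, a] * Y2[j, b]
  out / (n - 1)
}

bruteAsync <- function(Y1, Y2) {
  n <- nrow(Y1)
  M <- matrix(0, n, n)
  for (j in seq_len(n))
    for (k in seq_len(n))
      if (j != k) M[j, k] <- 1 / (pi * (k - j))
  out <- matrix(0, ncol(Y1), ncol(Y2))
  for (a in seq_len(ncol(Y1)))
    for (b in seq_len(ncol(Y2)))
      for (j in seq_len(n)) {
        inner <- 0
        for (k in seq_len(n)) inner <- inner + M[j, k] * Y2[k, b]
        out[a, b] <- out[a, b] + Y1[j, a] * inner
      }
  out / (n - 1)
}
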