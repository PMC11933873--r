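#' @include hsi-io.R
NULL

#' Build the dynamic spectra of a SpectrumSet
#'
#' The dynamic spectrum of 2D correlation analysis: samples are ordered by
#' the perturbation variable (by default; `sortBy = "given_order"` keeps
#' the stored order) and each band is centred by a reference spectrum,
#' \eqn{\tilde y(v, p_j) = y(v, p_j) - \bar y(v)}.
#'
#' The reference is the arithmetic mean spectrum (`referenceDivisor =
#' "n"`). Some formulations print the reference sum divided by N-1
#' instead; that convention is available as `referenceDivisor = "n-1"`,
#' in which case the columns of the result are not exactly mean-centred.
#'
#' @param set a [SpectrumSet-class] with at least 3 samples.
#' @param sortBy `"perturbation"` (default) or `"given_order"`. Ties in
#'   the perturbation are broken stably by sample id.
#' @param referenceDivisor `"n"` (arithmetic mean, default) or `"n-1"`.
#' @return A [DynamicSpectra-class] object.
#' @export
makeDynamic <- function(set, sortBy = c("perturbation", "given_order"),
                        referenceDivisor = c("n", "n-1")) {
  stopifnot(is(set, "SpectrumSet"))
  sortBy <- match.arg(sortBy)
  referenceDivisor <- match.arg(referenceDivisor)
  n <- nrow(set@X)
  if (n < 3) stop("at least 3 samples are required for correlation analysis")
  ord <- if (sortBy == "perturbation") {
    if (anyDuplicated(set@perturbation))
      message("ties in perturbation broken by sample id")
    order(set@perturbation, set@ids)
  } else seq_len(n)
  X <- set@X[ord, , drop = FALSE]
  ref <- colSums(X) / if (referenceDivisor == "n") n else (n - 1)
  Y <- sweep(X, 2, ref)
  new("DynamicSpectra", Y = Y, wavelengths = set@wavelengths,
      perturbation = set@perturbation[ord], reference = ref,
      ids = set@ids[ord], modality = set@modality)
}

#' Hilbert-Noda transformation matrix
#'
#' The antisymmetric matrix implementing the discrete Hilbert transform
#' used by the asynchronous correlation map:
#' \eqn{M_{jk} = 0} if \eqn{j = k}, else \eqn{1 / (\pi (k - j))}.
#'
#' @param n number of perturbation points (>= 2).
#' @return n x n numeric matrix.
#' @examples
#' hilbertNoda(3)[1, 3]  # 1 / (2 * pi)
#' @export
hilbertNoda <- function(n) {
  if (n < 2) stop("n must be >= 2")
  k <- matrix(seq_len(n), n, n, byrow = TRUE)
  j <- matrix(seq_len(n), n, n)
  M <- 1 / (pi * (k - j))
  diag(M) <- 0
  M
}

.checkAligned <- function(d1, d2) {
  if (nrow(d1@Y) != nrow(d2@Y))
    stop(sprintf("perturbation counts differ (%d vs %d)",
                 nrow(d1@Y), nrow(d2@Y)))
  if (!identical(d1@ids, d2@ids)) {
    bad <- utils::head(which(d1@ids != d2@ids), 5)
    stop("sample id order differs between the two dynamic spectra at ",
         "position(s) ", paste(bad, collapse = ", "),
         ": the perturbation sequences are not paired")
  }
}

#' Synchronous 2D correlation map
#'
#' \deqn{\Phi(v_1, v_2) = \frac{1}{N-1} \sum_{j=1}^{N}
#'   \tilde y(v_1, p_j)\, \tilde z(v_2, p_j)}
#' computed in matrix form as \eqn{Y_1^\top Y_2 / (N-1)}. For the
#' homogeneous case (`d2` missing or equal to `d1`) the diagonal holds
#' the per-band sample variances.
#'
#' @param d1,d2 [DynamicSpectra-class] with identical sample ordering;
#'   `d2` defaults to `d1` (homogeneous analysis).
#' @return B1 x B2 numeric matrix.
#' @export
computeSyncMap <- function(d1, d2 = d1) {
  .checkAligned(d1, d2)
  crossprod(d1@Y, d2@Y) / (nrow(d1@Y) - 1)
}

#' Asynchronous 2D correlation map
#'
#' \deqn{\Psi(v_1, v_2) = \frac{1}{N-1} \sum_{j=1}^{N}
#'   \tilde y(v_1, p_j) \sum_{k=1}^{N} M_{jk}\, \tilde z(v_2, p_k)}
#' with \eqn{M} the Hilbert-Noda matrix ([hilbertNoda()]); matrix form
#' \eqn{Y_1^\top M Y_2 / (N-1)}. Vanishes identically for in-phase
#' (proportional) band trajectories.
#'
#' @inheritParams computeSyncMap
#' @return B1 x B2 numeric matrix.
#' @export
computeAsyncMap <- function(d1, d2 = d1) {
  .checkAligned(d1, d2)
  n <- nrow(d1@Y)
  crossprod(d1@Y, hilbertNoda(n) %*% d2@Y) / (n - 1)
}

#' Full 2D-COS between two dynamic spectra
#'
#' Assembles the synchronous and asynchronous maps into a
#' [CorrelationMaps-class] object. The complex correlation intensity is
#' \eqn{X(v_1, v_2) = \Phi(v_1, v_2) + i\,\Psi(v_1, v_2)}; its real and
#' imaginary parts are stored separately.
#'
#' @inheritParams computeSyncMap
#' @param hetero logical; `NULL` (default) infers it from whether the two
#'   inputs share wavelength axis and intensities.
#' @return A [CorrelationMaps-class].
#' @export
correlationMaps <- function(d1, d2 = d1, hetero = NULL) {
  if (is.null(hetero))
    hetero <- !(isTRUE(all.equal(d1@wavelengths, d2@wavelengths)) &&
                isTRUE(all.equal(d1@Y, d2@Y)))
  new("CorrelationMaps",
      sync = computeSyncMap(d1, d2),
      async = computeAsyncMap(d1, d2),
      wl1 = d1@wavelengths, wl2 = d2@wavelengths,
      hetero = hetero, n = nrow(d1@Y),
      provenance = list(modality1 = d1@modality, modality2 = d2@modality))
}

#' Heterogeneous 2D correlation spectroscopy between two instruments
#'
#' Builds dynamic spectra for paired measurements from two instruments
#' (e.g. microscopic and macroscopic hyperspectral imaging of the same
#' leaves, ordered by SOD activity) and returns the cross-instrument
#' synchronous and asynchronous maps over the grid
#' (wavelengths of `set1`) x (wavelengths of `set2`),
#' \eqn{X(v_1, v_2) = \langle \tilde y(v_1, t)\, \tilde z(v_2, t')\rangle}.
#' The opposite direction is the transpose (up to the sign convention of
#' the Hilbert-Noda matrix for the asynchronous part).
#'
#' Both sets must contain the same samples in the same stored order; the
#' perturbation ordering is then applied identically to both.
#'
#' @param set1,set2 [SpectrumSet-class] objects with paired sample ids.
#' @param sortBy,referenceDivisor passed to [makeDynamic()].
#' @return A [CorrelationMaps-class] with `hetero` determined from the
#'   inputs (a copy of the same set degenerates to a homogeneous map).
#' @export
heteroCorr <- function(set1, set2, sortBy = "perturbation",
                       referenceDivisor = "n") {
  stopifnot(is(set1, "SpectrumSet"), is(set2, "SpectrumSet"))
  if (!identical(set1@ids, set2@ids)) {
    off <- union(setdiff(set1@ids, set2@ids), setdiff(set2@ids, set1@ids))
    if (length(off))
      stop("unpaired samples between modalities: ",
           paste(utils::head(off, 10), collapse = ", "))
    stop("sample order differs between modalities; pair the sets first ",
         "(first mismatch at position ",
         which(set1@ids != set2@ids)[1], ")")
  }
  d1 <- makeDynamic(set1, sortBy, referenceDivisor)
  d2 <- makeDynamic(set2, sortBy, referenceDivisor)
  maps <- correlationMaps(d1, d2)
  maps@provenance$preprocess1 <- set1@provenance$preprocess
  maps@provenance$preprocess2 <- set2@provenance$preprocess
  maps
}

#' Extract a slice spectrum from a correlation map
#'
#' A slice is one row (axis 1) or column (axis 2) of the synchronous or
#' asynchronous map at a fixed wavelength, expressed over the other
#' axis's wavelengths; it localizes which partner-wavelengths co-vary
#' with the chosen band.
#'
#' The requested wavelength is snapped to the nearest band of the chosen
#' axis (half-way ties snap downward); a message reports the snap when it
#' moves the position. Requests outside the axis range are an error.
#'
#' @param maps a [CorrelationMaps-class].
#' @param which `"sync"` or `"async"`.
#' @param axis 1 (slice at fixed v1, returned over wl2) or 2.
#' @param at wavelength, nm, on the chosen axis.
#' @return A list of class `corrSlice` with elements `values`,
#'   `wavelengths` (the other axis), `at` (snapped nm), `axis`, `which`.
#' @export
sliceSpectrum <- function(maps, which = c("sync", "async"), axis = 1,
                          at) {
  stopifnot(is(maps, "CorrelationMaps"))
  which <- match.arg(which)
  stopifnot(axis %in% c(1, 2))
  grid <- if (axis == 1) maps@wl1 else maps@wl2
  if (at < min(grid) || at > max(grid))
    stop(sprintf("requested wavelength %.4g nm outside axis range [%.4g, %.4g]",
                 at, min(grid), max(grid)))
  dist <- abs(grid - at)
  idx <- which(dist == min(dist))[1]  # half-way ties snap downward
  if (grid[idx] != at)
    message(sprintf("slice position snapped from %.4g to %.4g nm",
                    at, grid[idx]))
  M <- if (which == "sync") maps@sync else maps@async
  vals <- if (axis == 1) M[idx, ] else M[, idx]
  structure(list(values = as.numeric(vals),
                 wavelengths = if (axis == 1) maps@wl2 else maps@wl1,
                 at = grid[idx], axis = axis, which = which),
            class = "corrSlice")
}

#' @export
print.corrSlice <- function(x, ...) {
  cat(sprintf("corrSlice (%s, axis %d) at %.4g nm: %d bands\n",
              x$which, x$axis, x$at, length(x$values)))
  invisible(x)
}

#' Sensitive-peak selection from a slice spectrum
#'
#' Finds local maxima of the slice magnitude after masking: the
#' `edgeBands` bands at each end are excluded (instrument instability at
#' the spectrum ends), as are bands above `maxWavelength` (the long-wave
#' region carries little information for this system) -- except that an
#' isolated peak above the cutoff is retained when its magnitude exceeds
#' `retainStrong` of the global slice maximum, which is how a strong
#' long-wave feature (e.g. an O-H overtone band near 950 nm) survives the
#' cutoff. Peaks below `minProminence` of the maximum magnitude are
#' dropped.
#'
#' @param slice a `corrSlice` from [sliceSpectrum()], or a numeric vector
#'   (then `wavelengths` must be supplied).
#' @param edgeBands bands masked at each end (default 5).
#' @param maxWavelength nm cutoff above which peaks are masked; `NULL`
#'   disables the cutoff (default 750).
#' @param minProminence fraction of the maximum slice magnitude below
#'   which peaks are dropped (default 0.05).
#' @param retainStrong fraction of the maximum magnitude above which a
#'   peak beyond `maxWavelength` is retained anyway (default 0.5); `NULL`
#'   disables retention.
#' @param maxPeaks keep only the `maxPeaks` strongest peaks (by slice
#'   magnitude); `NULL` (default) keeps all passing peaks.
#' @param wavelengths numeric axis when `slice` is a bare vector.
#' @return A [PeakList-class], sorted by wavelength.
#' @export
findSensitivePeaks <- function(slice, edgeBands = 5, maxWavelength = 750,
                               minProminence = 0.05, retainStrong = 0.5,
                               maxPeaks = NULL, wavelengths = NULL) {
  if (inherits(slice, "corrSlice")) {
    v <- abs(slice$values)
    wl <- slice$wavelengths
    src <- slice$at
  } else {
    v <- abs(as.numeric(slice))
    wl <- wavelengths
    src <- NA_real_
    if (is.null(wl)) stop("wavelengths must be supplied for a bare slice")
  }
  B <- length(v)
  if (B < 2 * edgeBands + 3)
    stop("slice too short for the requested edge exclusion")
  keep <- rep(TRUE, B)
  if (edgeBands > 0)
    keep[c(seq_len(edgeBands), (B - edgeBands + 1):B)] <- FALSE
  vmax <- max(v[keep])
  aboveCut <- if (is.null(maxWavelength)) rep(FALSE, B) else wl > maxWavelength
  retained <- if (is.null(retainStrong)) rep(FALSE, B)
              else v >= retainStrong * vmax
  domain <- keep & (!aboveCut | retained)
  if (!any(domain)) stop("all bands masked: empty peak-search domain")
  isPeak <- rep(FALSE, B)
  for (i in 2:(B - 1))
    isPeak[i] <- v[i] > v[i - 1] && v[i] >= v[i + 1]
  sel <- which(isPeak & domain & v >= minProminence * vmax)
  if (!is.null(maxPeaks) && length(sel) > maxPeaks)
    sel <- sort(sel[order(v[sel], decreasing = TRUE)[seq_len(maxPeaks)]])
  new("PeakList", wavelengths = wl[sel], intensities = v[sel],
      sourceSlice = src,
      exclusions = list(edge_bands = edgeBands,
                        max_wavelength = maxWavelength,
                        min_prominence = minProminence,
                        retain_strong = retainStrong))
}

#' Write / read correlation maps
#'
#' The maps are stored as plain-text: `<path>_sync.csv` and
#' `<path>_async.csv` (matrices with wl1 rows and wl2 columns) and
#' `<path>_meta.json` (axes, hetero flag, n, provenance).
#'
#' @param maps a [CorrelationMaps-class].
#' @param path output path prefix.
#' @return `path` invisibly for `writeMaps`; a CorrelationMaps for
#'   `readMaps`.
#' @export
writeMaps <- function(maps, path) {
  stopifnot(is(maps, "CorrelationMaps"))
  utils::write.table(maps@sync, paste0(path, "_sync.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(maps@async, paste0(path, "_async.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(wl1 = maps@wl1, wl2 = maps@wl2, hetero = maps@hetero,
               n = maps@n, provenance = maps@provenance)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, "_meta.json"))
  invisible(path)
}

#' @rdname writeMaps
#' @export
readMaps <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, "_meta.json"))
  syncM <- as.matrix(utils::read.table(paste0(path, "_sync.csv"),
                                       sep = ",", header = FALSE))
  asyncM <- as.matrix(utils::read.table(paste0(path, "_async.csv"),
                                        sep = ",", header = FALSE))
  dimnames(syncM) <- dimnames(asyncM) <- NULL
  new("CorrelationMaps", sync = syncM, async = asyncM,
      wl1 = as.numeric(meta$wl1), wl2 = as.numeric(meta$wl2),
      hetero = as.logical(meta$hetero), n = as.integer(meta$n),
      provenance = as.list(meta$provenance))
}
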