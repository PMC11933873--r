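#' @include AllClasses.R
NULL

#' Construct a SpectrumSet
#'
#' Columns are re-ordered so the wavelength axis is strictly ascending;
#' duplicate wavelengths are an error.
#'
#' @param X numeric matrix, samples x bands.
#' @param wavelengths numeric, nm, one per column of `X`.
#' @param ids character sample identifiers; defaults to `s1, s2, ...`.
#' @param perturbation numeric per-sample perturbation (SOD activity U/mg
#'   or treatment code); defaults to zeros.
#' @param modality `"micro"` or `"macro"`.
#' @param meta optional data.frame of per-sample covariates.
#' @param provenance optional list.
#' @return A [SpectrumSet-class] object.
#' @export
spectrumSet <- function(X, wavelengths, ids = NULL, perturbation = NULL,
                        modality = "micro", meta = data.frame(),
                        provenance = list()) {
  X <- as.matrix(X)
  dimnames(X) <- NULL
  storage.mode(X) <- "double"
  if (anyDuplicated(wavelengths))
    stop("duplicate wavelengths are not allowed")
  ord <- order(wavelengths)
  X <- X[, ord, drop = FALSE]
  wavelengths <- wavelengths[ord]
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  if (is.null(perturbation)) perturbation <- numeric(nrow(X))
  new("SpectrumSet", ids = as.character(ids), X = X,
      wavelengths = as.numeric(wavelengths),
      perturbation = as.numeric(perturbation),
      modality = modality, meta = meta, provenance = provenance)
}

#' Construct a SpectralCube
#'
#' @param values numeric 3-D array `[row, col, band]`.
#' @param wavelengths numeric, nm.
#' @param modality `"micro"` or `"macro"`.
#' @param calibrated logical.
#' @param metadata list.
#' @return A [SpectralCube-class] object.
#' @export
spectralCube <- function(values, wavelengths, modality = "micro",
                         calibrated = FALSE, metadata = list()) {
  new("SpectralCube", values = values,
      wavelengths = as.numeric(wavelengths), modality = modality,
      calibrated = calibrated, metadata = metadata)
}

# broadcast a dark/white frame (per-band vector or full array) onto
# a cube's shape; returns an array of dim d
.broadcastFrame <- function(frame, d, what) {
  if (is.null(dim(frame)) || length(dim(frame)) == 1) {
    if (length(frame) != d[3])
      stop(sprintf("%s frame vector length (%d) must equal band count (%d)",
                   what, length(frame), d[3]))
    aperm(array(rep(as.numeric(frame), each = d[1] * d[2]), dim = d),
          c(1, 2, 3))
  } else if (identical(dim(frame), as.integer(d)) ||
             identical(as.integer(dim(frame)), as.integer(d))) {
    frame
  } else {
    stop(sprintf("%s frame shape (%s) incompatible with cube shape (%s)",
                 what, paste(dim(frame), collapse = "x"),
                 paste(d, collapse = "x")))
  }
}

#' Black/white reflectance calibration
#'
#' Converts raw counts to reflectance, \eqn{R = (R_0 - D) / (W - D)},
#' where \eqn{R_0} is the raw image, \eqn{D} the dark frame and \eqn{W}
#' the white-reference frame. Frames may be full images matching the cube
#' or per-band vectors broadcast across pixels.
#'
#' @param raw an uncalibrated [SpectralCube-class].
#' @param frames a [CalibrationFrames-class] object.
#' @return A calibrated SpectralCube with the same wavelength axis.
#' @examples
#' cube <- spectralCube(array(0.5, c(2, 2, 3)), c(400, 500, 600))
#' frames <- calibrationFrames(dark = rep(0.1, 3), white = rep(0.9, 3))
#' cubeValues(calibrateCube(cube, frames))[1, 1, ]  # 0.5 everywhere
#' @export
calibrateCube <- function(raw, frames) {
  stopifnot(is(raw, "SpectralCube"), is(frames, "CalibrationFrames"))
  if (raw@calibrated)
    stop("cube is already calibrated")
  d <- dim(raw@values)
  D <- .broadcastFrame(frames@dark, d, "dark")
  W <- .broadcastFrame(frames@white, d, "white")
  denom <- W - D
  if (any(denom == 0)) {
    bad <- which(apply(denom == 0, 3, any))
    stop(sprintf(
      "white - dark is zero at band(s) %s (%s nm): cannot divide",
      paste(utils::head(bad, 5), collapse = ", "),
      paste(round(raw@wavelengths[utils::head(bad, 5)], 1), collapse = ", ")))
  }
  out <- (raw@values - D) / denom
  spectralCube(out, raw@wavelengths, raw@modality, calibrated = TRUE,
               metadata = raw@metadata)
}

#' Construct CalibrationFrames
#'
#' @param dark,white numeric per-band vectors or full `[row, col, band]`
#'   arrays of counts.
#' @return A [CalibrationFrames-class] object.
#' @export
calibrationFrames <- function(dark, white) {
  new("CalibrationFrames", dark = dark, white = white)
}

#' Mean spectrum over a masked region
#'
#' @param cube a [SpectralCube-class].
#' @param mask logical (or 0/1) matrix matching the cube's spatial shape;
#'   `TRUE`/nonzero pixels are averaged.
#' @return Numeric vector of length = band count: the per-band mean over
#'   the masked pixels.
#' @export
extractMeanSpectrum <- function(cube, mask) {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@values)
  mask <- mask != 0
  if (!identical(as.integer(dim(mask)), as.integer(d[1:2])))
    stop("mask shape must equal the cube's spatial shape")
  idx <- which(mask)
  if (!length(idx))
    stop("mask selects no pixels")
  flat <- matrix(cube@values, nrow = d[1] * d[2], ncol = d[3])
  colMeans(flat[idx, , drop = FALSE])
}

## ---- ENVI cube I/O ---------------------------------------------------

# ENVI data type codes used here: 4 = float32, 5 = float64
.enviSizes <- c(`4` = 4L, `5` = 8L)

#' Write a SpectralCube as an ENVI header + binary pair
#'
#' Writes `path` (binary, BSQ interleave, little-endian float64) and
#' `paste0(path, ".hdr")` (text header with the wavelength list and
#' modality/calibration metadata).
#'
#' @param cube a [SpectralCube-class].
#' @param path output binary path; the header gets a `.hdr` suffix.
#' @return `path`, invisibly.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@values)
  hdr <- c(
    "ENVI",
    "description = { h2dcos spectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("modality = %s", cube@modality),
    sprintf("calibrated = %d", as.integer(cube@calibrated)),
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(format(cube@wavelengths, digits = 15, trim = TRUE,
                         scientific = FALSE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-sequential; within a band, row-major (line by line)
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(cube@values[, , b])), con, size = 8,
             endian = "little")
  invisible(path)
}

.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getField <- function(name, required = TRUE) {
    m <- regmatches(txt, regexpr(
      paste0("(?im)^\\s*", name, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
      txt, perl = TRUE))
    if (!length(m)) {
      if (required) stop(sprintf("malformed ENVI header: missing '%s'", name))
      return(NULL)
    }
    val <- sub(paste0("(?i)^\\s*", name, "\\s*=\\s*"), "", m[1], perl = TRUE)
    trimws(val)
  }
  numList <- function(s) {
    s <- gsub("[{}]", "", s)
    as.numeric(trimws(strsplit(s, ",")[[1]]))
  }
  list(
    samples = as.integer(getField("samples")),
    lines = as.integer(getField("lines")),
    bands = as.integer(getField("bands")),
    dtype = as.integer(getField("data type")),
    interleave = tolower(getField("interleave")),
    byteOrder = as.integer(getField("byte order")),
    offset = {
      o <- getField("header offset", required = FALSE)
      if (is.null(o)) 0L else as.integer(o)
    },
    modality = {
      m <- getField("modality", required = FALSE)
      if (is.null(m)) "micro" else m
    },
    calibrated = {
      cc <- getField("calibrated", required = FALSE)
      !is.null(cc) && as.integer(cc) == 1L
    },
    wavelength = {
      w <- getField("wavelength", required = FALSE)
      if (is.null(w)) NULL else numList(w)
    }
  )
}

#' Read an ENVI header + binary pair as a SpectralCube
#'
#' Accepts BSQ, BIL and BIP interleaves and float32/float64 data types;
#' the wavelength list is taken from the header.
#'
#' @param path path to the binary file; the header is found at
#'   `paste0(path, ".hdr")` (or `path` with its extension replaced).
#' @return A [SpectralCube-class].
#' @export
readCube <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath))
    hdrPath <- sub("\\.[^.]*$", ".hdr", path)
  if (!file.exists(hdrPath))
    stop("ENVI header not found for ", path)
  h <- .parseEnviHeader(hdrPath)
  if (!h$dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", h$dtype)
  nel <- h$samples * h$lines * h$bands
  sz <- .enviSizes[[as.character(h$dtype)]]
  expect <- h$offset + nel * sz
  actual <- file.info(path)$size
  if (is.na(actual) || actual < expect)
    stop(sprintf(
      "ENVI data size mismatch: header implies %d bytes, file has %s",
      expect, ifelse(is.na(actual), "none", actual)))
  if (!is.null(h$wavelength) && length(h$wavelength) != h$bands)
    stop(sprintf(
      "wavelength count (%d) does not match header band count (%d)",
      length(h$wavelength), h$bands))
  con <- file(path, "rb")
  on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", n = h$offset)
  vals <- readBin(con, "numeric", n = nel, size = sz,
                  endian = if (h$byteOrder == 0) "little" else "big")
  cube <- array(0, dim = c(h$lines, h$samples, h$bands))
  if (h$interleave == "bsq") {
    # [col, row, band] in read order (row-major lines) -> aperm
    a <- array(vals, dim = c(h$samples, h$lines, h$bands))
    cube <- aperm(a, c(2, 1, 3))
  } else if (h$interleave == "bil") {
    a <- array(vals, dim = c(h$samples, h$bands, h$lines))
    cube <- aperm(a, c(3, 1, 2))
  } else if (h$interleave == "bip") {
    a <- array(vals, dim = c(h$bands, h$samples, h$lines))
    cube <- aperm(a, c(3, 2, 1))
  } else stop("unsupported interleave: ", h$interleave)
  wl <- if (is.null(h$wavelength)) seq_len(h$bands) else h$wavelength
  spectralCube(cube, wl, h$modality, calibrated = h$calibrated)
}

## ---- SpectrumSet CSV I/O ---------------------------------------------

#' Write a SpectrumSet as CSV
#'
#' One row per sample with columns `id`, optional metadata columns
#' (`treatment`, `stage`, ...), `sod_u_per_mg` (the perturbation), then
#' one reflectance column per wavelength named `wl_<nm>`.
#'
#' @param set a [SpectrumSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(set, path) {
  stopifnot(is(set, "SpectrumSet"))
  df <- data.frame(id = set@ids, stringsAsFactors = FALSE)
  if (nrow(set@meta)) df <- cbind(df, set@meta)
  df$sod_u_per_mg <- set@perturbation
  sp <- as.data.frame(set@X)
  names(sp) <- paste0("wl_", format(set@wavelengths, digits = 12,
                                    trim = TRUE, scientific = FALSE))
  df <- cbind(df, sp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a SpectrumSet from CSV
#'
#' Inverse of [writeSpectra()]; wavelength columns (`wl_<nm>`) are
#' re-sorted into ascending order if shuffled.
#'
#' @param path CSV path.
#' @param modality instrument tag to attach.
#' @return A [SpectrumSet-class].
#' @export
readSpectra <- function(path, modality = "micro") {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  wlCols <- grep("^wl_", names(df))
  if (!length(wlCols)) stop("no wavelength (wl_*) columns found in ", path)
  wl <- as.numeric(sub("^wl_", "", names(df)[wlCols]))
  if (any(is.na(wl))) stop("malformed wavelength column names in ", path)
  X <- as.matrix(df[, wlCols, drop = FALSE])
  storage.mode(X) <- "double"
  ids <- as.character(df$id)
  pert <- if ("sod_u_per_mg" %in% names(df)) df$sod_u_per_mg
          else numeric(nrow(df))
  metaCols <- setdiff(names(df)[-wlCols], c("id", "sod_u_per_mg"))
  meta <- if (length(metaCols)) df[, metaCols, drop = FALSE] else data.frame()
  spectrumSet(X, wl, ids, pert, modality, meta)
}

#' Read a pixel mask from PNG
#'
#' @param path PNG path; any nonzero pixel (first channel) is selected.
#' @return Logical matrix.
#' @export
readMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img != 0
}
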