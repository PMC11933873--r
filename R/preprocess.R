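#' @include hsi-io.R
NULL

# central Savitzky-Golay filter coefficients for the m-th derivative
.sgCoef <- function(window, polyorder, deriv = 0) {
  if (window %% 2 != 1 || window < 3)
    stop("window must be odd and >= 3")
  if (polyorder >= window)
    stop("polyorder must be < window")
  Fm <- signal::sgolay(p = polyorder, n = window, m = deriv)
  as.numeric(Fm[(window + 1) / 2, ])
}

# band-space linear operator: out = X %*% M applies the centred filter
# `coef` to every row, with edge bands copied from the nearest interior
# band (the ends are discarded downstream anyway during peak selection)
.sgOperator <- function(B, coef) {
  h <- (length(coef) - 1) / 2
  if (B < length(coef))
    stop(sprintf("window (%d) must not exceed band count (%d)",
                 length(coef), B))
  M <- matrix(0, B, B)
  for (j in (h + 1):(B - h)) M[(j - h):(j + h), j] <- coef
  for (j in seq_len(h)) M[, j] <- M[, h + 1]
  for (j in (B - h + 1):B) M[, j] <- M[, B - h]
  M
}

#' Spectral pretreatment of a SpectrumSet
#'
#' Applies one of the pretreatments compared in the modelling study to
#' every spectrum (row): Savitzky-Golay `"smoothing"`, polynomial
#' `"baseline"` removal, Savitzky-Golay first derivative `"fd"` (scaled by
#' band spacing, units reflectance per nm), or `"none"`. All three
#' operators are linear in the spectra; sample ids, ordering, perturbation
#' and wavelengths are preserved, and the method applied is recorded in
#' the set's provenance.
#'
#' Edge handling for the Savitzky-Golay operators: the centred filter is
#' applied on the interior and the `(window-1)/2` edge bands copy the
#' nearest interior value; downstream peak selection masks spectrum ends
#' regardless.
#'
#' @param set a [SpectrumSet-class].
#' @param method `"none"`, `"smoothing"`, `"baseline"` or `"fd"`.
#' @param window odd Savitzky-Golay window length in bands (default 7).
#' @param polyorder Savitzky-Golay polynomial order (default 2, < window).
#' @param baselineOrder degree of the least-squares polynomial subtracted
#'   by `"baseline"` (default 2; 0 mean-centres each spectrum).
#' @return A [SpectrumSet-class] with transformed spectra.
#' @export
preprocessSpectra <- function(set,
                              method = c("none", "smoothing", "baseline",
                                         "fd"),
                              window = 7, polyorder = 2,
                              baselineOrder = 2) {
  stopifnot(is(set, "SpectrumSet"))
  method <- match.arg(method)
  X <- set@X
  B <- ncol(X)
  out <- switch(method,
    none = X,
    smoothing = {
      X %*% .sgOperator(B, .sgCoef(window, polyorder, 0))
    },
    fd = {
      dx <- mean(diff(set@wavelengths))
      (X %*% .sgOperator(B, .sgCoef(window, polyorder, 1))) / dx
    },
    baseline = {
      if (B <= baselineOrder + 1)
        stop("band count must exceed baselineOrder + 1")
      wl <- set@wavelengths
      t0 <- (wl - mean(wl)) / (diff(range(wl)) / 2)
      V <- outer(t0, 0:baselineOrder, `^`)
      Q <- qr.Q(qr(V))
      X - (X %*% Q) %*% t(Q)
    })
  prov <- set@provenance
  prov$preprocess <- c(prov$preprocess, method)
  prov$preprocess_params <- list(window = window, polyorder = polyorder,
                                 baselineOrder = baselineOrder)
  initialize(set, X = out, provenance = prov)
}

#' @rdname preprocessSpectra
#' @export
smoothSpectra <- function(set, window = 7, polyorder = 2)
  preprocessSpectra(set, "smoothing", window = window,
                    polyorder = polyorder)

#' @rdname preprocessSpectra
#' @export
baselineCorrect <- function(set, baselineOrder = 2)
  preprocessSpectra(set, "baseline", baselineOrder = baselineOrder)

#' @rdname preprocessSpectra
#' @export
firstDerivative <- function(set, window = 7, polyorder = 2)
  preprocessSpectra(set, "fd", window = window, polyorder = polyorder)
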