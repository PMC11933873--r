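#' SOD activity from NBT photochemical assay absorbances
#'
#' Computes superoxide dismutase activity from the nitroblue tetrazolium
#' (NBT) photoreduction assay, where one unit of activity is the amount of
#' enzyme inhibiting NBT photoreduction by 50\%:
#' \deqn{\mathrm{SOD} = \frac{(A_{S0} - A_S)\, V_t}{A_{S0}\, W\, V_S \cdot
#'   0.5 \cdot 1000}}
#' with \eqn{A_{S0}} the absorbance of the illuminated control tube,
#' \eqn{A_S} the sample tube absorbance (both at 560 nm), \eqn{V_t} the
#' total extract volume (mL), \eqn{V_S} the extract volume assayed (mL)
#' and \eqn{W} the fresh sample weight.
#'
#' The weight unit convention is explicit: with `weightUnit = "g"`
#' (default) `w` is in grams and the result is in U per mg fresh weight
#' via the constant 1000; with `weightUnit = "mg"` `w` is taken in mg and
#' converted to grams first, so the same formula applies. Negative
#' activities (sample absorbance above the control) are returned as
#' computed, with a warning.
#'
#' @param aS0 absorbance of the illuminated control tube (> 0).
#' @param aS absorbance of the sample tube (>= 0).
#' @param vT total extract volume, mL (> 0).
#' @param vS extract volume assayed, mL (> 0).
#' @param w fresh sample weight in `weightUnit` (> 0).
#' @param weightUnit `"g"` or `"mg"`.
#' @return SOD activity in U/mg fresh weight; vectorized over all
#'   arguments.
#' @examples
#' sodActivity(aS0 = 0.8, aS = 0.4, vT = 2, vS = 0.05, w = 0.3)  # 0.1333
#' @export
sodActivity <- function(aS0, aS, vT, vS, w, weightUnit = c("g", "mg")) {
  weightUnit <- match.arg(weightUnit)
  if (any(aS0 == 0)) stop("aS0 must be nonzero (division by control absorbance)")
  if (any(aS0 < 0) || any(aS < 0)) stop("absorbances must be non-negative")
  if (any(vT <= 0) || any(vS <= 0) || any(w <= 0))
    stop("volumes and weight must be positive")
  if (weightUnit == "mg") w <- w / 1000
  act <- ((aS0 - aS) * vT) / (aS0 * w * vS * 0.5 * 1000)
  if (any(act < 0))
    warning(sprintf(
      "%d record(s) have sample absorbance above the control (negative activity)",
      sum(act < 0)))
  act
}

#' Append SOD activity to an assay table
#'
#' Reads a CSV of assay records (columns `a_s0`, `a_s`, `v_t`, `v_s`, `w`),
#' appends a `sod_u_per_mg` column and optionally writes the result.
#'
#' @param records data.frame or CSV path.
#' @param out optional output CSV path.
#' @param weightUnit passed to [sodActivity()].
#' @return The labelled data.frame, invisibly when `out` is given.
#' @export
sodActivityTable <- function(records, out = NULL, weightUnit = "g") {
  df <- if (is.character(records)) utils::read.csv(records) else records
  need <- c("a_s0", "a_s", "v_t", "v_s", "w")
  if (!all(need %in% names(df)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  df$sod_u_per_mg <- sodActivity(df$a_s0, df$a_s, df$v_t, df$v_s, df$w,
                                 weightUnit = weightUnit)
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE)
    return(invisible(df))
  }
  df
}
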