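#' Savitzky-Golay filter parameters
#'
#' Window length, polynomial order and derivative order for the
#' Savitzky-Golay smoother/differentiator. The defaults (window 21 points,
#' second-order polynomial, first derivative) are the standard choice for
#' removing additive baselines from NIR absorbance spectra while keeping the
#' band structure.
#'
#' @param window Odd positive integer, number of grid points in the local
#'   fitting window.
#' @param polyorder Non-negative integer, degree of the local polynomial;
#'   must be smaller than `window`.
#' @param deriv Non-negative integer derivative order; must not exceed
#'   `polyorder`. `deriv = 0` smooths without differentiating.
#' @return An object of class `sg_params`.
#' @export
sg_params <- function(window = 21L, polyorder = 2L, deriv = 1L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  check(window > 0L && window %% 2L == 1L, "window must be odd and positive")
  check(polyorder >= 0L && polyorder < window,
        "polyorder must satisfy 0 <= polyorder < window")
  check(deriv >= 0L && deriv <= polyorder,
        "deriv must satisfy 0 <= deriv <= polyorder")
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sg_params")
}

#' @export
print.sg_params <- function(x, ...) {
  cat(sprintf("<sg_params> window=%d polyorder=%d deriv=%d\n",
              x$window, x$polyorder, x$deriv))
  invisible(x)
}

#' Savitzky-Golay smoothing / derivative of a spectra dataset
#'
#' Applies the Savitzky-Golay filter row-wise to the absorbance matrix.
#' The derivative is taken with respect to wavenumber (units
#' absorbance * cm for `deriv = 1`), so results are invariant to the grid
#' resolution. Edge points are handled by evaluating the polynomial fitted
#' to the terminal window, which keeps the number of wavenumbers unchanged
#' and is exact for polynomial spectra of degree at most `polyorder`.
#' Requires a uniform wavenumber grid.
#'
#' @param ds A `spectra_dataset`.
#' @param params An [sg_params()] object.
#' @return A `spectra_dataset` with the same wavenumbers, targets and
#'   metadata, and filtered absorbance.
#' @export
savitzky_golay <- function(ds, params = sg_params()) {
  validate_spectra_dataset(ds)
  check(inherits(params, "sg_params"), "params must be an sg_params object")
  n <- length(ds$wavenumbers)
  check(n >= params$window, "window (%d) exceeds number of wavenumbers (%d)",
        params$window, n)
  steps <- diff(ds$wavenumbers)
  h <- mean(steps)
  check(all(abs(steps - h) <= 1e-6 * abs(h)),
        "wavenumber grid must be uniform (relative tolerance 1e-6)")

  filt <- t(apply(ds$absorbance, 1, function(row) {
    signal::sgolayfilt(row, p = params$polyorder, n = params$window,
                       m = params$deriv, ts = h)
  }))
  out <- ds
  out$absorbance <- filt
  colnames(out$absorbance) <- colnames(ds$absorbance)
  validate_spectra_dataset(out)
  out
}
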