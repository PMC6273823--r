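#' Hartree to electron-volt conversion factor
#'
#' CODATA recommended value of the Hartree energy expressed in electron
#' volts. All energies are stored in Hartree internally and converted to
#' eV only when a quantity is reported, so the constant lives in exactly
#' one place.
#'
#' @format A length-one numeric, eV per Hartree.
#' @export
EV_PER_HARTREE <- 27.211386245988

#' Convert Hartree to electron volts
#'
#' @param x Numeric vector of energies in Hartree. Must be finite.
#' @return `x` expressed in eV.
#' @seealso [ev_to_hartree()] for the inverse.
#' @examples
#' hartree_to_ev(0.042)
#' @export
hartree_to_ev <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("hartree_to_ev: input must be finite numeric", call. = FALSE)
  }
  x * EV_PER_HARTREE
}

#' Convert electron volts to Hartree
#'
#' @param x Numeric vector of energies in eV. Must be finite.
#' @return `x` expressed in Hartree.
#' @export
ev_to_hartree <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("ev_to_hartree: input must be finite numeric", call. = FALSE)
  }
  x / EV_PER_HARTREE
}

#' Round for reporting, half away from zero
#'
#' Report tables print 2 or 3 decimals with ties rounded away from zero
#' (so -3.185 prints as -3.19), unlike [round()]'s round-half-even.
#' Decimal scaling is pre-rounded at 9 decimals to keep binary floating
#' point representation error from flipping a tie.
#'
#' @param x Numeric vector (eV in the report tables, but unit-agnostic).
#' @param digits Number of decimals, 2 or 3.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' report_round(-3.185, 2)  # -3.19
#' report_round(1.1428, 3)  # 1.143
#' @export
report_round <- function(x, digits) {
  if (!digits %in% c(2L, 3L)) {
    stop("report_round: digits must be 2 or 3", call. = FALSE)
  }
  scaled <- round(abs(x) * 10^digits, 9)
  sign(x) * floor(scaled + 0.5) / 10^digits
}
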