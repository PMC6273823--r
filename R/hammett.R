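#' Default Hammett sigma-para table
#'
#' Standard sigma_p values from the Hansch-Leo-Taft compilation for the
#' para substituents covered by the piperidone curcuminoid series.
#' User-overridable wherever a sigma table is consumed; "H" is 0 by
#' definition.
#'
#' @return Named numeric vector, substituent -> sigma_p.
#' @export
default_sigma_table <- function() {
  c("H" = 0.00, "4-Cl" = 0.23, "4-Br" = 0.23, "4-NMe2" = -0.83,
    "4-CN" = 0.66, "4-CF3" = 0.54)
}

#' Read a sigma table from CSV
#'
#' Expected columns: `substituent,sigma_p`.
#'
#' @param path CSV path.
#' @return Named numeric vector, substituent -> sigma_p.
#' @export
read_sigma_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("substituent", "sigma_p") %in% names(df))) {
    stop("sigma table needs columns substituent,sigma_p", call. = FALSE)
  }
  stats::setNames(as.numeric(df$sigma_p), df$substituent)
}

#' Ordinary least squares of a descriptor against sigma
#'
#' Closed-form simple linear regression: slope = Sxy/Sxx, intercept =
#' mean(y) - slope*mean(x), R^2 = Sxy^2/(Sxx*Syy) (0 when y is
#' constant). This is the linear free-energy-relationship kernel; the
#' fitted slope is the reaction constant rho when x is Hammett sigma.
#'
#' @param x Numeric sigma values, not all equal, length >= 3.
#' @param y Numeric descriptor values, same length.
#' @return An object of class `hammett_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("linear_fit: need n >= 3 points", call. = FALSE)
  if (length(y) != n) stop("linear_fit: x/y length mismatch", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("linear_fit: x values are all equal", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  structure(
    list(slope = slope, intercept = mean(y) - slope * mean(x),
         r_squared = if (syy == 0) 0 else sxy^2 / (sxx * syy),
         n = n),
    class = "hammett_fit"
  )
}

#' @export
print.hammett_fit <- function(x, ...) {
  cat(sprintf("<hammett_fit> slope %.4f  intercept %.4f  R^2 %.3f  n %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Correlate a descriptor series with Hammett sigma
#'
#' Joins per-compound descriptor values to sigma_p through a
#' compound -> substituent map and delegates to [linear_fit()].
#'
#' @param descriptors Named numeric vector, compound id -> descriptor
#'   value (AEA, VEA, VDE, omega, ...).
#' @param substituents Named character vector, compound id ->
#'   substituent key present in `sigma`.
#' @param sigma Named numeric sigma table; default
#'   [default_sigma_table()].
#' @param series Optional character vector of compound ids to include;
#'   default all of `descriptors`.
#' @return A `hammett_fit` with an extra `compounds` field listing the
#'   ids that entered the fit.
#' @export
hammett_screen <- function(descriptors, substituents,
                           sigma = default_sigma_table(),
                           series = names(descriptors)) {
  if (!all(series %in% names(descriptors))) {
    stop("hammett_screen: series ids missing from descriptors",
         call. = FALSE)
  }
  if (!all(series %in% names(substituents))) {
    stop("hammett_screen: series ids missing from substituent map",
         call. = FALSE)
  }
  subs <- substituents[series]
  unmapped <- setdiff(subs, names(sigma))
  if (length(unmapped)) {
    stop("hammett_screen: no sigma value for substituent(s) ",
         paste(unique(unmapped), collapse = ", "), call. = FALSE)
  }
  fit <- linear_fit(unname(sigma[subs]), unname(descriptors[series]))
  fit$compounds <- series
  fit
}
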