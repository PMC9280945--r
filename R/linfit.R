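#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] used by every regression in the
#' package; carries the slope, intercept, their standard errors, R^2 and
#' the number of points, so each fitted table column is auditable.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return An object of class `"linear_fit"`: a list with elements
#'   `slope`, `intercept`, `r_squared`, `slope_stderr`, `intercept_stderr`,
#'   `n_points`, `residuals` and `fitted`.
#' @keywords internal
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("linear fit requires at least 3 points")
  if (anyNA(x) || anyNA(y)) stop("NA values in regression input")
  fm <- stats::lm(y ~ x)
  cf <- stats::coef(fm)
  ssr <- sum(stats::residuals(fm)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  # standard errors computed directly (summary.lm warns on exact fits)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  s2 <- ssr / (n - 2L)
  se <- c(sqrt(s2 * (1 / n + mean(x)^2 / sxx)), sqrt(s2 / sxx))
  structure(list(
    slope = unname(cf[2L]),
    intercept = unname(cf[1L]),
    r_squared = max(0, min(1, r2)),
    slope_stderr = unname(se[2L]),
    intercept_stderr = unname(se[1L]),
    n_points = length(x),
    residuals = unname(stats::residuals(fm)),
    fitted = unname(stats::fitted(fm))
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): slope = %.6g (SE %.3g), intercept = %.6g (SE %.3g), R^2 = %.5f\n",
              x$n_points, x$slope, x$slope_stderr, x$intercept,
              x$intercept_stderr, x$r_squared))
  invisible(x)
}
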