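#' Fit the full quenching model to one titration
#'
#' The central fitting function. For a single intensity-vs-quencher
#' titration it runs the whole steady-state analysis chain:
#' \enumerate{
#'   \item intensity ratios I0/I and the naive linear Stern-Volmer slope;
#'   \item quadratic curvature diagnosis (upward curvature flags combined
#'     static + dynamic quenching);
#'   \item the modified Stern-Volmer fit giving K_SV and the static
#'     intercept b, with the unquenched-fraction series W = 1 - b[Q];
#'   \item sphere-of-action volume V (slope of ln(1/W) vs [Q]) and the
#'     kinetic distance r;
#'   \item bimolecular rate k_q = K_SV/tau0;
#'   \item the ground-state-complex quadratic, rejected when its roots are
#'     complex;
#'   \item the finite-sink extrapolation (K_SV0, D, R', k_d) from
#'     1/K_SV([Q]) vs [Q]^(1/3);
#'   \item Stokes-Einstein mutual diffusion (when the solvent carries
#'     viscosity data) and the mechanism classification.
#' }
#'
#' @param titration A [quench_titration()].
#' @param constants A [probe_constants()] (lifetime, radii, slip/stick a).
#' @param k_a Optional activation rate, 10^9 M^-1 s^-1 (usually unknown).
#' @param eq_coefficient Finite-sink slope-to-D coefficient; see
#'   [finite_sink_fit()].
#' @return An object of class `"quench_fit"` with components `titration`,
#'   `ratios`, `linear`, `curvature`, `modsv`, `soa`, `k_q`, `gsc`,
#'   `apparent`, `finite_sink`, `stokes`, `classification`, `constants`.
#'   Supported methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `simulate`, `plot`.
#' @export
#' @examples
#' fit <- quench_fit(example_titrations()[["0% ACN + 100% DXN"]])
#' coef(fit)
quench_fit <- function(titration, constants = probe_constants(),
                       k_a = NA_real_,
                       eq_coefficient = (4 * pi * .N_PRIME / 3)^(1 / 3)) {
  stopifnot(inherits(titration, "quench_titration"),
            inherits(constants, "probe_constants"))
  ratios <- intensity_ratios(titration)
  if (any(ratios$ratio <= 1))
    stop("no net quenching: I0/I <= 1 at some concentration")
  lin <- linear_sv_fit(ratios)
  curv <- curvature_diagnostic(ratios)
  modsv <- modified_sv_fit(ratios)
  soa <- static_volume_fit(modsv$W_series)
  kq <- bimolecular_rate(modsv$K_SV, constants$tau0_ns)
  gsc <- ground_state_complex_fit(ratios)
  app <- apparent_sv_constants(ratios)
  fs <- finite_sink_fit(app, constants$tau0_ns, eq_coefficient)
  stokes <- if (!is.na(titration$solvent$inverse_viscosity))
    stokes_einstein_diffusion(titration$solvent, constants) else NULL
  cls <- classify_quenching(modsv, soa, fs, constants,
                            curvature = curv, k_a = k_a)
  cls$ground_state_complex_rejected <- gsc$complex_roots
  structure(list(titration = titration, ratios = ratios, linear = lin,
                 curvature = curv, modsv = modsv, soa = soa, k_q = kq,
                 gsc = gsc, apparent = app, finite_sink = fs,
                 stokes = stokes, classification = cls,
                 constants = constants),
            class = "quench_fit")
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("quench_fit: %s\n", x$titration$solvent$label))
  cat(sprintf("  K_SV = %.4f M^-1, b = %.4f M^-1, k_q = %.3f x10^9 M^-1 s^-1\n",
              x$modsv$K_SV, x$modsv$intercept_b, x$k_q))
  cat(sprintf("  V = %.4f M^-1, r = %.3f A; K_SV0 = %.4f M^-1, R' = %.3f A, k_d = %.3f x10^9\n",
              x$soa$V, x$soa$r_A, x$finite_sink$K_SV0,
              x$finite_sink$R_prime_A, x$finite_sink$k_d))
  verdict <- x$classification$diffusion_limited
  cat(sprintf("  curvature: %s; ground-state complex %s; diffusion-limited: %s\n",
              x$curvature$verdict,
              if (x$gsc$complex_roots) "rejected (imaginary k_g)" else "not rejected",
              if (is.na(verdict)) "indeterminate" else if (verdict) "yes" else "no"))
  invisible(x)
}

#' @export
summary.quench_fit <- function(object, ...) {
  print(object)
  cat("\nmodified S-V regression:\n  ")
  print(object$modsv$fit)
  cat("sphere-of-action regression (ln(1/W) vs [Q]):\n  ")
  print(object$soa$fit)
  cat("finite-sink regression (1/K_SV vs [Q]^(1/3)):\n  ")
  print(object$finite_sink$fit)
  print(object$gsc)
  print(object$classification)
  invisible(object)
}

#' @export
coef.quench_fit <- function(object, ...) {
  c(K_SV = object$modsv$K_SV,
    b = object$modsv$intercept_b,
    V = object$soa$V,
    r_A = object$soa$r_A,
    k_q = object$k_q,
    K_SV0 = object$finite_sink$K_SV0,
    D_fs = object$finite_sink$D_fs,
    R_prime_A = object$finite_sink$R_prime_A,
    k_d = object$finite_sink$k_d)
}

#' Predicted intensity ratios from a fitted quenching model
#'
#' @param object A `"quench_fit"`.
#' @param newdata Optional numeric vector of quencher concentrations (M);
#'   defaults to the fitted concentrations.
#' @param ... Unused.
#' @return Predicted I0/I under the fitted quenched-fraction model
#'   (1 + K_SV[Q])/(1 - b[Q]).
#' @export
predict.quench_fit <- function(object, newdata = NULL, ...) {
  Q <- if (is.null(newdata)) object$ratios$Q else as.numeric(newdata)
  K <- object$modsv$K_SV; b <- object$modsv$intercept_b
  if (any(b * Q >= 1)) stop("prediction outside model support: b*[Q] >= 1")
  (1 + K * Q) / (1 - b * Q)
}

#' @export
residuals.quench_fit <- function(object, ...) {
  object$ratios$ratio - predict(object)
}

#' Simulate titrations from a fitted quenching model
#'
#' Draws new titrations from the fitted quenched-fraction model with
#' multiplicative Gaussian intensity noise, via [simulate_quench_table()].
#'
#' @param object A `"quench_fit"`.
#' @param nsim Number of titrations.
#' @param seed Integer seed (reproducible; `NULL` for current stream).
#' @param noise_cv Fractional intensity noise (default 0.01).
#' @param ... Unused.
#' @return A list of `nsim` [quench_titration()] objects.
#' @export
simulate.quench_fit <- function(object, nsim = 1, seed = NULL,
                                noise_cv = 0.01, ...) {
  seeds <- .with_seed(seed,
    sample.int(.Machine$integer.max - 1L, nsim, replace = TRUE))
  lapply(seeds, function(s) {
    simulate_quench_table(synthetic_spec(
      "linear_w", K_SV = object$modsv$K_SV,
      second_param = object$modsv$intercept_b,
      I0 = object$titration$intensity[1L],
      Q_grid = object$ratios$Q, noise_cv = noise_cv, seed = s))
  })
}

#' Diagnostic plots for a quenching fit
#'
#' Four panels: the Stern-Volmer plot with the fitted quenched-fraction
#' curve, the modified S-V regression, ln(1/W) vs [Q] (sphere of action),
#' and the finite-sink extrapolation.
#'
#' @param x A `"quench_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.quench_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  r <- x$ratios
  qq <- seq(0, max(r$Q), length.out = 100)
  graphics::plot(r$Q, r$ratio, xlab = "[Q] (M)", ylab = "I0/I",
                 main = x$titration$solvent$label, ...)
  graphics::lines(qq, (1 + x$modsv$K_SV * qq) /
                        (1 - x$modsv$intercept_b * qq), col = 2)
  xv <- 1 / r$ratio; yv <- (1 - xv) / r$Q
  graphics::plot(xv, yv, xlab = "I/I0", ylab = "(1 - I/I0)/[Q]",
                 main = "modified S-V")
  graphics::abline(x$modsv$fit$intercept, x$modsv$fit$slope, col = 2)
  W <- x$modsv$W_series
  graphics::plot(W$Q, log(1 / W$W), xlab = "[Q] (M)", ylab = "ln(1/W)",
                 main = sprintf("sphere of action (V = %.2f)", x$soa$V))
  graphics::abline(x$soa$fit$intercept, x$soa$fit$slope, col = 2)
  a <- x$apparent
  graphics::plot(a$Q^(1 / 3), 1 / a$K_app, xlab = "[Q]^(1/3)",
                 ylab = "1/K_SV", main = sprintf("finite sink (K0 = %.2f)",
                                                 x$finite_sink$K_SV0))
  graphics::abline(x$finite_sink$fit$intercept, x$finite_sink$fit$slope,
                   col = 2)
  invisible(x)
}
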