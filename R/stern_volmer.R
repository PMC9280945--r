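## Steady-state Stern-Volmer analysis.
##
## Model chain: I0/I ratios -> naive linear S-V slope -> curvature check ->
## modified S-V (quenched-fraction) fit -> sphere-of-action volume V and
## kinetic distance r -> bimolecular rate k_q -> ground-state-complex test.

.as_ratios <- function(x) {
  if (inherits(x, "quench_titration")) x <- intensity_ratios(x)
  if (!is.data.frame(x) || !all(c("Q", "ratio") %in% names(x)))
    stop("expected a quench_titration or a data frame with columns Q, ratio")
  if (any(x$Q <= 0)) stop("ratio series must use nonzero [Q] only")
  x
}

#' Naive linear Stern-Volmer fit
#'
#' Ordinary least squares of I0/I on [Q]. For purely dynamic (collisional)
#' quenching the slope is the Stern-Volmer constant K_SV; when the plot
#' curves upward the slope overstates K_SV and the modified fit
#' ([modified_sv_fit()]) should be used instead.
#'
#' @param x A [quench_titration()] or data frame with columns `Q`, `ratio`.
#' @return A `"linear_fit"` (slope = K_SV in M^-1).
#' @export
linear_sv_fit <- function(x) {
  r <- .as_ratios(x)
  if (nrow(r) < 3L) stop("need at least 3 points")
  linear_fit(r$Q, r$ratio)
}

#' Diagnose Stern-Volmer curvature
#'
#' Fits the quadratic I0/I = a + b1[Q] + b2[Q]^2 and calls the plot
#' "upward" (positive deviation from linearity, the signature of combined
#' static and dynamic quenching) when the quadratic coefficient exceeds
#' twice its standard error; "downward" symmetrically; otherwise "linear".
#' With the short series typical of titrations (5-6 points) this 2-sigma
#' rule is a pragmatic screen, not a formal test.
#'
#' @inheritParams linear_sv_fit
#' @return A list with `beta2`, `beta2_stderr`, and `verdict` in
#'   `c("upward", "downward", "linear")`.
#' @export
curvature_diagnostic <- function(x) {
  r <- .as_ratios(x)
  if (nrow(r) < 4L) stop("need at least 4 points for a curvature test")
  fm <- stats::lm(ratio ~ Q + I(Q^2), data = r)
  b2 <- unname(stats::coef(fm)[3L])
  se <- suppressWarnings(sqrt(diag(stats::vcov(fm)))[3L]) # exact-fit guard
  verdict <- if (is.finite(se) && abs(b2) > 2 * se) {
    if (b2 > 0) "upward" else "downward"
  } else "linear"
  list(beta2 = b2, beta2_stderr = unname(se), verdict = verdict)
}

#' Modified Stern-Volmer (quenched-fraction) fit
#'
#' For quenching that is partly static, the intensity ratio follows
#' I0/I = (1 + K_SV[Q]) / (1 - b[Q]), where W = 1 - b[Q] is the fraction
#' of fluorophores that remain quenchable only dynamically and b is the
#' (assumed constant) (1 - W)/[Q]. The linearisation regresses
#' y = (1 - I/I0)/[Q] on x = I/I0: the slope is K_SV, the intercept is b.
#' On data generated by that model the estimator is exact; on
#' sphere-of-action data it carries a known positive bias in K_SV.
#'
#' @inheritParams linear_sv_fit
#' @return An object of class `"modified_sv_fit"`: list with `K_SV` (M^-1),
#'   `intercept_b` (M^-1), `W_series` (data frame `Q`, `W`), and `fit`
#'   (the underlying `"linear_fit"`).
#' @export
#' @examples
#' Q <- seq(0.02, 0.10, by = 0.02)
#' r <- data.frame(Q = Q, ratio = (1 + 3 * Q) / (1 - 2 * Q))
#' modified_sv_fit(r) # recovers K_SV = 3, b = 2
modified_sv_fit <- function(x) {
  r <- .as_ratios(x)
  if (nrow(r) < 4L) stop("need at least 4 nonzero-[Q] points")
  xv <- 1 / r$ratio          # I/I0
  yv <- (1 - xv) / r$Q
  fit <- linear_fit(xv, yv)
  K <- fit$slope
  b <- fit$intercept
  W <- 1 - b * r$Q
  if (any(W <= 0))
    stop("intercept inconsistent with W in (0, 1]: b * max([Q]) >= 1")
  if (max(W) < 1 + 1e-9) W <- pmin(W, 1) # round-off guard at b ~ 0
  structure(list(K_SV = K, intercept_b = b,
                 W_series = data.frame(Q = r$Q, W = W),
                 fit = fit),
            class = "modified_sv_fit")
}

#' @export
print.modified_sv_fit <- function(x, ...) {
  cat(sprintf("modified Stern-Volmer fit: K_SV = %.4f M^-1, b = %.4f M^-1 (R^2 = %.4f)\n",
              x$K_SV, x$intercept_b, x$fit$r_squared))
  cat(sprintf("  unquenched fraction W: %.3f-%.3f over [Q] = %.3g-%.3g M\n",
              min(x$W_series$W), max(x$W_series$W),
              min(x$W_series$Q), max(x$W_series$Q)))
  invisible(x)
}

#' Unquenched-fraction series W = 1 - b[Q]
#'
#' @param b Fitted modified-S-V intercept (M^-1), or a `"modified_sv_fit"`.
#' @param Q Quencher concentrations (M).
#' @return A data frame with columns `Q` and `W`, and attribute `"range"`
#'   = c(min, max).
#' @export
quenched_fraction <- function(b, Q) {
  if (inherits(b, "modified_sv_fit")) b <- b$intercept_b
  if (b * max(Q) >= 1) stop("b * max([Q]) must be < 1 for W in (0, 1]")
  W <- 1 - b * Q
  structure(data.frame(Q = Q, W = W), range = c(min(W), max(W)))
}

#' Sphere-of-action static quenching volume
#'
#' Under the sphere-of-action picture the unquenched fraction decays as
#' W = exp(-V[Q]), so ln(1/W) is linear in [Q] with slope V, the molar
#' volume of the "active sphere" within which quenching is immediate. The
#' regression keeps a free intercept.
#'
#' @param W Unquenched fractions in (0, 1] (or a data frame `Q`, `W` as
#'   returned by [quenched_fraction()], in which case `Q` may be omitted).
#' @param Q Quencher concentrations (M).
#' @return An object of class `"sphere_of_action"`: list with `V` (M^-1),
#'   `r_A` (kinetic distance, Angstrom, via [kinetic_radius()]), and `fit`.
#' @export
static_volume_fit <- function(W, Q = NULL) {
  if (is.data.frame(W)) { Q <- W$Q; W <- W$W }
  if (length(W) < 4L) stop("need at least 4 points")
  if (any(W <= 0) || any(W > 1 + 1e-9)) stop("W values must lie in (0, 1]")
  W <- pmin(W, 1)
  fit <- linear_fit(Q, log(1 / W))
  V <- max(fit$slope, 0)
  structure(list(V = V, r_A = kinetic_radius(V), fit = fit),
            class = "sphere_of_action")
}

#' @export
print.sphere_of_action <- function(x, ...) {
  cat(sprintf("sphere of action: V = %.4f M^-1, kinetic distance r = %.3f A\n",
              x$V, x$r_A))
  invisible(x)
}

#' Kinetic distance from the active-sphere volume
#'
#' Inverts V = (4/3) pi r^3 N_A x 10^-3 (V in L mol^-1, r in cm):
#' r = (3 V x 10^3 / (4 pi N_A))^(1/3), returned in Angstrom. Scales as
#' V^(1/3), so r(8V) = 2 r(V).
#'
#' @param V Static quenching constant, M^-1 (>= 0).
#' @return Kinetic distance r in Angstrom.
#' @export
#' @examples
#' kinetic_radius(8.472) # ~14.98 A
kinetic_radius <- function(V) {
  if (any(V < 0)) stop("V must be non-negative")
  (3 * V * 1e3 / (4 * pi * .N_AVOGADRO))^(1 / 3) / .CM_PER_ANGSTROM
}

#' Bimolecular quenching rate constant
#'
#' k_q = K_SV / tau0, reported in the conventional 10^9 M^-1 s^-1 units.
#'
#' @param K_SV Stern-Volmer constant, M^-1.
#' @param tau0_ns Unquenched lifetime, ns.
#' @return k_q in 10^9 M^-1 s^-1.
#' @export
#' @examples
#' bimolecular_rate(14.516, 1.10) # 13.196
bimolecular_rate <- function(K_SV, tau0_ns) {
  if (tau0_ns <= 0) stop("tau0 must be positive")
  K_SV / tau0_ns # M^-1 / ns = 1e9 M^-1 s^-1
}

#' Ground-state complex model fit
#'
#' If static quenching arose from a non-emissive 1:1 ground-state complex
#' with association constant k_g alongside dynamic quenching K_SV, the
#' ratio would follow I0/I = (1 + K_SV[Q])(1 + k_g[Q]) =
#' 1 + S[Q] + P[Q]^2 with S = K_SV + k_g and P = K_SV k_g. The fit
#' regresses (I0/I - 1) on [Q] and [Q]^2 with the intercept pinned at 1 and
#' recovers the pair as roots of z^2 - Sz + P = 0. A negative discriminant
#' (complex roots, "imaginary k_g") rejects the model; |discriminant| <=
#' 1e-12 is reported as a degenerate repeated root rather than imaginary.
#'
#' @inheritParams linear_sv_fit
#' @return An object of class `"gsc_fit"`: list with `sum_constant` (S,
#'   M^-1), `product_constant` (P, M^-2), `discriminant`, `roots` (numeric
#'   descending when real, complex pair otherwise), `complex_roots` and
#'   `degenerate` flags.
#' @export
ground_state_complex_fit <- function(x) {
  r <- .as_ratios(x)
  if (nrow(r) < 4L) stop("need at least 4 points")
  X <- cbind(r$Q, r$Q^2)
  if (qr(X)$rank < 2L) stop("singular design: [Q] grid cannot separate S and P")
  cf <- stats::coef(stats::lm((r$ratio - 1) ~ 0 + X))
  S <- unname(cf[1L]); P <- unname(cf[2L])
  disc <- S^2 - 4 * P
  degenerate <- abs(disc) <= 1e-12
  complex_roots <- !degenerate && disc < 0
  roots <- if (complex_roots) {
    (S + c(1, -1) * sqrt(as.complex(disc))) / 2
  } else if (degenerate) {
    c(S / 2, S / 2)
  } else {
    sort((S + c(1, -1) * sqrt(disc)) / 2, decreasing = TRUE)
  }
  structure(list(sum_constant = S, product_constant = P, discriminant = disc,
                 roots = roots, complex_roots = complex_roots,
                 degenerate = degenerate),
            class = "gsc_fit")
}

#' @export
print.gsc_fit <- function(x, ...) {
  cat(sprintf("ground-state complex fit: S = %.4f M^-1, P = %.4f M^-2\n",
              x$sum_constant, x$product_constant))
  if (x$complex_roots) {
    cat("  discriminant < 0: k_g imaginary -> ground-state complex model rejected\n")
  } else if (x$degenerate) {
    cat(sprintf("  repeated root at %.4f M^-1\n", Re(x$roots[1L])))
  } else {
    cat(sprintf("  real roots (K_SV, k_g candidates): %.4f, %.4f M^-1\n",
                x$roots[1L], x$roots[2L]))
  }
  invisible(x)
}
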