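## TCSPC decay analysis: multiexponential tail fitting and the
## transient-state (lifetime-based) Stern-Volmer plot.

#' Fit a multiexponential model to a TCSPC decay tail
#'
#' Fits counts(t) = background + sum_i A_i exp(-(t - t_peak)/tau_i) to the
#' bins after the histogram maximum (tail fitting; no instrument-response
#' deconvolution), by Levenberg-Marquardt weighted least squares with
#' Poisson weights (variance approximated by max(counts, 1)). Positivity
#' of amplitudes and lifetimes is enforced by fitting on the log scale.
#'
#' Initial values come from deterministic exponential peeling: the tail is
#' cut into `n_components` equal time segments, and log-linear fits from
#' the slowest segment backwards supply one (A, tau) pair each. A small
#' fixed ladder of lifetime rescalings provides extra deterministic
#' starts; the converged fit with the lowest weighted residual sum wins.
#'
#' @param trace A [decay_trace()].
#' @param n_components 1, 2 or 3 exponential components.
#' @param background Known constant background counts per bin (default 0),
#'   held fixed during the fit.
#' @return An object of class `"multiexp_fit"`: list with `amplitudes`
#'   (fractional, summing to 1, ordered with `lifetimes_ns` descending),
#'   `lifetimes_ns`, `amplitude_weighted_mean_ns` (sum alpha_i tau_i),
#'   `intensity_weighted_mean_ns` (sum alpha tau^2 / sum alpha tau),
#'   `chi2_reduced`, `n_components`, and the raw `A_counts`.
#' @export
fit_multiexponential <- function(trace, n_components = 2L, background = 0) {
  stopifnot(inherits(trace, "decay_trace"))
  n_components <- as.integer(n_components)
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3")
  peak <- which.max(trace$counts)
  t <- trace$time_ns[-seq_len(peak)] - trace$time_ns[peak]
  y <- trace$counts[-seq_len(peak)]
  if (length(t) < 10L * (2L * n_components + 1L))
    stop("too few bins past the peak for ", n_components, " components")
  w <- 1 / pmax(y, 1)

  peel <- .peel_starts(t, y, background, n_components)
  starts <- c(list(peel), lapply(c(0.5, 2), function(f) {
    s <- peel; s$tau <- s$tau * f; s
  }))

  model_fun <- function(p, t) {
    A <- exp(p[seq_len(n_components)])
    tau <- exp(p[n_components + seq_len(n_components)])
    background + colSums(A * exp(-outer(1 / tau, t)))
  }
  best <- NULL
  for (s in starts) {
    p0 <- c(log(pmax(s$A, 1e-6)), log(pmax(s$tau, 1e-6)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) sqrt(w) * (y - model_fun(p, t)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
  }
  if (is.null(best))
    stop("multiexponential fit failed to converge from all starts (",
         length(starts), " deterministic initialisations tried)")

  A <- exp(best$par[seq_len(n_components)])
  tau <- exp(best$par[n_components + seq_len(n_components)])
  o <- order(tau, decreasing = TRUE)
  A <- A[o]; tau <- tau[o]
  alpha <- A / sum(A)
  dof <- length(t) - 2L * n_components
  structure(list(
    amplitudes = alpha,
    lifetimes_ns = tau,
    amplitude_weighted_mean_ns = sum(alpha * tau),
    intensity_weighted_mean_ns = sum(alpha * tau^2) / sum(alpha * tau),
    chi2_reduced = best$ssr / dof,
    n_components = n_components,
    A_counts = A,
    background = background
  ), class = "multiexp_fit")
}

# Exponential peeling on log(counts): slowest component from the last time
# segment, subtracted off, and so on. Deterministic.
.peel_starts <- function(t, y, background, n) {
  resid <- pmax(y - background, 0)
  brk <- seq(min(t), max(t), length.out = n + 1L)
  A <- numeric(n); tau <- numeric(n)
  for (k in rev(seq_len(n))) {
    seg <- t >= brk[k] & t <= brk[k + 1L] & resid > 0
    if (sum(seg) < 3L) seg <- resid > 0 # fall back to the whole tail
    cf <- stats::coef(stats::lm(log(resid[seg]) ~ t[seg]))
    tau[k] <- if (is.na(cf[2L]) || cf[2L] >= 0) max(t) / (2 * k)
              else -1 / cf[2L]
    A[k] <- exp(cf[1L])
    resid <- pmax(resid - A[k] * exp(-t / tau[k]), 0)
  }
  list(A = A, tau = tau)
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("%d-exponential tail fit (chi2_red = %.3f)\n",
              x$n_components, x$chi2_reduced))
  for (i in seq_len(x$n_components))
    cat(sprintf("  tau%d = %.4f ns (alpha = %.3f)\n",
                i, x$lifetimes_ns[i], x$amplitudes[i]))
  cat(sprintf("  amplitude-weighted mean = %.4f ns; intensity-weighted = %.4f ns\n",
              x$amplitude_weighted_mean_ns, x$intensity_weighted_mean_ns))
  invisible(x)
}

#' Transient-state Stern-Volmer fit
#'
#' Dynamic quenching shortens the lifetime as tau0/tau = 1 + K_D [Q];
#' static quenching leaves lifetimes untouched. The regression of tau0/tau
#' on [Q] therefore isolates the dynamic constant K_D, and comparing it
#' with the steady-state slope quantifies how strongly static processes
#' dominate.
#'
#' @param lifetimes Data frame with columns `Q` (M) and `tau_ns`.
#' @param tau0_ns Unquenched lifetime, ns.
#' @return A `"linear_fit"`; slope = dynamic quenching constant K_D (M^-1).
#' @export
transient_sv_fit <- function(lifetimes, tau0_ns) {
  stopifnot(is.data.frame(lifetimes),
            all(c("Q", "tau_ns") %in% names(lifetimes)))
  if (nrow(lifetimes) < 3L) stop("need at least 3 points")
  if (any(lifetimes$tau_ns <= 0)) stop("lifetimes must be positive")
  if (tau0_ns <= 0) stop("tau0 must be positive")
  linear_fit(lifetimes$Q, tau0_ns / lifetimes$tau_ns)
}

#' Steady-state vs transient divergence
#'
#' Flags "static dominant" quenching when the steady-state Stern-Volmer
#' slope exceeds the transient (lifetime) slope by more than `factor`.
#'
#' @param K_steady Steady-state S-V slope, M^-1.
#' @param K_transient Transient S-V slope, M^-1.
#' @param factor Dominance threshold (default 2).
#' @return One of `"static dominant"`, `"mixed"`, `"dynamic only"`.
#' @export
quenching_divergence <- function(K_steady, K_transient, factor = 2) {
  if (K_transient <= 0) return("static dominant")
  ratio <- K_steady / K_transient
  if (ratio > factor) "static dominant"
  else if (ratio > 1.05) "mixed"
  else "dynamic only"
}
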