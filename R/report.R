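#' Run the quenching analysis over a set of titrations
#'
#' Applies [quench_fit()] to every titration and assembles a per-solvent
#' record table mirroring the conventional presentation of quenching
#' studies (K_SV, k_q, intercept, W range, V, r; K_SV0, D, R', k_d;
#' Stokes-Einstein D; verdict flags). Failures in one solvent are isolated:
#' the record carries the error message and the remaining systems are
#' still analysed.
#'
#' @param titrations A list of [quench_titration()] objects (e.g. from
#'   [read_titration()] or [example_titrations()]).
#' @param constants A [probe_constants()].
#' @param k_a Optional activation rate, 10^9 M^-1 s^-1.
#' @param seed Seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return An object of class `"quench_analysis"`: list with `fits` (named
#'   list of `"quench_fit"`), `records` (data frame, one row per solvent),
#'   `errors` (named character), and `provenance`.
#' @export
#' @examples
#' rep <- quench_analysis(example_titrations())
#' as.data.frame(rep)[, c("solvent", "K_SV", "V", "K_SV0")]
quench_analysis <- function(titrations, constants = probe_constants(),
                            k_a = NA_real_, seed = NA_integer_) {
  if (inherits(titrations, "quench_titration")) titrations <- list(titrations)
  if (!length(titrations)) stop("need at least one titration")
  labs <- vapply(titrations, function(t) t$solvent$label, character(1))
  fits <- list(); errors <- character(0)
  records <- lapply(seq_along(titrations), function(k) {
    res <- tryCatch(quench_fit(titrations[[k]], constants, k_a = k_a),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[labs[k]]] <<- conditionMessage(res)
      return(data.frame(solvent = labs[k], error = conditionMessage(res)))
    }
    fits[[labs[k]]] <<- res
    .record_row(res)
  })
  records <- do.call(rbind, lapply(records, function(r) {
    # pad failed rows to the full column set
    full <- .record_row(NULL)
    for (nm in names(r)) full[[nm]] <- r[[nm]]
    full
  }))
  prov <- list(schema_version = "1.0",
               package = "svquench",
               package_version = as.character(utils::packageVersion("svquench")),
               tau0_ns = constants$tau0_ns,
               radius_solute_A = constants$radius_solute_A,
               radius_quencher_A = constants$radius_quencher_A,
               stokes_einstein_a = constants$stokes_einstein_a,
               seed = seed)
  structure(list(fits = fits, records = records, errors = errors,
                 provenance = prov),
            class = "quench_analysis")
}

.record_row <- function(fit) {
  if (is.null(fit)) {
    return(data.frame(solvent = NA_character_, error = NA_character_,
                      dielectric_constant = NA_real_, K_SV = NA_real_,
                      k_q = NA_real_, intercept_b = NA_real_,
                      W_min = NA_real_, W_max = NA_real_, V = NA_real_,
                      r_A = NA_real_, K_SV0 = NA_real_, D_fs = NA_real_,
                      R_prime_A = NA_real_, k_d = NA_real_,
                      k_q_total = NA_real_, D_stokes = NA_real_,
                      upward_curvature = NA, static_present = NA,
                      dynamic_present = NA, gsc_rejected = NA,
                      diffusion_limited = NA, r_vs_R_ratio = NA_real_))
  }
  cls <- fit$classification
  data.frame(solvent = fit$titration$solvent$label, error = NA_character_,
             dielectric_constant = fit$titration$solvent$dielectric_constant,
             K_SV = fit$modsv$K_SV, k_q = fit$k_q,
             intercept_b = fit$modsv$intercept_b,
             W_min = min(fit$modsv$W_series$W),
             W_max = max(fit$modsv$W_series$W),
             V = fit$soa$V, r_A = fit$soa$r_A,
             K_SV0 = fit$finite_sink$K_SV0, D_fs = fit$finite_sink$D_fs,
             R_prime_A = fit$finite_sink$R_prime_A,
             k_d = fit$finite_sink$k_d, k_q_total = cls$k_q_total,
             D_stokes = if (is.null(fit$stokes)) NA_real_
                        else fit$stokes$D_mutual,
             upward_curvature = cls$upward_curvature,
             static_present = cls$static_present,
             dynamic_present = cls$dynamic_present,
             gsc_rejected = cls$ground_state_complex_rejected,
             diffusion_limited = cls$diffusion_limited,
             r_vs_R_ratio = cls$r_vs_R_ratio)
}

#' @export
print.quench_analysis <- function(x, ...) {
  cat(sprintf("quench_analysis: %d solvent system(s), %d failed\n",
              nrow(x$records), length(x$errors)))
  cols <- c("solvent", "K_SV", "k_q", "intercept_b", "V", "r_A", "K_SV0",
            "R_prime_A", "k_d")
  print(format(x$records[, cols], digits = 5), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.quench_analysis <- function(x, ...) x$records

#' Write an analysis report to JSON
#'
#' Versioned-schema JSON with full numeric precision; round-trips
#' losslessly through [read_quench_report()]. No timestamps are written,
#' so identical analyses give byte-identical reports.
#'
#' @param report A `"quench_analysis"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quench_report <- function(report, path) {
  stopifnot(inherits(report, "quench_analysis"))
  payload <- list(provenance = report$provenance,
                  records = report$records,
                  errors = as.list(report$errors))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an analysis report written by [write_quench_report()]
#'
#' @param path JSON path.
#' @return A list with `provenance`, `records` (data frame) and `errors`.
#' @export
read_quench_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$provenance$schema_version))
    stop("not a svquench report: missing schema version")
  payload$records <- as.data.frame(payload$records)
  payload
}
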