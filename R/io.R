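#' Read quenching titrations from CSV
#'
#' Two layouts are supported. `"wide"` mirrors the way titration tables are
#' usually printed: a `Q` column of quencher concentrations (M, including
#' the 0 row) followed by one intensity column per solvent system, whose
#' header is the solvent label. `"long"` has columns `solvent`, `Q`, `I`
#' (one row per measurement).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect `"wide"` or `"long"`.
#' @param solvents Optional data frame of solvent metadata with a `label`
#'   column and any of `fraction_acn`, `dielectric_constant`,
#'   `inverse_viscosity_P`, `temperature_K`, `excitation_nm`,
#'   `emission_nm`; matched to titrations by label.
#' @return A named list of [quench_titration()] objects, one per solvent.
#' @export
read_titration <- function(path, dialect = c("wide", "long"), solvents = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(df) < 2L) stop("wide layout needs a Q column plus >= 1 intensity column")
    q <- as.numeric(df[[1L]])
    out <- lapply(names(df)[-1L], function(lab) {
      .build_titration(q, as.numeric(df[[lab]]), lab, solvents)
    })
    names(out) <- names(df)[-1L]
  } else {
    need <- c("solvent", "Q", "I")
    if (!all(need %in% names(df)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    out <- lapply(split(df, factor(df$solvent, levels = unique(df$solvent))),
                  function(g) {
                    o <- order(g$Q)
                    .build_titration(as.numeric(g$Q[o]), as.numeric(g$I[o]),
                                     g$solvent[1L], solvents)
                  })
  }
  out
}

.build_titration <- function(q, i, label, solvents = NULL) {
  if (!any(q == 0)) stop("no unquenched reference ([Q] = 0 row) for ", label)
  sol <- solvent_system(label)
  exi <- NA_real_; emi <- NA_real_
  if (!is.null(solvents)) {
    row <- solvents[solvents$label == label, , drop = FALSE]
    if (nrow(row) == 1L) {
      grab <- function(col, default = NA_real_)
        if (col %in% names(row)) as.numeric(row[[col]]) else default
      sol <- solvent_system(label,
        fraction_acn = grab("fraction_acn"),
        dielectric_constant = grab("dielectric_constant"),
        inverse_viscosity = grab("inverse_viscosity_P"),
        temperature = grab("temperature_K", 298.15))
      exi <- grab("excitation_nm"); emi <- grab("emission_nm")
    }
  }
  quench_titration(q, i, sol, excitation_nm = exi, emission_nm = emi)
}

#' Write quenching titrations to CSV
#'
#' Inverse of [read_titration()]; round-trips numeric values at full
#' precision (15 significant digits).
#'
#' @param titrations A `quench_titration` or list of them.
#' @param path Output CSV path.
#' @param dialect `"wide"` (requires a common concentration grid) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_titration <- function(titrations, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (inherits(titrations, "quench_titration")) titrations <- list(titrations)
  labs <- vapply(titrations, function(t) t$solvent$label, character(1))
  fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  if (dialect == "wide") {
    q0 <- titrations[[1L]]$quencher_conc
    same <- vapply(titrations, function(t)
      length(t$quencher_conc) == length(q0) && all(t$quencher_conc == q0),
      logical(1))
    if (!all(same)) stop("wide layout requires a common [Q] grid")
    df <- data.frame(Q = fmt(q0), check.names = FALSE)
    for (k in seq_along(titrations)) df[[labs[k]]] <- fmt(titrations[[k]]$intensity)
  } else {
    df <- do.call(rbind, lapply(seq_along(titrations), function(k)
      data.frame(solvent = unname(labs[k]),
                 Q = fmt(titrations[[k]]$quencher_conc),
                 I = fmt(titrations[[k]]$intensity))))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Intensity quenching ratios I0/I
#'
#' @param titration A [quench_titration()].
#' @return A data frame with columns `Q` (M, the nonzero concentrations)
#'   and `ratio` (I0/I, dimensionless), plus a logical attribute
#'   `"enhancement"` set when any ratio falls below 1 (intensity grew with
#'   quencher — flagged, not an error).
#' @export
#' @examples
#' t <- quench_titration(c(0, 0.05), c(100, 50), "demo")
#' intensity_ratios(t) # ratio 2 at Q = 0.05
intensity_ratios <- function(titration) {
  stopifnot(inherits(titration, "quench_titration"))
  i0 <- titration$intensity[titration$quencher_conc == 0][1L]
  keep <- titration$quencher_conc > 0
  out <- data.frame(Q = titration$quencher_conc[keep],
                    ratio = i0 / titration$intensity[keep])
  attr(out, "enhancement") <- any(out$ratio < 1)
  out
}

#' Read a two-column spectrum CSV (wavelength_nm, intensity)
#' @param path CSV path.
#' @return A [spectrum_trace()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spectrum_trace(df[[1L]], df[[2L]])
}

#' Read a two-column TCSPC decay CSV (time_ns, counts)
#' @param path CSV path.
#' @return A [decay_trace()].
#' @export
read_decay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  decay_trace(df[[1L]], df[[2L]])
}

#' Bundled example titrations
#'
#' The package ships the published intensity-vs-aniline titration table of
#' the coumarin probe 2AHBC in six acetonitrile/1,4-dioxane (ACN/DXN)
#' mixtures (quencher 0-0.10 M in 0.02 M steps), together with each
#' mixture's dielectric constant, inverse viscosity and band maxima.
#'
#' @return A named list of six [quench_titration()] objects.
#' @export
#' @examples
#' tabs <- example_titrations()
#' intensity_ratios(tabs[["0% ACN + 100% DXN"]])
example_titrations <- function() {
  dir <- system.file("extdata", package = "svquench")
  sol <- utils::read.csv(file.path(dir, "acn_dxn_solvents.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  read_titration(file.path(dir, "acn_dxn_titration.csv"),
                 dialect = "wide", solvents = sol)
}
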