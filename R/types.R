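#' Describe a solvent system
#'
#' A solvent system records the composition and bulk properties of one
#' binary solvent mixture in which a titration was carried out. Viscosity
#' is stored as its reciprocal in poise^-1, the form diffusion formulas
#' consume directly.
#'
#' @param label Character label, e.g. `"100% ACN + 0% DXN"`.
#' @param fraction_acn Volume fraction of the polar co-solvent, in [0, 1].
#' @param dielectric_constant Relative permittivity (dimensionless, >= 1).
#' @param inverse_viscosity Reciprocal viscosity in P^-1 (> 0), or `NA` if
#'   unknown.
#' @param temperature Absolute temperature in K. Default 298.15.
#' @return An object of class `"solvent_system"`.
#' @export
#' @examples
#' solvent_system("100% ACN + 0% DXN", 1, 36.0, 290.4)
solvent_system <- function(label, fraction_acn = NA_real_,
                           dielectric_constant = NA_real_,
                           inverse_viscosity = NA_real_,
                           temperature = 298.15) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.na(fraction_acn) && (fraction_acn < 0 || fraction_acn > 1))
    stop("fraction_acn must lie in [0, 1]")
  if (!is.na(dielectric_constant) && dielectric_constant < 1)
    stop("dielectric constant must be >= 1")
  if (!is.na(inverse_viscosity) && inverse_viscosity <= 0)
    stop("inverse_viscosity must be positive")
  if (temperature <= 0) stop("temperature must be positive (K)")
  structure(list(label = label,
                 fraction_acn = as.numeric(fraction_acn),
                 dielectric_constant = as.numeric(dielectric_constant),
                 inverse_viscosity = as.numeric(inverse_viscosity),
                 temperature = as.numeric(temperature)),
            class = "solvent_system")
}

#' Construct a quenching titration
#'
#' One titration is a series of fluorescence intensities measured at
#' increasing quencher concentrations in a single solvent system, with the
#' unquenched reference intensity I0 at [Q] = 0.
#'
#' @param quencher_conc Quencher concentrations in M, strictly increasing,
#'   first entry 0 (the unquenched reference).
#' @param intensity Fluorescence intensities (arbitrary units, > 0), same
#'   length as `quencher_conc`.
#' @param solvent A [solvent_system()], or a character label.
#' @param excitation_nm,emission_nm Optional band maxima in nm.
#' @return An object of class `"quench_titration"`.
#' @details If any intensity at [Q] > 0 exceeds I0 the constructor warns
#'   (fluorescence enhancement rather than quenching); downstream ratio
#'   computations flag such points rather than fail.
#' @export
#' @examples
#' quench_titration(c(0, 0.05), c(100, 50), "demo")
quench_titration <- function(quencher_conc, intensity, solvent = "unspecified",
                             excitation_nm = NA_real_, emission_nm = NA_real_) {
  quencher_conc <- as.numeric(quencher_conc)
  intensity <- as.numeric(intensity)
  if (length(quencher_conc) != length(intensity))
    stop("quencher_conc and intensity must have equal length")
  if (length(quencher_conc) < 2L) stop("a titration needs at least 2 points")
  if (any(diff(quencher_conc) <= 0))
    stop("quencher concentrations must be strictly increasing")
  if (quencher_conc[1L] != 0)
    stop("no unquenched reference: first row must have [Q] = 0")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("all intensities must be positive and finite")
  if (is.character(solvent)) solvent <- solvent_system(solvent)
  stopifnot(inherits(solvent, "solvent_system"))
  if (any(intensity[-1L] > intensity[1L]))
    warning("intensity exceeds I0 at some [Q] > 0: enhancement, not quenching")
  structure(list(solvent = solvent,
                 quencher_conc = quencher_conc,
                 intensity = intensity,
                 excitation_nm = as.numeric(excitation_nm),
                 emission_nm = as.numeric(emission_nm)),
            class = "quench_titration")
}

#' @export
print.quench_titration <- function(x, ...) {
  cat(sprintf("quench_titration: %s\n", x$solvent$label))
  cat(sprintf("  I0 = %.3f at [Q] = 0; %d titration points, [Q] up to %.3g M\n",
              x$intensity[1L], length(x$quencher_conc) - 1L,
              max(x$quencher_conc)))
  invisible(x)
}

#' Physical constants of the probe/quencher pair
#'
#' Holds the unquenched lifetime and the molecular radii entering the
#' encounter-distance and Stokes-Einstein computations. Defaults are the
#' coumarin-probe/aniline pair studied by the shipped example data:
#' tau0 = 1.10 ns, R_S = 3.68 A, R_Q = 2.84 A (so R = 6.52 A).
#'
#' @param tau0_ns Unquenched excited-state lifetime, ns.
#' @param radius_solute_A Solute (fluorophore) radius, Angstrom.
#' @param radius_quencher_A Quencher radius, Angstrom.
#' @param stokes_einstein_a Dimensionless slip/stick boundary parameter of
#'   the Stokes-Einstein relation, conventionally 6 (stick) or 4 (slip).
#' @return An object of class `"probe_constants"` with the derived
#'   `encounter_distance_A` = R_S + R_Q.
#' @export
probe_constants <- function(tau0_ns = 1.10, radius_solute_A = 3.68,
                            radius_quencher_A = 2.84, stokes_einstein_a = 6) {
  if (tau0_ns <= 0) stop("tau0 must be positive")
  if (radius_solute_A <= 0 || radius_quencher_A <= 0)
    stop("radii must be positive")
  if (stokes_einstein_a < 4 || stokes_einstein_a > 6)
    stop("stokes_einstein_a outside the conventional [4, 6] range")
  structure(list(tau0_ns = tau0_ns,
                 radius_solute_A = radius_solute_A,
                 radius_quencher_A = radius_quencher_A,
                 encounter_distance_A = radius_solute_A + radius_quencher_A,
                 stokes_einstein_a = stokes_einstein_a,
                 n_prime = .N_PRIME),
            class = "probe_constants")
}

#' Construct a spectrum trace
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param intensity Non-negative intensities, same length.
#' @param normalized Logical; `TRUE` if the trace has unit peak height.
#' @return An object of class `"spectrum_trace"`.
#' @export
spectrum_trace <- function(wavelength_nm, intensity, normalized = FALSE) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  stopifnot(length(wavelength_nm) == length(intensity))
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (isTRUE(normalized) && !isTRUE(all.equal(max(intensity), 1)))
    stop("normalized trace must have maximum intensity 1")
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 normalized = isTRUE(normalized)),
            class = "spectrum_trace")
}

#' Construct a TCSPC decay trace
#'
#' @param time_ns Ascending, uniformly spaced bin times, ns.
#' @param counts Non-negative integer photon counts per bin.
#' @return An object of class `"decay_trace"`.
#' @export
decay_trace <- function(time_ns, counts) {
  time_ns <- as.numeric(time_ns)
  counts <- as.numeric(counts)
  stopifnot(length(time_ns) == length(counts), length(time_ns) >= 2L)
  dt <- diff(time_ns)
  if (any(dt <= 0)) stop("time grid must be ascending")
  if (max(dt) - min(dt) > 1e-9 * mean(dt)) stop("time bins must be uniform")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(time_ns = time_ns, counts = counts, bin_width_ns = mean(dt)),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("decay_trace: %d bins of %.4g ns, %.0f total counts\n",
              length(x$time_ns), x$bin_width_ns, sum(x$counts)))
  invisible(x)
}
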