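## Physical constants (CGS where rate formulas need them).
## N' converts per-molecule, per-cm^3 encounter rates into M^-1 s^-1:
## N' = N_A x 1e-3 molecules cm^-3 per mol L^-1.
.N_AVOGADRO <- 6.02214076e23
.N_PRIME <- .N_AVOGADRO * 1e-3
.KB_ERG <- 1.380649e-16 # erg K^-1
.CM_PER_ANGSTROM <- 1e-8

#' Avogadro-scaled concentration conversion constant
#'
#' Returns N' = N_A x 10^-3, the number of molecules per cm^3 at a
#' concentration of 1 mol L^-1. Rate expressions of the form 4*pi*N'*R*D
#' (R in cm, D in cm^2 s^-1) then carry units of M^-1 s^-1.
#'
#' @return A single number, 6.02214076e20.
#' @export
n_prime <- function() .N_PRIME
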