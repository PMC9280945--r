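# Shared fixtures: the bundled ACN/DXN titration table and the published
# reference values its analysis should reproduce.

fixture_titrations <- function() example_titrations()

dxn_label <- "0% ACN + 100% DXN"
acn_label <- "100% ACN + 0% DXN"

# Published per-solvent quenching parameters (steady-state analysis).
table2_ref <- data.frame(
  solvent = c("100% ACN + 0% DXN", "80% ACN + 20% DXN", "60% ACN + 40% DXN",
              "40% ACN + 60% DXN", "20% ACN + 80% DXN", "0% ACN + 100% DXN"),
  epsilon = c(36.0, 28.6, 22.0, 15.3, 8.1, 2.1),
  K_SV    = c(14.516, 8.274, 7.820, 7.248, 4.852, 2.545),
  k_q     = c(13.196, 7.522, 7.109, 6.589, 4.411, 2.314),
  b       = c(4.420, 5.509, 3.804, 5.445, 4.644, 5.498),
  W_min   = c(0.558, 0.449, 0.619, 0.455, 0.535, 0.450),
  W_max   = c(0.912, 0.889, 0.924, 0.891, 0.907, 0.890),
  V       = c(6.119, 8.499, 4.985, 8.340, 6.563, 8.472),
  r_A     = c(13.430, 14.990, 12.550, 14.890, 13.750, 14.970),
  stringsAsFactors = FALSE)

# Published finite-sink parameters.
table3_ref <- data.frame(
  solvent = table2_ref$solvent,
  K_SV0 = c(13.119, 9.009, 8.436, 8.268, 6.536, 5.228),
  D_e5  = c(1.918, 1.155, 1.376, 1.058, 0.931, 0.666),
  R_prime_A = c(8.220, 9.370, 7.330, 9.390, 8.430, 9.430),
  k_d   = c(11.926, 8.190, 7.639, 7.516, 5.942, 4.752),
  stringsAsFactors = FALSE)

ref_tau0_ns <- 1.10
ref_R_A <- 6.52 # encounter distance, R_S (3.68) + R_Q (2.84)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Independent brute-force OLS oracle: iteratively refined grid search over
# (intercept, slope) minimising the residual sum of squares. Never calls lm.
grid_search_line <- function(x, y, span = 50, n = 81, rounds = 6) {
  ic <- mean(y); sc <- 0
  iw <- span; sw <- span
  for (r in seq_len(rounds)) {
    is <- seq(ic - iw, ic + iw, length.out = n)
    ss <- seq(sc - sw, sc + sw, length.out = n)
    sse <- outer(is, ss, Vectorize(function(a, b) sum((y - a - b * x)^2)))
    k <- arrayInd(which.min(sse), dim(sse))
    ic <- is[k[1]]; sc <- ss[k[2]]
    iw <- iw * 4 / n; sw <- sw * 4 / n
  }
  c(intercept = ic, slope = sc)
}
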