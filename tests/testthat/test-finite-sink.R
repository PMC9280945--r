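qgrid <- seq(0.02, 0.10, by = 0.02)

test_that("apparent S-V constants are (I0/I - 1)/[Q]", {
  r <- intensity_ratios(fixture_titrations()[[acn_label]])
  app <- apparent_sv_constants(r)
  # hand division at [Q] = 0.02: (4665.500/3301.952 - 1)/0.02
  expect_equal(app$K_app[1L], 20.6476, tolerance = 1e-4)
  lin <- data.frame(Q = qgrid, ratio = 1 + 5 * qgrid)
  expect_equal(apparent_sv_constants(lin)$K_app, rep(5, 5), tolerance = 1e-12)
  expect_error(apparent_sv_constants(
    data.frame(Q = qgrid, ratio = c(0.99, 1.2, 1.4, 1.6, 1.8))),
    "no net quenching")
})

test_that("apparent constants on quenched-fraction data follow (K+b)/(1-bQ)", {
  K <- 3; b <- 2
  r <- data.frame(Q = qgrid, ratio = (1 + K * qgrid) / (1 - b * qgrid))
  app <- apparent_sv_constants(r)
  expect_equal(app$K_app, (K + b) / (1 - b * qgrid), tolerance = 1e-12)
  expect_true(all(diff(app$K_app) > 0))
})

test_that("finite-sink extrapolation reproduces the published K_SV0", {
  tabs <- fixture_titrations()
  for (k in seq_len(nrow(table3_ref))) {
    fs <- finite_sink_fit(tabs[[table3_ref$solvent[k]]], ref_tau0_ns)
    expect_lt(rel_err(fs$K_SV0, table3_ref$K_SV0[k]), 0.02)
  }
})

test_that("constant apparent constants give zero slope and exact K_SV0", {
  lin <- data.frame(Q = qgrid, ratio = 1 + 7 * qgrid)
  fs <- finite_sink_fit(lin, 1.10)
  expect_equal(fs$fit$slope, 0, tolerance = 1e-10)
  expect_equal(fs$K_SV0, 7, tolerance = 1e-9)
  expect_equal(fs$k_d, 7 / 1.10, tolerance = 1e-9)
})

test_that("extrapolated K_SV0 stays below the smallest apparent constant", {
  # On quenched-fraction data 1/K_app rises towards [Q] = 0, so the
  # [Q]^(1/3) extrapolation lands below every observed apparent constant.
  for (K in c(0.5, 2.545, 10, 25)) for (b in c(0.5, 2, 5.5, 9)) {
    r <- data.frame(Q = qgrid, ratio = (1 + K * qgrid) / (1 - b * qgrid))
    fs <- finite_sink_fit(r, 1.10)
    expect_gt(fs$K_SV0, 0)
    expect_lt(fs$K_SV0, min(apparent_sv_constants(r)$K_app))
  }
})

test_that("distance parameter matches the published rows and scales as 1/D", {
  expect_equal(distance_parameter(13.119, 1.918e-5, 1.10), 8.220,
               tolerance = 1e-3 * 8.22)
  expect_equal(distance_parameter(5.228, 0.666e-5, 1.10), 9.430,
               tolerance = 1e-3 * 9.43)
  expect_equal(distance_parameter(10, 2e-5, 1.1),
               distance_parameter(10, 1e-5, 1.1) / 2, tolerance = 1e-12)
  expect_error(distance_parameter(-1, 1e-5, 1.1), "positive")
})

test_that("encounter rate matches the published rows and the K_SV0/tau0 identity", {
  expect_equal(encounter_rate(8.220, 1.918e-5), 11.926,
               tolerance = 5e-3 * 11.926)
  expect_equal(encounter_rate(9.430, 0.666e-5), 4.752,
               tolerance = 5e-3 * 4.752)
  # identity 4 pi N' R' D = K_SV0/tau0 for any positive inputs
  set.seed(11)
  for (i in 1:25) {
    K0 <- stats::runif(1, 0.5, 30)
    D <- stats::runif(1, 1e-6, 5e-5)
    tau <- stats::runif(1, 0.2, 10)
    kd <- encounter_rate(distance_parameter(K0, D, tau), D)
    expect_equal(kd, K0 / tau, tolerance = 1e-9)
  }
})

test_that("Stokes-Einstein diffusion has the right magnitude and scalings", {
  sol <- solvent_system("ACN", 1, 36, inverse_viscosity = 1 / 0.00344,
                        temperature = 298)
  pc <- probe_constants(stokes_einstein_a = 6)
  d <- stokes_einstein_diffusion(sol, pc)
  # hand evaluation: kB*T/(6*pi*eta*R) per species, eta = 0.344 cP
  kb <- 1.380649e-16
  D_hand <- kb * 298 / (6 * pi * 0.00344 * 3.68e-8) +
    kb * 298 / (6 * pi * 0.00344 * 2.84e-8)
  expect_equal(d$D_mutual, D_hand, tolerance = 1e-12)
  expect_lt(rel_err(d$D_mutual, 3.96e-5), 0.01)
  expect_equal(d$D_mutual, d$D_solute + d$D_quencher)
  # slip vs stick: a = 4 scales by 6/4
  pc4 <- probe_constants(stokes_einstein_a = 4)
  expect_equal(stokes_einstein_diffusion(sol, pc4)$D_mutual,
               d$D_mutual * 6 / 4, tolerance = 1e-12)
  # doubling viscosity halves D
  sol2 <- solvent_system("ACN2", 1, 36, inverse_viscosity = 1 / 0.00688,
                         temperature = 298)
  expect_equal(stokes_einstein_diffusion(sol2, pc)$D_mutual, d$D_mutual / 2,
               tolerance = 1e-12)
})

test_that("all bundled mixtures classify as diffusion-limited", {
  rep <- quench_analysis(fixture_titrations())
  rec <- as.data.frame(rep)
  expect_true(all(rec$diffusion_limited))
  expect_true(all(rec$R_prime_A > ref_R_A))
  expect_true(all(rec$k_q_total > rec$k_d))
  expect_true(all(rec$static_present))
  expect_true(all(rec$dynamic_present))
  # kinetic distance roughly double the encounter distance, as published
  expect_true(all(rec$r_vs_R_ratio > 1.8 & rec$r_vs_R_ratio < 2.4))
  acn <- rec[rec$solvent == acn_label, ]
  expect_equal(acn$r_vs_R_ratio, 13.43 / 6.52, tolerance = 0.01)
})

test_that("pure-dynamic data classify as dynamic-only", {
  r <- simulate_quench_table(synthetic_spec("pure_dynamic", K_SV = 5))
  fit <- quench_fit(r)
  expect_false(fit$classification$static_present)
  expect_true(fit$classification$dynamic_present)
  expect_true(is.na(fit$classification$diffusion_limited))
  expect_equal(fit$soa$V, 0, tolerance = 1e-9)
})

test_that("classification refuses incomplete inputs, naming the gap", {
  t <- fixture_titrations()[[dxn_label]]
  m <- modified_sv_fit(t)
  s <- static_volume_fit(m$W_series)
  expect_error(classify_quenching(m, s, NULL), "finite_sink_fit")
  expect_error(classify_quenching(NULL, s, NULL),
               "modified_sv_fit, finite_sink_fit")
})
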