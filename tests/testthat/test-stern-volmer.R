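qgrid <- seq(0.02, 0.10, by = 0.02)

test_that("linear S-V fit recovers an exact line and is shift-invariant", {
  r <- data.frame(Q = qgrid, ratio = 1 + 5 * qgrid)
  f <- linear_sv_fit(r)
  expect_equal(f$slope, 5, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  shifted <- transform(r, ratio = ratio + 0.37)
  expect_equal(linear_sv_fit(shifted)$slope, f$slope, tolerance = 1e-12)
})

test_that("naive linear slope on curved data matches the closed-form OLS", {
  # hand computation of Sxy/Sxx on the 100% ACN ratios: ~36.56, far above
  # the modified-S-V K_SV (~14.5) because the plot curves upward
  r <- intensity_ratios(fixture_titrations()[[acn_label]])
  sxy <- sum((r$Q - mean(r$Q)) * (r$ratio - mean(r$ratio)))
  sxx <- sum((r$Q - mean(r$Q))^2)
  f <- linear_sv_fit(r)
  expect_equal(f$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(f$slope, 36.5646, tolerance = 1e-4)
  expect_gt(f$slope, 2 * 14.516)
})

test_that("curvature diagnostic separates upward, linear and curved model data", {
  for (t in fixture_titrations())
    expect_identical(curvature_diagnostic(t)$verdict, "upward")
  line <- data.frame(Q = qgrid, ratio = 1 + 4 * qgrid)
  d <- curvature_diagnostic(line)
  expect_equal(d$beta2, 0, tolerance = 1e-8)
  expect_identical(d$verdict, "linear")
  # series expansion of (1+2Q)/(1-5Q) = 1 + 7Q + 35Q^2 + ... : upward
  lw <- data.frame(Q = qgrid, ratio = (1 + 2 * qgrid) / (1 - 5 * qgrid))
  expect_identical(curvature_diagnostic(lw)$verdict, "upward")
})

test_that("modified S-V fit is exact on its own generative model", {
  for (K in c(0.5, 3, 14.5)) for (b in c(0.3, 2, 5.5)) {
    r <- data.frame(Q = qgrid, ratio = (1 + K * qgrid) / (1 - b * qgrid))
    f <- modified_sv_fit(r)
    expect_equal(f$K_SV, K, tolerance = 1e-9)
    expect_equal(f$intercept_b, b, tolerance = 1e-9)
    expect_equal(f$W_series$W, 1 - b * qgrid, tolerance = 1e-9)
  }
})

test_that("modified S-V fit reproduces the published per-solvent constants", {
  tabs <- fixture_titrations()
  f_dxn <- modified_sv_fit(tabs[[dxn_label]])
  expect_lt(rel_err(f_dxn$K_SV, 2.545), 0.002)
  expect_lt(rel_err(f_dxn$intercept_b, 5.498), 0.002)
  f_acn <- modified_sv_fit(tabs[[acn_label]])
  expect_lt(rel_err(f_acn$K_SV, 14.516), 0.015)
  expect_lt(rel_err(f_acn$intercept_b, 4.420), 0.015)
})

test_that("modified S-V fit matches an independent grid-search minimiser", {
  r <- intensity_ratios(fixture_titrations()[[dxn_label]])
  x <- 1 / r$ratio
  y <- (1 - x) / r$Q
  o <- grid_search_line(x, y)
  f <- modified_sv_fit(r)
  expect_equal(f$K_SV, unname(o["slope"]), tolerance = 1e-6)
  expect_equal(f$intercept_b, unname(o["intercept"]), tolerance = 1e-6)
})

test_that("an intercept incompatible with W in (0,1] is an error", {
  r <- data.frame(Q = qgrid, ratio = 1 / (1 - 11 * qgrid))
  expect_error(modified_sv_fit(r), "inconsistent with W")
})

test_that("modified S-V overestimates K_SV on sphere-of-action data", {
  # model mismatch: data follow (1+K*Q)exp(V*Q), the estimator assumes
  # linear W; the bias magnitude is pinned by the grid-search oracle
  K <- 2.545; V <- 8.472
  r <- data.frame(Q = qgrid, ratio = (1 + K * qgrid) * exp(V * qgrid))
  f <- modified_sv_fit(r)
  expect_gt(f$K_SV, K)
  x <- 1 / r$ratio; y <- (1 - x) / r$Q
  o <- grid_search_line(x, y)
  expect_equal(f$K_SV, unname(o["slope"]), tolerance = 1e-6)
})

test_that("quenched fractions match the published W range", {
  W <- quenched_fraction(4.420, c(0.02, 0.10))
  expect_equal(W$W[1L], 0.912, tolerance = 0.001)
  expect_equal(W$W[2L], 0.558, tolerance = 0.001)
  expect_equal(quenched_fraction(0, qgrid)$W, rep(1, 5))
  expect_error(quenched_fraction(11, qgrid), "must be < 1")
})

test_that("sphere-of-action volume reproduces the published values", {
  V_dxn <- static_volume_fit(quenched_fraction(5.498, qgrid))
  expect_lt(rel_err(V_dxn$V, 8.472), 0.002)
  V_acn <- static_volume_fit(quenched_fraction(4.420, qgrid))
  expect_lt(rel_err(V_acn$V, 6.119), 0.002)
  expect_equal(static_volume_fit(rep(1, 5), qgrid)$V, 0)
})

test_that("kinetic radius follows the cube-root volume law", {
  expect_equal(kinetic_radius(8.472), 14.970, tolerance = 1e-3 * 14.97)
  expect_equal(kinetic_radius(6.119), 13.430, tolerance = 1e-3 * 13.43)
  expect_equal(kinetic_radius(0), 0)
  V <- c(0.5, 2, 8.472)
  expect_equal(kinetic_radius(8 * V), 2 * kinetic_radius(V),
               tolerance = 1e-12)
  expect_true(all(diff(kinetic_radius(seq(0.1, 10, by = 0.1))) > 0))
  expect_error(kinetic_radius(-1), "non-negative")
})

test_that("bimolecular rate is K_SV/tau0 in 1e9 M^-1 s^-1", {
  expect_equal(bimolecular_rate(14.516, 1.10), 13.196, tolerance = 5e-4 * 13.196)
  expect_equal(bimolecular_rate(2.545, 1.10), 2.314, tolerance = 5e-4 * 2.314)
  expect_equal(bimolecular_rate(0, 1.10), 0)
  expect_error(bimolecular_rate(5, 0), "positive")
})

test_that("ground-state complex model is rejected on every bundled mixture", {
  for (t in fixture_titrations()) {
    g <- ground_state_complex_fit(t)
    expect_true(g$complex_roots)
    expect_lt(g$discriminant, 0)
    expect_true(is.complex(g$roots))
  }
})

test_that("ground-state complex fit factorises exact product data", {
  r <- data.frame(Q = qgrid, ratio = (1 + 2 * qgrid) * (1 + 3 * qgrid))
  g <- ground_state_complex_fit(r)
  expect_false(g$complex_roots)
  expect_equal(g$roots, c(3, 2), tolerance = 1e-9)
  # P -> 0 limit on exact linear data: roots {S, 0} by the quadratic formula
  lin <- data.frame(Q = qgrid, ratio = 1 + 5 * qgrid)
  gl <- ground_state_complex_fit(lin)
  expect_false(gl$complex_roots)
  expect_equal(gl$roots, c(5, 0), tolerance = 1e-7)
  # repeated-root boundary is reported as degenerate, not imaginary
  sq <- data.frame(Q = qgrid, ratio = (1 + 2 * qgrid)^2)
  gs <- ground_state_complex_fit(sq)
  expect_true(gs$degenerate)
  expect_false(gs$complex_roots)
  expect_equal(Re(gs$roots), c(2, 2), tolerance = 1e-6)
})
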