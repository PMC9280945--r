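test_that("titration generator is seed-deterministic, bit for bit", {
  s <- synthetic_spec("linear_w", K_SV = 2.545, second_param = 5.498,
                      noise_cv = 0.02, seed = 99)
  expect_identical(simulate_quench_table(s)$intensity,
                   simulate_quench_table(s)$intensity)
  s2 <- s; s2$seed <- 100
  expect_false(identical(simulate_quench_table(s)$intensity,
                         simulate_quench_table(s2)$intensity))
})

test_that("generator models produce their defining ratio curves", {
  Q <- seq(0.02, 0.10, by = 0.02)
  pd <- simulate_quench_table(synthetic_spec("pure_dynamic", K_SV = 5))
  expect_equal(intensity_ratios(pd)$ratio, 1 + 5 * Q, tolerance = 1e-12)
  lw <- simulate_quench_table(synthetic_spec("linear_w", 3, 2))
  expect_equal(intensity_ratios(lw)$ratio, (1 + 3 * Q) / (1 - 2 * Q),
               tolerance = 1e-12)
  sa <- simulate_quench_table(synthetic_spec("sphere_of_action", 3, 4))
  expect_equal(intensity_ratios(sa)$ratio, (1 + 3 * Q) * exp(4 * Q),
               tolerance = 1e-12)
})

test_that("invalid generator specifications are rejected", {
  expect_error(synthetic_spec("linear_w", 3, second_param = 12), "b \\* max")
  expect_error(synthetic_spec("linear_w", -1, 2), "positive")
  expect_error(synthetic_spec("linear_w", 3, 2, noise_cv = -0.1),
               "non-negative")
})

test_that("noise-free quenched-fraction data reproduce the full record chain", {
  # generator truth (K, b) determines W, V and r deterministically; the
  # fitted chain must land on the same numbers
  K <- 2.545; b <- 5.498
  tab <- simulate_quench_table(synthetic_spec("linear_w", K, b))
  fit <- quench_fit(tab)
  expect_equal(fit$modsv$K_SV, K, tolerance = 1e-9)
  expect_equal(fit$modsv$intercept_b, b, tolerance = 1e-9)
  Q <- fit$modsv$W_series$Q
  oracle_V <- local({ # direct ln(1/W) regression from the truth values
    W <- 1 - b * Q
    x <- Q; y <- log(1 / W)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  })
  expect_equal(fit$soa$V, oracle_V, tolerance = 1e-9)
  expect_equal(fit$soa$r_A, kinetic_radius(oracle_V), tolerance = 1e-9)
})

test_that("recovery harness reports zero bias on noise-free quenched-fraction specs", {
  specs <- list(synthetic_spec("linear_w", 2.545, 5.498),
                synthetic_spec("linear_w", 8, 3),
                synthetic_spec("pure_dynamic", 5))
  out <- recovery_experiment(specs, n_replicates = 3, seed = 1)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$n_fail == 0))
  expect_true(all(abs(out$K_SV_bias) < 1e-9))
  expect_true(all(abs(out$b_bias[out$model == "linear_w"]) < 1e-9))
})

test_that("recovery harness exposes the sphere-of-action estimator bias", {
  out <- recovery_experiment(
    synthetic_spec("sphere_of_action", 2.545, 8.472), n_replicates = 1,
    seed = 1)
  expect_gt(out$K_SV_bias, 0) # documented model-mismatch overestimate
})

test_that("recovery harness is deterministic and accurate under noise", {
  sp <- synthetic_spec("linear_w", 2.545, 5.498, noise_cv = 0.01)
  out1 <- recovery_experiment(sp, n_replicates = 500, seed = 2026)
  out2 <- recovery_experiment(sp, n_replicates = 500, seed = 2026)
  expect_identical(out1, out2)
  expect_equal(out1$n_ok, 500L)
  expect_lt(rel_err(out1$K_SV_median, 2.545), 0.05)
})

test_that("densifying the concentration grid shrinks the RMSE", {
  coarse <- synthetic_spec("linear_w", 2.545, 5.498, noise_cv = 0.01)
  dense <- synthetic_spec("linear_w", 2.545, 5.498, noise_cv = 0.01,
                          Q_grid = seq(0.02, 0.10, length.out = 20))
  out <- recovery_experiment(list(coarse, dense), n_replicates = 200,
                             seed = 17)
  expect_lt(out$K_SV_rmse[2L], out$K_SV_rmse[1L])
})

test_that("failed replicates are counted, not fatal", {
  # b*max(Q) close to 1 plus noise occasionally drives the fitted W
  # negative; those replicates must be tallied as failures
  sp <- synthetic_spec("linear_w", 1, 9.9, noise_cv = 0.25, seed = NULL)
  out <- recovery_experiment(sp, n_replicates = 50, seed = 4)
  expect_equal(out$n_ok + out$n_fail, 50L)
  expect_gt(out$n_ok, 0L)
})

test_that("the bundled fixture passes the titration invariants", {
  for (t in fixture_titrations()) {
    expect_identical(t$quencher_conc[1L], 0)
    expect_true(all(diff(t$quencher_conc) > 0))
    expect_true(all(t$intensity > 0))
    expect_equal(max(t$intensity), t$intensity[1L]) # I0 is the maximum
  }
})
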