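test_that("weighted residuals are zero at agreement and scale by sd", {
  meas <- data.frame(emu_id = c("X:1", "X:1"), time = c(1, 1),
                     mass_shift = c(0, 1), value = c(0.6, 0.4),
                     sd = c(0.01, 0.02))
  pred <- list("X:1@1" = c(0.6, 0.4))
  expect_equal(weighted_residuals(pred, meas), c(0, 0))
  pred2 <- list("X:1@1" = c(0.61, 0.42))
  expect_equal(weighted_residuals(pred2, meas), c(1, 1))
  # permuting records permutes residuals identically
  perm <- c(2, 1)
  expect_equal(weighted_residuals(pred2, meas[perm, ]),
               weighted_residuals(pred2, meas)[perm])
  # missing prediction names the record
  expect_error(weighted_residuals(list(), meas), "X:1@1")
})

test_that("degrees of freedom subtract free parameters and refuse dof <= 0", {
  expect_equal(degrees_of_freedom(2040, 853), 1187L)
  expect_equal(degrees_of_freedom(10, 0), 10L)
  expect_error(degrees_of_freedom(10, 10), "under-determined")
})

test_that("goodness of fit brackets L with chi-square quantiles", {
  # oracle: invert the chi-square CDF by root finding rather than qchisq
  inv <- function(p, dof) uniroot(function(x) pchisq(x, dof) - p,
                                  c(1e-12, 10 * dof + 100))$root
  g <- goodness_of_fit(1, 1000, 0.05)
  expect_true(g$accept)
  expect_equal(g$lower, inv(0.025, 1000) / 1000, tolerance = 1e-6)
  expect_equal(g$upper, inv(0.975, 1000) / 1000, tolerance = 1e-6)
  # a perfect fit of noisy data is over-fitting
  g0 <- goodness_of_fit(0, 10, 0.05)
  expect_false(g0$accept)
  expect_true(g0$overfit)
  # alpha = 1: empty acceptance interval, always reject
  expect_false(goodness_of_fit(1, 10, 1)$accept)
})

test_that("measurement validation enforces the schema", {
  meas <- data.frame(emu_id = "X:1", time = 1, mass_shift = 0:1,
                     value = c(0.6, 0.4), sd = c(0.01, 0))
  expect_error(validate_measurements(meas), "sd <= 0")
  meas2 <- data.frame(emu_id = "X:1", time = 1, mass_shift = 0:1,
                      value = c(0.8, 0.4), sd = 0.01)
  expect_error(validate_measurements(meas2), "sum")
  meas3 <- data.frame(emu_id = "X:1", time = 1, value = 1)
  expect_error(validate_measurements(meas3), "lacks column")
})

test_that("measurement CSVs round-trip", {
  sc <- toy_sc()
  meas <- synth_measurements(sc, seed = 123)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(meas, path)
  meas2 <- read_measurements(path)
  expect_equal(meas2$value, meas$value, tolerance = 1e-12)
  expect_equal(meas2$emu_id, meas$emu_id)
})

test_that("oracle-mode fitting recovers the true fluxes from noiseless data", {
  sc <- toy_sc()
  meas <- synth_measurements(sc, noise_sd = 0)
  fit <- oracle_fit(sc, meas, n_starts = 2, seed = 5)
  expect_true(fit$converged)
  expect_lt(fit$ssr, 1e-6)
  expect_lt(max(abs(fit$net - sc$true_flux$net) / abs(sc$true_flux$net)), 0.01)
  expect_lt(max(abs(fit$basis$S %*% fit$v_hat)), 1e-8)
  expect_equal(fit$dof, nrow(meas) - 1L)  # one free flux, pools fixed
})

test_that("more starts never worsen the best SSR", {
  sc <- toy_sc()
  meas <- synth_measurements(sc, seed = 77)
  pred <- simulator_predictor(sc$emu_network, sc$timepoints)
  f1 <- fit_fluxes(pred, meas, sc$network, n_starts = 1, seed = 13,
                   conc_mode = "fixed", conc_fixed = sc$true_conc)
  f3 <- fit_fluxes(pred, meas, sc$network, n_starts = 3, seed = 13,
                   conc_mode = "fixed", conc_fixed = sc$true_conc)
  expect_lte(f3$ssr, f1$ssr + 1e-9)
  expect_length(f3$per_start_ssr, 3)
})

test_that("co-estimated pools stay inside their bounds", {
  sc <- toy_sc()
  meas <- synth_measurements(sc, seed = 31)
  pred <- simulator_predictor(sc$emu_network, sc$timepoints)
  fit <- fit_fluxes(pred, meas, sc$network, n_starts = 2, seed = 3,
                    conc_mode = "estimate")
  pb <- vapply(c("B[c]", "D[c]"),
               function(m) sc$network$metabolites[[m]]$pool_bounds, numeric(2))
  expect_true(all(fit$c_hat >= pb[1, ] - 1e-9 & fit$c_hat <= pb[2, ] + 1e-9))
  expect_equal(fit$dof, nrow(meas) - 3L)  # one free flux + two log pools
})
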