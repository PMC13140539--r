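# shared small training set for the toy scenario
surrogate_training_set <- function() {
  memo("surr_ts", function() {
    sc <- toy_sc()
    fs <- sample_flux_space(sc$network, 320, seed = 31)
    cs <- sample_concentrations(sc$network, 320, seed = 32)
    simulate_training_set(sc$emu_network, fs, cs, sc$timepoints)
  })
}

test_that("training tables have the right shape and standardisation", {
  ts <- surrogate_training_set()
  tab <- build_training_table(ts, "B[c]:1.2", 1)
  # 3 directed fluxes + 2 pools in, size-2 EMU (3 mass shifts) out
  expect_equal(dim(tab$inputs), c(320, 5))
  expect_equal(dim(tab$targets), c(320, 3))
  expect_equal(tab$input_ids, c("R1", "R2", "R3", "B[c]", "D[c]"))
  # round-trip de-standardisation
  back <- sweep(sweep(tab$inputs, 2, tab$x_scale, "*"), 2, tab$x_center, "+")
  raw <- cbind(ts$flux_mat, log(ts$conc_mat))
  expect_equal(back, raw, tolerance = 1e-12, ignore_attr = TRUE)
  # a zero-variance column keeps scale 1 (no divide-by-zero): the toy B12
  # M+1 component is structurally zero
  expect_equal(unname(tab$y_scale[2]), 1)
  expect_true(all(tab$targets[, 2] == 0))
  # missing cell is an error
  expect_error(build_training_table(ts, "B[c]:1.2", 99), "no simulated MIDs")
})

test_that("a constant target is learned to near-zero holdout error", {
  ts <- surrogate_training_set()
  tab <- build_training_table(ts, "B[c]:1.2", 1)
  tab$targets <- matrix(0, nrow(tab$targets), 3)  # standardised constant
  tab$y_center <- c(1, 0, 0); tab$y_scale <- rep(1, 3)
  spec <- surrogate_spec(epochs = 150, seed = 2)
  m <- train_surrogate(spec, tab)
  expect_lt(m$holdout_sd, 1e-3)
  expect_lt(m$loss_final, m$loss_init)
})

test_that("training is deterministic for a fixed seed", {
  ts <- surrogate_training_set()
  spec <- surrogate_spec(epochs = 15, seed = 7)
  tab <- build_training_table(ts, "D[c]:1", 0.5, spec)
  m1 <- train_surrogate(spec, tab)
  m2 <- train_surrogate(spec, tab)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$holdout_sd, m2$holdout_sd)
  m3 <- train_surrogate(surrogate_spec(epochs = 15, seed = 8), tab)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("ensemble predictions sit on the simplex and flag out-of-domain input", {
  ts <- surrogate_training_set()
  ens <- memo("surr_ens", function() {
    train_ensemble(subset_training_set(ts, 1:300),
                   surrogate_spec(epochs = 30, seed = 3))
  })
  p <- predict_mids(ens, ts$flux_mat[301, ], ts$conc_mat[301, ])
  expect_length(p, 10)
  for (mid in p) {
    expect_equal(sum(mid), 1, tolerance = 1e-12)
    expect_true(all(mid >= 0))
  }
  expect_false(attr(p, "out_of_domain"))
  # a flux far outside the sampled bounds raises the flag
  v0 <- ts$flux_mat[301, ]; v0[] <- 0
  p_ood <- predict_mids(ens, v0, ts$conc_mat[301, ])
  expect_true(attr(p_ood, "out_of_domain"))
  # misaligned ids are an error
  bad <- ts$flux_mat[301, ]; names(bad) <- c("X1", "X2", "X3")
  expect_error(predict_mids(ens, bad, ts$conc_mat[301, ]), "align")
})

test_that("validation reports per-cell sd and rejects training overlap", {
  ts <- surrogate_training_set()
  ens <- memo("surr_ens", function() {
    train_ensemble(subset_training_set(ts, 1:300),
                   surrogate_spec(epochs = 30, seed = 3))
  })
  val <- validate_ensemble(ens, subset_training_set(ts, 301:320))
  expect_equal(nrow(val), 10)  # 2 EMUs x 5 time points
  expect_true(all(val$sd >= 0))
  expect_type(attr(val, "median_sd"), "double")
  expect_error(validate_ensemble(ens, subset_training_set(ts, 1:20)),
               "overlap")
})

test_that("the exact simulator honours the same prediction contract", {
  sc <- toy_sc()
  pred <- simulator_predictor(sc$emu_network, sc$timepoints)
  p <- predict_mids(pred, sc$true_flux, sc$true_conc)
  tj <- simulate_mids(sc$emu_network, sc$true_flux, sc$true_conc,
                      sc$timepoints)
  expect_equal(p[["B[c]:1.2@1"]], get_mid(tj, "B[c]:1.2", 1))
  expect_false(attr(p, "out_of_domain"))
})

test_that("ensembles survive a save/load round trip", {
  ts <- surrogate_training_set()
  ens <- memo("surr_ens", function() {
    train_ensemble(subset_training_set(ts, 1:300),
                   surrogate_spec(epochs = 30, seed = 3))
  })
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  ens2 <- load_ensemble(path)
  p1 <- predict_mids(ens, ts$flux_mat[310, ], ts$conc_mat[310, ])
  p2 <- predict_mids(ens2, ts$flux_mat[310, ], ts$conc_mat[310, ])
  expect_identical(p1, p2)
})
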