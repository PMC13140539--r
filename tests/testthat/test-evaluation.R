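test_that("per-reaction Pearson correlation behaves as a correlation should", {
  set.seed(1)
  true_m <- matrix(rnorm(60, 5), 20, 3, dimnames = list(NULL, c("R1", "R2", "R3")))
  expect_equal(unname(pearson_by_reaction(true_m, true_m)), rep(1, 3))
  expect_equal(unname(pearson_by_reaction(true_m, -true_m)), rep(-1, 3))
  # location shifts leave r untouched
  expect_equal(unname(pearson_by_reaction(true_m, true_m + 2)), rep(1, 3))
  # zero-variance columns are undefined, not a number
  est <- true_m; est[, 2] <- 7
  r <- pearson_by_reaction(true_m, est)
  expect_true(is.na(r[["R2"]]))
  expect_false(anyNA(r[c("R1", "R3")]))
  expect_error(pearson_by_reaction(true_m, est[1:10, ]), "shape")
  expect_error(pearson_by_reaction(true_m[1, , drop = FALSE],
                                   est[1, , drop = FALSE]), ">= 2")
})

test_that("classification uses the documented boundary convention", {
  r <- c(a = 0.1, b = 0.5, c = 0.9)
  cls <- classify_reactions(r)
  expect_equal(as.character(cls$labels), c("low", "mid", "high"))
  # thresholds quoted as "< 0.3" and "> 0.85": both boundaries fall to mid
  cls2 <- classify_reactions(c(x = 0.3, y = 0.85))
  expect_equal(as.character(cls2$labels), c("mid", "mid"))
  expect_equal(cls$counts, c(low = 1L, mid = 1L, high = 1L))
  # undefined correlations are counted separately
  cls3 <- classify_reactions(c(NA_real_, NA_real_))
  expect_equal(sum(cls3$counts), 0L)
  expect_equal(cls3$n_undefined, 2L)
})

test_that("permutation p-values hit the smoothing floor for perfect estimates", {
  set.seed(2)
  true_m <- matrix(rnorm(60, 5), 20, 3, dimnames = list(NULL, c("R1", "R2", "R3")))
  sig <- permutation_significance(pearson_by_reaction(true_m, true_m),
                                  true_m, true_m, n_permutations = 1000,
                                  seed = 3)
  expect_true(all(sig$p <= 0.002))
  # smallest attainable p with 100 permutations is 1/101
  sig100 <- permutation_significance(pearson_by_reaction(true_m, true_m),
                                     true_m, true_m, n_permutations = 100,
                                     seed = 3)
  expect_equal(min(sig100$p), 1 / 101)
  expect_error(permutation_significance(c(R1 = 1), true_m, true_m,
                                        n_permutations = 10), "100")
})

test_that("row shuffling destroys the estimate-truth pairing", {
  set.seed(4)
  true_m <- matrix(rnorm(100, 5), 25, 4)
  est <- true_m + matrix(rnorm(100, 0, 0.1), 25, 4)
  colnames(true_m) <- colnames(est) <- paste0("R", 1:4)
  expect_true(all(pearson_by_reaction(true_m, est) > 0.99))
  shuffled <- est[sample(nrow(est)), ]
  expect_lt(median(abs(pearson_by_reaction(true_m, shuffled))), 0.5)
})

test_that("oracle-mode recovery places identifiable reactions in the high group", {
  rec <- memo("toy_recovery", function() {
    recovery_experiment(toy_net(), 8, c(0.25, 0.5, 1, 2, 4),
                        c("B[c]:1.2", "D[c]:1"), noise_sd = 0, seed = 17,
                        n_starts = 2)
  })
  expect_equal(dim(rec$true), c(8, 3))
  expect_true(all(rec$converged))
  r <- pearson_by_reaction(rec$true, rec$est)
  expect_true(all(r > 0.99))
  rep <- recovery_report(rec, n_permutations = 200, seed = 1)
  expect_equal(unname(rep$counts[["high"]]), 3L)
  expect_true(all(rep$table$p < 0.05))
})

test_that("a two-distribution experiment warns about unstable correlations", {
  expect_warning(
    recovery_experiment(toy_net(), 2, c(0.5, 2), c("B[c]:1.2", "D[c]:1"),
                        noise_sd = 0, seed = 3, n_starts = 1),
    "unstable")
})
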