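test_that("a linear chain decomposes to one EMU per tier plus the feed", {
  en <- decompose(chain_net(), "C:1.2")
  expect_setequal(names(en$emus), c("C:1.2", "B:1.2"))
  expect_setequal(names(en$sources), "A:1.2")
  expect_length(en$reactions, 2)
  expect_true(all(vapply(en$reactions, function(r) length(r$sources), 0L) == 1))
  rep <- emu_count_report(en)
  expect_equal(rep$size, 2L)
  expect_equal(rep$n_emus + rep$n_sources, 3L)  # C12, B12, A12
  expect_equal(rep$n_reactions, 2L)
})

test_that("a condensation yields one convolution reaction", {
  mets <- list(metabolite("A", "[c]", 1, is_boundary = TRUE),
               metabolite("B", "[c]", 1, is_boundary = TRUE),
               metabolite("C", "[c]", 2, pool_bounds = c(0.5, 5)),
               metabolite("S", "[c]", 2, is_boundary = TRUE))
  rxns <- list(reaction("Rc", c(A = -1, B = -1, C = 1), FALSE, c(0.1, 10),
                        list(parse_transition("A (a) + B (b) -> C (ab)"))),
               reaction("Ro", c(C = -1, S = 2), FALSE, c(0.1, 10),
                        list(parse_transition("C (ab) -> S (ab)"))))
  net <- reaction_network(mets, rxns, tracer_spec("A"))
  en <- decompose(net, "C:1.2")
  expect_length(en$reactions, 1)
  expect_equal(en$reactions[[1]]$sources, c("A:1", "B:1"))
  rep <- emu_count_report(en)
  expect_equal(rep$n_sources[rep$size == 1], 2L)
  expect_equal(rep$n_emus[rep$size == 2], 1L)
})

test_that("the traced EMU set stays within the brute-force enumeration bound", {
  net <- toy_net()
  # all single-metabolite full-atom targets
  targets <- c("A[c]:1.2", "B[c]:1.2", "C[c]:1", "D[c]:1")
  en <- decompose(net, targets)
  # oracle: enumerate every possible EMU of every traced metabolite
  all_emus <- sum(vapply(net$metabolites, function(m) 2^m$n_atoms - 1, 0))
  expect_lte(length(en$emus) + length(en$sources), all_emus)
  # a single target traces a strict subset
  en_b <- decompose(net, "B[c]:1.2")
  expect_lt(length(en_b$emus) + length(en_b$sources), all_emus)
})

test_that("decomposition is idempotent and monotone in the target set", {
  net <- rich_net()
  t_all <- c("B[c]:1.2", "C[h]:1.2", "D[h]:1", "F[h]:1.2")
  en1 <- decompose(net, t_all)
  en2 <- decompose(net, t_all)
  en2$network <- en1$network
  expect_identical(en1[c("emus", "sources", "reactions")],
                   en2[c("emus", "sources", "reactions")])
  # removing a target never adds EMUs
  en_sub <- decompose(net, t_all[-4])
  expect_true(all(names(en_sub$emus) %in% names(en1$emus)))
  expect_true(all(names(en_sub$sources) %in% names(en1$sources)))
})

test_that("count report totals match the flattened network", {
  en <- decompose(rich_net(), c("B[c]:1.2", "C[h]:1.2", "D[h]:1", "F[h]:1.2"))
  rep <- emu_count_report(en)
  expect_equal(sum(rep$n_emus), length(en$emus))
  expect_equal(sum(rep$n_sources), length(en$sources))
  expect_equal(sum(rep$n_reactions), length(en$reactions))
})

test_that("target atom indices out of range are rejected", {
  expect_error(decompose(toy_net(), "B[c]:1.3"), "out of range")
})

test_that("EMU network TSV dump reloads to an equivalent system", {
  en <- decompose(rich_net(), c("B[c]:1.2", "F[h]:1.2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_emu_network(en, path)
  en2 <- read_emu_network(path, rich_net(), en$targets)
  expect_setequal(names(en2$emus), names(en$emus))
  expect_setequal(names(en2$sources), names(en$sources))
  key <- function(x) sort(vapply(x$reactions, function(r) {
    paste(r$target, paste(r$sources, collapse = "+"), r$col, r$coeff)
  }, ""))
  expect_equal(key(en2), key(en))
  # and it simulates identically
  fs <- sample_flux_space(rich_net(), 1, seed = 5)[[1]]
  cs <- sample_concentrations(rich_net(), 1, seed = 6)[[1]]
  tj1 <- simulate_mids(en, fs, cs, c(0.5, 2))
  tj2 <- simulate_mids(en2, fs, cs, c(0.5, 2))
  expect_equal(tj2[["F[h]:1.2"]]$mids, tj1[["F[h]:1.2"]]$mids, tolerance = 1e-9)
})
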