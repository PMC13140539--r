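test_that("single-pool washout follows the closed-form exponential", {
  en <- decompose(washout_net(), "B:1")
  tt <- c(0.25, 0.5, 1, 2, 5)
  tj <- simulate_mids(en, c(Rin = 1, Rout = 1), c(B = 1), tt)
  expect_equal(tj[["B:1"]]$mids[, "M1"], 1 - exp(-tt), tolerance = 1e-7)
  expect_equal(unname(get_mid(tj, "B:1", 1)[2]), 1 - exp(-1), tolerance = 1e-7)
  # v/c sets the rate: v = 2, c = 0.5 quadruples it
  tj2 <- simulate_mids(en, c(Rin = 2, Rout = 2), c(B = 0.5), tt)
  expect_equal(tj2[["B:1"]]$mids[, "M1"], 1 - exp(-4 * tt), tolerance = 1e-7)
})

test_that("the assembled EMU system satisfies label mass balance", {
  for (net in list(toy_net(), rich_net())) {
    en <- decompose(net, vapply(
      balanced_mets <- Filter(function(m) !net$metabolites[[m]]$is_boundary,
                              names(net$metabolites)),
      function(m) paste0(m, ":", paste(seq_len(net$metabolites[[m]]$n_atoms),
                                       collapse = ".")), ""))
    fs <- sample_flux_space(net, 1, seed = 3)[[1]]
    cs <- sample_concentrations(net, 1, seed = 4)[[1]]
    sys <- build_emu_odes(en, fs, cs)
    for (lev in sys$levels) {
      rowsum <- rowSums(cbind(lev$A, lev$B))
      expect_lt(max(abs(rowsum)), 1e-10)
      expect_true(all(diag(lev$A) < 0))
      # diagonal drain equals independently summed influx
      for (id in lev$emu_ids) {
        influx <- sum(vapply(en$reactions, function(r) {
          if (r$target == id) r$coeff * sys$flux[[r$col]] else 0
        }, 0))
        expect_equal(-lev$A[id, id], influx, tolerance = 1e-12)
      }
    }
  }
})

test_that("trajectories start unlabelled and stay on the simplex", {
  sc <- rich_sc()
  tj <- simulate_mids(sc$emu_network, sc$true_flux, sc$true_conc,
                      c(0, 0.3, 1.7, 4))
  for (id in names(tj)) {
    expect_equal(unname(tj[[id]]$mids[1, ]),
                 c(1, rep(0, ncol(tj[[id]]$mids) - 1)))
    expect_true(all(abs(rowSums(tj[[id]]$mids) - 1) < 1e-6))
    expect_true(all(tj[[id]]$mids >= 0))
  }
})

test_that("scaling all fluxes by k compresses time by k", {
  sc <- rich_sc()
  k <- 2.5
  t1 <- c(0.4, 1, 2.4)
  tj_base <- simulate_mids(sc$emu_network, sc$true_flux, sc$true_conc, t1)
  vk <- sc$true_flux$v * k
  tj_fast <- simulate_mids(sc$emu_network, vk, sc$true_conc, t1 / k)
  for (id in sc$measured_emus) {
    expect_equal(tj_fast[[id]]$mids, tj_base[[id]]$mids, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("EMU and brute-force isotopomer simulations agree (partial labelling)", {
  net <- rich_net_partial()
  en <- decompose(net, c("B[c]:1.2", "C[h]:1.2", "D[h]:1", "F[h]:1.2"))
  fs <- sample_flux_space(net, 1, seed = 3)[[1]]
  cs <- sample_concentrations(net, 1, seed = 4)[[1]]
  tp <- c(0.25, 1, 4)
  tj <- simulate_mids(en, fs, cs, tp)
  iso <- simulate_isotopomers_bruteforce(net, fs, cs, tp)
  for (id in names(en$emus)) {
    expect_lt(max(abs(tj[[id]]$mids - bruteforce_mid(iso, id))), 1e-6)
  }
  # isotopomer fractions are conserved
  for (m in names(iso$dists)) {
    expect_true(all(abs(rowSums(iso$dists[[m]]) - 1) < 1e-6))
  }
})

test_that("a condensation's M+2 approaches the product of feed label fractions", {
  net <- condensation_net()  # feed atoms labelled at 0.7 and 0.4
  en <- decompose(net, "P[c]:1.2")
  tj <- simulate_mids(en, c(Rsplit = 1, Rcond = 1, Rout = 1),
                      c("D[c]" = 0.6, "E[c]" = 0.6, "P[c]" = 0.6), 60)
  mid <- get_mid(tj, "P[c]:1.2", 60)
  expect_equal(unname(mid[3]), 0.7 * 0.4, tolerance = 1e-4)
  iso <- simulate_isotopomers_bruteforce(net, c(Rsplit = 1, Rcond = 1, Rout = 1),
                                         c("D[c]" = 0.6, "E[c]" = 0.6,
                                           "P[c]" = 0.6), 60)
  expect_lt(max(abs(bruteforce_mid(iso, "P[c]:1.2") - mid)), 1e-6)
})

test_that("the exact linear solution matches the stiff integrator", {
  sc <- toy_sc()
  tt <- c(0.25, 1, 4)
  tj_lin <- simulate_mids(sc$emu_network, sc$true_flux, sc$true_conc, tt,
                          solver_opts = list(method = "linear"))
  tj_ode <- simulate_mids(sc$emu_network, sc$true_flux, sc$true_conc, tt,
                          solver_opts = list(method = "lsoda"))
  for (id in names(tj_lin)) {
    expect_equal(tj_ode[[id]]$mids, tj_lin[[id]]$mids, tolerance = 1e-7)
  }
})

test_that("every reachable EMU is fully labelled after 50 pool turnovers", {
  for (sc in list(toy_sc(), rich_sc())) {
    turnover <- max(sc$true_conc) / min(sc$true_flux$net)
    tj <- simulate_mids(sc$emu_network, sc$true_flux, sc$true_conc,
                        50 * turnover)
    for (id in names(tj)) {
      mid <- tj[[id]]$mids[1, ]
      expect_gt(mid[length(mid)], 1 - 1e-4)
    }
  }
})

test_that("the brute-force simulator refuses oversized networks", {
  net <- rich_net()
  fs <- sample_flux_space(net, 1, seed = 1)[[1]]
  cs <- sample_concentrations(net, 1, seed = 2)[[1]]
  expect_error(simulate_isotopomers_bruteforce(net, fs, cs, 1, max_states = 4),
               "exceeds cap")
})
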