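# Shared fixtures, memoised so expensive objects build once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

toy_net <- function() memo("toy_net", toy_network)
rich_net <- function() memo("rich_net", rich_network)

toy_sc <- function() memo("toy_sc", function() make_scenario(toy_net(), seed = 9L))

rich_sc <- function() memo("rich_sc", function() {
  make_scenario(rich_net(),
                measured_emus = c("B[c]:1.2", "C[h]:1.2", "D[h]:1", "F[h]:1.2"),
                seed = 7L)
})

# rich network fed with a partially labelled tracer: exercises genuine
# isotopomer mixing (a fully labelled feed keeps atom pairs correlated)
rich_net_partial <- function() memo("rich_net_partial", function() {
  net <- rich_network()
  net$tracer <- tracer_spec("A[c]", fractions = c(0.9, 0.4))
  net
})

# two boundary feeds condensing into one product: the convolution fixture
condensation_net <- function() memo("condensation_net", function() {
  mets <- list(
    metabolite("T[c]", "[c]", 2, is_boundary = TRUE),
    metabolite("D[c]", "[c]", 1, pool_bounds = c(0.5, 5)),
    metabolite("E[c]", "[c]", 1, pool_bounds = c(0.5, 5)),
    metabolite("P[c]", "[c]", 2, pool_bounds = c(0.5, 5)),
    metabolite("S[c]", "[c]", 2, is_boundary = TRUE))
  rxns <- list(
    reaction("Rsplit", c("T[c]" = -1, "D[c]" = 1, "E[c]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("T[c] (ab) -> D[c] (a) + E[c] (b)"))),
    reaction("Rcond", c("D[c]" = -1, "E[c]" = -1, "P[c]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("D[c] (a) + E[c] (b) -> P[c] (ab)"))),
    reaction("Rout", c("P[c]" = -1, "S[c]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("P[c] (ab) -> S[c] (ab)"))))
  reaction_network(mets, rxns, tracer_spec("T[c]", fractions = c(0.7, 0.4)))
})

# single-pool washout network: B fed by fully labelled one-atom A
washout_net <- function() memo("washout_net", function() {
  mets <- list(metabolite("A", "[c]", 1, is_boundary = TRUE),
               metabolite("B", "[c]", 1, pool_bounds = c(0.2, 5)),
               metabolite("C", "[c]", 1, is_boundary = TRUE))
  rxns <- list(
    reaction("Rin", c(A = -1, B = 1), FALSE, c(0.1, 10),
             list(parse_transition("A (a) -> B (a)"))),
    reaction("Rout", c(B = -1, C = 1), FALSE, c(0.1, 10),
             list(parse_transition("B (a) -> C (a)"))))
  reaction_network(mets, rxns, tracer_spec("A"))
})

# linear chain with 2-atom metabolites, all atoms carried through
chain_net <- function() memo("chain_net", function() {
  mets <- list(metabolite("A", "[c]", 2, is_boundary = TRUE),
               metabolite("B", "[c]", 2, pool_bounds = c(0.5, 5)),
               metabolite("C", "[c]", 2, pool_bounds = c(0.5, 5)),
               metabolite("X", "[c]", 2, is_boundary = TRUE))
  rxns <- list(
    reaction("R1", c(A = -1, B = 1), FALSE, c(0.1, 10),
             list(parse_transition("A (ab) -> B (ab)"))),
    reaction("R2", c(B = -1, C = 1), FALSE, c(0.1, 10),
             list(parse_transition("B (ab) -> C (ab)"))),
    reaction("R3", c(C = -1, X = 1), FALSE, c(0.1, 10),
             list(parse_transition("C (ab) -> X (ab)"))))
  reaction_network(mets, rxns, tracer_spec("A"))
})

# two parallel routes into one balanced pool: a 2-D flux polytope (triangle)
triangle_net <- function() memo("triangle_net", function() {
  mets <- list(metabolite("A", "[c]", 1, is_boundary = TRUE),
               metabolite("B", "[c]", 1, pool_bounds = c(0.5, 5)),
               metabolite("C", "[c]", 1, is_boundary = TRUE))
  rxns <- list(
    reaction("R1", c(A = -1, B = 1), FALSE, c(0, 1),
             list(parse_transition("A (a) -> B (a)"))),
    reaction("R2", c(A = -1, B = 1), FALSE, c(0, 1),
             list(parse_transition("A (a) -> B (a)"))),
    reaction("R3", c(B = -1, C = 1), FALSE, c(0, 1),
             list(parse_transition("B (a) -> C (a)"))))
  reaction_network(mets, rxns, tracer_spec("A"))
})

subset_training_set <- function(set, idx) {
  list(flux_mat = set$flux_mat[idx, , drop = FALSE],
       conc_mat = set$conc_mat[idx, , drop = FALSE],
       mids = lapply(set$mids, function(m) m[idx, , drop = FALSE]),
       cells = set$cells)
}

oracle_fit <- function(scenario, meas, n_starts = 2, seed = 1L) {
  pred <- simulator_predictor(scenario$emu_network, scenario$timepoints)
  fit_fluxes(pred, meas, scenario$network, n_starts = n_starts, seed = seed,
             conc_mode = "fixed", conc_fixed = scenario$true_conc)
}
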