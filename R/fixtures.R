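#' @title Built-in toy networks and synthetic scenarios
#' @description Small atom-mapped networks and seed-reproducible synthetic
#'   measurement generators that make every module testable without external
#'   files. The atom transitions are the package's own documented stand-ins
#'   (synthetic), chosen to be atom-balanced and to exercise the machinery.
#' @name fixtures
NULL

#' Four-metabolite, three-reaction toy network
#'
#' A linear chain with a cleavage: `R1: A(ab) -> B(ab)`,
#' `R2: B(ab) -> C(a) + D(b)`, `R3: D(b) ->` (export). `A` is the fully
#' labelled boundary tracer input, `C` a boundary sink; `B` and `D` are
#' balanced. The null space is one-dimensional (all fluxes equal at steady
#' state).
#'
#' @param flux_bounds common flux bounds (default `c(0.1, 10)`).
#' @param pool_bounds common pool bounds for balanced metabolites
#'   (default `c(0.5, 5)`).
#' @return a validated [reaction_network()].
#' @export
toy_network <- function(flux_bounds = c(0.1, 10), pool_bounds = c(0.5, 5)) {
  mets <- list(
    metabolite("A[c]", "[c]", 2, is_boundary = TRUE),
    metabolite("B[c]", "[c]", 2, pool_bounds),
    metabolite("C[c]", "[c]", 1, is_boundary = TRUE),
    metabolite("D[c]", "[c]", 1, pool_bounds))
  rxns <- list(
    reaction("R1", c("A[c]" = -1, "B[c]" = 1), FALSE, flux_bounds,
             list(parse_transition("A[c] (ab) -> B[c] (ab)"))),
    reaction("R2", c("B[c]" = -1, "C[c]" = 1, "D[c]" = 1), FALSE, flux_bounds,
             list(parse_transition("B[c] (ab) -> C[c] (a) + D[c] (b)"))),
    reaction("R3", c("D[c]" = -1), FALSE, flux_bounds,
             list(parse_transition("D[c] (b) ->"))))
  reaction_network(mets, rxns, tracer_spec("A[c]"))
}

#' Eight-metabolite rich network
#'
#' Two compartments (cytosol `[c]`, chloroplast `[h]`), one reversible
#' exchange, one cleavage, one condensation (EMU convolution) and a branch:
#' `R1: A(ab) -> B(ab)`, `R2: B(ab) <-> C(ab)`, `R3: C(ab) -> D(a) + E(b)`,
#' `R4: D(a) + E(b) -> F(ab)`, `R5: F(ab) -> G(ab)`, `R6: B(ab) -> H(ab)`.
#' `A` is the fully labelled tracer input, `G` and `H` are boundary sinks.
#'
#' @param pool_bounds common pool bounds for balanced metabolites.
#' @return a validated [reaction_network()].
#' @export
rich_network <- function(pool_bounds = c(0.5, 5)) {
  mets <- list(
    metabolite("A[c]", "[c]", 2, is_boundary = TRUE),
    metabolite("B[c]", "[c]", 2, pool_bounds),
    metabolite("C[h]", "[h]", 2, pool_bounds),
    metabolite("D[h]", "[h]", 1, pool_bounds),
    metabolite("E[h]", "[h]", 1, pool_bounds),
    metabolite("F[h]", "[h]", 2, pool_bounds),
    metabolite("G[c]", "[c]", 2, is_boundary = TRUE),
    metabolite("H[c]", "[c]", 2, is_boundary = TRUE))
  rxns <- list(
    reaction("R1", c("A[c]" = -1, "B[c]" = 1), FALSE, c(0.2, 10),
             list(parse_transition("A[c] (ab) -> B[c] (ab)"))),
    reaction("R2", c("B[c]" = -1, "C[h]" = 1), TRUE, c(-5, 10),
             list(parse_transition("B[c] (ab) -> C[h] (ab)"))),
    reaction("R3", c("C[h]" = -1, "D[h]" = 1, "E[h]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("C[h] (ab) -> D[h] (a) + E[h] (b)"))),
    reaction("R4", c("D[h]" = -1, "E[h]" = -1, "F[h]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("D[h] (a) + E[h] (b) -> F[h] (ab)"))),
    reaction("R5", c("F[h]" = -1, "G[c]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("F[h] (ab) -> G[c] (ab)"))),
    reaction("R6", c("B[c]" = -1, "H[c]" = 1), FALSE, c(0.1, 10),
             list(parse_transition("B[c] (ab) -> H[c] (ab)"))))
  reaction_network(mets, rxns, tracer_spec("A[c]"))
}

#' Build a self-consistent synthetic scenario
#'
#' Draws a true flux distribution and pool vector, decomposes the EMU network
#' for the measured EMUs, and packages everything needed to generate synthetic
#' measurements and evaluate estimators against known ground truth. Cheap
#' post conditions (steady state, simplex-valid simulation at the first time
#' point) are asserted at generation time.
#'
#' @param network a [reaction_network()] (default [toy_network()]).
#' @param measured_emus target EMU ids; defaults to the full-atom EMUs of the
#'   scenario's measurable balanced metabolites.
#' @param timepoints measurement times (default `c(0.25, 0.5, 1, 2, 4)`).
#' @param noise_sd measurement noise in MID units (default 0.01).
#' @param seed seed for the true flux/pool draw.
#' @return list of class `toy_scenario`.
#' @export
make_scenario <- function(network = toy_network(), measured_emus = NULL,
                          timepoints = c(0.25, 0.5, 1, 2, 4),
                          noise_sd = 0.01, seed = 42L) {
  if (is.null(measured_emus)) {
    mets <- balanced_metabolites(network)
    measured_emus <- vapply(mets, function(m) {
      emu_id(m, seq_len(network$metabolites[[m]]$n_atoms))
    }, character(1))
    measured_emus <- unname(measured_emus[
      vapply(mets, function(m) network$metabolites[[m]]$n_atoms > 0, logical(1))])
  }
  en <- decompose(network, measured_emus)
  true_flux <- sample_flux_space(network, 1, seed = seed)[[1]]
  true_conc <- sample_concentrations(network, 1, seed = seed + 1L)[[1]]
  sc <- structure(list(network = network, emu_network = en,
                       true_flux = true_flux, true_conc = true_conc,
                       timepoints = sort(timepoints),
                       measured_emus = measured_emus,
                       noise_sd = noise_sd, seed = seed),
                  class = "toy_scenario")
  tj <- simulate_mids(en, true_flux, true_conc, sc$timepoints[1])
  for (id in names(tj)) {
    stopifnot(abs(sum(tj[[id]]$mids[1, ]) - 1) < 1e-6, all(tj[[id]]$mids >= 0))
  }
  sc
}

#' Synthetic noisy measurements for a scenario
#'
#' Simulates exact MIDs, adds independent Gaussian noise, clips to `[0, 1]`
#' and renormalises each (EMU, time point) MID; the pre-renormalisation
#' values are kept in the `"raw"` attribute. With `noise_sd = 0` the
#' measurements equal the simulation exactly and the attached sd falls back
#' to 0.01 (the package-wide default measurement sd).
#'
#' @param scenario a [make_scenario()] result.
#' @param seed RNG seed for the noise draw.
#' @param noise_sd override of the scenario's noise level.
#' @param post_process `"clip_renorm"` (default: clip to `[0, 1]` and
#'   renormalise each MID, what a measurement pipeline reports) or `"none"`
#'   (keep the raw Gaussian perturbation, so the noise exactly matches the
#'   attached sd -- the right generator for chi-square calibration studies).
#' @return a `measurement_set` data.frame (`emu_id`, `time`, `mass_shift`,
#'   `value`, `sd`) with attributes `raw` (pre-renormalisation values) and
#'   `exact` (noise-free values).
#' @export
synth_measurements <- function(scenario, seed = scenario$seed + 100L,
                               noise_sd = scenario$noise_sd,
                               post_process = c("clip_renorm", "none")) {
  post_process <- match.arg(post_process)
  en <- scenario$emu_network
  tj <- simulate_mids(en, scenario$true_flux, scenario$true_conc,
                      scenario$timepoints)
  rows <- list(); raw <- list(); exact <- list()
  set.seed(as.integer(seed))
  attach_sd <- if (noise_sd > 0) noise_sd else 0.01
  for (id in scenario$measured_emus) {
    for (tp in scenario$timepoints) {
      mid <- get_mid(tj, id, tp)
      noisy <- mid + rnorm(length(mid), 0, noise_sd)
      value <- if (post_process == "clip_renorm") {
        clipped <- pmin(pmax(noisy, 0), 1)
        clipped / sum(clipped)
      } else {
        # keep the raw Gaussian perturbation; redraw the rare (> ~4 sigma)
        # cells whose sum would break measurement-set validity
        tries <- 0L
        while (abs(sum(noisy) - 1) > 0.05 && tries < 100L) {
          noisy <- mid + rnorm(length(mid), 0, noise_sd)
          tries <- tries + 1L
        }
        noisy
      }
      rows[[length(rows) + 1L]] <- data.frame(
        emu_id = id, time = tp, mass_shift = seq_along(mid) - 1L,
        value = value, sd = attach_sd, stringsAsFactors = FALSE)
      raw[[length(raw) + 1L]] <- unname(noisy)
      exact[[length(exact) + 1L]] <- unname(mid)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "raw") <- unlist(raw)
  attr(out, "exact") <- unlist(exact)
  validate_measurements(out)
}
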