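#' @title Flux recoverability evaluation
#' @description Fits many sampled "true" flux distributions from their own
#'   simulated measurements, computes per-reaction Pearson correlations
#'   between estimated and true net fluxes, classifies reactions into
#'   low/mid/high recoverability groups, and tests significance against a
#'   permutation null that breaks the pairing between true and estimated
#'   distributions.
#' @name evaluation
NULL

#' Run a recovery experiment
#'
#' For each of `n_distributions` sampled true (flux, pool) pairs, simulate
#' noisy measurements and re-estimate the fluxes with pools fixed at their
#' true values (the recoverability protocol: concentrations enter as known
#' inputs).
#'
#' @param network a [reaction_network()].
#' @param n_distributions number of sampled true distributions (>= 2).
#' @param timepoints measurement time points.
#' @param measured_emus target EMU ids (or [emu()] objects).
#' @param noise_sd Gaussian measurement noise (MID units); 0 for noiseless.
#' @param seed master seed.
#' @param predictor optional predictor; default is the exact simulator over
#'   the decomposed EMU network.
#' @param n_starts multi-start count per fit.
#' @return list of class `recovery_result`: `true` and `est`
#'   (n_distributions x n_reactions net-flux matrices), `converged` (logical),
#'   `fits` metadata list.
#' @export
recovery_experiment <- function(network, n_distributions, timepoints,
                                measured_emus, noise_sd = 0.01, seed = 1L,
                                predictor = NULL, n_starts = 3) {
  stopifnot(n_distributions >= 2)
  if (n_distributions == 2) {
    warning("n_distributions = 2: per-reaction correlations will be unstable")
  }
  en <- decompose(network, measured_emus)
  if (is.null(predictor)) predictor <- simulator_predictor(en, timepoints)
  fluxes <- sample_flux_space(network, n_distributions, seed = seed)
  concs <- sample_concentrations(network, n_distributions, seed = seed + 1L)
  rxn_ids <- names(network$reactions)
  true_m <- est_m <- matrix(NA_real_, n_distributions, length(rxn_ids),
                            dimnames = list(NULL, rxn_ids))
  converged <- logical(n_distributions)
  fits <- vector("list", n_distributions)
  for (i in seq_len(n_distributions)) {
    sc <- list(network = network, emu_network = en,
               true_flux = fluxes[[i]], true_conc = concs[[i]],
               timepoints = timepoints, measured_emus = measured_emus,
               noise_sd = noise_sd)
    meas <- synth_measurements(sc, seed = seed + 1000L + i)
    fit <- fit_fluxes(predictor, meas, network, n_starts = n_starts,
                      seed = seed + 2000L + i, conc_mode = "fixed",
                      conc_fixed = concs[[i]])
    true_m[i, ] <- fluxes[[i]]$net[rxn_ids]
    est_m[i, ] <- fit$net[rxn_ids]
    converged[i] <- fit$converged
    fits[[i]] <- list(ssr = fit$ssr, L = fit$L, dof = fit$dof,
                      converged = fit$converged)
  }
  if (any(!converged)) {
    warning(sum(!converged), " fit(s) did not converge; excluded from correlations")
  }
  structure(list(true = true_m, est = est_m, converged = converged,
                 fits = fits, seed = seed, noise_sd = noise_sd),
            class = "recovery_result")
}

#' Per-reaction Pearson correlation between true and estimated fluxes
#'
#' @param true_matrix,est_matrix equal-shaped matrices, rows = distributions,
#'   columns = reactions (>= 2 rows).
#' @return named numeric vector of correlations; columns with zero variance
#'   on either side yield `NA` (undefined, never a number).
#' @export
pearson_by_reaction <- function(true_matrix, est_matrix) {
  if (!all(dim(true_matrix) == dim(est_matrix))) {
    stop("true and estimated matrices differ in shape")
  }
  if (nrow(true_matrix) < 2) stop("need >= 2 distributions")
  vapply(seq_len(ncol(true_matrix)), function(j) {
    x <- true_matrix[, j]; y <- est_matrix[, j]
    if (sd(x) < 1e-12 || sd(y) < 1e-12 || anyNA(x) || anyNA(y)) NA_real_
    else cor(x, y)
  }, numeric(1)) |> setNames(colnames(true_matrix))
}

#' Classify reactions by recoverability
#'
#' Boundary convention: correlations exactly at a threshold fall in the
#' middle group (`low`: r < t1; `mid`: t1 <= r <= t2; `high`: r > t2).
#'
#' @param r named correlation vector (`NA` = undefined).
#' @param thresholds increasing pair; default `c(0.3, 0.85)`.
#' @return list with `labels` (factor `low`/`mid`/`high`, `NA` kept),
#'   `counts` (named integer vector), `n_undefined`.
#' @export
classify_reactions <- function(r, thresholds = c(0.3, 0.85)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lab <- ifelse(is.na(r), NA_character_,
                ifelse(r < thresholds[1], "low",
                       ifelse(r > thresholds[2], "high", "mid")))
  lab <- factor(lab, levels = c("low", "mid", "high"))
  names(lab) <- names(r)
  counts <- table(lab)
  list(labels = lab,
       counts = setNames(as.integer(counts), names(counts)),
       n_undefined = sum(is.na(r)), thresholds = thresholds)
}

#' Permutation significance of per-reaction correlations
#'
#' Null: estimates are unrelated to the truth, realised by permuting the rows
#' of the estimated matrix (breaking the pairing while preserving marginals).
#' One-sided smoothed p-value per reaction, with Benjamini-Hochberg
#' adjustment alongside.
#'
#' @param r observed correlations ([pearson_by_reaction()]).
#' @param true_matrix,est_matrix the matrices behind `r`.
#' @param n_permutations >= 100.
#' @param seed RNG seed.
#' @return data.frame: `reaction_id`, `r`, `p` (`(1 + #{r_perm >= r}) /
#'   (n_permutations + 1)`), `p_adj` (BH).
#' @export
permutation_significance <- function(r, true_matrix, est_matrix,
                                     n_permutations = 1000, seed = 1L) {
  stopifnot(n_permutations >= 100)
  set.seed(as.integer(seed))
  n <- nrow(true_matrix)
  exceed <- integer(length(r))
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    r_b <- pearson_by_reaction(true_matrix, est_matrix[perm, , drop = FALSE])
    exceed <- exceed + ifelse(!is.na(r_b) & !is.na(r) & r_b >= r, 1L, 0L)
  }
  p <- (1 + exceed) / (n_permutations + 1)
  p[is.na(r)] <- NA_real_
  data.frame(reaction_id = names(r) %||% as.character(seq_along(r)),
             r = as.numeric(r), p = p, p_adj = p.adjust(p, "BH"))
}

#' Full recovery report
#'
#' @param recovery a [recovery_experiment()] result.
#' @param thresholds classification thresholds (default `c(0.3, 0.85)`).
#' @param n_permutations permutations for the significance test.
#' @param seed RNG seed for the permutation null.
#' @return list of class `recovery_report`: `table` (per-reaction r, group,
#'   p, p_adj), `counts`, `n_undefined`, `thresholds`.
#' @export
recovery_report <- function(recovery, thresholds = c(0.3, 0.85),
                            n_permutations = 1000, seed = 1L) {
  keep <- recovery$converged
  true_m <- recovery$true[keep, , drop = FALSE]
  est_m <- recovery$est[keep, , drop = FALSE]
  r <- pearson_by_reaction(true_m, est_m)
  cls <- classify_reactions(r, thresholds)
  sig <- permutation_significance(r, true_m, est_m, n_permutations, seed)
  tab <- data.frame(reaction_id = names(r), r = as.numeric(r),
                    group = as.character(cls$labels), p = sig$p,
                    p_adj = sig$p_adj)
  structure(list(table = tab, counts = cls$counts,
                 n_undefined = cls$n_undefined, thresholds = thresholds,
                 n_distributions = sum(keep)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d distributions; groups low/mid/high = %d/%d/%d (undefined %d)\n",
              x$n_distributions, x$counts[["low"]], x$counts[["mid"]],
              x$counts[["high"]], x$n_undefined))
  invisible(x)
}
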