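#' @title Flux and pool-size estimation
#' @description Bounded weighted least squares on the reduced parameterisation
#'   (free fluxes in null-space coordinates plus log pool sizes), minimising
#'   the reduced chi-square statistic with multi-start, via
#'   Levenberg-Marquardt (`minpack.lm`). Steady state holds exactly at every
#'   iterate by construction; box bounds on physical fluxes are enforced by
#'   ramped penalty residuals and verified at the solution.
#' @name estimation
NULL

#' Read / write the measurement CSV schema
#'
#' Columns: `emu_id`, `time`, `mass_shift`, `value`, `sd` (header required,
#' UTF-8, decimal point). Records with `sd <= 0` are rejected; per
#' (EMU, time point) the values must sum to 1 within 0.05.
#'
#' @param path CSV path.
#' @return data.frame of class `measurement_set`.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' @rdname read_measurements
#' @param measurements a measurement data.frame.
#' @export
write_measurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
validate_measurements <- function(measurements) {
  need <- c("emu_id", "time", "mass_shift", "value", "sd")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurement table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(measurements$sd <= 0)) {
    stop("measurement records with sd <= 0 are rejected (record ",
         which(measurements$sd <= 0)[1], ")")
  }
  sums <- tapply(measurements$value,
                 cell_key(measurements$emu_id, measurements$time), sum)
  bad <- names(sums)[abs(sums - 1) > 0.05]
  if (length(bad)) {
    stop("MID values for ", bad[1], " sum to ", round(sums[bad[1]], 3),
         " (must be 1 within 0.05)")
  }
  class(measurements) <- unique(c("measurement_set", class(measurements)))
  measurements
}

#' Weighted residuals between predictions and measurements
#'
#' @param predicted named list, cell key (`emu@time`) -> MID vector, as
#'   returned by [predict_mids()].
#' @param measurements a measurement data.frame.
#' @return numeric vector `(pred - meas) / sd`, one entry per record, in
#'   record order.
#' @export
weighted_residuals <- function(predicted, measurements) {
  r <- numeric(nrow(measurements))
  for (i in seq_len(nrow(measurements))) {
    key <- cell_key(measurements$emu_id[i], measurements$time[i])
    mid <- predicted[[key]]
    shift <- measurements$mass_shift[i]
    if (is.null(mid) || shift + 1L > length(mid)) {
      stop("no prediction for record ", i, " (", key, ", M+", shift, ")")
    }
    r[i] <- (mid[shift + 1L] - measurements$value[i]) / measurements$sd[i]
  }
  r
}

#' Degrees of freedom of a fit
#'
#' @param n_measurements number of measurement records.
#' @param n_free_parameters number of fitted parameters.
#' @return `n_measurements - n_free_parameters`; an error if not positive
#'   (under-determined fits must not report a reduced chi-square).
#' @export
degrees_of_freedom <- function(n_measurements, n_free_parameters) {
  dof <- n_measurements - n_free_parameters
  if (dof <= 0) {
    stop("under-determined fit: ", n_measurements, " measurements for ",
         n_free_parameters, " free parameters")
  }
  as.integer(dof)
}

#' Chi-square goodness-of-fit acceptance
#'
#' Accepts a fit when the reduced chi-square `L` lies inside
#' `[qchisq(alpha/2, dof), qchisq(1 - alpha/2, dof)] / dof`. `L` below the
#' lower bound flags over-fitting.
#'
#' @param L reduced chi-square statistic.
#' @param dof degrees of freedom (>= 1).
#' @param alpha two-sided test level; `alpha >= 1` gives an empty acceptance
#'   interval (always reject).
#' @return list with `accept`, `lower`, `upper`, `overfit`.
#' @export
goodness_of_fit <- function(L, dof, alpha = 0.05) {
  stopifnot(dof >= 1, L >= 0)
  if (alpha >= 1) {
    return(list(accept = FALSE, lower = NA_real_, upper = NA_real_,
                overfit = FALSE))
  }
  lower <- qchisq(alpha / 2, dof) / dof
  upper <- qchisq(1 - alpha / 2, dof) / dof
  list(accept = L >= lower && L <= upper, lower = lower, upper = upper,
       overfit = L < lower)
}

pool_bounds_matrix <- function(network) {
  mets <- balanced_metabolites(network)
  cbind(lb = vapply(mets, function(m) network$metabolites[[m]]$pool_bounds[1], 0),
        ub = vapply(mets, function(m) network$metabolites[[m]]$pool_bounds[2], 0))
}

# residual closure shared by fit_fluxes and profile_ci
make_residual_fn <- function(predictor, measurements, basis, conc_mode,
                             conc_fixed, pool_b, penalty_weight, v_particular) {
  k <- ncol(basis$K)
  rng <- pmax(basis$ub - basis$lb, 1e-9)
  ood_count <- 0L
  fn <- function(par) {
    u <- par[seq_len(k)]
    v <- v_particular + if (k > 0) drop(basis$K %*% u) else 0
    names(v) <- basis$cols$col
    conc <- if (conc_mode == "estimate") {
      setNames(exp(par[-seq_len(k)]), rownames(pool_b))
    } else conc_fixed
    v_eval <- pmin(pmax(v, basis$lb), basis$ub)  # predictor sees feasible v
    pred <- predict_mids(predictor, v_eval, conc)
    if (isTRUE(attr(pred, "out_of_domain"))) ood_count <<- ood_count + 1L
    c(weighted_residuals(pred, measurements),
      sqrt(penalty_weight) * c(pmax(basis$lb - v, 0), pmax(v - basis$ub, 0)) / rng)
  }
  list(fn = fn, ood = function() ood_count)
}

meas_ssr <- function(predictor, measurements, v, conc) {
  sum(weighted_residuals(predict_mids(predictor, v, conc), measurements)^2)
}

#' Fit fluxes (and optionally pool sizes) to measured MIDs
#'
#' Minimises the weighted sum of squared residuals over the null-space flux
#' coordinates (steady state exact at every iterate) and, by default, log
#' pool sizes, from multiple starts drawn by the sampling module. The best
#' start by SSR is returned together with the reduced chi-square `L = ssr/dof`.
#'
#' @param predictor a `surrogate_ensemble` or [simulator_predictor()].
#' @param measurements a measurement data.frame (see [read_measurements()]).
#' @param network a [reaction_network()].
#' @param n_starts number of multi-start optimisations (default 10).
#' @param seed master seed; start points derive from it.
#' @param conc_mode `"estimate"` (co-estimate log pools, the default) or
#'   `"fixed"` (pools supplied in `conc_fixed`).
#' @param conc_fixed named pool vector when `conc_mode = "fixed"`.
#' @param control list: `maxiter` (400), `ftol` (1e-10), `ptol` (1e-10),
#'   `gtol` (1e-8), `penalty_weight` (1e3), `penalty_ramps` (4).
#' @return list of class `fit_result`: `v_hat` (directed fluxes), `net`
#'   (net reaction fluxes), `c_hat`, `ssr`, `dof`, `L`, `converged`,
#'   `n_starts`, `best_start`, `per_start_ssr`, `n_out_of_domain`,
#'   `bound_violation`, `basis`, `conc_mode`.
#' @export
fit_fluxes <- function(predictor, measurements, network, n_starts = 10,
                       seed = 1L, conc_mode = c("estimate", "fixed"),
                       conc_fixed = NULL, control = list()) {
  conc_mode <- match.arg(conc_mode)
  measurements <- validate_measurements(measurements)
  ctl <- modifyList(list(maxiter = 400, ftol = 1e-10, ptol = 1e-10,
                         gtol = 1e-8, penalty_weight = 1e3, penalty_ramps = 4),
                    control)
  basis <- free_flux_basis(network)
  k <- ncol(basis$K)
  pool_b <- pool_bounds_matrix(network)
  if (conc_mode == "fixed") {
    if (is.null(conc_fixed)) stop("conc_mode = 'fixed' needs conc_fixed")
    conc_fixed <- conc_fixed[rownames(pool_b)]
  }
  n_par <- k + if (conc_mode == "estimate") nrow(pool_b) else 0L
  dof <- degrees_of_freedom(nrow(measurements), n_par)

  # start points from the sampling module
  flux_starts <- sample_flux_space(network, n_starts, seed = seed + 7919L)
  conc_starts <- sample_concentrations(network, n_starts, seed = seed + 104729L)
  lower <- c(rep(-Inf, k), if (conc_mode == "estimate") log(pool_b[, "lb"]))
  upper <- c(rep(Inf, k), if (conc_mode == "estimate") log(pool_b[, "ub"]))

  run_start <- function(s) {
    u0 <- if (k > 0) drop(crossprod(basis$K, flux_starts[[s]]$v - basis$v0)) else numeric(0)
    par <- c(u0, if (conc_mode == "estimate") log(conc_starts[[s]]))
    w <- ctl$penalty_weight
    res <- NULL
    for (ramp in seq_len(ctl$penalty_ramps)) {
      rf <- make_residual_fn(predictor, measurements, basis, conc_mode,
                             conc_fixed, pool_b, w, basis$v0)
      res <- minpack.lm::nls.lm(
        par = par, fn = rf$fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = ctl$maxiter, ftol = ctl$ftol, ptol = ctl$ptol,
          gtol = ctl$gtol))
      par <- res$par
      v <- basis$v0 + if (k > 0) drop(basis$K %*% par[seq_len(k)]) else 0
      viol <- max(c(basis$lb - v, v - basis$ub, 0))
      if (viol < 1e-8) break
      w <- w * 10
    }
    v <- basis$v0 + if (k > 0) drop(basis$K %*% par[seq_len(k)]) else 0
    names(v) <- basis$cols$col
    conc <- if (conc_mode == "estimate") {
      setNames(exp(par[-seq_len(k)]), rownames(pool_b))
    } else conc_fixed
    ssr <- meas_ssr(predictor, measurements, pmin(pmax(v, basis$lb), basis$ub), conc)
    list(par = par, v = v, conc = conc, ssr = ssr,
         converged = res$info %in% 1:4,
         viol = max(c(basis$lb - v, v - basis$ub, 0)), ood = rf$ood())
  }

  results <- lapply(seq_len(n_starts), run_start)
  ssrs <- vapply(results, `[[`, 0, "ssr")
  best <- which.min(ssrs)
  b <- results[[best]]
  structure(list(
    v_hat = b$v, net = drop(basis$net_map %*% b$v), c_hat = b$conc,
    u_hat = b$par[seq_len(k)], ssr = b$ssr, dof = dof, L = b$ssr / dof,
    n_starts = n_starts, best_start = best, per_start_ssr = ssrs,
    converged = b$converged && b$viol < 1e-6,
    bound_violation = b$viol,
    n_out_of_domain = sum(vapply(results, `[[`, 0L, "ood")),
    basis = basis, conc_mode = conc_mode, n_measurements = nrow(measurements),
    seed = seed), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> ssr %.4g, dof %d, L %.4g, %s (best of %d starts)\n",
              x$ssr, x$dof, x$L,
              if (x$converged) "converged" else "NOT converged", x$n_starts))
  invisible(x)
}

#' Serialise a fit result
#'
#' JSON carries fluxes, pools, L, dof and per-start diagnostics; the CSV is a
#' flat table of net flux estimates.
#'
#' @param fit a `fit_result`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return `fit`, invisibly.
#' @export
write_fit_result <- function(fit, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      net_fluxes = as.list(fit$net), directed_fluxes = as.list(fit$v_hat),
      pools = as.list(fit$c_hat), ssr = fit$ssr, dof = fit$dof, L = fit$L,
      converged = fit$converged, n_starts = fit$n_starts,
      best_start = fit$best_start, per_start_ssr = fit$per_start_ssr,
      n_out_of_domain = fit$n_out_of_domain),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    write.csv(data.frame(reaction_id = names(fit$net), flux = as.numeric(fit$net)),
              csv_path, row.names = FALSE)
  }
  invisible(fit)
}
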