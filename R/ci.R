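#' @title Profile confidence intervals
#' @description Per-reaction confidence intervals by chi-square profiling:
#'   one reaction's net flux is constrained away from its optimum with a hard
#'   linear equality (the null-space basis is re-derived under the added
#'   constraint), all remaining parameters are re-optimised, and the interval
#'   endpoints are where the SSR crosses the best-fit SSR plus the
#'   one-parameter chi-square quantile.
#' @name confidence_intervals
NULL

pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d[1], 1)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

# re-optimise all parameters with reaction `rid`'s net flux fixed at w;
# returns the measurement SSR (Inf if the constraint is infeasible)
profile_ssr_fn <- function(fit, rid, predictor, measurements, network, ctl) {
  basis <- fit$basis
  a <- basis$net_map[rid, ]
  Saug <- rbind(basis$S, a)
  K2 <- null_space(Saug)
  pool_b <- pool_bounds_matrix(network)
  conc_mode <- fit$conc_mode
  k2 <- ncol(K2)
  lower <- c(rep(-Inf, k2), if (conc_mode == "estimate") log(pool_b[, "lb"]))
  upper <- c(rep(Inf, k2), if (conc_mode == "estimate") log(pool_b[, "ub"]))

  function(w) {
    vp <- pinv_solve(Saug, c(rep(0, nrow(basis$S)), w))
    names(vp) <- basis$cols$col
    u0 <- if (k2 > 0) drop(crossprod(K2, fit$v_hat - vp)) else numeric(0)
    par0 <- c(u0, if (conc_mode == "estimate") log(fit$c_hat))
    if (length(par0) == 0) {
      v <- pmin(pmax(vp, basis$lb), basis$ub)
      if (max(abs(v - vp)) > 1e-6) return(list(ssr = Inf, converged = FALSE))
      return(list(ssr = meas_ssr(predictor, measurements, v, fit$c_hat),
                  converged = TRUE))
    }
    b2 <- basis; b2$K <- K2
    rf <- make_residual_fn(predictor, measurements, b2, conc_mode,
                           fit$c_hat, pool_b, ctl$penalty_weight, vp)
    res <- minpack.lm::nls.lm(
      par = par0, fn = rf$fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = ctl$maxiter,
                                           ftol = ctl$ftol, ptol = ctl$ptol,
                                           gtol = ctl$gtol))
    v <- vp + if (k2 > 0) drop(K2 %*% res$par[seq_len(k2)]) else 0
    viol <- max(c(basis$lb - v, v - basis$ub, 0))
    if (viol > 1e-6) return(list(ssr = Inf, converged = FALSE))
    conc <- if (conc_mode == "estimate") {
      setNames(exp(res$par[-seq_len(k2)]), rownames(pool_b))
    } else fit$c_hat
    list(ssr = meas_ssr(predictor, measurements,
                        pmin(pmax(v, basis$lb), basis$ub), conc),
         converged = res$info %in% 1:4)
  }
}

#' Profile confidence interval for one reaction's net flux
#'
#' Walks outward from the best-fit value with adaptive (doubling) steps until
#' the re-optimised SSR crosses `ssr_min + qchisq(level, 1)`, then refines the
#' crossing by bisection. Endpoints at the flux bounds are reported censored.
#'
#' @param fit a converged [fit_fluxes()] result.
#' @param reaction_id reaction to profile.
#' @param predictor the predictor used for the fit.
#' @param measurements the fitted measurement set.
#' @param network the reaction network.
#' @param level confidence level (default 0.99).
#' @param opts list: `step_frac` (initial step, fraction of `|v_hat|`, 0.02),
#'   `floor_frac` (step floor, fraction of bound range, 0.01), `tol_frac`
#'   (bisection tolerance, fraction of bound range, 1e-4), `max_steps` (40),
#'   `control` (optimiser control as in [fit_fluxes()]).
#' @return list of class `confidence_interval`: `reaction_id`, `level`,
#'   `lower`, `upper`, `censored_low`, `censored_high`, `v_hat`, `threshold`,
#'   `profile` (data.frame `value`, `ssr`, `converged`).
#' @export
profile_ci <- function(fit, reaction_id, predictor, measurements, network,
                       level = 0.99, opts = list()) {
  if (!fit$converged) stop("profile_ci requires a converged fit")
  if (!(reaction_id %in% rownames(fit$basis$net_map))) {
    stop("unknown reaction '", reaction_id, "'")
  }
  o <- modifyList(list(step_frac = 0.02, floor_frac = 0.01, tol_frac = 1e-4,
                       max_steps = 40, control = list()), opts)
  ctl <- modifyList(list(maxiter = 400, ftol = 1e-10, ptol = 1e-10,
                         gtol = 1e-8, penalty_weight = 1e3), o$control)
  rx <- network$reactions[[reaction_id]]
  lb <- rx$flux_bounds[1]; ub <- rx$flux_bounds[2]
  rng <- ub - lb
  v_hat <- fit$net[[reaction_id]]
  thr <- fit$ssr + qchisq(level, 1)
  pfn <- profile_ssr_fn(fit, reaction_id, predictor, measurements, network, ctl)

  prof <- data.frame(value = v_hat, ssr = fit$ssr, converged = TRUE)
  note <- function(w, r) {
    prof <<- rbind(prof, data.frame(value = w, ssr = r$ssr,
                                    converged = r$converged))
    if (is.finite(r$ssr) && r$ssr < fit$ssr - 1e-6) {
      warning("profile for ", reaction_id, " dips below the best-fit SSR at ",
              signif(w, 6), ": possible local-minimum hop")
    }
    r$ssr
  }

  walk <- function(dir) {
    bound <- if (dir > 0) ub else lb
    step <- max(o$step_frac * abs(v_hat), o$floor_frac * rng)
    inside <- v_hat; outside <- NULL
    for (i in seq_len(o$max_steps)) {
      w <- v_hat + dir * step
      hit_bound <- (dir > 0 && w >= bound) || (dir < 0 && w <= bound)
      if (hit_bound) w <- bound
      s <- note(w, pfn(w))
      if (s >= thr) { outside <- w; break }
      inside <- w
      if (hit_bound) break
      step <- step * 2
    }
    if (is.null(outside)) {
      return(list(endpoint = bound, censored = TRUE))
    }
    lo <- inside; hi <- outside
    while (abs(hi - lo) > o$tol_frac * rng) {
      mid <- (lo + hi) / 2
      s <- note(mid, pfn(mid))
      if (s >= thr) hi <- mid else lo <- mid
    }
    list(endpoint = (lo + hi) / 2, censored = FALSE)
  }

  up <- walk(+1)
  dn <- walk(-1)
  structure(list(reaction_id = reaction_id, level = level,
                 lower = dn$endpoint, upper = up$endpoint,
                 censored_low = dn$censored, censored_high = up$censored,
                 v_hat = v_hat, threshold = thr,
                 profile = prof[order(prof$value), ]),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("<confidence_interval> %s: %.0f%% CI [%s%.4g, %.4g%s], v_hat %.4g\n",
              x$reaction_id, 100 * x$level,
              if (x$censored_low) "<=" else "", x$lower,
              x$upper, if (x$censored_high) "=>" else "", x$v_hat))
  invisible(x)
}

#' Tabulate confidence intervals
#'
#' @param cis list of [profile_ci()] results.
#' @return data.frame with one row per reaction, ready for CSV export.
#' @export
ci_report <- function(cis) {
  do.call(rbind, lapply(cis, function(ci) {
    data.frame(reaction_id = ci$reaction_id, level = ci$level,
               v_hat = ci$v_hat, lower = ci$lower, upper = ci$upper,
               censored_low = ci$censored_low, censored_high = ci$censored_high,
               n_profile_points = nrow(ci$profile))
  }))
}
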