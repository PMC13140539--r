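#' @title MID simulation
#' @description The forward model: assemble the coupled EMU ODEs for one flux
#'   distribution and one pool-size vector and solve them at requested time
#'   points. Systems without state-state convolutions are linear
#'   time-invariant and solved exactly by matrix exponentials; systems with
#'   convolutions are integrated with a stiff solver.
#' @name mid_simulation
NULL

#' Tracer specification
#'
#' @param metabolite id of the fed (boundary) nutrient.
#' @param fractions per-atom labelled fraction, recycled to the metabolite's
#'   atom count; default 1 (fully labelled, e.g. 13CO2 or 15NO3-).
#' @param switch_time time at which unlabelled feed is replaced by tracer.
#' @return list of class `tracer_spec`.
#' @export
tracer_spec <- function(metabolite, fractions = 1, switch_time = 0) {
  fractions <- as.numeric(fractions)
  if (any(fractions < 0 | fractions > 1)) stop("label fractions must lie in [0, 1]")
  structure(list(metabolite = metabolite, fractions = fractions,
                 switch_time = as.numeric(switch_time)), class = "tracer_spec")
}

#' Convolve two MID vectors
#'
#' The MID of a molecule assembled from two independent fragments is the
#' convolution of the fragment MIDs.
#'
#' @param a,b numeric MID vectors (M+0 first).
#' @return numeric vector of length `length(a) + length(b) - 1`.
#' @export
convolve_mids <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

conv_list <- function(mids) Reduce(convolve_mids, mids)

# MID of a source (boundary) EMU under the tracer spec: independent atoms,
# labelled fraction p per atom for the tracer metabolite, 0 elsewhere.
source_emu_mid <- function(network, e, tracer, labelled = TRUE) {
  m <- network$metabolites[[e$met]]
  p <- rep(0, m$n_atoms)
  if (labelled && !is.null(tracer) && e$met == tracer$metabolite) {
    p <- rep(tracer$fractions, length.out = m$n_atoms)
  }
  conv_list(lapply(e$atoms, function(a) c(1 - p[a], p[a])))
}

as_directed_flux <- function(network, v) {
  ds <- directed_system(network)
  if (inherits(v, "flux_sample")) v <- v$v
  if (!is.null(names(v)) && all(ds$cols$col %in% names(v))) {
    return(v[ds$cols$col])
  }
  if (!is.null(names(v)) && all(names(network$reactions) %in% names(v))) {
    out <- numeric(nrow(ds$cols))
    names(out) <- ds$cols$col
    for (k in seq_len(nrow(ds$cols))) {
      vn <- v[[ds$cols$rxn[k]]]
      out[k] <- if (ds$cols$dir[k] > 0) max(vn, 0) else max(-vn, 0)
    }
    return(out)
  }
  if (is.null(names(v)) && length(v) == nrow(ds$cols)) {
    return(setNames(as.numeric(v), ds$cols$col))
  }
  stop("flux vector names match neither directed columns nor reaction ids")
}

#' Assemble the EMU ODE system
#'
#' Builds, per EMU size level, the balance matrices `A` (same-size coupling,
#' negative diagonal = total influx) and `B` (inputs from source EMUs and
#' smaller-size convolutions) of the system `c * dX/dt = A X + B Y`, plus the
#' flat term structure used by the integrator. Label mass balance makes every
#' row of `[A | B]` sum to zero.
#'
#' @param emu_network a [decompose()] result.
#' @param flux directed flux vector (or [sample_flux_space()] sample).
#' @param conc named pool-size vector over balanced metabolites.
#' @return list of class `emu_ode_system` with `levels` (per size: `emu_ids`,
#'   `A`, `B`, `inputs`), `terms`, `offsets`, `lengths`, `pool`, `linear`.
#' @export
build_emu_odes <- function(emu_network, flux, conc) {
  net <- emu_network$network
  v <- as_directed_flux(net, flux)
  ids <- names(emu_network$emus)
  if (length(ids) == 0) stop("EMU network has no state EMUs")
  sizes <- vapply(emu_network$emus, `[[`, 0L, "size")
  ord <- order(sizes, ids)
  ids <- ids[ord]; sizes <- sizes[ord]
  lens <- sizes + 1L
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  names(offsets) <- ids; names(lens) <- ids

  pool <- vapply(ids, function(id) {
    met <- emu_network$emus[[id]]$met
    ci <- conc[[met]]
    if (is.null(ci) || is.na(ci)) stop("no pool size supplied for metabolite '", met, "'")
    as.numeric(ci)
  }, numeric(1))

  tracer <- net$tracer
  src_mid <- lapply(emu_network$sources, function(e) {
    source_emu_mid(net, e, tracer, labelled = TRUE)
  })

  terms <- setNames(vector("list", length(ids)), ids)
  total_w <- setNames(numeric(length(ids)), ids)
  for (r in emu_network$reactions) {
    w <- r$coeff * v[[r$col]]
    if (w < -1e-12) stop("negative directed flux for column ", r$col)
    comps <- lapply(r$sources, function(sid) {
      if (!is.null(emu_network$emus[[sid]])) {
        list(kind = "state", id = sid)
      } else if (!is.null(src_mid[[sid]])) {
        list(kind = "source", id = sid, mid = src_mid[[sid]])
      } else stop("EMU reaction references unknown EMU '", sid, "'")
    })
    terms[[r$target]] <- c(terms[[r$target]],
                           list(list(w = w, comps = comps)))
    total_w[[r$target]] <- total_w[[r$target]] + w
  }
  for (id in ids) {
    if (total_w[[id]] <= 1e-12 && pool[[id]] <= 0) {
      stop("EMU ", id, " has zero influx and zero pool: state undefined")
    }
  }

  linear <- all(vapply(unlist(terms, recursive = FALSE), function(tm) {
    sum(vapply(tm$comps, function(cp) cp$kind == "state", logical(1))) <= 1L
  }, logical(1)))

  # per-level A/B matrices (the balance contract exposed for inspection/tests)
  levels <- list()
  for (s in sort(unique(sizes))) {
    lev_ids <- ids[sizes == s]
    A <- matrix(0, length(lev_ids), length(lev_ids),
                dimnames = list(lev_ids, lev_ids))
    inputs <- list(); Bcols <- list()
    for (id in lev_ids) {
      A[id, id] <- -total_w[[id]]
      for (tm in terms[[id]]) {
        if (length(tm$comps) == 1L && tm$comps[[1]]$kind == "state" &&
            tm$comps[[1]]$id %in% lev_ids) {
          A[id, tm$comps[[1]]$id] <- A[id, tm$comps[[1]]$id] + tm$w
        } else {
          key <- paste(vapply(tm$comps, `[[`, "", "id"), collapse = "*")
          if (is.null(inputs[[key]])) {
            inputs[[key]] <- lapply(tm$comps, function(cp) cp[c("kind", "id")])
            Bcols[[key]] <- setNames(numeric(length(lev_ids)), lev_ids)
          }
          Bcols[[key]][id] <- Bcols[[key]][id] + tm$w
        }
      }
    }
    B <- if (length(Bcols)) do.call(cbind, Bcols) else
      matrix(0, length(lev_ids), 0, dimnames = list(lev_ids, NULL))
    levels[[as.character(s)]] <- list(size = s, emu_ids = lev_ids, A = A, B = B,
                                      inputs = unname(inputs))
  }

  structure(list(levels = levels, terms = terms, total_w = total_w,
                 offsets = offsets, lengths = lens, pool = pool,
                 emu_ids = ids, n_state = sum(lens), linear = linear,
                 src_mid = src_mid, flux = v, conc = conc),
            class = "emu_ode_system")
}

chunk <- function(y, sys, id) {
  o <- sys$offsets[[id]]
  y[(o + 1L):(o + sys$lengths[[id]])]
}

emu_rhs <- function(sys) {
  ids <- sys$emu_ids
  function(t, y, parms) {
    dy <- numeric(length(y))
    for (id in ids) {
      o <- sys$offsets[[id]]; l <- sys$lengths[[id]]
      xi <- y[(o + 1L):(o + l)]
      acc <- numeric(l)
      for (tm in sys$terms[[id]]) {
        if (tm$w == 0) next
        mids <- lapply(tm$comps, function(cp) {
          if (cp$kind == "state") chunk(y, sys, cp$id) else cp$mid
        })
        acc <- acc + tm$w * conv_list(mids)
      }
      dy[(o + 1L):(o + l)] <- (acc - sys$total_w[[id]] * xi) / sys$pool[[id]]
    }
    list(dy)
  }
}

initial_state <- function(sys) {
  y0 <- numeric(sys$n_state)
  y0[sys$offsets + 1L] <- 1
  y0
}

# linear time-invariant assembly: x' = D^{-1} (M x + b)
linear_system <- function(sys) {
  n <- sys$n_state
  M <- matrix(0, n, n)
  b <- numeric(n)
  for (id in sys$emu_ids) {
    o <- sys$offsets[[id]]; l <- sys$lengths[[id]]
    rows <- (o + 1L):(o + l)
    M[cbind(rows, rows)] <- M[cbind(rows, rows)] - sys$total_w[[id]]
    for (tm in sys$terms[[id]]) {
      if (tm$w == 0) next
      st <- Filter(function(cp) cp$kind == "state", tm$comps)
      const_mid <- conv_list(c(list(1), lapply(
        Filter(function(cp) cp$kind != "state", tm$comps), `[[`, "mid")))
      if (length(st) == 0) {
        b[rows] <- b[rows] + tm$w * const_mid
      } else {
        so <- sys$offsets[[st[[1]]$id]]; sl <- sys$lengths[[st[[1]]$id]]
        for (j in seq_along(const_mid)) {
          # conv(x, k)[i + j - 1] += x[i] * k[j]
          tr <- o + seq_len(sl) + (j - 1L)
          M[cbind(tr, so + seq_len(sl))] <-
            M[cbind(tr, so + seq_len(sl))] + tm$w * const_mid[j]
        }
      }
    }
  }
  D <- rep(sys$pool, times = sys$lengths)
  list(M = M, b = b, D = D)
}

solve_linear <- function(sys, times) {
  ls <- linear_system(sys)
  x_ss <- tryCatch(solve(ls$M, -ls$b), error = function(e) NULL)
  if (is.null(x_ss)) return(NULL)
  G <- ls$M / ls$D
  x0 <- initial_state(sys)
  d0 <- x0 - x_ss
  out <- matrix(0, length(times), length(x0))
  for (i in seq_along(times)) {
    out[i, ] <- if (times[i] == 0) x0 else
      x_ss + as.numeric(Matrix::expm(Matrix::Matrix(G * times[i])) %*% d0)
  }
  out
}

clip_renorm <- function(mid, floor_tol = -1e-9) {
  if (any(mid < floor_tol - 1e-6)) {
    # large negatives signal solver trouble; keep but warn upstream via attr
  }
  mid <- pmax(mid, 0)
  s <- sum(mid)
  if (s <= 0) stop("degenerate MID: all components nonpositive")
  mid / s
}

#' Simulate MID trajectories for an EMU network
#'
#' Integrates the coupled EMU ODEs from an unlabelled initial state at the
#' tracer switch time. Linear systems (no state-state convolution) are solved
#' exactly by matrix exponentials; otherwise `deSolve::ode` (lsoda, rtol 1e-8 /
#' atol 1e-10) is used, with a BDF retry at tighter tolerance on failure.
#'
#' @param emu_network a [decompose()] result.
#' @param flux directed flux vector or [sample_flux_space()] sample.
#' @param conc named pool-size vector over balanced metabolites.
#' @param timepoints output times (>= tracer switch time).
#' @param tracer optional [tracer_spec()] override (default: the network's).
#' @param solver_opts list: `rtol`, `atol`, `method` ("auto", "lsoda", "bdf",
#'   "linear"), `raw` (keep unclipped MIDs as attribute).
#' @return named list (by EMU id) of `mid_trajectory` objects: `emu`, `times`,
#'   `mids` (time x mass-shift matrix, each row on the probability simplex).
#' @export
simulate_mids <- function(emu_network, flux, conc, timepoints,
                          tracer = NULL, solver_opts = list()) {
  net <- emu_network$network
  if (!is.null(tracer)) {
    net <- emu_network$network
    net$tracer <- tracer
    emu_network$network <- net
  }
  tr <- emu_network$network$tracer
  if (is.null(tr)) stop("no tracer specified (network$tracer or `tracer` argument)")
  timepoints <- sort(as.numeric(timepoints))
  if (any(timepoints < tr$switch_time - 1e-12)) {
    stop("timepoints must be >= tracer switch_time")
  }
  rel_t <- timepoints - tr$switch_time

  opts <- modifyList(list(rtol = 1e-8, atol = 1e-10, method = "auto",
                          raw = FALSE), solver_opts)
  sys <- build_emu_odes(emu_network, flux, conc)

  sol <- NULL
  if (sys$linear && opts$method %in% c("auto", "linear")) {
    sol <- solve_linear(sys, rel_t)
  }
  if (is.null(sol)) {
    method <- if (opts$method %in% c("auto", "linear")) "lsoda" else opts$method
    tt <- unique(c(0, rel_t))
    run <- function(method, rtol, atol) {
      out <- try(deSolve::ode(y = initial_state(sys), times = tt,
                              func = emu_rhs(sys), parms = NULL,
                              method = method, rtol = rtol, atol = atol),
                 silent = TRUE)
      if (inherits(out, "try-error") || nrow(out) < length(tt)) NULL else out
    }
    out <- run(method, opts$rtol, opts$atol)
    if (is.null(out)) out <- run("bdf", opts$rtol * 1e-2, opts$atol * 1e-2)
    if (is.null(out)) {
      stop("stiff-solver failure while simulating MIDs",
           if (!is.null(attr(flux, "sample_id"))) paste0(
             " (flux sample ", attr(flux, "sample_id"), ")") else "")
    }
    sol <- out[match(rel_t, tt), -1, drop = FALSE]
  }

  trajs <- list()
  for (id in sys$emu_ids) {
    o <- sys$offsets[[id]]; l <- sys$lengths[[id]]
    raw <- sol[, (o + 1L):(o + l), drop = FALSE]
    mids <- t(apply(raw, 1, clip_renorm))
    colnames(mids) <- paste0("M", 0:(l - 1L))
    tj <- structure(list(emu = emu_network$emus[[id]], id = id,
                         times = timepoints, mids = mids),
                    class = "mid_trajectory")
    if (opts$raw) attr(tj, "raw") <- raw
    trajs[[id]] <- tj
  }
  # requested boundary EMUs have known, constant labelled MIDs
  for (id in intersect(emu_network$targets, names(emu_network$sources))) {
    midv <- source_emu_mid(emu_network$network, emu_network$sources[[id]], tr)
    mids <- matrix(rep(midv, each = length(timepoints)), nrow = length(timepoints))
    mids[rel_t == 0, ] <- c(1, rep(0, length(midv) - 1L))
    colnames(mids) <- paste0("M", seq_along(midv) - 1L)
    trajs[[id]] <- structure(list(emu = emu_network$sources[[id]], id = id,
                                  times = timepoints, mids = mids),
                             class = "mid_trajectory")
  }
  trajs
}

#' Extract one MID vector from a trajectory list
#'
#' @param trajectories result of [simulate_mids()].
#' @param emu_id EMU id.
#' @param time a time present in the trajectories.
#' @return numeric MID vector.
#' @export
get_mid <- function(trajectories, emu_id, time) {
  tj <- trajectories[[emu_id]]
  if (is.null(tj)) stop("no trajectory for EMU '", emu_id, "'")
  i <- which(abs(tj$times - time) < 1e-9)
  if (length(i) != 1) stop("time ", time, " not simulated for EMU '", emu_id, "'")
  tj$mids[i, ]
}
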