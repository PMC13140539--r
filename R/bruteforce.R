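# Brute-force full-isotopomer simulator: the correctness oracle for the EMU
# reduction. Tracks all 2^n isotopomer fractions of every balanced traced
# metabolite; marginalising any EMU's atoms must reproduce its MID.

iso_index <- function(bits) 1L + sum(bits * 2L^(seq_along(bits) - 1L))

iso_bits <- function(index, n) as.integer(intToBits(index - 1L))[seq_len(n)]

# joint labelling distribution of a subset of atom positions
iso_marginal <- function(dist, n, positions) {
  k <- length(positions)
  out <- numeric(2^k)
  for (i in seq_along(dist)) {
    bits <- iso_bits(i, n)
    out[iso_index(bits[positions])] <- out[iso_index(bits[positions])] + dist[i]
  }
  out
}

iso_to_mid <- function(dist, n, positions = seq_len(n)) {
  marg <- iso_marginal(dist, n, positions)
  k <- length(positions)
  mid <- numeric(k + 1L)
  for (i in seq_along(marg)) {
    w <- sum(iso_bits(i, k))
    mid[w + 1L] <- mid[w + 1L] + marg[i]
  }
  mid
}

boundary_iso_dist <- function(network, met, tracer) {
  n <- network$metabolites[[met]]$n_atoms
  p <- rep(0, n)
  if (!is.null(tracer) && met == tracer$metabolite) {
    p <- rep(tracer$fractions, length.out = n)
  }
  dist <- numeric(2^n)
  for (i in seq_len(2^n)) {
    bits <- iso_bits(i, n)
    dist[i] <- prod(ifelse(bits == 1L, p, 1 - p))
  }
  dist
}

#' Brute-force full-isotopomer simulation
#'
#' Integrates the complete isotopomer balance (2^n states per balanced traced
#' metabolite) with `deSolve`. Intended as an independent oracle for the EMU
#' path on small fixtures; refuses networks above the state cap.
#'
#' @param network a [reaction_network()].
#' @param flux directed flux vector or sample.
#' @param conc named pool-size vector over balanced metabolites.
#' @param timepoints output times (>= tracer switch time).
#' @param tracer optional [tracer_spec()] override.
#' @param max_states cap on the summed isotopomer state count (default 4096).
#' @param solver_opts list with `rtol`, `atol`.
#' @return list of class `iso_trajectories`: `times`, `dists` (metabolite ->
#'   time x 2^n matrix), `network`.
#' @export
simulate_isotopomers_bruteforce <- function(network, flux, conc, timepoints,
                                            tracer = NULL, max_states = 4096,
                                            solver_opts = list()) {
  if (!is.null(tracer)) network$tracer <- tracer
  tr <- network$tracer
  if (is.null(tr)) stop("no tracer specified")
  opts <- modifyList(list(rtol = 1e-8, atol = 1e-10), solver_opts)
  v <- as_directed_flux(network, flux)

  mets <- balanced_metabolites(network)
  mets <- mets[vapply(mets, function(m) network$metabolites[[m]]$n_atoms > 0,
                      logical(1))]
  natoms <- vapply(mets, function(m) network$metabolites[[m]]$n_atoms, 0L)
  if (sum(2^natoms) > max_states) {
    stop("isotopomer state count ", sum(2^natoms), " exceeds cap ", max_states,
         "; use the EMU path for networks of this size")
  }
  lens <- as.integer(2^natoms)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  names(offsets) <- mets; names(lens) <- mets; names(natoms) <- mets

  orecs <- oriented_records(network)
  # precompute production terms: per balanced product metabolite, per record:
  # weight, and the layout of contributing substrate occurrences
  prod_terms <- setNames(vector("list", length(mets)), mets)
  total_w <- setNames(numeric(length(mets)), mets)
  for (col in names(orecs)) {
    for (rec in orecs[[col]]) {
      w0 <- rec$weight * v[[col]]
      for (occ in rec$products) {
        if (!(occ$met %in% mets)) next
        n_p <- length(occ$atoms)
        parts <- list()
        for (s in rec$substrates) {
          tgt_pos <- match(s$atoms, occ$atoms)   # product positions fed by s
          sub_pos <- which(!is.na(tgt_pos))
          tgt_pos <- tgt_pos[!is.na(tgt_pos)]
          if (length(sub_pos) == 0) next
          parts[[length(parts) + 1L]] <- list(met = s$met, sub_pos = sub_pos,
                                              tgt_pos = tgt_pos)
        }
        prod_terms[[occ$met]] <- c(prod_terms[[occ$met]],
                                   list(list(w = w0, parts = parts)))
        total_w[[occ$met]] <- total_w[[occ$met]] + w0
      }
    }
  }

  pool <- vapply(mets, function(m) {
    ci <- conc[[m]]
    if (is.null(ci) || ci <= 0) stop("positive pool size required for '", m, "'")
    as.numeric(ci)
  }, numeric(1))

  bdists <- list()  # cached boundary isotopomer distributions (labelled feed)
  get_dist <- function(y, met) {
    if (met %in% mets) {
      y[(offsets[[met]] + 1L):(offsets[[met]] + lens[[met]])]
    } else {
      if (is.null(bdists[[met]])) {
        bdists[[met]] <<- boundary_iso_dist(network, met, tr)
      }
      bdists[[met]]
    }
  }

  rhs <- function(t, y, parms) {
    dy <- numeric(length(y))
    for (m in mets) {
      n <- natoms[[m]]
      rows <- (offsets[[m]] + 1L):(offsets[[m]] + lens[[m]])
      acc <- numeric(lens[[m]])
      for (tm in prod_terms[[m]]) {
        if (tm$w == 0) next
        margs <- lapply(tm$parts, function(p) {
          d <- get_dist(y, p$met)
          iso_marginal(d, network$metabolites[[p$met]]$n_atoms, p$sub_pos)
        })
        q <- numeric(lens[[m]])
        for (i in seq_len(lens[[m]])) {
          bits <- iso_bits(i, n)
          pr <- 1
          for (j in seq_along(tm$parts)) {
            pr <- pr * margs[[j]][iso_index(bits[tm$parts[[j]]$tgt_pos])]
          }
          q[i] <- pr
        }
        acc <- acc + tm$w * q
      }
      dy[rows] <- (acc - total_w[[m]] * y[rows]) / pool[[m]]
    }
    list(dy)
  }

  timepoints <- sort(as.numeric(timepoints))
  rel_t <- timepoints - tr$switch_time
  if (any(rel_t < -1e-12)) stop("timepoints must be >= tracer switch_time")
  y0 <- numeric(sum(lens))
  y0[offsets + 1L] <- 1
  tt <- unique(c(0, rel_t))
  out <- deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = opts$rtol, atol = opts$atol)
  sol <- out[match(rel_t, tt), -1, drop = FALSE]

  dists <- list()
  for (m in mets) {
    dists[[m]] <- sol[, (offsets[[m]] + 1L):(offsets[[m]] + lens[[m]]),
                      drop = FALSE]
  }
  structure(list(times = timepoints, dists = dists, natoms = natoms,
                 network = network), class = "iso_trajectories")
}

#' Marginalise brute-force isotopomer trajectories to an EMU's MID
#'
#' @param iso an [simulate_isotopomers_bruteforce()] result.
#' @param e an [emu()] (or EMU id string) over a balanced metabolite.
#' @return time x (size+1) MID matrix.
#' @export
bruteforce_mid <- function(iso, e) {
  if (is.character(e)) e <- parse_emu_id(e)
  d <- iso$dists[[e$met]]
  if (is.null(d)) stop("metabolite '", e$met, "' not simulated")
  n <- iso$natoms[[e$met]]
  mids <- t(apply(d, 1, function(row) iso_to_mid(row, n, e$atoms)))
  colnames(mids) <- paste0("M", 0:e$size)
  mids
}
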