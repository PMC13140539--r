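#' @title Flux and pool-size sampling
#' @description Draws the training samples of steady-state flux distributions
#'   (uniform over the flux polytope via hit-and-run on the null-space
#'   parameterisation) and pool-size vectors (log-uniform within bounds) that
#'   define the surrogates' solution space.
#' @name sampling
NULL

#' Sample the steady-state flux polytope
#'
#' Coordinate-free hit-and-run on `v = v0 + K u`: random direction in the
#' null space, uniform step within the box bounds. Warm-up `100 * dim` steps,
#' thinning `dim` steps (the defaults; configurable). `corner_mix` instead
#' mixes boundary points pushed from the centre with Dirichlet weights --
#' cheaper, not uniform.
#'
#' @param network a [reaction_network()].
#' @param n number of samples (>= 1; `n = 0` returns an empty list).
#' @param seed integer RNG seed; fixed seed gives bit-identical samples.
#' @param method `"hit_and_run"` (default) or `"corner_mix"`.
#' @param warmup,thin hit-and-run warm-up and thinning step counts.
#' @return list of `flux_sample` objects, each with `v` (named directed flux
#'   vector satisfying `S v = 0` and bounds) and `net` (net reaction fluxes).
#' @export
sample_flux_space <- function(network, n, seed = 1L,
                              method = c("hit_and_run", "corner_mix"),
                              warmup = NULL, thin = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 0)
  basis <- free_flux_basis(network)
  K <- basis$K; v0 <- basis$v0; lb <- basis$lb; ub <- basis$ub
  dim_u <- ncol(K)
  if (n == 0) return(list())
  set.seed(as.integer(seed))

  mk_sample <- function(v, i) {
    v <- pmin(pmax(v, lb), ub)
    names(v) <- basis$cols$col
    resid <- max(abs(basis$S %*% v))
    if (resid >= 1e-8) stop("sampled flux violates steady state: |S v| = ", resid)
    structure(list(v = v, net = drop(basis$net_map %*% v), sample_id = i),
              class = "flux_sample")
  }

  if (dim_u == 0) {
    return(lapply(seq_len(n), function(i) mk_sample(v0, i)))
  }

  line_range <- function(v, d) {
    # t range with lb <= v + t d <= ub
    tmin <- -Inf; tmax <- Inf
    for (i in seq_along(d)) {
      if (abs(d[i]) < 1e-14) next
      lo <- (lb[i] - v[i]) / d[i]; hi <- (ub[i] - v[i]) / d[i]
      if (d[i] < 0) { tmp <- lo; lo <- hi; hi <- tmp }
      tmin <- max(tmin, lo); tmax <- min(tmax, hi)
    }
    c(tmin, tmax)
  }

  if (method == "hit_and_run") {
    warmup <- warmup %||% (100L * dim_u)
    thin <- thin %||% dim_u
    v <- v0
    samples <- vector("list", n)
    total <- warmup + n * thin
    taken <- 0L
    for (step in seq_len(total)) {
      g <- rnorm(dim_u)
      d <- drop(K %*% (g / sqrt(sum(g^2))))
      rg <- line_range(v, d)
      if (!is.finite(rg[1]) || !is.finite(rg[2]) || rg[2] < rg[1]) next
      v <- v + runif(1, rg[1], rg[2]) * d
      if (step > warmup && (step - warmup) %% thin == 0L) {
        taken <- taken + 1L
        samples[[taken]] <- mk_sample(v, taken)
        if (taken == n) break
      }
    }
    if (taken < n) {
      warning("hit-and-run produced only ", taken, " of ", n,
              " samples (degenerate directions); padding from current point")
      for (i in (taken + 1L):n) samples[[i]] <- mk_sample(v, i)
    }
    return(samples)
  }

  # corner_mix: push random null-space directions from the centre to the
  # boundary, mix with Dirichlet weights, shrink slightly inward
  n_corners <- max(2L * dim_u, 4L)
  corners <- matrix(0, n_corners, length(v0))
  for (j in seq_len(n_corners)) {
    g <- rnorm(dim_u)
    d <- drop(K %*% (g / sqrt(sum(g^2))))
    rg <- line_range(v0, d)
    t_edge <- if (j %% 2 == 0) rg[2] else rg[1]
    corners[j, ] <- v0 + 0.999 * t_edge * d
  }
  lapply(seq_len(n), function(i) {
    w <- -log(runif(n_corners)); w <- w / sum(w)
    v <- drop(w %*% corners)
    mk_sample(0.02 * v0 + 0.98 * v, i)
  })
}

#' Sample pool-size vectors
#'
#' @param network a [reaction_network()].
#' @param n number of samples (`n = 0` gives an empty list).
#' @param seed integer RNG seed.
#' @param distribution `"log_uniform"` (default; pool sizes span orders of
#'   magnitude) or `"uniform"`, within each balanced metabolite's pool bounds.
#' @return list of named numeric vectors over balanced metabolites, strictly
#'   positive and within bounds.
#' @export
sample_concentrations <- function(network, n, seed = 1L,
                                  distribution = c("log_uniform", "uniform")) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 0)
  mets <- balanced_metabolites(network)
  lb <- vapply(mets, function(m) network$metabolites[[m]]$pool_bounds[1], 0)
  ub <- vapply(mets, function(m) network$metabolites[[m]]$pool_bounds[2], 0)
  if (any(lb <= 0)) {
    stop("nonpositive pool lower bound for metabolite '", mets[which(lb <= 0)[1]], "'")
  }
  if (n == 0) return(list())
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    c_i <- if (distribution == "log_uniform") {
      exp(runif(length(mets), log(lb), log(ub)))
    } else {
      runif(length(mets), lb, ub)
    }
    setNames(pmin(pmax(c_i, lb), ub), mets)
  })
}

#' Persist flux/concentration samples as CSV with a JSON sidecar
#'
#' @param samples list of flux samples (or concentration vectors).
#' @param path CSV output path; a `.json` sidecar records seed/method/bounds.
#' @param meta named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, meta = list()) {
  if (length(samples) == 0) stop("no samples to write")
  mat <- if (inherits(samples[[1]], "flux_sample")) {
    do.call(rbind, lapply(samples, `[[`, "v"))
  } else {
    do.call(rbind, samples)
  }
  write.csv(as.data.frame(mat), path, row.names = FALSE)
  meta$n <- length(samples)
  meta$columns <- colnames(mat)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
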