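#' @title Reaction networks with atom transitions
#' @description Constructors and validators for compartmentalised metabolic
#'   networks carrying atom-transition maps, plus the stoichiometric machinery
#'   (S matrix, null-space basis, feasible interior point) every downstream
#'   module consumes.
#' @name network_model
NULL

#' Create a metabolite record
#'
#' @param id metabolite identifier including the compartment tag, e.g. `"A[c]"`.
#' @param compartment compartment code, e.g. `"[c]"`, `"[h]"`.
#' @param n_atoms number of traced atoms (carbon or nitrogen); 0 for untraced
#'   species.
#' @param pool_bounds length-2 numeric `(lower, upper)` pool-size bounds in
#'   arbitrary concentration units; the lower bound must be strictly positive
#'   for any balanced metabolite.
#' @param is_boundary `TRUE` for unbalanced source/sink species exempt from
#'   the steady-state constraint.
#' @return a list of class `mf_metabolite`.
#' @export
metabolite <- function(id, compartment, n_atoms, pool_bounds = c(0.1, 10),
                       is_boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, n_atoms >= 0)
  if (!is_boundary && n_atoms > 0 && pool_bounds[1] <= 0) {
    stop("metabolite '", id, "': pool lower bound must be strictly positive ",
         "for balanced metabolites")
  }
  structure(list(id = id, compartment = compartment,
                 n_atoms = as.integer(n_atoms),
                 pool_bounds = as.numeric(pool_bounds),
                 is_boundary = isTRUE(is_boundary)),
            class = "mf_metabolite")
}

#' Create a reaction record
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (substrates negative, products positive).
#' @param reversible logical; reversible reactions are split internally into
#'   non-negative forward/backward sub-fluxes for EMU balances.
#' @param flux_bounds length-2 numeric `(lower, upper)` in flux units;
#'   irreversible reactions require `lower >= 0`.
#' @param transitions list of atom-transition records as produced by
#'   [parse_transition()]; several equiprobable records encode molecular
#'   symmetry and are averaged in EMU balances.
#' @return a list of class `mf_reaction`.
#' @export
reaction <- function(id, stoich, reversible = FALSE, flux_bounds = c(0, 10),
                     transitions = list()) {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  flux_bounds <- as.numeric(flux_bounds)
  if (flux_bounds[1] > flux_bounds[2]) {
    stop("reaction '", id, "': lower flux bound exceeds upper bound")
  }
  if (!reversible && flux_bounds[1] < 0) {
    stop("reaction '", id, "': irreversible reaction with negative lower bound")
  }
  structure(list(id = id, stoich = stoich, reversible = isTRUE(reversible),
                 flux_bounds = flux_bounds, transitions = transitions),
            class = "mf_reaction")
}

# ---- atom-map dialect ------------------------------------------------------
# One row per transition record:
#   reaction_id <TAB> A[c] (ab) + B[c] (c) -> C[h] (abc)
# Lowercase letters name atoms; a letter present on both sides maps that
# substrate atom to that product atom. Substrate atoms may be dropped
# (export/cleavage to untraced species); every traced product atom must be
# mapped exactly once. The right-hand side may be empty for pure exports.

parse_side <- function(txt) {
  txt <- trimws(txt)
  if (txt == "") return(list())
  terms <- strsplit(txt, "\\s*\\+\\s*")[[1]]
  lapply(terms, function(tm) {
    m <- regmatches(tm, regexec("^\\s*(.+?)\\s*\\(([a-z]*)\\)\\s*$", tm))[[1]]
    if (length(m) == 0) {
      # bare metabolite without atom list: untraced participant
      return(list(met = trimws(tm), atoms = character(0)))
    }
    list(met = m[2], atoms = if (nzchar(m[3])) strsplit(m[3], "")[[1]] else character(0))
  })
}

#' Parse one atom-transition record
#'
#' @param txt a transition string such as `"A[c] (ab) + B[c] (c) -> C[h] (abc)"`.
#' @return a list with `substrates` and `products`, each a list of
#'   `(met, atoms)` occurrences; atoms are lowercase letter labels.
#' @export
parse_transition <- function(txt) {
  parts <- strsplit(txt, "->", fixed = TRUE)[[1]]
  if (length(parts) < 1 || length(parts) > 2) {
    stop("malformed transition: '", txt, "'")
  }
  lhs <- parse_side(parts[1])
  rhs <- if (length(parts) == 2) parse_side(parts[2]) else list()
  rec <- list(substrates = lhs, products = rhs)
  check_transition(rec, txt)
  rec
}

check_transition <- function(rec, txt = "") {
  sub_letters <- unlist(lapply(rec$substrates, `[[`, "atoms"))
  prod_letters <- unlist(lapply(rec$products, `[[`, "atoms"))
  if (anyDuplicated(sub_letters)) {
    stop("transition '", txt, "': substrate atom label used twice: ",
         sub_letters[duplicated(sub_letters)][1])
  }
  if (anyDuplicated(prod_letters)) {
    stop("transition '", txt, "': atom '",
         prod_letters[duplicated(prod_letters)][1],
         "' maps to two product atoms")
  }
  missing <- setdiff(prod_letters, sub_letters)
  if (length(missing)) {
    stop("transition '", txt, "': product atom '", missing[1],
         "' is not mapped from any substrate atom")
  }
  invisible(rec)
}

format_transition <- function(rec) {
  fmt_side <- function(side) {
    paste(vapply(side, function(o) {
      sprintf("%s (%s)", o$met, paste(o$atoms, collapse = ""))
    }, character(1)), collapse = " + ")
  }
  paste(fmt_side(rec$substrates), "->", fmt_side(rec$products))
}

#' Read an atom-map TSV
#'
#' One row per transition record: `reaction_id <TAB> transition`; several rows
#' with the same reaction id encode equiprobable (symmetry) variants.
#'
#' @param path path to the TSV file.
#' @return named list, reaction id -> list of transition records.
#' @export
read_atommap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("atom map row is not 'id<TAB>transition': ", ln)
    rid <- trimws(parts[1])
    out[[rid]] <- c(out[[rid]], list(parse_transition(parts[2])))
  }
  out
}

#' Write an atom-map TSV
#'
#' @param network a [reaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atommap <- function(network, path) {
  rows <- character(0)
  for (rx in network$reactions) {
    for (rec in rx$transitions) {
      rows <- c(rows, paste(rx$id, format_transition(rec), sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

# ---- network ---------------------------------------------------------------

#' Assemble and validate a reaction network
#'
#' Checks referential integrity, per-reaction atom balance (every traced
#' product atom mapped exactly once, atom lists matching declared atom
#' counts), and that the steady-state flux polytope is nonempty.
#'
#' @param metabolites list of [metabolite()] records.
#' @param reactions list of [reaction()] records (order defines column order
#'   of the stoichiometric matrix).
#' @param tracer a [tracer_spec()] describing the labelled nutrient.
#' @return a list of class `reaction_network` with elements `metabolites`
#'   (named list), `reactions` (named list), `tracer`.
#' @export
reaction_network <- function(metabolites, reactions, tracer = NULL) {
  mets <- setNames(metabolites, vapply(metabolites, `[[`, "", "id"))
  rxns <- setNames(reactions, vapply(reactions, `[[`, "", "id"))
  if (anyDuplicated(names(mets))) stop("duplicate metabolite ids")
  if (anyDuplicated(names(rxns))) stop("duplicate reaction ids")
  net <- structure(list(metabolites = mets, reactions = rxns, tracer = tracer),
                   class = "reaction_network")
  validate_network(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  nb <- sum(!vapply(x$metabolites, `[[`, TRUE, "is_boundary"))
  cat(sprintf("<reaction_network> %d metabolites (%d balanced), %d reactions\n",
              length(x$metabolites), nb, length(x$reactions)))
  invisible(x)
}

validate_network <- function(net) {
  for (rx in net$reactions) {
    bad <- setdiff(names(rx$stoich), names(net$metabolites))
    if (length(bad)) {
      stop("reaction '", rx$id, "' references unknown metabolite '", bad[1], "'")
    }
    traced <- names(rx$stoich)[vapply(names(rx$stoich), function(m) {
      net$metabolites[[m]]$n_atoms > 0
    }, logical(1))]
    if (length(traced) && length(rx$transitions) == 0) {
      stop("reaction '", rx$id, "' carries traced metabolites but has no atom map")
    }
    for (rec in rx$transitions) {
      check_transition(rec, rx$id)
      for (occ in c(rec$substrates, rec$products)) {
        met <- net$metabolites[[occ$met]]
        if (is.null(met)) {
          stop("reaction '", rx$id, "': atom map references unknown metabolite '",
               occ$met, "'")
        }
        if (length(occ$atoms) != met$n_atoms) {
          stop("reaction '", rx$id, "': atom balance violation for '", occ$met,
               "': map lists ", length(occ$atoms), " atoms, metabolite declares ",
               met$n_atoms)
        }
      }
    }
  }
  # nonempty polytope (errors if infeasible)
  invisible(free_flux_basis(net))
}

balanced_metabolites <- function(net) {
  ids <- names(net$metabolites)
  ids[!vapply(net$metabolites, `[[`, TRUE, "is_boundary")]
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param network a [reaction_network()].
#' @param directed if `TRUE`, columns are the directed sub-fluxes (reversible
#'   reactions split into forward/backward non-negative columns); if `FALSE`,
#'   columns are net reaction fluxes in declaration order.
#' @return numeric matrix, rows = balanced metabolites, columns = (directed)
#'   reactions; `dimnames` carry the ids.
#' @export
stoichiometric_matrix <- function(network, directed = FALSE) {
  if (directed) return(directed_system(network)$S)
  mets <- balanced_metabolites(network)
  rxns <- names(network$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (rx in network$reactions) {
    keep <- intersect(names(rx$stoich), mets)
    S[keep, rx$id] <- rx$stoich[keep]
  }
  S
}

#' Directed expansion of a network
#'
#' Reversible reactions are split into forward and backward columns with
#' non-negative bounds; net flux = forward - backward. All EMU balances,
#' sampling and estimation operate on this directed system.
#'
#' @param network a [reaction_network()].
#' @return list with `S` (balanced metabolites x directed columns), `cols`
#'   (data.frame: `col`, `rxn`, `dir`, `lb`, `ub`) and `net_map` (matrix
#'   mapping directed fluxes to net reaction fluxes).
#' @export
directed_system <- function(network) {
  mets <- balanced_metabolites(network)
  cols <- list()
  for (rx in network$reactions) {
    if (rx$reversible) {
      cols[[length(cols) + 1L]] <- data.frame(
        col = paste0(rx$id, "_f"), rxn = rx$id, dir = 1,
        lb = 0, ub = max(rx$flux_bounds[2], 0), stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- data.frame(
        col = paste0(rx$id, "_b"), rxn = rx$id, dir = -1,
        lb = 0, ub = max(-rx$flux_bounds[1], 0), stringsAsFactors = FALSE)
    } else {
      cols[[length(cols) + 1L]] <- data.frame(
        col = rx$id, rxn = rx$id, dir = 1,
        lb = rx$flux_bounds[1], ub = rx$flux_bounds[2], stringsAsFactors = FALSE)
    }
  }
  cols <- do.call(rbind, cols)
  S <- matrix(0, length(mets), nrow(cols), dimnames = list(mets, cols$col))
  net_map <- matrix(0, length(network$reactions), nrow(cols),
                    dimnames = list(names(network$reactions), cols$col))
  for (k in seq_len(nrow(cols))) {
    rx <- network$reactions[[cols$rxn[k]]]
    keep <- intersect(names(rx$stoich), mets)
    S[keep, k] <- rx$stoich[keep] * cols$dir[k]
    net_map[rx$id, k] <- cols$dir[k]
  }
  list(S = S, cols = cols, net_map = net_map)
}

#' Net reaction fluxes from a directed flux vector
#'
#' @param network a [reaction_network()].
#' @param v_directed named directed flux vector (order of
#'   `directed_system(network)$cols`).
#' @return named numeric vector of net fluxes over reactions.
#' @export
net_fluxes <- function(network, v_directed) {
  ds <- directed_system(network)
  drop(ds$net_map %*% v_directed[ds$cols$col])
}

null_space <- function(S, tol = 1e-10) {
  if (nrow(S) == 0) return(diag(ncol(S)))
  sv <- svd(S, nu = 0, nv = ncol(S))
  keep <- c(sv$d, rep(0, ncol(S) - length(sv$d))) < tol * max(sv$d[1], 1)
  K <- sv$v[, keep, drop = FALSE]
  rownames(K) <- colnames(S)
  K
}

#' Null-space parameterisation of the steady-state flux polytope
#'
#' Returns an orthonormal basis `K` of the null space of the directed
#' stoichiometric matrix and a strictly feasible interior point `v0`, so that
#' every `v = v0 + K u` satisfies `S v = 0` exactly and the box bounds define
#' a polytope in `u`.
#'
#' @param network a [reaction_network()].
#' @return list with `v0` (feasible directed flux vector), `K` (basis,
#'   `S %*% K = 0`), `lb`, `ub` (directed bounds), `S` and `cols`.
#' @export
free_flux_basis <- function(network) {
  ds <- directed_system(network)
  K <- null_space(ds$S)
  lb <- ds$cols$lb; ub <- ds$cols$ub
  if (ncol(K) == 0) {
    v0 <- rep(0, nrow(ds$cols))
    if (any(v0 < lb - 1e-9 | v0 > ub + 1e-9)) {
      stop("infeasible flux bounds: steady state requires zero flux outside bounds")
    }
  } else {
    v0 <- find_interior_point(K, lb, ub)
  }
  names(v0) <- ds$cols$col
  list(v0 = v0, K = K, lb = lb, ub = ub, S = ds$S, cols = ds$cols,
       net_map = ds$net_map)
}

find_interior_point <- function(K, lb, ub) {
  mid <- (lb + ub) / 2
  u <- drop(crossprod(K, mid))
  pen <- function(u) {
    v <- drop(K %*% u)
    sum(pmax(lb - v, 0)^2 + pmax(v - ub, 0)^2)
  }
  if (pen(u) > 0) {
    u <- optim(u, pen, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
  }
  v <- drop(K %*% u)
  if (any(v < lb - 1e-9 | v > ub + 1e-9)) {
    stop("infeasible flux bounds: the steady-state flux polytope is empty")
  }
  # centre: maximise the minimum relative slack so sampling can start strictly
  # inside the polytope
  rng <- pmax(ub - lb, 1e-12)
  negslack <- function(u) {
    v <- drop(K %*% u)
    -min(pmin(v - lb, ub - v) / rng)
  }
  opt <- suppressWarnings(optim(u, negslack, method = "Nelder-Mead",
                                control = list(maxit = 5000, reltol = 1e-12)))
  if (negslack(opt$par) < negslack(u)) u <- opt$par
  drop(K %*% u)
}

# ---- loading ---------------------------------------------------------------

#' Load a network from SBML + atom map + bounds config
#'
#' Reads stoichiometry, compartments, reversibility and boundary flags from an
#' SBML Level 3 document, atom transitions from the atom-map TSV dialect, and
#' merges flux/pool bounds from a YAML config (config values win over SBML
#' defaults). Every reaction touching traced metabolites must have an atom-map
#' row or be listed under `untraced_reactions` in the config.
#'
#' @param sbml_source path to an SBML L3 file.
#' @param atommap_source path to the atom-map TSV.
#' @param bounds_config path to a YAML config, or an equivalent named list,
#'   with optional sections `flux_bounds` (reaction id -> c(lb, ub)),
#'   `pool_bounds` (metabolite id -> c(lb, ub)), `n_atoms` (metabolite id ->
#'   count), `boundary_metabolites`, `untraced_reactions`, `tracer`
#'   (`metabolite`, `fractions`, `switch_time`), `compartments` (allowed codes).
#' @return a validated [reaction_network()].
#' @export
load_network <- function(sbml_source, atommap_source, bounds_config = list()) {
  cfg <- if (is.character(bounds_config)) yaml::read_yaml(bounds_config) else bounds_config
  sb <- read_sbml_model(sbml_source)
  amap <- read_atommap(atommap_source)

  allowed <- cfg$compartments
  n_atoms_cfg <- cfg$n_atoms %||% list()
  # atom counts: config first, else inferred from the atom map
  inferred <- list()
  for (recs in amap) for (rec in recs) {
    for (occ in c(rec$substrates, rec$products)) {
      inferred[[occ$met]] <- max(inferred[[occ$met]] %||% 0L, length(occ$atoms))
    }
  }
  mets <- lapply(sb$species, function(sp) {
    if (!is.null(allowed) && !(sp$compartment %in% allowed)) {
      stop("unknown compartment '", sp$compartment, "' for species '", sp$id,
           "' (allowed: ", paste(allowed, collapse = ", "), ")")
    }
    pb <- cfg$pool_bounds[[sp$id]] %||% c(0.1, 10)
    na <- n_atoms_cfg[[sp$id]] %||% inferred[[sp$id]] %||% 0L
    boundary <- sp$boundary || sp$id %in% (cfg$boundary_metabolites %||% character(0))
    metabolite(sp$id, sp$compartment, na, as.numeric(pb), boundary)
  })
  met_ids <- vapply(mets, `[[`, "", "id")
  untraced <- cfg$untraced_reactions %||% character(0)
  rxns <- lapply(sb$reactions, function(rx) {
    trans <- amap[[rx$id]]
    traced <- any(vapply(names(rx$stoich), function(m) {
      i <- match(m, met_ids)
      !is.na(i) && mets[[i]]$n_atoms > 0
    }, logical(1)))
    if (is.null(trans)) {
      if (traced && !(rx$id %in% untraced)) {
        stop("reaction '", rx$id, "' carries traced metabolites but has no ",
             "atom-map row and is not declared untraced")
      }
      trans <- list()
    }
    fb <- cfg$flux_bounds[[rx$id]] %||%
      (if (rx$reversible) c(-10, 10) else c(0, 10))
    reaction(rx$id, rx$stoich, rx$reversible, as.numeric(fb), trans)
  })
  tracer <- NULL
  if (!is.null(cfg$tracer)) {
    tracer <- tracer_spec(cfg$tracer$metabolite,
                          fractions = cfg$tracer$fractions %||% 1,
                          switch_time = cfg$tracer$switch_time %||% 0)
  }
  reaction_network(mets, rxns, tracer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
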