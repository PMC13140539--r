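#' @title EMU decomposition
#' @description Backward tracing from measurement-target EMUs to the minimal
#'   size-stratified EMU reaction network whose balances determine their MIDs.
#' @name emu_decomposition
NULL

#' Construct an EMU (elementary metabolic unit)
#'
#' @param met metabolite id.
#' @param atoms 1-based traced-atom positions (any order; stored sorted).
#' @return list of class `emu` with `met`, `atoms`, `size`, `id`.
#' @export
emu <- function(met, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  if (length(atoms) < 1 || any(atoms < 1)) stop("EMU needs >= 1 positive atom index")
  structure(list(met = met, atoms = atoms, size = length(atoms),
                 id = emu_id(met, atoms)), class = "emu")
}

emu_id <- function(met, atoms) paste0(met, ":", paste(atoms, collapse = "."))

parse_emu_id <- function(id) {
  i <- regexpr(":[0-9.]+$", id)
  if (i < 0) stop("malformed EMU id: ", id)
  emu(substr(id, 1, i - 1),
      as.integer(strsplit(substr(id, i + 1, nchar(id)), ".", fixed = TRUE)[[1]]))
}

# orient the transition records of every directed column; backward columns of
# reversible reactions swap substrate and product sides
oriented_records <- function(network) {
  ds <- directed_system(network)
  out <- vector("list", nrow(ds$cols))
  names(out) <- ds$cols$col
  for (k in seq_len(nrow(ds$cols))) {
    rx <- network$reactions[[ds$cols$rxn[k]]]
    recs <- rx$transitions
    if (length(recs) == 0) { out[[k]] <- list(); next }
    w <- 1 / length(recs)
    out[[k]] <- lapply(recs, function(rec) {
      if (ds$cols$dir[k] < 0) rec <- list(substrates = rec$products,
                                          products = rec$substrates)
      rec$weight <- w
      rec
    })
  }
  out
}

#' Decompose a network into the minimal EMU network for given targets
#'
#' Traces backwards from each target EMU through every directed reaction that
#' produces its metabolite, emitting one EMU reaction per transition record
#' and product occurrence (symmetry variants carry weight 1/n records;
#' identical contributions are merged by summing coefficients). EMUs of
#' boundary metabolites are sources with known MIDs; all other traced EMUs
#' become state variables, stratified by size.
#'
#' @param network a [reaction_network()].
#' @param targets list of [emu()] targets (or EMU id strings).
#' @return list of class `emu_network`: `emus` (state EMUs, named, in
#'   lexicographic order), `sources` (source EMUs), `reactions` (list of
#'   `(target, sources, col, coeff)`), `targets`, `network`.
#' @export
decompose <- function(network, targets) {
  targets <- lapply(targets, function(t) if (is.character(t)) parse_emu_id(t) else t)
  for (t in targets) {
    m <- network$metabolites[[t$met]]
    if (is.null(m)) stop("target EMU references unknown metabolite '", t$met, "'")
    if (any(t$atoms > m$n_atoms)) {
      stop("target EMU ", t$id, ": atom index out of range (metabolite has ",
           m$n_atoms, " atoms)")
    }
  }
  orecs <- oriented_records(network)
  # source EMUs (known MIDs) belong to metabolites nothing in the network
  # produces -- external feeds -- or to the tracer itself; boundary *sinks*
  # are traced through to their producers
  produced <- unique(unlist(lapply(orecs, function(recs) {
    unlist(lapply(recs, function(rec) vapply(rec$products, `[[`, "", "met")))
  })))
  is_src <- function(met) {
    (!is.null(network$tracer) && met == network$tracer$metabolite) ||
      !(met %in% produced)
  }

  state <- list(); sources <- list(); reactions <- list()
  seen <- character(0)
  pending <- list()
  for (t in targets) pending[[t$id]] <- t

  while (length(pending)) {
    nxt <- sort(names(pending))[1]
    e <- pending[[nxt]]; pending[[nxt]] <- NULL
    if (e$id %in% seen) next
    seen <- c(seen, e$id)
    if (is_src(e$met)) { sources[[e$id]] <- e; next }
    state[[e$id]] <- e
    for (col in names(orecs)) {
      for (rec in orecs[[col]]) {
        for (occ in rec$products) {
          if (occ$met != e$met) next
          letters <- occ$atoms[e$atoms]
          src_list <- list()
          for (s in rec$substrates) {
            pos <- which(s$atoms %in% letters)
            if (length(pos)) src_list[[length(src_list) + 1L]] <- emu(s$met, pos)
          }
          if (sum(vapply(src_list, `[[`, 0L, "size")) != e$size) {
            stop("internal: unmapped atoms while tracing EMU ", e$id,
                 " through column ", col)
          }
          ord <- order(vapply(src_list, `[[`, "", "id"))
          src_list <- src_list[ord]
          reactions[[length(reactions) + 1L]] <- list(
            target = e$id,
            sources = vapply(src_list, `[[`, "", "id"),
            col = col, coeff = rec$weight)
          for (s in src_list) {
            if (!(s$id %in% seen) && is.null(pending[[s$id]])) pending[[s$id]] <- s
          }
        }
      }
    }
  }

  # merge identical (target, sources, col) contributions
  if (length(reactions)) {
    key <- vapply(reactions, function(r) {
      paste(r$target, paste(r$sources, collapse = "+"), r$col, sep = "|")
    }, character(1))
    merged <- lapply(split(seq_along(reactions), key), function(idx) {
      r <- reactions[[idx[1]]]
      r$coeff <- sum(vapply(reactions[idx], `[[`, 0, "coeff"))
      r
    })
    ord <- order(vapply(merged, `[[`, "", "target"),
                 vapply(merged, `[[`, "", "col"))
    reactions <- unname(merged[ord])
  }
  state <- state[sort(names(state))]
  sources <- sources[sort(names(sources))]
  structure(list(emus = state, sources = sources, reactions = reactions,
                 targets = vapply(targets, `[[`, "", "id"), network = network),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("<emu_network> %d state EMUs, %d source EMUs, %d EMU reactions\n",
              length(x$emus), length(x$sources), length(x$reactions)))
  invisible(x)
}

#' Per-size summary of an EMU network
#'
#' @param emu_network an [decompose()] result.
#' @return data.frame with `size`, `n_emus`, `n_sources`, `n_reactions`.
#' @export
emu_count_report <- function(emu_network) {
  sizes <- sort(unique(c(
    vapply(emu_network$emus, `[[`, 0L, "size"),
    vapply(emu_network$sources, `[[`, 0L, "size"))))
  esize <- vapply(emu_network$emus, `[[`, 0L, "size")
  ssize <- vapply(emu_network$sources, `[[`, 0L, "size")
  rsize <- vapply(emu_network$reactions, function(r) {
    emu_network_size(emu_network, r$target)
  }, 0L)
  data.frame(size = sizes,
             n_emus = vapply(sizes, function(s) sum(esize == s), 0L),
             n_sources = vapply(sizes, function(s) sum(ssize == s), 0L),
             n_reactions = vapply(sizes, function(s) sum(rsize == s), 0L))
}

emu_network_size <- function(en, id) {
  e <- en$emus[[id]] %||% en$sources[[id]]
  if (is.null(e)) stop("unknown EMU id: ", id)
  e$size
}

#' Write an EMU network as TSV (one EMU reaction per row)
#'
#' @param emu_network a decomposed EMU network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emu_network <- function(emu_network, path) {
  rows <- vapply(emu_network$reactions, function(r) {
    paste(r$target, paste(r$sources, collapse = ","), r$col,
          format(r$coeff, digits = 15), sep = "\t")
  }, character(1))
  writeLines(c("# target\tsources\tflux_col\tcoeff", rows), path)
  invisible(path)
}

#' Read an EMU network TSV written by [write_emu_network()]
#'
#' @param path input path.
#' @param network the originating [reaction_network()] (supplies boundary
#'   flags and pools).
#' @param targets the target EMU ids.
#' @return an `emu_network` equivalent to the dumped one.
#' @export
read_emu_network <- function(path, network, targets) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  reactions <- lapply(lines, function(ln) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    list(target = p[1], sources = strsplit(p[2], ",", fixed = TRUE)[[1]],
         col = p[3], coeff = as.numeric(p[4]))
  })
  ids <- unique(c(vapply(reactions, `[[`, "", "target"),
                  unlist(lapply(reactions, `[[`, "sources")), targets))
  is_state <- ids %in% vapply(reactions, `[[`, "", "target")
  state <- list(); sources <- list()
  for (i in order(ids)) {
    e <- parse_emu_id(ids[i])
    if (is_state[i]) state[[ids[i]]] <- e else sources[[ids[i]]] <- e
  }
  structure(list(emus = state, sources = sources, reactions = reactions,
                 targets = targets, network = network), class = "emu_network")
}
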