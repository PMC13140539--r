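#' @title Neural-network surrogates of the MID forward model
#' @description One small fully connected regressor per (EMU, time point)
#'   mapping the concatenated (directed flux, pool size) vector to that EMU's
#'   MID, replacing the ODE solver inside estimation. The exact simulator and
#'   a trained ensemble expose the same prediction contract, so either can be
#'   plugged into [fit_fluxes()].
#' @name surrogates
NULL

cell_key <- function(emu_id, time) sprintf("%s@%.10g", emu_id, time)

#' Surrogate specification
#'
#' @param hidden_sizes hidden-layer widths; default `c(216, 36, 6)`.
#' @param activation hidden activation (only `"relu"` is implemented).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param validation_fraction held-out fraction used for `holdout_sd`.
#' @param seed integer; fixes initialisation and minibatch order.
#' @param log_conc standardise log pool sizes rather than raw values.
#' @return list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(hidden_sizes = c(216, 36, 6), activation = "relu",
                           epochs = 200, batch_size = 32, learning_rate = 1e-3,
                           validation_fraction = 0.2, seed = 1L,
                           log_conc = TRUE) {
  stopifnot(all(hidden_sizes > 0), identical(activation, "relu"),
            validation_fraction > 0, validation_fraction < 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes), activation = activation,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), log_conc = isTRUE(log_conc)),
            class = "surrogate_spec")
}

standardise <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1  # zero-variance left untouched
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"), center = center,
       scale = scale)
}

destandardise <- function(X, center, scale) {
  sweep(sweep(X, 2, scale, "*"), 2, center, "+")
}

raw_inputs <- function(flux_mat, conc_mat, log_conc) {
  if (log_conc) conc_mat <- log(conc_mat)
  cbind(flux_mat, conc_mat)
}

#' Simulate the training set for a surrogate ensemble
#'
#' Runs the exact forward model for every (flux, concentration) sample and
#' collects the MIDs of all target EMUs at the requested time points.
#'
#' @param emu_network a [decompose()] result.
#' @param flux_samples list from [sample_flux_space()].
#' @param conc_samples list from [sample_concentrations()] (same length).
#' @param timepoints simulation output times.
#' @param solver_opts passed to [simulate_mids()].
#' @return list with `flux_mat` (n x directed columns), `conc_mat` (n x
#'   balanced metabolites), `mids` (named list cell key -> n x (size+1)
#'   matrix), `cells` (data.frame `emu_id`, `time`, `size`).
#' @export
simulate_training_set <- function(emu_network, flux_samples, conc_samples,
                                  timepoints, solver_opts = list()) {
  stopifnot(length(flux_samples) == length(conc_samples),
            length(flux_samples) >= 1)
  emu_ids <- emu_network$targets
  sizes <- vapply(emu_ids, function(id) emu_network_size(emu_network, id), 0L)
  cells <- expand.grid(emu_id = emu_ids, time = timepoints,
                       stringsAsFactors = FALSE)
  cells$size <- sizes[cells$emu_id]
  n <- length(flux_samples)
  mids <- setNames(lapply(seq_len(nrow(cells)), function(i) {
    matrix(NA_real_, n, cells$size[i] + 1L)
  }), cell_key(cells$emu_id, cells$time))
  flux_mat <- do.call(rbind, lapply(flux_samples, `[[`, "v"))
  conc_mat <- do.call(rbind, conc_samples)
  for (s in seq_len(n)) {
    tj <- simulate_mids(emu_network, flux_samples[[s]], conc_samples[[s]],
                        timepoints, solver_opts = solver_opts)
    for (i in seq_len(nrow(cells))) {
      mids[[i]][s, ] <- get_mid(tj, cells$emu_id[i], cells$time[i])
    }
  }
  list(flux_mat = flux_mat, conc_mat = conc_mat, mids = mids, cells = cells)
}

#' Build the standardised training table for one (EMU, time point) cell
#'
#' @param training_set result of [simulate_training_set()].
#' @param emu_id target EMU id.
#' @param timepoint time point.
#' @param spec a [surrogate_spec()] (controls log-concentration inputs).
#' @return list with standardised `inputs` and `targets`, standardisation
#'   parameters, the transformed-input bounding box (`x_min`, `x_max`) used
#'   for out-of-domain flagging, and `input_ids`.
#' @export
build_training_table <- function(training_set, emu_id, timepoint,
                                 spec = surrogate_spec()) {
  key <- cell_key(emu_id, timepoint)
  Y <- training_set$mids[[key]]
  if (is.null(Y)) stop("no simulated MIDs for cell ", key)
  Xraw <- raw_inputs(training_set$flux_mat, training_set$conc_mat, spec$log_conc)
  sx <- standardise(Xraw)
  sy <- standardise(Y)
  list(inputs = sx$X, targets = sy$X,
       x_center = sx$center, x_scale = sx$scale,
       y_center = sy$center, y_scale = sy$scale,
       x_min = apply(Xraw, 2, min), x_max = apply(Xraw, 2, max),
       input_ids = colnames(Xraw),
       emu_id = emu_id, timepoint = timepoint)
}

#' Train one surrogate
#'
#' @param spec a [surrogate_spec()].
#' @param table a [build_training_table()] result.
#' @return list of class `trained_surrogate` carrying weights, the
#'   standardisation parameters, and `holdout_sd`: the standard deviation of
#'   (predicted - simulated) MID components on the held-out fraction.
#' @export
train_surrogate <- function(spec, table) {
  n <- nrow(table$inputs)
  if (n < 10) stop("need >= 10 training rows, got ", n)
  set.seed(spec$seed)
  perm <- sample.int(n)
  n_hold <- max(1L, floor(spec$validation_fraction * n))
  hold <- perm[seq_len(n_hold)]
  train <- perm[-seq_len(n_hold)]

  res <- .mlp_train(table$inputs[train, , drop = FALSE],
                    table$targets[train, , drop = FALSE],
                    spec$hidden_sizes, spec$epochs, spec$batch_size,
                    spec$learning_rate, spec$seed)
  pred_h <- .mlp_predict(res, table$inputs[hold, , drop = FALSE])
  err <- destandardise(pred_h, table$y_center, table$y_scale) -
    destandardise(table$targets[hold, , drop = FALSE], table$y_center, table$y_scale)
  structure(list(spec = spec, weights = res[c("W", "b")],
                 emu_id = table$emu_id, timepoint = table$timepoint,
                 holdout_sd = sd(as.numeric(err)),
                 loss_init = res$loss_init, loss_final = res$loss_final,
                 x_center = table$x_center, x_scale = table$x_scale,
                 y_center = table$y_center, y_scale = table$y_scale,
                 x_min = table$x_min, x_max = table$x_max,
                 input_ids = table$input_ids,
                 holdout_rows = sort(hold)),
            class = "trained_surrogate")
}

#' Train a full surrogate ensemble
#'
#' One model per (target EMU, time point); the per-cell seed is derived from
#' `spec$seed` so the ensemble is reproducible as a whole.
#'
#' @param training_set result of [simulate_training_set()].
#' @param spec a [surrogate_spec()].
#' @param verbose print one line per trained cell.
#' @return list of class `surrogate_ensemble`.
#' @export
train_ensemble <- function(training_set, spec = surrogate_spec(),
                           verbose = FALSE) {
  cells <- training_set$cells
  models <- list()
  for (i in seq_len(nrow(cells))) {
    cspec <- spec
    cspec$seed <- spec$seed + i
    tab <- build_training_table(training_set, cells$emu_id[i], cells$time[i],
                                cspec)
    key <- cell_key(cells$emu_id[i], cells$time[i])
    models[[key]] <- train_surrogate(cspec, tab)
    if (verbose) {
      message(sprintf("trained %s: holdout sd %.2e", key,
                      models[[key]]$holdout_sd))
    }
  }
  structure(list(models = models, cells = cells,
                 input_ids = models[[1]]$input_ids,
                 log_conc = spec$log_conc,
                 provenance = list(
                   seed = spec$seed, n_samples = nrow(training_set$flux_mat),
                   train_keys = training_row_keys(training_set))),
            class = "surrogate_ensemble")
}

training_row_keys <- function(training_set) {
  apply(round(cbind(training_set$flux_mat, training_set$conc_mat), 10), 1,
        paste, collapse = ",")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d models over %d EMUs x %d time points\n",
              length(x$models), length(unique(x$cells$emu_id)),
              length(unique(x$cells$time))))
  invisible(x)
}

#' Predict MIDs for all (EMU, time point) cells of a predictor
#'
#' Generic shared by [train_ensemble()] ensembles and the exact-simulator
#' predictor from [simulator_predictor()], making the simulator a supported
#' drop-in for the ensemble inside [fit_fluxes()].
#'
#' @param predictor a `surrogate_ensemble` or `simulator_predictor`.
#' @param flux directed flux vector or flux sample.
#' @param conc named pool-size vector.
#' @param ... passed to methods.
#' @return named list, cell key (`emu@time`) -> MID vector on the simplex;
#'   attribute `out_of_domain` is `TRUE` when inputs leave the training box.
#' @export
predict_mids <- function(predictor, flux, conc, ...) UseMethod("predict_mids")

#' @rdname predict_mids
#' @export
predict_mids.surrogate_ensemble <- function(predictor, flux, conc, ...) {
  if (inherits(flux, "flux_sample")) flux <- flux$v
  n_flux <- length(predictor$input_ids) - length(conc)
  x_flux <- flux[predictor$input_ids[seq_len(n_flux)]]
  x_conc <- conc[predictor$input_ids[-seq_len(n_flux)]]
  if (anyNA(x_flux) || anyNA(x_conc)) {
    stop("flux/concentration names do not align with ensemble input ids")
  }
  if (predictor$log_conc) x_conc <- log(x_conc)
  x <- c(x_flux, x_conc)
  ood <- FALSE
  out <- list()
  for (key in names(predictor$models)) {
    m <- predictor$models[[key]]
    if (any(x < m$x_min - 1e-9) || any(x > m$x_max + 1e-9)) ood <- TRUE
    xs <- (x - m$x_center) / m$x_scale
    pred <- .mlp_predict(m$weights, matrix(xs, nrow = 1))
    out[[key]] <- clip_renorm(drop(destandardise(pred, m$y_center, m$y_scale)))
  }
  attr(out, "out_of_domain") <- ood
  out
}

#' Exact-simulator predictor
#'
#' Wraps [simulate_mids()] behind the [predict_mids()] contract.
#'
#' @param emu_network a [decompose()] result.
#' @param timepoints prediction time points.
#' @param solver_opts passed to [simulate_mids()].
#' @return list of class `simulator_predictor`.
#' @export
simulator_predictor <- function(emu_network, timepoints, solver_opts = list()) {
  structure(list(emu_network = emu_network, timepoints = sort(timepoints),
                 solver_opts = solver_opts),
            class = "simulator_predictor")
}

#' @rdname predict_mids
#' @export
predict_mids.simulator_predictor <- function(predictor, flux, conc, ...) {
  tj <- simulate_mids(predictor$emu_network, flux, conc, predictor$timepoints,
                      solver_opts = predictor$solver_opts)
  out <- list()
  for (id in predictor$emu_network$targets) {
    for (tp in predictor$timepoints) {
      out[[cell_key(id, tp)]] <- get_mid(tj, id, tp)
    }
  }
  attr(out, "out_of_domain") <- FALSE
  out
}

#' Validate an ensemble on held-out samples
#'
#' @param ensemble a trained `surrogate_ensemble`.
#' @param heldout_set a [simulate_training_set()] result disjoint from the
#'   training samples (checked by row fingerprints; overlap is an error).
#' @return data.frame of class `ensemble_validation` with one row per
#'   (EMU, time point) cell: `emu_id`, `time`, `sd`; attribute `median_sd`.
#' @export
validate_ensemble <- function(ensemble, heldout_set) {
  keys <- training_row_keys(heldout_set)
  if (any(keys %in% ensemble$provenance$train_keys)) {
    stop("held-out set overlaps the training samples")
  }
  n <- nrow(heldout_set$flux_mat)
  cells <- ensemble$cells
  sds <- numeric(nrow(cells))
  errs <- lapply(seq_len(nrow(cells)), function(i) {
    matrix(NA_real_, n, cells$size[i] + 1L)
  })
  for (s in seq_len(n)) {
    pred <- predict_mids(ensemble, heldout_set$flux_mat[s, ],
                         heldout_set$conc_mat[s, ])
    for (i in seq_len(nrow(cells))) {
      key <- cell_key(cells$emu_id[i], cells$time[i])
      errs[[i]][s, ] <- pred[[key]] - heldout_set$mids[[key]][s, ]
    }
  }
  for (i in seq_len(nrow(cells))) sds[i] <- sd(as.numeric(errs[[i]]))
  out <- data.frame(emu_id = cells$emu_id, time = cells$time, sd = sds)
  attr(out, "median_sd") <- stats::median(sds)
  class(out) <- c("ensemble_validation", "data.frame")
  out
}

#' Save / load a surrogate ensemble
#'
#' Ensembles are serialised with R's native format; all weights, specs and
#' provenance travel in one archive.
#'
#' @param ensemble a `surrogate_ensemble`.
#' @param path archive path.
#' @return `path` (save) or the ensemble (load).
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) readRDS(path)
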