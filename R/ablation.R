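#' Cumulative decay-ordered neuron ablation
#'
#' Probes the functional importance of the two operation modes by cumulatively
#' removing hidden neurons of a binned-uniform model in order of their decay
#' time: `"ascending"` deletes coincidence detectors (low decay times) first,
#' forcing the network to rely on integrators; `"descending"` deletes
#' integrators first. Ablation masks the neurons' outputs (their spike counts
#' are zeroed before the readout — equivalent to zeroing their readout rows);
#' there is no retraining, so the decay-time effect is not confounded. The
#' evaluation split is encoded once with a fixed seed, so the only difference
#' between curve steps is the ablation mask.
#'
#' @param model a `trained_model` with a binned-uniform decay scheme (ordering
#'   is undefined for constant decay times).
#' @param dataset the evaluation `image_dataset`.
#' @param order `"ascending"` or `"descending"` decay time.
#' @param seed Poisson-encoding seed, shared across all ablation steps.
#' @param granularity `"bin"` (default: one bin of neurons per step) or
#'   `"neuron"`.
#' @return an object of class `ablation_curve`: data.frame with
#'   `n_ablated_groups`, `n_neurons_ablated`, `accuracy`, `macro_f1`, `auc`;
#'   row 1 is the un-ablated baseline and the final row has every hidden
#'   neuron ablated.
#' @export
ablate_cumulative <- function(model, dataset, order = c("ascending", "descending"),
                              seed = 1L, granularity = c("bin", "neuron")) {
  order <- match.arg(order)
  granularity <- match.arg(granularity)
  .assert(inherits(model, "trained_model"), "model must be a trained_model")
  td <- model$params$t_decay
  .assert(length(unique(td)) > 1,
          "ablation order is undefined for a constant-decay model")
  batch <- poisson_encode(dataset, n_steps = model$params$n_steps,
                          seed = seed, dt = model$params$dt)
  counts <- .hidden_counts(batch, model$params)
  groups <- if (granularity == "bin") {
    vals <- sort(unique(td), decreasing = (order == "descending"))
    lapply(vals, function(v) which(td == v))
  } else {
    ord <- order(td, decreasing = (order == "descending"))
    as.list(ord)
  }
  mask <- rep(1, length(td))
  rows <- vector("list", length(groups) + 1L)
  eval_masked <- function(mask) {
    sc <- readout(counts * matrix(mask, nrow(counts), length(mask), byrow = TRUE),
                  model$w_out, n_steps = model$params$n_steps)$scores
    classification_metrics(sc, dataset$labels)
  }
  m0 <- eval_masked(mask)
  rows[[1]] <- data.frame(n_ablated_groups = 0L, n_neurons_ablated = 0L,
                          accuracy = m0$accuracy, macro_f1 = m0$macro_f1,
                          auc = m0$auc)
  for (g in seq_along(groups)) {
    mask[groups[[g]]] <- 0
    m <- eval_masked(mask)
    rows[[g + 1L]] <- data.frame(n_ablated_groups = g,
                                 n_neurons_ablated = sum(mask == 0),
                                 accuracy = m$accuracy, macro_f1 = m$macro_f1,
                                 auc = m$auc)
  }
  out <- do.call(rbind, rows)
  attr(out, "order") <- order
  attr(out, "granularity") <- granularity
  class(out) <- c("ablation_curve", "data.frame")
  out
}

#' Mean ascending-minus-descending accuracy gap
#'
#' The gap statistic of an ablation pair: the mean over curve steps of
#' `accuracy(ascending) - accuracy(descending)`. Positive values mean that
#' deleting integrators first hurts more, i.e. integrators carry more of the
#' classification performance.
#'
#' @param asc,desc ablation curves from [ablate_cumulative()] for the same
#'   model and seed.
#' @return the mean gap (a number).
#' @export
ablation_gap <- function(asc, desc) {
  .assert(nrow(asc) == nrow(desc), "curves must have the same number of steps")
  .assert(isTRUE(all.equal(asc$accuracy[1], desc$accuracy[1])) &&
            isTRUE(all.equal(asc$accuracy[nrow(asc)], desc$accuracy[nrow(desc)])),
          "curves must share the un-ablated and fully-ablated endpoints")
  mean(asc$accuracy - desc$accuracy)
}

#' Ablation gap across image brightness levels
#'
#' Runs the full pipeline — generate, train, ablate in both orders — for each
#' dataset spec (differing in target mean brightness) and reports the
#' ascending/descending accuracy gap per brightness. Lower brightness means
#' sparser Poisson spike trains, fewer coincidences, and hence a larger
#' advantage of integrator neurons (a larger gap).
#'
#' @param dataset_specs list of [dataset_spec()]s (at least 2, typically
#'   differing only in `target_mean_brightness`).
#' @param config a [train_config()].
#' @param scheme a [decay_scheme()] (binned uniform).
#' @param eval_fraction fraction of each dataset held out for
#'   ablation evaluation (default 0.2, stratified).
#' @return object of class `brightness_sweep`: data.frame with `brightness`,
#'   `gap`, `baseline_accuracy`; curves attached as attribute `"curves"`.
#' @export
ablation_brightness_sweep <- function(dataset_specs, config,
                                      scheme = decay_scheme("binned_uniform"),
                                      eval_fraction = 0.2) {
  .assert(is.list(dataset_specs) && length(dataset_specs) >= 2,
          "need at least 2 dataset specs (brightness levels)")
  .assert(all(vapply(dataset_specs, inherits, logical(1), "dataset_spec")),
          "dataset_specs must be dataset_spec objects")
  rows <- vector("list", length(dataset_specs))
  curves <- vector("list", length(dataset_specs))
  for (i in seq_along(dataset_specs)) {
    spec <- dataset_specs[[i]]
    ds <- make_dataset(spec)
    k <- max(2L, as.integer(round(1 / eval_fraction)))
    fold <- stratified_folds(ds$labels, k, seed = derive_seed(config$seed, "split"))
    tr <- .subset_dataset(ds, fold != 1L)
    te <- .subset_dataset(ds, fold == 1L)
    model <- train_snn(tr, config, scheme)
    eseed <- derive_seed(config$seed, "ablate_eval")
    asc <- ablate_cumulative(model, te, "ascending", seed = eseed)
    desc <- ablate_cumulative(model, te, "descending", seed = eseed)
    rows[[i]] <- data.frame(brightness = spec$target_mean_brightness,
                            gap = ablation_gap(asc, desc),
                            baseline_accuracy = asc$accuracy[1])
    curves[[i]] <- list(ascending = asc, descending = desc)
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  class(out) <- c("brightness_sweep", "data.frame")
  out
}
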