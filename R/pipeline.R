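# End-to-end orchestration: per-fold CSP fitting, SBS with an inner-CV RBF
# network evaluator, outer cross-validation, m-sweep and ablation drivers.

#' Configuration for a cross-validated decoding run
#'
#' @param seed RNG seed (mandatory); drives fold assignment and any other
#'   randomness, making runs deterministic end to end.
#' @param bands band-grid parameters `list(lo, hi, width, step)` in Hz
#'   (default the 17-band 4-40 Hz bank).
#' @param windows window-grid parameters `list(lo, hi, length, step)` in ms
#'   (default the five 2-s windows over 500-4500 ms).
#' @param preprocess broadband prefilter `list(low_hz, high_hz, order)`
#'   applied before the per-band filter bank; `NULL` to skip.
#' @param filter_order Butterworth design order of the per-band filters.
#' @param m CSP components retained per tail (default 2).
#' @param spread RBF width hyperparameter (default 16).
#' @param sigma_mode `"literal"` or `"matlab"`, see [fit_rbfnn()].
#' @param folds outer cross-validation fold count (default 5).
#' @param inner_folds folds of the inner evaluator CV inside each outer
#'   training partition (default 5).
#' @param min_size stop size for the backward elimination (default 1).
#' @param protocol `"nested"` (default; selection sees training trials only)
#'   or `"flat"` (selection scored on the outer folds themselves, the
#'   best trajectory accuracy reported - optimistic, kept for comparison).
#' @param order_mode per-cell composition order, see [decompose_epochs()].
#' @return An object of class `run_config` with all parameters echoed.
#' @export
run_config <- function(seed,
                       bands = list(lo = 4, hi = 40, width = 4, step = 2),
                       windows = list(lo = 500, hi = 4500, length = 2000,
                                      step = 500),
                       preprocess = list(low_hz = 4, high_hz = 40, order = 5),
                       filter_order = 5,
                       m = 2, spread = 16,
                       sigma_mode = c("literal", "matlab"),
                       folds = 5, inner_folds = 5, min_size = 1,
                       protocol = c("nested", "flat"),
                       order_mode = c("filter_first", "window_first")) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    tfb_stop("a single numeric seed is mandatory", "tfbcsp_invalid_parameter")
  }
  if (m < 1) tfb_stop("m must be >= 1", "tfbcsp_invalid_parameter")
  if (folds < 2) tfb_stop("folds must be >= 2", "tfbcsp_invalid_parameter")
  structure(
    list(seed = as.integer(seed), bands = bands, windows = windows,
         preprocess = preprocess, filter_order = filter_order, m = m,
         spread = spread, sigma_mode = match.arg(sigma_mode),
         folds = folds, inner_folds = inner_folds, min_size = min_size,
         protocol = match.arg(protocol), order_mode = match.arg(order_mode)),
    class = "run_config"
  )
}

#' Build the temporal-spectral grid of a configuration
#'
#' @param config a [run_config()].
#' @return A [tf_grid()].
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tf_grid(
    make_band_grid(config$bands$lo, config$bands$hi, config$bands$width,
                   config$bands$step),
    make_window_grid(config$windows$lo, config$windows$hi,
                     config$windows$length, config$windows$step)
  )
}

# Preprocess + decompose according to the configuration.
prepare_cells <- function(epochs, config) {
  if (!is.null(config$preprocess)) {
    epochs <- bandpass_filter(epochs, config$preprocess$low_hz,
                              config$preprocess$high_hz,
                              config$preprocess$order %||% 5)
  }
  decompose_epochs(epochs, build_grid(config), order = config$filter_order,
                   order_mode = config$order_mode)
}

# Fit per-cell CSP models on the given training trials and return the
# log-variance feature matrix of *all* trials for each cell. `note_fit`
# records which trial indices entered a fitting routine.
fold_features <- function(cells, train_idx, m, note_fit) {
  lapply(cells, function(ce) {
    note_fit(train_idx)
    model <- fit_csp(subset_trials(ce, train_idx), m = m)
    csp_transform(model, ce)
  })
}

#' Cross-validated decoding run
#'
#' For each outer fold (stratified by class), CSP spatial filters are fitted
#' per grid cell on the training trials only; Sequential Backward Selection
#' over the cells is driven by the mean inner-CV accuracy of an RBF network
#' trained on the training partition; the network is then refitted on the
#' full training partition restricted to the selected cells and evaluated
#' once on the held-out fold. A bookkeeping audit of every fitting call
#' verifies that held-out trials never entered any fitting routine
#' (`leakage$ok`).
#'
#' Under `protocol = "flat"` selection is instead scored directly on
#' the outer folds (train on each fold's training part, test on its held-out
#' part, averaged) and the best accuracy along the whole elimination
#' trajectory is reported - the flat, optimistic reading.
#'
#' @param epochs an [epoch_set()] with both classes.
#' @param config a [run_config()].
#' @param .folds optional precomputed fold assignment (integer per trial),
#'   used by [sweep_m()]/[run_ablation()] to share folds across runs.
#' @return An object of class `cv_result`: `fold_accuracy`, `mean_accuracy`,
#'   `sd_accuracy`, `fold_reports` (per-fold [report()]s), `fold_traces`
#'   (per-fold `sbs_trace`), `selection_freq` (how often each cell entered a
#'   best subset), `folds`, `leakage`, `config`.
#' @export
run_cv <- function(epochs, config, .folds = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(config, "run_config"))
  labels <- epochs$labels
  cells <- prepare_cells(epochs, config)
  grid <- attr(cells, "grid")
  fold <- .folds %||% stratified_folds(labels, config$folds, config$seed)
  if (config$protocol == "flat") {
    return(run_cv_flat(cells, grid, labels, fold, config))
  }
  nf <- max(fold)
  fold_acc <- numeric(nf)
  fold_reports <- vector("list", nf)
  fold_traces <- vector("list", nf)
  leak <- vector("list", nf)
  for (f in seq_len(nf)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (length(unique(labels[train_idx])) < 2L ||
        length(unique(labels[test_idx])) < 2L) {
      tfb_stop("a fold lacks one of the classes", "tfbcsp_stratification_error")
    }
    fitted_ids <- integer(0)
    note_fit <- function(idx) fitted_ids <<- union(fitted_ids, idx)
    feats <- fold_features(cells, train_idx, config$m, note_fit)
    inner <- stratified_folds(labels[train_idx], config$inner_folds,
                              config$seed + 7919L * f)
    evaluator <- function(subset) {
      X <- do.call(cbind, feats[subset])
      acc <- numeric(max(inner))
      for (j in seq_len(max(inner))) {
        tr <- train_idx[inner != j]
        va <- train_idx[inner == j]
        note_fit(tr)
        net <- fit_rbfnn(X[tr, , drop = FALSE], labels[tr],
                         spread = config$spread, sigma_mode = config$sigma_mode)
        acc[j] <- mean(predict(net, X[va, , drop = FALSE]) == labels[va])
      }
      mean(acc)
    }
    trace <- run_sbs(seq_len(nrow(grid)), evaluator, min_size = config$min_size)
    Xbest <- do.call(cbind, feats[trace$best_subset])
    note_fit(train_idx)
    net <- fit_rbfnn(Xbest[train_idx, , drop = FALSE], labels[train_idx],
                     spread = config$spread, sigma_mode = config$sigma_mode)
    pred <- predict(net, Xbest[test_idx, , drop = FALSE])
    fold_acc[f] <- mean(pred == labels[test_idx])
    fold_reports[[f]] <- report(confusion(labels[test_idx], pred))
    fold_traces[[f]] <- trace
    leak[[f]] <- list(fitted = sort(fitted_ids), test = test_idx,
                      ok = length(intersect(fitted_ids, test_idx)) == 0L)
  }
  finish_cv(fold_acc, fold_reports, fold_traces, fold, grid, config,
            leakage_ok = all(vapply(leak, `[[`, logical(1), "ok")),
            leak = leak)
}

# Flat (non-nested) protocol: SBS scored on the outer folds themselves.
run_cv_flat <- function(cells, grid, labels, fold, config) {
  nf <- max(fold)
  feats_by_fold <- vector("list", nf)
  for (f in seq_len(nf)) {
    train_idx <- which(fold != f)
    feats_by_fold[[f]] <- fold_features(cells, train_idx, config$m,
                                        function(idx) invisible(idx))
  }
  fold_acc_for <- function(subset) {
    vapply(seq_len(nf), function(f) {
      X <- do.call(cbind, feats_by_fold[[f]][subset])
      tr <- which(fold != f); te <- which(fold == f)
      net <- fit_rbfnn(X[tr, , drop = FALSE], labels[tr],
                       spread = config$spread, sigma_mode = config$sigma_mode)
      mean(predict(net, X[te, , drop = FALSE]) == labels[te])
    }, numeric(1))
  }
  trace <- run_sbs(seq_len(nrow(grid)),
                   function(subset) mean(fold_acc_for(subset)),
                   min_size = config$min_size)
  fold_acc <- fold_acc_for(trace$best_subset)
  fold_reports <- lapply(seq_len(nf), function(f) {
    X <- do.call(cbind, feats_by_fold[[f]][trace$best_subset])
    tr <- which(fold != f); te <- which(fold == f)
    net <- fit_rbfnn(X[tr, , drop = FALSE], labels[tr],
                     spread = config$spread, sigma_mode = config$sigma_mode)
    report(confusion(labels[te], predict(net, X[te, , drop = FALSE])))
  })
  finish_cv(fold_acc, fold_reports, rep(list(trace), nf), fold, grid, config,
            leakage_ok = FALSE, leak = NULL)  # selection saw the test folds
}

finish_cv <- function(fold_acc, fold_reports, fold_traces, fold, grid,
                      config, leakage_ok, leak) {
  freq <- integer(nrow(grid))
  for (tr in fold_traces) freq[tr$best_subset] <- freq[tr$best_subset] + 1L
  structure(
    list(fold_accuracy = fold_acc,
         mean_accuracy = mean(fold_acc),
         sd_accuracy = stats::sd(fold_acc),
         fold_reports = fold_reports,
         fold_traces = fold_traces,
         selection_freq = data.frame(grid, times_selected = freq),
         folds = fold,
         leakage = list(ok = leakage_ok, detail = leak),
         config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: accuracy %.4f +/- %.4f (%s protocol)\n",
              length(x$fold_accuracy), x$mean_accuracy, x$sd_accuracy,
              x$config$protocol))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Sweep the CSP tail size m
#'
#' Runs [run_cv()] for every requested `m` on one shared outer-fold
#' assignment, so the per-m accuracies are paired.
#'
#' @param epochs an [epoch_set()].
#' @param config a [run_config()]; its `m` is overridden per row.
#' @param m_values integer vector of tail sizes.
#' @return data.frame with one row per m (`m`, `mean_accuracy`,
#'   `sd_accuracy`); the across-m standard deviation of the means is
#'   attached as attribute `"across_m_sd"` and the full `cv_result`s as
#'   attribute `"results"`.
#' @export
sweep_m <- function(epochs, config, m_values) {
  stopifnot(inherits(config, "run_config"))
  fold <- stratified_folds(epochs$labels, config$folds, config$seed)
  results <- lapply(m_values, function(mm) {
    cfg <- config
    cfg$m <- mm
    run_cv(epochs, cfg, .folds = fold)
  })
  tab <- data.frame(
    m = m_values,
    mean_accuracy = vapply(results, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(results, `[[`, numeric(1), "sd_accuracy")
  )
  attr(tab, "across_m_sd") <- stats::sd(tab$mean_accuracy)
  attr(tab, "results") <- results
  tab
}

#' Canonical ablation grids
#'
#' The three reduced temporal-spectral grids used to probe which input axis
#' carries the performance: fewer bands (12 x 5 = 60 cells), fewer windows
#' (17 x 3 = 51), or both (12 x 3 = 36), against the full 17 x 5 = 85 grid.
#'
#' @return Named list of `list(bands, windows)` parameter sets.
#' @export
ablation_variants <- function() {
  list(
    ablation1 = list(bands = list(lo = 4, hi = 30, width = 4, step = 2),
                     windows = list(lo = 500, hi = 4500, length = 2000,
                                    step = 500)),
    ablation2 = list(bands = list(lo = 4, hi = 40, width = 4, step = 2),
                     windows = list(lo = 500, hi = 3500, length = 2000,
                                    step = 500)),
    ablation3 = list(bands = list(lo = 4, hi = 30, width = 4, step = 2),
                     windows = list(lo = 500, hi = 3500, length = 2000,
                                    step = 500))
  )
}

#' Ablation driver: rerun the pipeline on reduced grids
#'
#' Runs [run_cv()] for the full configuration and every named variant with
#' identical folds and seed, reporting accuracy deltas against the full
#' grid.
#'
#' @param epochs an [epoch_set()].
#' @param variants named list of `list(bands, windows)` parameter sets, e.g.
#'   [ablation_variants()].
#' @param config a [run_config()] defining the full grid and all shared
#'   parameters.
#' @return data.frame with rows `full` + variants: `variant`, `n_cells`,
#'   `mean_accuracy`, `sd_accuracy`, `delta_vs_full`; full `cv_result`s in
#'   attribute `"results"`.
#' @export
run_ablation <- function(epochs, variants, config) {
  stopifnot(inherits(config, "run_config"))
  fold <- stratified_folds(epochs$labels, config$folds, config$seed)
  configs <- c(list(full = list(bands = config$bands,
                                windows = config$windows)), variants)
  results <- lapply(configs, function(v) {
    cfg <- config
    cfg$bands <- v$bands
    cfg$windows <- v$windows
    run_cv(epochs, cfg, .folds = fold)
  })
  acc <- vapply(results, `[[`, numeric(1), "mean_accuracy")
  tab <- data.frame(
    variant = names(configs),
    n_cells = vapply(results, function(r) nrow(r$selection_freq), integer(1)),
    mean_accuracy = acc,
    sd_accuracy = vapply(results, `[[`, numeric(1), "sd_accuracy"),
    delta_vs_full = acc - acc[[1]],
    row.names = NULL
  )
  attr(tab, "results") <- results
  tab
}
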