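# Common Spatial Patterns: trace-normalized covariances, whitening,
# joint diagonalization of the two class covariances, and normalized
# log-variance features of the extremal components.

#' Trace-normalized trial covariance
#'
#' `C = X X' / trace(X X')`, so every trial contributes a unit-trace,
#' symmetric positive semidefinite covariance regardless of its amplitude.
#'
#' @param trial channels x samples numeric matrix.
#' @return channels x channels covariance matrix with unit trace.
#' @examples
#' x <- matrix(rnorm(2 * 100), 2)
#' sum(diag(normalized_covariance(x)))  # 1
#' @export
normalized_covariance <- function(trial) {
  if (!is.matrix(trial) || !is.numeric(trial)) {
    tfb_stop("trial must be a numeric matrix", "tfbcsp_invalid_data")
  }
  cc <- tcrossprod(trial)
  tr <- sum(diag(cc))
  if (tr <= 0) tfb_stop("all-zero trial has no covariance", "tfbcsp_degenerate_trial")
  cc / tr
}

# Core decomposition shared by fit_csp and the property tests: takes the two
# class-mean covariances directly. Whitens the composite covariance
# (eigenvalue scaling by lambda^{-1/2}), then eigendecomposes the whitened
# first-class covariance; both whitened class matrices share those
# eigenvectors, with eigenvalues summing to 1 componentwise.
#' CSP decomposition from class covariance matrices
#'
#' @param C1,C2 class-mean covariance matrices (symmetric, same size). `C1`
#'   is the class whose variance the leading components maximize.
#' @param m components retained per tail of the eigenvalue spectrum.
#' @param ridge_threshold condition-number threshold above which the
#'   composite covariance is ridge-regularized (with a warning).
#' @param ridge_eps ridge magnitude as a fraction of mean diagonal energy.
#' @return A `csp_model`; see [fit_csp()].
#' @export
csp_from_covariances <- function(C1, C2, m = 1, ridge_threshold = 1e10,
                                 ridge_eps = 1e-8) {
  nch <- nrow(C1)
  stopifnot(is.matrix(C1), is.matrix(C2), all(dim(C1) == dim(C2)), nch == ncol(C1))
  if (m < 1 || m != round(m)) {
    tfb_stop("m must be a positive integer", "tfbcsp_invalid_parameter")
  }
  if (m > nch) {
    tfb_stop("m cannot exceed the channel count", "tfbcsp_invalid_parameter")
  }
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= 0 || max(ec$values) / min(ec$values) > ridge_threshold) {
    warning("composite covariance is ill-conditioned; applying ridge regularization")
    Cc <- Cc + diag(ridge_eps * sum(diag(Cc)) / nch, nch)
    ec <- eigen(Cc, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(ec$values), nch) %*% t(ec$vectors)
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  es <- eigen(S1, symmetric = TRUE)  # eigenvalues in decreasing order
  W <- t(es$vectors) %*% P
  # sign convention: largest-magnitude entry of each row positive
  for (r in seq_len(nch)) {
    if (W[r, which.max(abs(W[r, ]))] < 0) W[r, ] <- -W[r, ]
  }
  sel <- c(seq_len(m), seq(nch - m + 1, nch))
  structure(
    list(W = W, m = m,
         selected_rows = sel,
         lambda_left = es$values,
         lambda_right = 1 - es$values,
         diagnostics = list(C_bar = list(C1, C2), C_c = C1 + C2,
                            U_C = ec$vectors, lambda_C = ec$values, P = P,
                            S = list(S1, diag(nch) - S1), B = es$vectors)),
    class = "csp_model"
  )
}

#' Fit Common Spatial Patterns on one grid cell
#'
#' Averages trace-normalized trial covariances per class, whitens their sum,
#' and jointly diagonalizes the class covariances. Rows of the projection
#' matrix `W` are ordered by decreasing variance ratio for the first class
#' (sorted label order); the retained components are the first and last `m`
#' rows. When `2m` exceeds the channel count the literal first/last-row rule
#' is kept, so middle rows are duplicated; `dedupe_components = TRUE` drops
#' the duplicates instead.
#'
#' @param cell_epochs an [epoch_set()] carrying one grid cell's segments;
#'   both classes must be present with at least 2 trials each.
#' @param m components retained per tail (default 1).
#' @param dedupe_components drop duplicated row indices when `2m > channels`.
#' @param ... passed to [csp_from_covariances()].
#' @return A `csp_model` with fields `W` (components x channels), `m`,
#'   `selected_rows`, `lambda_left`/`lambda_right` (complementary eigenvalue
#'   spectra), `classes`, and whitening/eigen `diagnostics`.
#' @export
fit_csp <- function(cell_epochs, m = 1, dedupe_components = FALSE, ...) {
  stopifnot(inherits(cell_epochs, "epoch_set"))
  classes <- sort(unique(cell_epochs$labels))
  if (length(classes) != 2L) {
    tfb_stop("CSP requires exactly two classes in the training trials",
             "tfbcsp_invalid_labels")
  }
  counts <- table(factor(cell_epochs$labels, levels = classes))
  if (any(counts < 2L)) {
    tfb_stop("each class needs at least 2 trials", "tfbcsp_invalid_labels")
  }
  mean_cov <- function(cl) {
    idx <- which(cell_epochs$labels == cl)
    acc <- 0
    for (i in idx) acc <- acc + normalized_covariance(trial_matrix(cell_epochs, i))
    acc / length(idx)
  }
  model <- csp_from_covariances(mean_cov(classes[1]), mean_cov(classes[2]),
                                m = m, ...)
  if (dedupe_components) model$selected_rows <- unique(model$selected_rows)
  model$classes <- classes
  model$channel_names <- cell_epochs$channel_names
  model
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, m = %d (%d features/trial)\n",
              ncol(x$W), x$m, length(x$selected_rows)))
  cat("  lambda_left:", paste(sprintf("%.3f", x$lambda_left), collapse = " "), "\n")
  invisible(x)
}

#' Normalized log-variance features of the retained CSP components
#'
#' Projects a trial through the retained rows of `W` and returns
#' `f_p = log(var(Z_p) / sum_i var(Z_i))`, the sum running over the retained
#' components only. Variances use the population denominator without mean
#' removal (band-passed signals are zero-mean to numerical precision), so
#' the features are invariant to global amplitude scaling, all are <= 0, and
#' their exponentials sum to 1.
#'
#' @param model a `csp_model`.
#' @param trial channels x samples matrix with the model's channel count.
#' @return Numeric feature vector of length `length(model$selected_rows)`.
#' @export
logvar_features <- function(model, trial) {
  stopifnot(inherits(model, "csp_model"))
  if (!is.matrix(trial) || nrow(trial) != ncol(model$W)) {
    tfb_stop("trial channel count does not match the fitted model",
             "tfbcsp_contract_error")
  }
  Z <- model$W[model$selected_rows, , drop = FALSE] %*% trial
  v <- rowSums(Z^2) / ncol(Z)
  if (any(v <= 0)) {
    tfb_stop("zero-variance projected component", "tfbcsp_degenerate_trial")
  }
  log(v / sum(v))
}

#' Extract log-variance features for every trial of an epoch set
#'
#' @param model a `csp_model` fitted on the same cell.
#' @param epochs an [epoch_set()] whose channel count matches the model.
#' @return trials x n_features numeric matrix.
#' @export
csp_transform <- function(model, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- matrix(NA_real_, n_trials(epochs), length(model$selected_rows))
  for (i in seq_len(n_trials(epochs))) {
    out[i, ] <- logvar_features(model, trial_matrix(epochs, i))
  }
  colnames(out) <- paste0("csp", seq_len(ncol(out)))
  out
}
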