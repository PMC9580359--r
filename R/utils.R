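# Internal helpers: classed conditions, seeded evaluation, least squares,
# stratified fold assignment.

# Classed error so callers can distinguish failure modes programmatically.
# `class` is one of the tfbcsp_* condition classes used throughout.
tfb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "tfbcsp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Minimum-norm least-squares solution of A x = y. Fast path: for a
# full-row-rank wide system the minimum-norm solution is A' (A A')^{-1} y;
# fall back to an SVD pseudoinverse (LAPACK default rank tolerance) when the
# Gram system is singular or leaves a visible residual (rank deficiency from
# duplicate rows, or a numerically flat kernel design).
lstsq_minnorm <- function(A, y) {
  co <- tryCatch(drop(crossprod(A, solve(tcrossprod(A), y))),
                 error = function(e) NULL)
  if (!is.null(co) && max(abs(A %*% co - y)) < 1e-4) return(co)
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * s$d[1]
  keep <- s$d > tol
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep]))
}

# Stratified fold assignment: within each class, trials are shuffled and
# dealt round-robin so every fold carries both classes; the round-robin
# start is rotated across classes so the leftover trials of each class land
# on different folds and total fold sizes stay within one of each other.
# Returns an integer vector of fold ids (1..k) aligned with `labels`.
stratified_folds <- function(labels, k, seed) {
  if (k < 2) tfb_stop("fold count must be at least 2", "tfbcsp_invalid_parameter")
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < k)) {
    tfb_stop(sprintf(
      "cannot stratify: class '%s' has %d trials but %d folds requested",
      names(counts)[which.min(counts)], min(counts), k
    ), "tfbcsp_stratification_error")
  }
  fold <- integer(length(labels))
  shift <- 0L
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((rep_len(seq_len(k), length(idx)) + shift - 1L) %% k) + 1L
      shift <- (shift + length(idx)) %% k
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
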