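# Exhaustive Sequential Backward Selection over feature cells, driven by a
# caller-supplied subset-accuracy evaluator.

#' Sequential Backward Selection over feature cells
#'
#' Starting from the full cell set, every elimination round evaluates all
#' leave-one-out candidate subsets of the active set and discards the cell
#' whose removal yields the highest remaining-subset accuracy (the cell
#' contributing least). The trajectory down to `min_size` cells is recorded
#' in full, and the best subset is the argmax over every subset evaluated,
#' including the initial full set.
#'
#' `eval_count` counts evaluator invocations: the initial full-set anchor
#' plus every leave-one-out candidate, i.e. `F(F+1)/2` for a full run from
#' `F` cells down to one (3,655 from an 85-cell grid). Subset evaluations
#' are memoized within a run; the evaluator must therefore be deterministic
#' for a given subset (seed any internal randomness before calling).
#'
#' @param cells vector of cell identifiers (integer or character), unique.
#' @param evaluator `function(cell_subset) -> accuracy in [0, 1]`.
#' @param min_size stop when the active set reaches this size (default 1).
#' @return An object of class `sbs_trace`: `steps` (one entry per
#'   elimination round with the active set, named candidate accuracies, the
#'   discarded cell and the round's best accuracy), `best_subset`,
#'   `best_accuracy`, `initial_accuracy`, `eval_count`.
#' @examples
#' merit <- c(a = 0.9, b = 0.2, c = 0.7)
#' tr <- run_sbs(names(merit), function(s) mean(merit[s]))
#' tr$best_subset  # "a"
#' @export
run_sbs <- function(cells, evaluator, min_size = 1) {
  if (length(cells) < 1L) tfb_stop("need at least one cell", "tfbcsp_invalid_parameter")
  if (anyDuplicated(cells)) tfb_stop("cells must be unique", "tfbcsp_invalid_parameter")
  if (min_size < 1 || min_size > length(cells)) {
    tfb_stop("min_size must lie in [1, |cells|]", "tfbcsp_invalid_parameter")
  }
  memo <- new.env(parent = emptyenv())
  n_evals <- 0L
  eval_subset <- function(subset) {
    key <- paste(subset, collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    acc <- evaluator(subset)
    if (!is.numeric(acc) || length(acc) != 1L || !is.finite(acc) ||
        acc < 0 || acc > 1) {
      tfb_stop("evaluator must return a single accuracy in [0, 1]",
               "tfbcsp_contract_error")
    }
    n_evals <<- n_evals + 1L
    memo[[key]] <- acc
    acc
  }
  best_acc <- eval_subset(cells)
  best_subset <- cells
  initial_acc <- best_acc
  active <- cells
  steps <- list()
  while (length(active) > min_size) {
    cand <- vapply(seq_along(active),
                   function(i) eval_subset(active[-i]), numeric(1))
    names(cand) <- as.character(active)
    top <- which(cand >= max(cand) - 0)  # exact ties
    # tie-break: discard the cell appearing earliest in the original ordering
    drop_i <- top[which.min(match(active[top], cells))]
    discarded <- active[drop_i]
    remaining <- active[-drop_i]
    step_best <- cand[[drop_i]]
    if (step_best > best_acc) {
      best_acc <- step_best
      best_subset <- remaining
    }
    steps[[length(steps) + 1L]] <- list(
      active = active, candidate_accuracy = cand,
      discarded = discarded, step_best_accuracy = step_best
    )
    active <- remaining
  }
  structure(
    list(steps = steps, best_subset = best_subset, best_accuracy = best_acc,
         initial_accuracy = initial_acc, eval_count = n_evals,
         cells = cells, min_size = min_size),
    class = "sbs_trace"
  )
}

#' Tabular report of an elimination trajectory
#'
#' @param x an `sbs_trace`.
#' @param ... unused.
#' @return data.frame with one row per elimination round: `step`,
#'   `n_active` (before removal), `discarded`, `accuracy` (the accuracy of
#'   the remaining subset). Row 0 carries the initial full-set evaluation.
#' @export
as.data.frame.sbs_trace <- function(x, ...) {
  rows <- data.frame(step = 0L, n_active = length(x$cells),
                     discarded = NA_character_, accuracy = x$initial_accuracy,
                     stringsAsFactors = FALSE)
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    rows <- rbind(rows, data.frame(
      step = i, n_active = length(s$active),
      discarded = as.character(s$discarded),
      accuracy = s$step_best_accuracy, stringsAsFactors = FALSE
    ))
  }
  rows
}

#' @export
print.sbs_trace <- function(x, ...) {
  cat(sprintf("<sbs_trace> %d -> %d cells, %d evaluations\n",
              length(x$cells), length(x$cells) - length(x$steps),
              x$eval_count))
  cat(sprintf("  best accuracy %.4f with %d cells: %s\n", x$best_accuracy,
              length(x$best_subset),
              paste(x$best_subset, collapse = ", ")))
  invisible(x)
}
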