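#' Labeled EEG epoch container
#'
#' Bundles a trials x channels x samples array of epoched EEG with per-trial
#' class labels, the sampling rate, channel names and the time of the first
#' sample relative to trial onset. All downstream stages (filtering,
#' windowing, CSP, cross-validation) operate on this container.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param labels per-trial class labels; at most two distinct values.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names optional character vector of channel identifiers;
#'   defaults to `ch01`, `ch02`, ...
#' @param t0 time of the first sample relative to trial onset, in ms.
#'
#' @return An object of class `epoch_set` with fields `data`, `labels`
#'   (character), `fs`, `channel_names`, `t0`.
#' @examples
#' x <- array(rnorm(4 * 3 * 100), dim = c(4, 3, 100))
#' ep <- epoch_set(x, labels = c("L", "L", "R", "R"), fs = 100)
#' ep
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    tfb_stop("data must be a 3-d array (trials x channels x samples)",
             "tfbcsp_invalid_data")
  }
  if (!is.numeric(data)) tfb_stop("data must be numeric", "tfbcsp_invalid_data")
  d <- dim(data)
  if (any(d < 1L)) tfb_stop("all array extents must be >= 1", "tfbcsp_invalid_data")
  if (length(labels) != d[1]) {
    tfb_stop("labels length must equal the number of trials", "tfbcsp_invalid_data")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) > 2L) {
    tfb_stop("labels must take at most 2 distinct values", "tfbcsp_invalid_labels")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    tfb_stop("fs must be a positive number", "tfbcsp_invalid_parameter")
  }
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(d[2]))
  if (length(channel_names) != d[2]) {
    tfb_stop("channel_names length must equal the number of channels",
             "tfbcsp_invalid_data")
  }
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names), t0 = as.numeric(t0)),
    class = "epoch_set"
  )
}

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

# End of the epoch (ms, exclusive) in trial-relative time.
epoch_end_ms <- function(x) x$t0 + n_samples(x) / x$fs * 1000

# channels x samples matrix for one trial
trial_matrix <- function(x, i) {
  m <- x$data[i, , , drop = FALSE]
  dim(m) <- dim(x$data)[2:3]
  m
}

#' Subset an epoch set by trial index
#'
#' @param epochs an [epoch_set()].
#' @param idx integer vector of trial indices.
#' @return An `epoch_set` with the selected trials, labels aligned.
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (any(idx < 1L) || any(idx > n_trials(epochs))) {
    tfb_stop("trial index out of range", "tfbcsp_out_of_range")
  }
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$fs, epochs$channel_names, epochs$t0)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              n_trials(x), n_channels(x), n_samples(x), x$fs))
  cat(sprintf("  window: [%g, %g) ms; labels: %s\n", x$t0, epoch_end_ms(x),
              paste(sprintf("%s (%d)", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read the plain on-disk epoch container
#'
#' The container is two plain-text files sharing a path prefix:
#' `<prefix>_data.csv` holds a headerless numeric matrix with
#' `trials * channels` rows and `samples` columns, rows ordered trial-major
#' (trial 1 channel 1, trial 1 channel 2, ..., trial 2 channel 1, ...);
#' `<prefix>_meta.json` holds `fs`, `labels`, `channel_names`, `t0`,
#' `n_trials` and `n_channels`.
#'
#' @param epochs an [epoch_set()].
#' @param prefix path prefix for the two files.
#' @return `write_epoch_container` returns the prefix invisibly;
#'   `read_epoch_container` returns the reconstructed `epoch_set`.
#' @export
write_epoch_container <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_trials(epochs); nc <- n_channels(epochs); ns <- n_samples(epochs)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = ns)  # samples x (ch*trial)
  flat <- t(flat)  # rows: trial-major (trial slow, channel fast)
  data.table::fwrite(data.table::as.data.table(flat),
                     paste0(prefix, "_data.csv"), col.names = FALSE)
  meta <- list(fs = epochs$fs, labels = epochs$labels,
               channel_names = epochs$channel_names, t0 = epochs$t0,
               n_trials = nt, n_channels = nc, n_samples = ns)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epoch_container
#' @export
read_epoch_container <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(paste0(prefix, "_data.csv"),
                                      header = FALSE))
  dimnames(flat) <- NULL
  nt <- meta$n_trials; nc <- meta$n_channels; ns <- meta$n_samples
  if (nrow(flat) != nt * nc || ncol(flat) != ns) {
    tfb_stop("container data shape does not match its metadata",
             "tfbcsp_invalid_data")
  }
  arr <- aperm(array(t(flat), dim = c(ns, nc, nt)), c(3, 2, 1))
  epoch_set(arr, meta$labels, meta$fs, meta$channel_names, meta$t0)
}
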