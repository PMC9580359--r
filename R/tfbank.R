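# Temporal-spectral grid: overlapping frequency bands crossed with
# overlapping time windows, and the per-cell decomposition of an epoch set.

grid_axis <- function(lo, hi, size, step, what) {
  if (!(lo < hi)) tfb_stop(sprintf("%s range empty", what), "tfbcsp_invalid_grid")
  if (!(size > 0 && size <= hi - lo)) {
    tfb_stop(sprintf("%s size must lie in (0, range]", what), "tfbcsp_invalid_grid")
  }
  if (step <= 0) tfb_stop(sprintf("%s step must be positive", what),
                          "tfbcsp_invalid_grid")
  k <- (hi - lo - size) / step
  if (abs(k - round(k)) > 1e-8) {
    tfb_stop(sprintf(
      "%s grid does not tile the range: (%g - %g - %g) not divisible by %g",
      what, hi, lo, size, step), "tfbcsp_invalid_grid")
  }
  starts <- lo + step * (0:round(k))
  cbind(starts, starts + size)
}

#' Build an overlapping frequency-band grid
#'
#' Bands of width `width` Hz start at `f_lo` and advance by `step` Hz; the
#' last band ends exactly at `f_hi`. The default analysis bank (4-40 Hz,
#' 4 Hz bands, 2 Hz step) yields 17 overlapping bands.
#'
#' @param f_lo,f_hi frequency range in Hz.
#' @param width band width in Hz.
#' @param step band start increment in Hz; `(f_hi - f_lo - width)` must be
#'   divisible by `step`.
#' @return data.frame with columns `low_hz`, `high_hz`, one row per band.
#' @examples
#' nrow(make_band_grid(4, 40, 4, 2))  # 17
#' nrow(make_band_grid(4, 30, 4, 2))  # 12
#' @export
make_band_grid <- function(f_lo, f_hi, width, step) {
  ax <- grid_axis(f_lo, f_hi, width, step, "band")
  data.frame(low_hz = ax[, 1], high_hz = ax[, 2])
}

#' Build an overlapping time-window grid
#'
#' Windows of `length` ms start at `t_lo` and advance by `step` ms; the last
#' window ends exactly at `t_hi`. The default analysis layout (500-4500 ms,
#' 2-s windows, 500 ms step) yields 5 overlapping windows.
#'
#' @param t_lo,t_hi window range in ms (trial-relative).
#' @param length window length in ms.
#' @param step window start increment in ms; `(t_hi - t_lo - length)` must
#'   be divisible by `step`.
#' @return data.frame with columns `t_start`, `t_end`, one row per window.
#' @examples
#' nrow(make_window_grid(500, 4500, 2000, 500))  # 5
#' @export
make_window_grid <- function(t_lo, t_hi, length, step) {
  ax <- grid_axis(t_lo, t_hi, length, step, "window")
  data.frame(t_start = ax[, 1], t_end = ax[, 2])
}

#' Cross bands and windows into a temporal-spectral feature grid
#'
#' Cell ordering is band-major and deterministic:
#' `cell = (band_index - 1) * n_windows + window_index`.
#'
#' @param bands data.frame from [make_band_grid()].
#' @param windows data.frame from [make_window_grid()].
#' @return data.frame of class `tf_grid` with columns `cell`, `band`,
#'   `window`, `low_hz`, `high_hz`, `t_start`, `t_end`.
#' @examples
#' g <- tf_grid(make_band_grid(4, 40, 4, 2), make_window_grid(500, 4500, 2000, 500))
#' nrow(g)  # 85
#' @export
tf_grid <- function(bands, windows) {
  nb <- nrow(bands); nw <- nrow(windows)
  g <- data.frame(
    cell = seq_len(nb * nw),
    band = rep(seq_len(nb), each = nw),
    window = rep(seq_len(nw), times = nb),
    low_hz = rep(bands$low_hz, each = nw),
    high_hz = rep(bands$high_hz, each = nw),
    t_start = rep(windows$t_start, times = nb),
    t_end = rep(windows$t_end, times = nb)
  )
  class(g) <- c("tf_grid", "data.frame")
  g
}

#' Decompose epochs into per-cell band-limited, time-windowed segments
#'
#' For every grid cell, the epochs are bandpass filtered to the cell's band
#' and cropped to its window, producing one `epoch_set` per cell with trial
#' count and labels preserved. By default each band filter is applied to the
#' full epoch before any window is cropped (`filter_first`), so all windows
#' of a band share one transient-free filtered signal; `window_first`
#' reverses the composition.
#'
#' @param epochs an [epoch_set()] (typically already broadband-filtered).
#' @param grid a [tf_grid()].
#' @param order Butterworth design order for the per-band filters.
#' @param order_mode `"filter_first"` (default) or `"window_first"`.
#' @return Named list of `epoch_set`, one per cell in grid order, with the
#'   grid attached as attribute `"grid"`.
#' @export
decompose_epochs <- function(epochs, grid, order = 5,
                             order_mode = c("filter_first", "window_first")) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "tf_grid"))
  order_mode <- match.arg(order_mode)
  cells <- vector("list", nrow(grid))
  cell_op <- function(expr, i) {
    tryCatch(expr, tfbcsp_error = function(e) {
      tfb_stop(sprintf("cell %d (band %g-%g Hz, window %g-%g ms): %s",
                       grid$cell[i], grid$low_hz[i], grid$high_hz[i],
                       grid$t_start[i], grid$t_end[i], conditionMessage(e)),
               class(e)[1])
    })
  }
  if (order_mode == "filter_first") {
    for (b in unique(grid$band)) {
      rows <- which(grid$band == b)
      i0 <- rows[1]
      filtered <- cell_op(
        bandpass_filter(epochs, grid$low_hz[i0], grid$high_hz[i0], order), i0)
      for (i in rows) {
        cells[[i]] <- cell_op(crop_window(filtered, grid$t_start[i],
                                          grid$t_end[i]), i)
      }
    }
  } else {
    for (i in seq_len(nrow(grid))) {
      cells[[i]] <- cell_op({
        cropped <- crop_window(epochs, grid$t_start[i], grid$t_end[i])
        bandpass_filter(cropped, grid$low_hz[i], grid$high_hz[i], order)
      }, i)
    }
  }
  names(cells) <- sprintf("b%g-%g_t%g-%g", grid$low_hz, grid$high_hz,
                          grid$t_start, grid$t_end)
  attr(cells, "grid") <- grid
  cells
}
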