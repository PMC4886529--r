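# Mean squared displacement of 1D (arc-length) positions and the
# run/rest classification of inter-change-point segments.
#
# A directionally persistent run moves ballistically (MSD ~ t^2) while a
# rest is localized, diffusive motion (MSD ~ t). Segments are classified by
# the slope of log MSD vs log lag.

#' Time-averaged mean squared displacement
#'
#' MSD(lag) averaged over all frame pairs of the segment, on 1D arc-length
#' positions. The log-log slope `alpha` is fitted by least squares over all
#' positive lags up to the maximum lag; the maximum lag is a fraction of
#' the segment length but never below 6 frames (so that even the shortest
#' classifiable segments contribute enough support points) and never above
#' 30 frames (time-averaged MSD estimates from a single segment degrade
#' well below the segment length, flattening the apparent slope) (positional noise of the nucleus adds a constant floor to every
#' lag, which lowers run and rest slopes alike and is tolerated by the
#' midpoint threshold).
#'
#' @param x numeric vector of 1D positions (um), e.g. [arc_distance()], at
#'   uniform spacing.
#' @param dt frame interval in hours.
#' @param max_lag_fraction maximum lag as a fraction of the segment length
#'   (default 1/4).
#' @return A list of class `msd_curve`: `lag` (hours, starting at 0), `msd`
#'   (um^2, `msd[1] = 0`), `alpha` (log-log slope; `NA` for degenerate
#'   segments).
#' @export
msd <- function(x, dt, max_lag_fraction = 0.25) {
  x <- as.numeric(x)
  m <- length(x)
  if (m < 4) stopf("MSD needs at least 4 frames, got %d", m)
  max_lag <- min(m - 1L, max(6L, min(floor(m * max_lag_fraction), 30L)))
  lags <- seq_len(max_lag)
  ms <- vapply(lags, function(l) mean((x[(1 + l):m] - x[1:(m - l)])^2), 0)
  fit_l <- lags[ms > 0]
  alpha <- if (length(fit_l) >= 2) {
    unname(stats::coef(stats::lm(log(ms[fit_l]) ~ log(fit_l * dt)))[2])
  } else NA_real_
  structure(list(lag = c(0, lags * dt), msd = c(0, ms), alpha = alpha),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags up to %.2f h, log-log slope alpha = %.3f\n",
              length(x$lag) - 1L, max(x$lag), x$alpha))
  invisible(x)
}

#' Classify a segment as run or rest from its MSD slope
#'
#' @param x 1D arc positions of the segment (um).
#' @param dt frame interval (hours).
#' @param config a [seg_config()]; uses `alpha_threshold` (default 1.5, the
#'   midpoint between diffusive slope 1 and ballistic slope 2) and
#'   `max_lag_fraction`.
#' @return `"run"`, `"rest"`, or `NA` when the segment is too short (< 4
#'   frames) to support an MSD fit; such segments are merged into a
#'   neighbour by [segment_track()].
#' @export
classify_segment <- function(x, dt, config = seg_config()) {
  if (length(x) < 4) return(NA_character_)
  a <- msd(x, dt, config$max_lag_fraction)$alpha
  if (!is.finite(a)) return(NA_character_)
  if (a >= config$alpha_threshold) "run" else "rest"
}
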