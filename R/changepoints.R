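# Iterative CUSUM change-point detection on the tangential-velocity series.
#
# The detector locates time points at which the fundamental trend (the
# mean) of the velocity changes, by recursive segmentation. On each
# (sub)series the cumulative sum of deviations from the segment mean,
# S_k = sum_{i<=k}(v_i - vbar), is computed and a candidate change is
# accepted when its CUSUM statistic is significant against the permutation
# distribution of the same statistic; accepted changes recurse into the
# resulting parts until nothing further is found or segments reach the
# minimum length.
#
# Two statistics are available (see src/cusum_scan.cpp): the default
# standardized pair statistic max |S_j - S_i| / sqrt(w(1 - w/n)) tests
# every window against its complement and so retains power for short
# states embedded in long ones (a brief rest inside a long run); the
# classic CUSUM range max S - min S with an argmax |S_k| split is kept as
# an option.

#' Segmentation configuration
#'
#' @param min_segment_length minimum number of velocity samples per segment
#'   (3 samples = 30 min at the standard 10-min frame interval).
#' @param cp_alpha significance level of the permutation test for each
#'   candidate change point.
#' @param n_boot number of permutations per candidate.
#' @param stat CUSUM statistic: `"pair"` (standardized window-vs-complement
#'   scan, default) or `"range"` (max S - min S with a single argmax
#'   split).
#' @param confirm logical; additionally require a Welch t-test between the
#'   candidate window and its complement at level `confirm_alpha`.
#'   Permutation false alarms on trendless series show no mean contrast
#'   between window and complement, so even a weak contrast screen
#'   multiplies the per-series false-alarm rate well below `cp_alpha`
#'   while leaving genuine shifts untouched.
#' @param confirm_alpha level of the confirmation t-test (default 0.25;
#'   deliberately loose, see `confirm`).
#' @param alpha_threshold MSD log-log slope separating diffusive rest
#'   (slope ~ 1) from ballistic run (slope ~ 2) segments.
#' @param short_classify_frames segments spanning fewer frames than this
#'   are classified by state-velocity contrast instead of the (unstable)
#'   short-window MSD slope, see [segment_track()].
#' @param short_velocity_factor fraction of the track's run-speed
#'   reference above which a short segment counts as a run (0.65 roughly
#'   equalizes the two misclassification risks at the assay's noise
#'   level).
#' @param max_lag_fraction fraction of the segment length used as maximum
#'   MSD lag.
#' @param censor_window hours: states starting within `censor_window` of
#'   the track end are flagged censored (excluded from survival
#'   estimation).
#' @param smooth_window odd integer; moving-average window applied to the
#'   series before the CUSUM scan, inside the permutation test (each
#'   permutation is smoothed identically, so the test stays exact under
#'   exchangeability of the raw samples). 1 (default) disables; smoothing
#'   trades short-state sensitivity for noise suppression and is only
#'   useful for data much noisier than the standard assay. The
#'   confirmation t-test and the boundary refinement always use the raw
#'   samples.
#' @param rest_jump_um displacement (um) within a sub-window of a rest
#'   segment above which the excursion is treated as a swallowed run and
#'   split out, whatever the permutation test said: rest motion is
#'   spatially confined, so large jumps are physically inconsistent with
#'   the state. `Inf` disables.
#' @param refine_window half-width (samples) of the local least-squares
#'   boundary refinement after detection, see [refine_boundaries()]; 0
#'   disables.
#' @param seed integer seed for the permutation bootstrap.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(min_segment_length = 3, cp_alpha = 0.05,
                       n_boot = 1000, stat = c("pair", "range"),
                       confirm = TRUE, confirm_alpha = 0.25,
                       alpha_threshold = 1.5, short_classify_frames = 8,
                       short_velocity_factor = 0.65,
                       max_lag_fraction = 0.25, censor_window = 20,
                       smooth_window = 1, rest_jump_um = 25,
                       refine_window = 3, seed = 0) {
  stopifnot(min_segment_length >= 2, cp_alpha > 0, cp_alpha < 1, n_boot >= 1)
  stat <- match.arg(stat)
  structure(list(min_segment_length = as.integer(min_segment_length),
                 cp_alpha = cp_alpha, n_boot = as.integer(n_boot),
                 stat = stat, confirm = isTRUE(confirm),
                 confirm_alpha = confirm_alpha,
                 alpha_threshold = alpha_threshold,
                 short_classify_frames = as.integer(short_classify_frames),
                 short_velocity_factor = short_velocity_factor,
                 max_lag_fraction = max_lag_fraction,
                 censor_window = censor_window,
                 smooth_window = smooth_window, rest_jump_um = rest_jump_um,
                 refine_window = as.integer(refine_window), seed = seed),
            class = "seg_config")
}

#' Detect change points in a velocity series
#'
#' A change point at index `k` means a new state segment starts at sample
#' `k + 1`. Significance of each candidate is the permutation p-value of
#' its CUSUM statistic, `p = (1 + #exceedances) / (n_boot + 1)`, accepted
#' when `p <= cp_alpha` (the permutation loop is curtailed as soon as the
#' decision is certain).
#'
#' @param v a `velocity_series` (see [tangential_velocity()]) or a plain
#'   numeric vector.
#' @param config a [seg_config()].
#' @return A list of class `change_points`: `indices` (sorted),
#'   `significance` (1 - permutation p-value per accepted change), `n`
#'   (series length).
#' @export
detect_change_points <- function(v, config = seg_config()) {
  x <- if (inherits(v, "velocity_series")) v$v else as.numeric(v)
  smooth_w <- as.integer(config$smooth_window %||% 1L)
  n <- length(x)
  min_len <- config$min_segment_length
  empty <- structure(list(indices = integer(0), significance = numeric(0),
                          n = n), class = "change_points")
  if (n < 2 * min_len) {
    warnf("series of length %d is too short to segment (need >= %d)",
          n, 2 * min_len)
    return(empty)
  }
  max_exceed <- max(1L, floor(config$cp_alpha * (config$n_boot + 1)))
  cps <- list()
  with_seed(config$seed, {
    recurse <- function(lo, hi) {
      m <- hi - lo + 1L
      if (m < 2 * min_len) return()
      seg <- x[lo:hi]
      sc <- .cusum_scan(seg, min_len, config$stat, smooth_w)
      if (sc$j < 0 || sc$stat <= 0) return()
      pm <- .cusum_perm(seg, min_len, config$stat, config$n_boot, sc$stat,
                        max_exceed, smooth_w)
      if (pm$exceed >= max_exceed) return()   # curtailed: not significant
      pval <- (1 + pm$exceed) / (config$n_boot + 1)
      if (pval > config$cp_alpha) return()
      i <- sc$i; j <- sc$j                    # window (i, j], 0-based bounds
      if (config$confirm) {
        inside <- seg[(i + 1):j]
        outside <- seg[-((i + 1):j)]
        tp <- tryCatch(stats::t.test(inside, outside)$p.value,
                       # zero-variance groups: means differ, change is real
                       error = function(e) 0)
        if (is.finite(tp) && tp > config$confirm_alpha) return()
      }
      sig <- 1 - pval
      for (b in c(if (i > 0) i, if (j < m) j))
        cps[[length(cps) + 1L]] <<- c(lo + b - 1L, sig)
      if (i > 0) recurse(lo, lo + i - 1L)
      recurse(lo + i, lo + j - 1L)
      if (j < m) recurse(lo + j, hi)
    }
    recurse(1L, n)
  })
  if (!length(cps)) return(empty)
  m <- do.call(rbind, cps)
  o <- order(m[, 1])
  structure(list(indices = as.integer(m[o, 1]), significance = m[o, 2],
                 n = n), class = "change_points")
}

#' @export
print.change_points <- function(x, ...) {
  cat(sprintf("%d change point(s) in a series of %d samples\n",
              length(x$indices), x$n))
  if (length(x$indices))
    print(data.frame(index = x$indices,
                     significance = round(x$significance, 4)))
  invisible(x)
}
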