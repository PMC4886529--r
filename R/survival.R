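# Dwell-time survival functions and exponential-tail estimation of the
# state persistence times, plus the velocity summaries.
#
# S(t) = P(T > t) is the proportion of run (or rest) periods longer than t.
# Both states decay exponentially, S(t) ~ exp(-t/tau), beyond a few hours;
# tau is estimated by fitting log S(t) linearly inside a fit window that
# starts where the decay is clearly exponential (5 h for runs, 2.5 h for
# rests) and ends at 20 h. Only states starting at least 20 h before the
# end of their track enter the survival function, so that the estimate is
# not biased by the finite observation time.

#' Empirical survival function of state durations
#'
#' @param segs a `state_segments` data frame (see [segment_track()]).
#' @param label `"run"` or `"rest"`.
#' @return A list of class `survival_curve`: `durations` (uncensored dwell
#'   times, hours), `t` (grid: 0 and the sorted unique durations), `S`
#'   (survival values at `t`), `n` (number of states), `label`.
#' @export
state_survival <- function(segs, label = c("run", "rest")) {
  label <- match.arg(label)
  d <- segs$duration_h[segs$label == label & !segs$censored]
  if (!length(d)) stopf("insufficient uncensored %s states", label)
  tg <- c(0, sort(unique(d)))
  S <- vapply(tg, function(t) mean(d > t), 0)
  structure(list(durations = d, t = tg, S = S, n = length(d), label = label),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival of %d %s states; median %.2f h, max %.2f h\n",
              x$n, x$label, stats::median(x$durations), max(x$durations)))
  invisible(x)
}

#' Evaluate a survival curve
#'
#' @param sc a [state_survival()] curve.
#' @param t times (hours).
#' @return `S(t) = P(T > t)` at each `t`.
#' @export
surv_prob <- function(sc, t) vapply(t, function(ti) mean(sc$durations > ti), 0)

#' Fit the exponential tail of a survival function
#'
#' Ordinary least squares on (t, log S(t)) at the observed duration values
#' inside the window (t_min, t_max]; the persistence time is tau = -1/slope
#' and its 99% confidence interval is propagated from the slope's.
#'
#' @param sc a [state_survival()] curve.
#' @param t_min lower edge of the fit window (hours); the standard choices
#'   are 5 h for run states and 2.5 h for rest states.
#' @param t_max upper edge of the fit window (default 20 h).
#' @param conf confidence level of the reported interval (default 0.99).
#' @return A list of class `exp_tail_fit`: `tau` (hours), `ci` (two-sided
#'   interval at `conf`), `fit_range`, `n_states`, `n_points`, `label`.
#' @export
fit_exponential_tail <- function(sc, t_min, t_max = 20, conf = 0.99) {
  stopifnot(inherits(sc, "survival_curve"), t_min >= 0, t_max > t_min)
  tt <- sc$t[sc$t > t_min & sc$t <= t_max]
  Sv <- vapply(tt, function(ti) mean(sc$durations > ti), 0)
  keep <- Sv > 0
  if (!any(keep))
    stopf("survival reaches 0 before t_min = %g h; no tail to fit", t_min)
  tt <- tt[keep]; Sv <- Sv[keep]
  if (length(tt) < 5)
    stopf("too few support points (%d) in (%g, %g] for the tail fit",
          length(tt), t_min, t_max)
  fit <- stats::lm(log(Sv) ~ tt)
  b <- unname(stats::coef(fit)[2])
  if (b >= 0) stopf("non-decaying tail (slope %.3g >= 0)", b)
  # noiseless input gives a perfect fit; confint warns harmlessly there
  ci_b <- suppressWarnings(stats::confint(fit, "tt", level = conf))
  lo <- -1 / ci_b[1]  # most negative slope -> smallest tau
  hi <- if (ci_b[2] < 0) -1 / ci_b[2] else Inf
  structure(list(tau = -1 / b, ci = c(lo, hi), conf = conf,
                 fit_range = c(t_min, t_max), n_states = sc$n,
                 n_points = length(tt), label = sc$label),
            class = "exp_tail_fit")
}

#' @export
print.exp_tail_fit <- function(x, ...) {
  cat(sprintf("tau_%s = %.2f h (%d%% CI %.2f-%.2f), fit on (%g, %g] h, %d states\n",
              x$label, x$tau, round(100 * x$conf), x$ci[1], x$ci[2],
              x$fit_range[1], x$fit_range[2], x$n_states))
  invisible(x)
}

#' Run velocity of a cell population
#'
#' `v_run` is the mean over run states of the absolute within-state mean
#' tangential velocity, with the standard error of the mean across states.
#' All run states contribute, including censored ones (censoring only
#' matters for dwell-time estimation).
#'
#' @param segs a `state_segments` data frame.
#' @return List with `v_run`, `v_run_sem` (um/h) and `n_run_states`.
#' @export
run_velocity <- function(segs) {
  sp <- abs(segs$mean_v[segs$label == "run"])
  if (!length(sp)) stopf("no run states")
  list(v_run = mean(sp),
       v_run_sem = stats::sd(sp) / sqrt(length(sp)),
       n_run_states = length(sp))
}

#' Mean cell velocity over entire tracks
#'
#' Per cell, the mean absolute tangential velocity over the whole track
#' (rest periods included); reported as the mean over cells with its SEM.
#' For bimodal tracks this is smaller than [run_velocity()], which excludes
#' rest periods.
#'
#' @param polar_tracks list of [to_polar()] tracks.
#' @return List with `v_mean`, `v_mean_sem` (um/h) and `n_cells`.
#' @export
mean_velocity <- function(polar_tracks) {
  if (!length(polar_tracks)) stopf("no tracks")
  per_cell <- vapply(polar_tracks,
                     function(pt) mean(abs(tangential_velocity(pt)$v)), 0)
  list(v_mean = mean(per_cell),
       v_mean_sem = stats::sd(per_cell) / sqrt(length(per_cell)),
       n_cells = length(per_cell))
}
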