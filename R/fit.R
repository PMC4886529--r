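# The top-level fitting interface: from a set of tracks to the migratory
# fingerprint, via filtering, polar projection, CUSUM segmentation,
# survival-tail fits and (optionally) barrier analysis.

#' Fit the two-state migration model to a set of tracks
#'
#' Runs the full pipeline on one condition: quality filtering
#' ([filter_tracks()]), polar projection and CUSUM/MSD segmentation
#' ([segment_tracks()]), dwell-time survival functions with
#' exponential-tail persistence times ([fit_exponential_tail()]), and the
#' run/mean velocity summaries. When barrier encounter data are supplied
#' the barrier parameters complete the five-parameter migratory
#' fingerprint.
#'
#' @param tracks a [track_set()].
#' @param config a [seg_config()].
#' @param filter logical; apply [filter_tracks()] first (default `TRUE`).
#' @param min_duration,min_path_length filter thresholds, see
#'   [filter_tracks()].
#' @param R_nominal radius used for tangential velocities; defaults to the
#'   set's geometry hint (the 50-um design radius in the standard assay),
#'   falling back to per-track circle fits.
#' @param run_window,rest_window survival fit windows (t_min, t_max) in
#'   hours for the run and rest tails.
#' @param barrier_encounters optional: pooled [detect_encounters()] rows
#'   (or a list with `n`, `n_transits`) at the standardized 8-um gap, for
#'   P_turn(8).
#' @param p_turn_0 optional [spontaneous_turning()] result for P_turn(0);
#'   computed from the supplied tracks when `compute_p_turn0 = TRUE` (only
#'   meaningful on barrier-free lanes).
#' @param compute_p_turn0 logical; estimate P_turn(0) from these tracks
#'   with 8 virtual zones.
#' @return An object of class `ring_migration`.
#' @export
ring_migration <- function(tracks, config = seg_config(), filter = TRUE,
                           min_duration = 18, min_path_length = 50,
                           R_nominal = NULL,
                           run_window = c(5, 20), rest_window = c(2.5, 20),
                           barrier_encounters = NULL, p_turn_0 = NULL,
                           compute_p_turn0 = FALSE) {
  stopifnot(inherits(tracks, "track_set"))
  exclusions <- NULL
  if (filter) {
    tracks <- filter_tracks(tracks, min_duration, min_path_length)
    exclusions <- attr(tracks, "exclusions")
  }
  if (!length(tracks$tracks)) stopf("no tracks to analyze")
  segs <- segment_tracks(tracks, config, R_nominal = R_nominal)
  polar <- attr(segs, "polar")
  surv_run <- state_survival(segs, "run")
  surv_rest <- state_survival(segs, "rest")
  fit_run <- fit_exponential_tail(surv_run, run_window[1], run_window[2])
  fit_rest <- fit_exponential_tail(surv_rest, rest_window[1], rest_window[2])
  vel <- run_velocity(segs)
  vmean <- mean_velocity(polar)
  p8 <- if (!is.null(barrier_encounters)) {
    if (is.data.frame(barrier_encounters)) turning_probability(barrier_encounters)
    else {
      n <- barrier_encounters$n; k <- barrier_encounters$n_transits
      bt <- stats::binom.test(n - k, n)
      list(p_turn = (n - k) / n, ci = as.numeric(bt$conf.int), n = n,
           n_reversals = n - k, n_transits = k)
    }
  } else NULL
  p0 <- p_turn_0
  if (is.null(p0) && compute_p_turn0)
    p0 <- spontaneous_turning(polar)
  fp <- fingerprint(tracks$condition, vel, fit_run, fit_rest,
                    p_turn_8 = p8, p_turn_0 = p0,
                    n_cells = length(tracks$tracks))
  structure(list(condition = tracks$condition,
                 n_cells = length(tracks$tracks),
                 exclusions = exclusions,
                 segments = segs, polar = polar,
                 surv_run = surv_run, surv_rest = surv_rest,
                 tau_run = fit_run, tau_rest = fit_rest,
                 velocity = vel, v_mean = vmean,
                 p_turn_8 = p8, p_turn_0 = p0,
                 fingerprint = fp, config = config),
            class = "ring_migration")
}

#' @export
print.ring_migration <- function(x, ...) {
  cat(sprintf("Two-state migration fit: condition '%s', %d cells, %d states\n",
              x$condition, x$n_cells, nrow(x$segments)))
  cat(sprintf("  v_run    = %.2f +/- %.2f um/h (%d run states)\n",
              x$velocity$v_run, x$velocity$v_run_sem, x$velocity$n_run_states))
  cat(sprintf("  v_mean   = %.2f +/- %.2f um/h\n",
              x$v_mean$v_mean, x$v_mean$v_mean_sem))
  cat(sprintf("  tau_run  = %.2f h (99%% CI %.2f-%.2f)\n",
              x$tau_run$tau, x$tau_run$ci[1], x$tau_run$ci[2]))
  cat(sprintf("  tau_rest = %.2f h (99%% CI %.2f-%.2f)\n",
              x$tau_rest$tau, x$tau_rest$ci[1], x$tau_rest$ci[2]))
  if (!is.null(x$p_turn_8))
    cat(sprintf("  P_turn(8) = %.3f (95%% CI %.3f-%.3f)\n",
                x$p_turn_8$p_turn, x$p_turn_8$ci[1], x$p_turn_8$ci[2]))
  if (!is.null(x$p_turn_0))
    cat(sprintf("  P_turn(0) = %.3f (95%% CI %.3f-%.3f)\n",
                x$p_turn_0$p_turn0, x$p_turn_0$ci[1], x$p_turn_0$ci[2]))
  invisible(x)
}

#' @export
summary.ring_migration <- function(object, ...) {
  x <- object
  run <- x$segments$label == "run"
  out <- list(
    condition = x$condition, n_cells = x$n_cells,
    n_states = c(run = sum(run), rest = sum(!run)),
    n_uncensored = c(run = sum(run & !x$segments$censored),
                     rest = sum(!run & !x$segments$censored)),
    coef = stats::coef(x),
    v_mean = x$v_mean$v_mean, v_mean_sem = x$v_mean$v_mean_sem,
    run_fraction = sum(x$segments$duration_h[run]) /
      sum(x$segments$duration_h),
    exclusions = x$exclusions)
  class(out) <- "summary.ring_migration"
  out
}

#' @export
print.summary.ring_migration <- function(x, ...) {
  cat(sprintf("condition '%s': %d cells, %d run / %d rest states (%d/%d uncensored)\n",
              x$condition, x$n_cells, x$n_states["run"], x$n_states["rest"],
              x$n_uncensored["run"], x$n_uncensored["rest"]))
  cat(sprintf("time in run state: %.1f%%\n", 100 * x$run_fraction))
  print(round(x$coef, 3))
  if (!is.null(x$exclusions) && nrow(x$exclusions))
    cat(sprintf("%d tracks excluded (%s)\n", nrow(x$exclusions),
                paste(unique(x$exclusions$reason), collapse = ", ")))
  invisible(x)
}

#' Fingerprint parameters of a migration fit
#'
#' @param object a [ring_migration()] fit.
#' @param ... unused.
#' @return Named numeric vector `v_run`, `tau_run`, `tau_rest`,
#'   `p_turn_8`, `p_turn_0` (the latter two `NA` without barrier data).
#' @export
coef.ring_migration <- function(object, ...) {
  c(v_run = object$velocity$v_run,
    tau_run = object$tau_run$tau,
    tau_rest = object$tau_rest$tau,
    p_turn_8 = if (!is.null(object$p_turn_8)) object$p_turn_8$p_turn else NA_real_,
    p_turn_0 = if (!is.null(object$p_turn_0)) object$p_turn_0$p_turn0 else NA_real_)
}

#' Predicted dwell-time survival under the fitted exponentials
#'
#' @param object a [ring_migration()] fit.
#' @param t times (hours).
#' @param state `"run"` or `"rest"`.
#' @param ... unused.
#' @return `exp(-t / tau_state)` at the fitted persistence time.
#' @export
predict.ring_migration <- function(object, t, state = c("run", "rest"), ...) {
  state <- match.arg(state)
  tau <- if (state == "run") object$tau_run$tau else object$tau_rest$tau
  exp(-t / tau)
}

#' Plot a migration fit
#'
#' @param x a [ring_migration()] fit.
#' @param which `"survival"` (log-linear dwell survival with fitted
#'   exponential tails), `"velocity"` (histogram of state mean velocities),
#'   or `"radar"` (fingerprint radar chart; needs barrier data).
#' @param ... passed to the underlying plot calls.
#' @export
plot.ring_migration <- function(x, which = c("survival", "velocity", "radar"),
                                ...) {
  which <- match.arg(which)
  if (which == "survival") {
    S1 <- ifelse(x$surv_run$S > 0, x$surv_run$S, NA)
    S2 <- ifelse(x$surv_rest$S > 0, x$surv_rest$S, NA)
    graphics::plot(x$surv_run$t, S1, log = "y",
                   type = "s", col = "steelblue", lwd = 2,
                   xlab = "state duration T (h)", ylab = "S(t) = P(T > t)",
                   xlim = c(0, 20), ...)
    graphics::lines(x$surv_rest$t, S2, type = "s",
                    col = "firebrick", lwd = 2)
    tt <- seq(0, 20, 0.25)
    graphics::lines(tt, exp(-tt / x$tau_run$tau), lty = 2, col = "steelblue")
    graphics::lines(tt, exp(-tt / x$tau_rest$tau), lty = 2, col = "firebrick")
    graphics::legend("topright", bty = "n", lwd = 2,
                     col = c("steelblue", "firebrick"),
                     legend = c(sprintf("run, tau = %.1f h", x$tau_run$tau),
                                sprintf("rest, tau = %.1f h", x$tau_rest$tau)))
  } else if (which == "velocity") {
    run_v <- x$segments$mean_v[x$segments$label == "run"]
    rest_v <- x$segments$mean_v[x$segments$label == "rest"]
    brks <- pretty(c(run_v, rest_v), 40)
    hr <- graphics::hist(run_v, breaks = brks, plot = FALSE)
    hs <- graphics::hist(rest_v, breaks = brks, plot = FALSE)
    graphics::plot(hr, col = grDevices::adjustcolor("steelblue", 0.5),
                   border = NA, freq = FALSE,
                   xlab = "state mean tangential velocity (um/h)",
                   main = x$condition, ...)
    graphics::plot(hs, col = grDevices::adjustcolor("firebrick", 0.5),
                   border = NA, freq = FALSE, add = TRUE)
  } else {
    if (x$fingerprint$partial)
      stopf("radar chart needs the barrier parameters")
    radar_chart(x$fingerprint, ...)
  }
  invisible(x)
}

#' Simulate tracks from a fitted migration model
#'
#' Draws synthetic two-state tracks at the fitted v_run, tau_run and
#' tau_rest, which makes parametric-bootstrap checks of the pipeline a
#' one-liner.
#'
#' @param object a [ring_migration()] fit.
#' @param nsim number of tracks.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_params()].
#' @return See [simulate_tracks()].
#' @export
simulate.ring_migration <- function(object, nsim = 1, seed = 0, ...) {
  p <- sim_params(tau_run = object$tau_run$tau,
                  tau_rest = object$tau_rest$tau,
                  v_run = object$velocity$v_run, seed = seed, ...)
  simulate_tracks(p, nsim)
}
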