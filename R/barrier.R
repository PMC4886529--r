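# Cell-barrier interaction analysis: encounters with a PEGylated gap,
# turning probabilities with exact binomial confidence intervals, the
# exponential transit-decay length, state occupancy near the barrier, and
# the invasion-depth survival law.

#' Barrier specification
#'
#' @param angle angular position of the gap center (radians).
#' @param d_gap gap width along the arc (um).
#' @param zone_half_width half-width of the encounter zone (um, default 50):
#'   an encounter opens when the nucleus comes within this arc distance of
#'   the barrier.
#' @param reference `"edge"` (default): the zone extends `zone_half_width`
#'   beyond each gap edge, i.e. within 50 um of the barrier region;
#'   `"center"`: measured from the gap center.
#' @return A list of class `barrier_spec`.
#' @export
barrier_spec <- function(angle = 0, d_gap = 0, zone_half_width = 50,
                         reference = c("edge", "center")) {
  reference <- match.arg(reference)
  stopifnot(d_gap >= 0, zone_half_width > d_gap / 2 || reference == "edge")
  structure(list(angle = angle, d_gap = d_gap,
                 zone_half_width = zone_half_width, reference = reference),
            class = "barrier_spec")
}

# Effective half-width of the zone, in arc distance from the gap center.
zone_half_arc <- function(b) {
  if (b$reference == "edge") b$d_gap / 2 + b$zone_half_width
  else b$zone_half_width
}

#' Detect barrier encounters of one track
#'
#' An encounter opens when the signed arc distance of the nucleus to the gap
#' center first falls below the zone half-width and closes when it exceeds
#' it again; a track ending inside the zone leaves the encounter censored.
#' The outcome is a reversal when the cell leaves on the side it entered,
#' a transit otherwise.
#'
#' @param pt a [to_polar()] track.
#' @param b a [barrier_spec()].
#' @return Data frame of class `barrier_encounters`: `track_id`,
#'   `entry_frame`, `exit_frame` (`NA` if censored), `entry_side`,
#'   `exit_side` (+1/-1/`NA`), `outcome` (`"transit"`, `"reversal"`,
#'   `"censored"`).
#' @export
detect_encounters <- function(pt, b) {
  stopifnot(inherits(pt, "polar_track"), inherits(b, "barrier_spec"))
  R <- attr(pt, "R")
  delta <- R * wrap_angle(pt$phi - b$angle)  # signed arc distance to gap center
  zh <- zone_half_arc(b)
  inside <- abs(delta) < zh
  n <- length(inside)
  enc <- list()
  i <- 1L
  # skip a leading in-zone stretch: its entry side is unobserved
  while (i <= n && inside[i]) i <- i + 1L
  while (i <= n) {
    while (i <= n && !inside[i]) i <- i + 1L
    if (i > n) break
    entry <- i
    entry_side <- sign(delta[entry - 1L])
    while (i <= n && inside[i]) i <- i + 1L
    if (i > n) {
      enc[[length(enc) + 1L]] <- list(entry, NA_integer_, entry_side,
                                      NA_real_, "censored")
    } else {
      exit_side <- sign(delta[i])
      enc[[length(enc) + 1L]] <- list(
        entry, i, entry_side, exit_side,
        if (exit_side == entry_side) "reversal" else "transit")
    }
  }
  out <- data.frame(
    track_id = rep(attr(pt, "track_id") %||% "track", length(enc)),
    entry_frame = vapply(enc, function(e) e[[1]], 0L),
    exit_frame = vapply(enc, function(e) e[[2]], 0L),
    entry_side = vapply(enc, function(e) e[[3]], 0),
    exit_side = vapply(enc, function(e) e[[4]], 0),
    outcome = vapply(enc, function(e) e[[5]], ""),
    stringsAsFactors = FALSE)
  class(out) <- c("barrier_encounters", "data.frame")
  out
}

#' Turning probability with exact binomial confidence interval
#'
#' P_turn is the number of times a cell leaves the encounter zone on the
#' side it entered, divided by the number of zone entries; censored
#' encounters are excluded. The interval is the exact Clopper-Pearson 95%
#' binomial CI.
#'
#' @param enc a [detect_encounters()] data frame (possibly pooled over
#'   tracks with `rbind`).
#' @param conf confidence level (default 0.95).
#' @return List: `p_turn`, `ci` (length 2), `n` (non-censored encounters),
#'   `n_reversals`, `n_transits`.
#' @export
turning_probability <- function(enc, conf = 0.95) {
  k <- sum(enc$outcome == "reversal")
  m <- sum(enc$outcome == "transit")
  n <- k + m
  if (n == 0) stopf("no non-censored encounters")
  bt <- stats::binom.test(k, n, conf.level = conf)
  list(p_turn = k / n, ci = as.numeric(bt$conf.int), n = n,
       n_reversals = k, n_transits = m)
}

#' Spontaneous turning probability on barrier-free rings
#'
#' P_turn(0) is the mean of the turning probabilities at `n_regions`
#' equally spaced virtual 50-um zones placed on a lane without a barrier,
#' with a pooled Clopper-Pearson CI over all zone entries.
#'
#' @param polar_tracks list of [to_polar()] tracks on barrier-free rings.
#' @param n_regions number of virtual zones (default 8).
#' @param zone_half_width zone half-width in um (default 50).
#' @param conf confidence level (default 0.95).
#' @return List: `p_turn0`, `ci`, `per_region` (data frame of per-zone
#'   estimates), `n` (pooled non-censored encounters).
#' @export
spontaneous_turning <- function(polar_tracks, n_regions = 8,
                                zone_half_width = 50, conf = 0.95) {
  angles <- 2 * pi * (seq_len(n_regions) - 1) / n_regions
  per <- lapply(angles, function(a) {
    spec <- barrier_spec(angle = a, d_gap = 0,
                         zone_half_width = zone_half_width,
                         reference = "center")
    enc <- do.call(rbind, lapply(polar_tracks, detect_encounters, b = spec))
    k <- sum(enc$outcome == "reversal")
    m <- sum(enc$outcome == "transit")
    data.frame(angle = a, n = k + m, n_reversals = k,
               p_turn = if (k + m > 0) k / (k + m) else NA_real_)
  })
  per <- do.call(rbind, per)
  ktot <- sum(per$n_reversals)
  ntot <- sum(per$n)
  if (ntot == 0) stopf("no zone entries on the barrier-free tracks")
  bt <- stats::binom.test(ktot, ntot, conf.level = conf)
  list(p_turn0 = mean(per$p_turn, na.rm = TRUE),
       ci = as.numeric(bt$conf.int), per_region = per, n = ntot)
}

#' Transit-probability curve over gap widths
#'
#' @param encounters_by_gap named list: for each gap width (names coercible
#'   to numeric, um) a pooled [detect_encounters()] data frame, or a list
#'   with integer fields `n_transits` and `n` (non-censored encounters).
#' @param conf confidence level for the per-width Clopper-Pearson CIs.
#' @return Data frame of class `transit_curve`: `d_gap`, `n`, `n_transits`,
#'   `p_trans`, `ci_lo`, `ci_hi`.
#' @export
transit_curve <- function(encounters_by_gap, conf = 0.95) {
  rows <- lapply(names(encounters_by_gap), function(nm) {
    e <- encounters_by_gap[[nm]]
    if (is.data.frame(e)) {
      k <- sum(e$outcome == "transit")
      n <- k + sum(e$outcome == "reversal")
    } else {
      k <- e$n_transits; n <- e$n
    }
    bt <- stats::binom.test(k, n, conf.level = conf)
    data.frame(d_gap = as.numeric(nm), n = n, n_transits = k,
               p_trans = k / n, ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$d_gap), ]
  rownames(out) <- NULL
  class(out) <- c("transit_curve", "data.frame")
  out
}

#' Fit the exponential decay of the transit probability
#'
#' Fits `P_trans(d_gap) = (1 - P_turn0) * exp(-d_gap / mu_trans)` with the
#' intercept fixed at the spontaneous transit probability, by weighted
#' least squares with inverse binomial-variance weights (an unweighted
#' two-parameter variant is available with `fixed_intercept = FALSE`).
#'
#' @param tc a [transit_curve()] data frame.
#' @param p_turn0 spontaneous turning probability fixing the intercept.
#' @param fixed_intercept logical; `FALSE` fits intercept and decay length.
#' @param conf confidence level of the reported CI (default 0.95).
#' @return List of class `transit_fit`: `mu_trans` (um), `ci`, `p_turn0`,
#'   `fit` (the `nls` object).
#' @export
fit_transit_decay <- function(tc, p_turn0, fixed_intercept = TRUE,
                              conf = 0.95) {
  stopifnot(nrow(tc) >= 2)
  if (all(tc$p_trans == 0)) stopf("all transit probabilities are zero")
  p_c <- pmin(pmax(tc$p_trans, 1 / (2 * tc$n)), 1 - 1 / (2 * tc$n))
  w <- tc$n / (p_c * (1 - p_c))
  pos <- tc$p_trans > 0
  mu0 <- -1 / stats::coef(stats::lm(log(tc$p_trans[pos]) ~ tc$d_gap[pos]))[2]
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- mean(tc$d_gap)
  df <- data.frame(d = tc$d_gap, p = tc$p_trans, w = w)
  fit <- if (fixed_intercept) {
    a0 <- 1 - p_turn0
    stats::nls(p ~ a0 * exp(-d / mu), data = df, weights = w,
               start = list(mu = mu0), algorithm = "port",
               lower = list(mu = 1e-6))
  } else {
    stats::nls(p ~ a * exp(-d / mu), data = df, weights = w,
               start = list(a = 1 - p_turn0, mu = mu0), algorithm = "port",
               lower = list(a = 1e-6, mu = 1e-6))
  }
  sm <- summary(fit)
  est <- sm$coefficients["mu", "Estimate"]
  se <- sm$coefficients["mu", "Std. Error"]
  tq <- stats::qt(1 - (1 - conf) / 2, df = sm$df[2])
  structure(list(mu_trans = est, ci = c(est - tq * se, est + tq * se),
                 p_turn0 = p_turn0, fit = fit),
            class = "transit_fit")
}

#' @export
print.transit_fit <- function(x, ...) {
  cat(sprintf("mu_trans = %.2f um (95%% CI %.2f-%.2f), P_turn(0) = %.3f\n",
              x$mu_trans, x$ci[1], x$ci[2], x$p_turn0))
  invisible(x)
}

#' Run/rest occupancy versus distance to the barrier
#'
#' For each arc-distance bin, the fraction of cell-frames spent in the run
#' and rest states, revealing the depletion of runs and accumulation of
#' rests next to the barrier.
#'
#' @param segs `state_segments` of barrier tracks (see [segment_tracks()]).
#' @param polar_tracks named list of the corresponding [to_polar()] tracks.
#' @param b a [barrier_spec()].
#' @param bin_width bin width in um (default 10).
#' @return Data frame: `dist_lo`, `dist_hi`, `dist_mid` (um from the gap
#'   center), `f_run`, `f_rest`, `n_frames`.
#' @export
state_occupancy_profile <- function(segs, polar_tracks, b, bin_width = 10) {
  dist <- numeric(0); lab <- character(0)
  for (id in names(polar_tracks)) {
    pt <- polar_tracks[[id]]
    R <- attr(pt, "R")
    d <- abs(R * wrap_angle(pt$phi - b$angle))
    s <- segs[segs$track_id == id, , drop = FALSE]
    if (!nrow(s)) next
    lab <- c(lab, frame_states(s, nrow(pt)))
    dist <- c(dist, d)
  }
  brks <- seq(0, max(dist) + bin_width, by = bin_width)
  bin <- cut(dist, brks, right = FALSE)
  tab <- table(bin, factor(lab, levels = c("run", "rest")))
  n <- rowSums(tab)
  keep <- n > 0
  data.frame(dist_lo = brks[-length(brks)][keep],
             dist_hi = brks[-1][keep],
             dist_mid = (brks[-1] - bin_width / 2)[keep],
             f_run = (tab[, "run"] / pmax(n, 1))[keep],
             f_rest = (tab[, "rest"] / pmax(n, 1))[keep],
             n_frames = as.integer(n[keep]),
             row.names = NULL)
}

#' Fit the invasion-depth survival law
#'
#' The maximal invasion depth of the lamellipodium into the PEGylated area,
#' d_inv, follows an exponential survival law S_inv(d) = s0 * exp(-d /
#' mu_inv). log S_inv is fitted linearly at the observed depths where the
#' empirical survival is positive (the largest depth, where S = 0, cannot
#' contribute).
#'
#' @param depths numeric vector of invasion depths (um), at least 10.
#' @param conf confidence level of the reported CI (default 0.95).
#' @return List of class `invasion_fit`: `mu_inv` (um), `ci`, `s0`, `n`.
#' @export
fit_invasion_survival <- function(depths, conf = 0.95) {
  depths <- as.numeric(depths)
  if (length(depths) < 10) stopf("need at least 10 invasion depths")
  if (diff(range(depths)) == 0) stopf("degenerate sample: all depths equal")
  d <- sort(unique(depths))
  S <- vapply(d, function(x) mean(depths > x), 0)
  keep <- S > 0
  if (sum(keep) < 3) stopf("too few support points for the survival fit")
  fit <- stats::lm(log(S[keep]) ~ d[keep])
  b <- unname(stats::coef(fit)[2])
  if (b >= 0) stopf("non-decaying invasion survival")
  ci_b <- suppressWarnings(stats::confint(fit, level = conf))[2, ]
  hi <- if (ci_b[2] < 0) -1 / ci_b[2] else Inf
  structure(list(mu_inv = -1 / b, ci = c(-1 / ci_b[1], hi),
                 s0 = min(1, exp(unname(stats::coef(fit)[1]))),
                 n = length(depths)),
            class = "invasion_fit")
}

#' @export
print.invasion_fit <- function(x, ...) {
  cat(sprintf("mu_inv = %.2f um (CI %.2f-%.2f), s0 = %.3f, n = %d depths\n",
              x$mu_inv, x$ci[1], x$ci[2], x$s0, x$n))
  invisible(x)
}
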