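# Synthetic two-state trajectory generator.
#
# A phenomenological stand-in for bimodal cell migration on a ring:
# alternating run and rest states with exponential dwell times Exp(tau_run)
# and Exp(tau_rest). Runs move at constant tangential speed +/- v_run (the
# direction flips with probability p_flip at each run onset); rests perform
# confined 1D diffusion on the arc (diffusion constant D, reflecting tether
# of half-length `confinement` around the rest anchor). Frame-wise Gaussian
# noise of sd `noise` is added to (x, y) to mimic jitter of the nucleus
# position. The initial state is drawn from the stationary occupancy
# tau_run / (tau_run + tau_rest); because exponential dwell times are
# memoryless, a fresh Exp draw is also the equilibrium residual dwell.

#' Simulation parameters
#'
#' Defaults reproduce the standard assay (10-min frames on a 50-um ring)
#' and the reference motility of MDA-MB-436 cells: tau_run = 13.6 h,
#' tau_rest = 6.5 h, v_run = 30.2 um/h.
#'
#' @param tau_run,tau_rest mean run/rest dwell times (h).
#' @param v_run run speed (um/h).
#' @param D rest-state diffusion constant (um^2/h).
#' @param confinement rest-state tether half-length (um); rest motion
#'   reflects at +/- `confinement` around the rest anchor.
#' @param noise frame-wise Gaussian position noise sd (um), applied to x
#'   and y.
#' @param p_flip probability that a new run reverses direction relative to
#'   the previous one.
#' @param R ring radius (um).
#' @param dt frame interval (h).
#' @param duration track duration (h).
#' @param seed integer seed; each track uses a substream derived from it,
#'   so earlier tracks are unchanged when more are requested.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(tau_run = 13.6, tau_rest = 6.5, v_run = 30.2,
                       D = 20, confinement = 10, noise = 1, p_flip = 0.5,
                       R = 50, dt = 1 / 6, duration = 48, seed = 0) {
  stopifnot(tau_run > 0, tau_rest > 0, v_run >= 0, D >= 0, confinement >= 0,
            noise >= 0, p_flip >= 0, p_flip <= 1, R > 0, dt > 0,
            duration >= dt)
  structure(list(tau_run = tau_run, tau_rest = tau_rest, v_run = v_run,
                 D = D, confinement = confinement, noise = noise,
                 p_flip = p_flip, R = R, dt = dt, duration = duration,
                 seed = seed),
            class = "sim_params")
}

# Reflect an offset into [-L, L] (triangle fold of period 4L).
fold_reflect <- function(u, L) {
  if (L <= 0) return(0)
  z <- (u + L) %% (4 * L)
  (if (z > 2 * L) 4 * L - z else z) - L
}

# Draw alternating dwell schedule covering [0, total]; returns start times,
# labels and the raw (untruncated) dwell draws.
draw_schedule <- function(p, total) {
  run_first <- stats::runif(1) < p$tau_run / (p$tau_run + p$tau_rest)
  starts <- 0
  labels <- character(0)
  dwells <- numeric(0)
  t <- 0
  is_run <- run_first
  while (t < total) {
    d <- stats::rexp(1, 1 / (if (is_run) p$tau_run else p$tau_rest))
    labels <- c(labels, if (is_run) "run" else "rest")
    dwells <- c(dwells, d)
    t <- t + d
    starts <- c(starts, t)
    is_run <- !is_run
  }
  list(starts = starts[-length(starts)], ends = pmin(starts[-1], total),
       labels = labels, dwells = dwells)
}

#' Simulate one two-state track on the ring
#'
#' @param p a [sim_params()].
#' @param track_id id attached to the track.
#' @param seed optional seed overriding `p$seed`.
#' @return A list with `track` (validated data frame t/x/y), `truth` (data
#'   frame of true segments: `start_h`, `end_h`, `label`, `dwell_h` -- the
#'   untruncated dwell draw, `truncated`), and `frame_state` (true label
#'   per frame).
#' @export
simulate_track <- function(p, track_id = "sim1", seed = NULL) {
  stopifnot(inherits(p, "sim_params"))
  with_seed(seed %||% p$seed, {
    n_frames <- floor(p$duration / p$dt) + 1L
    total <- (n_frames - 1L) * p$dt
    sch <- draw_schedule(p, total)
    t_frames <- (seq_len(n_frames) - 1L) * p$dt
    evs <- sort(unique(c(t_frames, sch$starts[sch$starts > 0 & sch$starts < total])))
    is_frame <- evs %in% t_frames
    seg_of <- findInterval(evs, sch$starts)
    dir <- sign(stats::runif(1) - 0.5)
    s <- 0          # arc-length position, unwrapped
    anchor <- 0; u <- 0
    cur_seg <- seg_of[1]
    if (sch$labels[cur_seg] == "rest") { anchor <- s; u <- 0 }
    pos <- numeric(n_frames)
    fi <- 1L
    if (is_frame[1]) { pos[fi] <- s; fi <- fi + 1L }
    for (j in seq_len(length(evs) - 1L)) {
      # transition bookkeeping at the start of the interval
      if (seg_of[j] != cur_seg) {
        for (k in (cur_seg + 1L):seg_of[j]) {
          if (sch$labels[k] == "rest") { anchor <- s; u <- 0 }
          else if (stats::runif(1) < p$p_flip) dir <- -dir
        }
        cur_seg <- seg_of[j]
      }
      dt_ev <- evs[j + 1L] - evs[j]
      if (sch$labels[cur_seg] == "run") {
        s <- s + dir * p$v_run * dt_ev
      } else {
        u <- fold_reflect(u + stats::rnorm(1, 0, sqrt(2 * p$D * dt_ev)),
                          p$confinement)
        s <- anchor + u
      }
      if (is_frame[j + 1L]) { pos[fi] <- s; fi <- fi + 1L }
    }
    phi <- pos / p$R
    df <- data.frame(t = t_frames,
                     x = p$R * cos(phi) + stats::rnorm(n_frames, 0, p$noise),
                     y = p$R * sin(phi) + stats::rnorm(n_frames, 0, p$noise))
    truth <- data.frame(start_h = sch$starts, end_h = sch$ends,
                        label = sch$labels, dwell_h = sch$dwells,
                        truncated = sch$starts + sch$dwells > total,
                        stringsAsFactors = FALSE)
    frame_state <- sch$labels[findInterval(t_frames, sch$starts)]
    list(track = validate_track(df, track_id), truth = truth,
         frame_state = frame_state)
  })
}

#' Simulate an ensemble of two-state tracks
#'
#' @param p a [sim_params()].
#' @param n_tracks number of tracks.
#' @param prefix track-id prefix.
#' @return A list with `tracks` (a [track_set()] with the ring geometry
#'   attached), `truth` (named list of per-track truth tables), and
#'   `frame_state` (named list of per-frame true labels).
#' @export
simulate_tracks <- function(p, n_tracks, prefix = "sim") {
  ids <- paste0(prefix, seq_len(n_tracks))
  sims <- lapply(seq_len(n_tracks), function(i)
    simulate_track(p, ids[i], seed = derive_seed(p$seed, i)))
  tracks <- lapply(sims, `[[`, "track")
  names(tracks) <- ids
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids
  fs <- lapply(sims, `[[`, "frame_state")
  names(fs) <- ids
  list(tracks = track_set(tracks, condition = "synthetic",
                          geometry = ring_geometry(c(0, 0), p$R)),
       truth = truth, frame_state = fs)
}

#' Barrier transit mechanisms
#'
#' `mechanism_bernoulli()`: each gap-edge arrival transits with probability
#' `(1 - p_turn0) * exp(-d_gap / mu_trans)`.
#' `mechanism_invasion()`: each arrival draws a maximal lamellipodium
#' invasion depth from the truncated shifted exponential of
#' [simulate_invasion_depths()] and transits iff the depth exceeds the gap
#' width, linking the transit-decay length to the invasion-depth scale.
#'
#' @param mu_trans,p_turn0 decay length (um) and spontaneous turning
#'   probability of the Bernoulli mechanism.
#' @param mu_inv,s0,d_min,d_max invasion-depth law parameters (um).
#' @return A list describing the mechanism.
#' @export
mechanism_bernoulli <- function(mu_trans = 8.3, p_turn0 = 0.2) {
  list(type = "bernoulli", mu_trans = mu_trans, p_turn0 = p_turn0)
}

#' @rdname mechanism_bernoulli
#' @export
mechanism_invasion <- function(mu_inv = 11.8, s0 = 1, d_min = 2, d_max = 30) {
  list(type = "invasion", mu_inv = mu_inv, s0 = s0, d_min = d_min,
       d_max = d_max)
}

transit_prob <- function(mech, d_gap) {
  switch(mech$type,
         bernoulli = (1 - mech$p_turn0) * exp(-d_gap / mech$mu_trans),
         invasion = {
           # P(d_inv > d_gap) under the truncated shifted exponential
           if (d_gap < mech$d_min) 1
           else if (d_gap >= mech$d_max) 0
           else mech$s0 * exp(-d_gap / mech$mu_inv)
         },
         stopf("unknown mechanism '%s'", mech$type))
}

draw_transit <- function(mech, d_gap) {
  if (mech$type == "bernoulli")
    stats::runif(1) < transit_prob(mech, d_gap)
  else
    sample_invasion(1, mech$mu_inv, mech$s0, mech$d_min, mech$d_max) > d_gap
}

#' Simulate encounter outcomes at given gap widths
#'
#' Draws the outcome (transit/reversal) of `n` independent barrier
#' encounters per gap width directly from the transit mechanism, without
#' emitting trajectories; the counts feed [transit_curve()] and
#' [fit_transit_decay()].
#'
#' @param d_gaps numeric vector of gap widths (um).
#' @param n encounters per width.
#' @param mech a [mechanism_bernoulli()] or [mechanism_invasion()].
#' @param seed integer seed.
#' @return Named list (by gap width) of lists with `n` and `n_transits`,
#'   ready for [transit_curve()].
#' @export
simulate_encounter_outcomes <- function(d_gaps, n, mech, seed = 0) {
  with_seed(seed, {
    out <- lapply(seq_along(d_gaps), function(i) {
      k <- if (mech$type == "bernoulli") {
        stats::rbinom(1, n, transit_prob(mech, d_gaps[i]))
      } else {
        depths <- sample_invasion(n, mech$mu_inv, mech$s0, mech$d_min,
                                  mech$d_max)
        sum(depths > d_gaps[i])
      }
      list(n = n, n_transits = k)
    })
    names(out) <- as.character(d_gaps)
    out
  })
}

#' Simulate tracks interacting with a PEGylated barrier
#'
#' Cells run and rest on the ring with a gap of width `d_gap` centred at
#' angle 0. When a running cell reaches the near gap edge, the transit
#' mechanism decides the outcome: on a transit the run carries the cell
#' across the gap; on a reversal the cell stops at the edge, rests for an
#' Exp(tau_rest) dwell, and repolarizes away from the barrier. Spontaneous
#' rests elsewhere on the lane do not flip the direction, so every zone
#' entry proceeds to a gap-edge arrival and the measured transit fraction
#' equals the mechanism's probability; rest-state diffusion is suppressed
#' in these datasets for the same reason (see the methods vignette).
#'
#' @param p a [sim_params()].
#' @param d_gap gap width (um).
#' @param mech a [mechanism_bernoulli()] or [mechanism_invasion()].
#' @param n_encounters target number of completed (non-censored) encounters.
#' @param max_tracks safety cap on the number of tracks.
#' @return A list with `tracks` (a [track_set()] carrying the barrier
#'   spec), `outcomes` (character vector of ground-truth outcomes in
#'   chronological order), and `barrier` (the [barrier_spec()]).
#' @export
simulate_barrier_dataset <- function(p, d_gap, mech = mechanism_bernoulli(),
                                     n_encounters = 300, max_tracks = 1000) {
  stopifnot(inherits(p, "sim_params"))
  b <- barrier_spec(angle = 0, d_gap = d_gap, zone_half_width = 50,
                    reference = "edge")
  tracks <- list(); outcomes <- character(0)
  i <- 0L
  while (length(outcomes) < n_encounters && i < max_tracks) {
    i <- i + 1L
    sim <- simulate_barrier_track(p, d_gap, mech,
                                  seed = derive_seed(p$seed + 7919L, i),
                                  track_id = paste0("bar", i))
    tracks[[sim$track_id]] <- sim$track
    outcomes <- c(outcomes, sim$outcomes)
  }
  list(tracks = track_set(tracks, condition = sprintf("gap_%g", d_gap),
                          geometry = ring_geometry(c(0, 0), p$R),
                          barrier = b),
       outcomes = outcomes, barrier = b)
}

# One barrier track: frame-resolution integration of the run/rest process
# with gap-edge interception. Gap occupies arc (-g/2, g/2) around angle 0;
# ring positions are tracked modulo the perimeter.
simulate_barrier_track <- function(p, d_gap, mech, seed, track_id) {
  per <- 2 * pi * p$R
  g2 <- d_gap / 2
  with_seed(seed, {
    n_frames <- floor(p$duration / p$dt) + 1L
    s <- per / 2                       # start at the antipode of the gap
    dir <- sign(stats::runif(1) - 0.5)
    state <- if (stats::runif(1) < p$tau_run / (p$tau_run + p$tau_rest))
      "run" else "rest"
    t_left <- stats::rexp(1, 1 / (if (state == "run") p$tau_run else p$tau_rest))
    pos <- numeric(n_frames)
    pos[1] <- s
    outcomes <- character(0)
    in_gap <- FALSE                    # currently traversing the gap
    for (f in 2:n_frames) {
      rem <- p$dt
      while (rem > 1e-12) {
        if (state == "rest") {
          step <- min(rem, t_left)
          t_left <- t_left - step
          rem <- rem - step
          if (t_left <= 1e-12) {
            state <- "run"
            t_left <- stats::rexp(1, 1 / p$tau_run)
            # spontaneous repolarization keeps the direction; reversals
            # happen only at the barrier
          }
          next
        }
        # running: time to dwell end and to the entrance edge
        step <- min(rem, t_left)
        m <- s %% per                  # position on the circle
        hit_t <- Inf
        if (!in_gap) {
          edge <- if (dir > 0) per - g2 else g2
          dist_arc <- ((edge - m) * dir) %% per
          if (dist_arc > 1e-9) hit_t <- dist_arc / p$v_run
          # dist_arc == 0 means standing at the edge right after a reversal
        }
        if (hit_t <= step) {
          s <- s + dir * p$v_run * hit_t
          t_left <- t_left - hit_t
          rem <- rem - hit_t
          if (draw_transit(mech, d_gap)) {
            outcomes <- c(outcomes, "transit")
            in_gap <- TRUE             # carry the run across the gap
          } else {
            outcomes <- c(outcomes, "reversal")
            state <- "rest"
            t_left <- stats::rexp(1, 1 / p$tau_rest)
            dir <- -dir
          }
          next
        }
        s <- s + dir * p$v_run * step
        if (in_gap) {
          mm <- s %% per
          if (mm > g2 && mm < per - g2) in_gap <- FALSE
        }
        t_left <- t_left - step
        rem <- rem - step
        if (t_left <= 1e-12) {
          if (in_gap) {
            # the lamellipodium has committed to bridging: finish crossing
            t_left <- (g2 * 2) / p$v_run
          } else {
            state <- "rest"
            t_left <- stats::rexp(1, 1 / p$tau_rest)
          }
        }
      }
      pos[f] <- s
    }
    phi <- pos / p$R
    t_frames <- (seq_len(n_frames) - 1L) * p$dt
    df <- data.frame(t = t_frames,
                     x = p$R * cos(phi) + stats::rnorm(n_frames, 0, p$noise),
                     y = p$R * sin(phi) + stats::rnorm(n_frames, 0, p$noise))
    # note: if the track ends inside the encounter zone, the last recorded
    # outcome corresponds to an encounter the analysis will see as censored
    list(track = validate_track(df, track_id), outcomes = outcomes,
         track_id = track_id)
  })
}

#' Sample invasion depths from the truncated shifted exponential law
#'
#' Depths are drawn so that the sample survival follows
#' `S_inv(d) = s0 * exp(-d / mu_inv)` on `[d_min, d_max]`, with point
#' masses at the bounds absorbing the truncated tails (every cell
#' penetrates at least `d_min` = 2 um; the deepest observed invasion is
#' about `d_max` = 30 um).
#'
#' @param n number of depths.
#' @param mu_inv decay length (um).
#' @param s0 survival amplitude (0 < s0 <= 1).
#' @param d_min,d_max support bounds (um).
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return Numeric vector of `n` depths in `[d_min, d_max]`.
#' @export
simulate_invasion_depths <- function(n, mu_inv = 11.8, s0 = 1, d_min = 2,
                                     d_max = 30, seed = 0) {
  stopifnot(n >= 1, mu_inv > 0, s0 > 0, s0 <= 1, d_min >= 0, d_max > d_min)
  if (is.null(seed)) sample_invasion(n, mu_inv, s0, d_min, d_max)
  else with_seed(seed, sample_invasion(n, mu_inv, s0, d_min, d_max))
}

sample_invasion <- function(n, mu_inv, s0, d_min, d_max) {
  u <- stats::runif(n)
  d <- ifelse(u <= s0 * exp(-d_max / mu_inv), d_max,
              ifelse(u >= s0 * exp(-d_min / mu_inv), d_min,
                     -mu_inv * log(u / s0)))
  d
}
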