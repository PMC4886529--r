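# Assembly of run/rest state segments for whole tracks.
#
# Change points are detected on the tangential-velocity series (n - 1
# samples for n frames); velocity sample i covers the frame interval
# [i, i + 1). A change point at sample k starts a new segment at sample
# k + 1. Segments are stored half-open in frame indices, [start_idx,
# end_idx), so that consecutive segments tile the track exactly and the
# durations sum to the track duration.

#' Refine change-point positions by local least squares
#'
#' Each boundary is moved within `+/- half_window` samples to the position
#' minimizing the residual sum of squares of the two adjacent segments
#' around their means (the exhaustive least-squares split localizer,
#' applied locally). The permutation test decides *whether* a change
#' exists; this pass sharpens *where*, which keeps boundary frames of the
#' neighbouring state out of short segments.
#'
#' @param v numeric velocity samples.
#' @param idx sorted change-point indices.
#' @param half_window search half-width in samples (0 disables).
#' @param min_len minimum segment length preserved.
#' @return Refined sorted indices.
#' @export
refine_boundaries <- function(v, idx, half_window = 3L, min_len = 3L) {
  n <- length(v)
  if (!length(idx) || half_window <= 0) return(idx)
  bnds <- c(0L, as.integer(idx), n)
  for (k in seq_along(idx)) {
    lo <- bnds[k]; hi <- bnds[k + 2L]; b0 <- bnds[k + 1L]
    cand <- seq.int(max(lo + min_len, b0 - half_window),
                    min(hi - min_len, b0 + half_window))
    if (length(cand) <= 1L) next
    rss <- vapply(cand, function(b) {
      l <- v[(lo + 1L):b]; r <- v[(b + 1L):hi]
      sum((l - mean(l))^2) + sum((r - mean(r))^2)
    }, 0)
    bnds[k + 1L] <- cand[which.min(rss)]
  }
  bnds[-c(1L, length(bnds))]
}

# Within-state mean velocity over the samples (a, b]. State switches fall
# inside a frame interval, so the first and last velocity sample of a
# segment mix the two adjacent states, and the boundary estimate itself is
# uncertain by about one sample; the mean is therefore taken over the
# interior samples (trimming up to two per side as length permits), which
# removes the dilution that otherwise biases the run velocity low
# (strongest for short runs).
seg_mean_v <- function(v, a, b) {
  m <- b - a + 1L
  tr <- if (m >= 7L) 2L else if (m >= 5L) 1L else 0L
  mean(v[(a + tr):(b - tr)])
}

# Classify inter-boundary segments (MSD slope, with velocity-contrast
# fallback for short windows), absorb unclassifiable slivers, and collapse
# adjacent segments of identical label. `idx` are change-point indices in
# velocity-sample space.
classify_and_merge <- function(v, d_arc, dt, idx, config) {
  n <- length(v)
  bounds <- c(0L, as.integer(idx), n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  labels <- character(length(starts))
  for (j in seq_along(starts)) {
    frames <- starts[j]:(ends[j] + 1L)  # positions spanned by the samples
    labels[j] <- classify_segment(d_arc[frames], dt, config)
  }
  mean_v <- vapply(seq_along(starts),
                   function(j) seg_mean_v(v, starts[j], ends[j]), 0)
  # The MSD slope of a window below ~8 frames rests on too few displacement
  # pairs to be stable; for those the state-velocity contrast is the more
  # reliable channel. Short segments are therefore classified against the
  # track's run-speed reference (median |mean v| of the long run windows).
  n_frames_seg <- ends - starts + 2L
  long_run <- !is.na(labels) & labels == "run" &
    n_frames_seg >= config$short_classify_frames
  v_ref <- stats::median(abs(mean_v[long_run]))
  if (is.finite(v_ref) && v_ref > 0) {
    short <- which(!is.na(labels) &
                     n_frames_seg < config$short_classify_frames)
    labels[short] <- ifelse(
      abs(mean_v[short]) >= config$short_velocity_factor * v_ref,
      "run", "rest")
  }
  # a "run" whose speed is far below the track's run-speed reference is a
  # spurious split, whatever its length: apply the same contrast screen to
  # every run window
  if (is.finite(v_ref) && v_ref > 0) {
    slow_run <- which(!is.na(labels) & labels == "run" &
                        abs(mean_v) < config$short_velocity_factor * v_ref)
    labels[slow_run] <- "rest"
  }
  # merge unclassifiable slivers into the neighbour with nearest mean velocity
  while (anyNA(labels) && length(starts) > 1L) {
    j <- which(is.na(labels))[1]
    cand <- c(if (j > 1L) j - 1L, if (j < length(starts)) j + 1L)
    cand <- cand[!is.na(labels[cand])]
    if (!length(cand)) cand <- c(if (j > 1L) j - 1L else j + 1L)
    tgt <- cand[which.min(abs(mean_v[cand] - mean_v[j]))]
    keep <- min(j, tgt); drop <- max(j, tgt)
    ends[keep] <- ends[drop]
    if (is.na(labels[keep])) labels[keep] <- labels[drop]
    mean_v[keep] <- seg_mean_v(v, starts[keep], ends[keep])
    starts <- starts[-drop]; ends <- ends[-drop]
    labels <- labels[-drop]; mean_v <- mean_v[-drop]
  }
  if (anyNA(labels)) labels[is.na(labels)] <- "rest"  # single unsplit sliver
  # collapse adjacent identical labels; adjacent runs merge only when they
  # share the direction of motion -- a sign reversal implies an intervening
  # repolarization and therefore a genuine state boundary
  j <- 1L
  while (j < length(starts)) {
    if (labels[j] == labels[j + 1L] &&
        (labels[j] == "rest" || sign(mean_v[j]) == sign(mean_v[j + 1L]))) {
      ends[j] <- ends[j + 1L]
      mean_v[j] <- seg_mean_v(v, starts[j], ends[j])
      starts <- starts[-(j + 1L)]; ends <- ends[-(j + 1L)]
      labels <- labels[-(j + 1L)]; mean_v <- mean_v[-(j + 1L)]
    } else j <- j + 1L
  }
  list(starts = starts, ends = ends, labels = labels, mean_v = mean_v)
}

# Physical-consistency check on rest segments: rest-state motion is
# confined (tether scale ~10 um plus positional noise), so a displacement
# jump larger than `rest_jump_um` within a short sub-window of a rest
# segment betrays a directed excursion -- a run too brief for the
# permutation test. Returns extra boundary indices (velocity-sample space)
# delimiting the largest such jump per rest segment.
jump_breaks <- function(d_arc, r, config) {
  thr <- config$rest_jump_um
  if (is.null(thr) || !is.finite(thr)) return(integer(0))
  out <- integer(0)
  for (j in which(r$labels == "rest")) {
    a <- r$starts[j]; b <- r$ends[j]
    x <- d_arc[a:(b + 1L)]
    len <- length(x)
    best <- 0; bq <- 0L; bw <- 0L
    for (w in 3:min(10L, len - 1L)) {
      dif <- abs(x[(1L + w):len] - x[1:(len - w)])
      q <- which.max(dif)
      if (dif[q] > best) { best <- dif[q]; bq <- q; bw <- w }
    }
    if (best > thr) {
      b1 <- a - 2L + bq
      b2 <- b1 + bw
      out <- c(out, b1[b1 >= 1L], b2[b2 <= attr(r, "n") %||% Inf])
    }
  }
  out
}

#' Segment one track into run and rest states
#'
#' Runs [detect_change_points()] on the tangential velocity, classifies each
#' inter-change-point segment by its MSD slope ([classify_segment()]) on the
#' arc-length positions, merges unclassifiable sub-4-frame slivers into the
#' neighbour with the nearest mean velocity, and collapses adjacent segments
#' of identical label. Each segment carries its signed mean tangential
#' velocity, duration, and a censoring flag: states starting within
#' `config$censor_window` (20 h) of the track end cannot be observed for
#' their full dwell time and are excluded from survival estimation.
#'
#' @param pt a [to_polar()] track.
#' @param config a [seg_config()].
#' @return Data frame of class `state_segments`: `track_id`, `start_idx`,
#'   `end_idx` (frames, half-open), `start_h`, `end_h`, `label`, `mean_v`
#'   (um/h, signed), `duration_h`, `censored`.
#' @export
segment_track <- function(pt, config = seg_config()) {
  vs <- tangential_velocity(pt)
  v <- vs$v
  n <- length(v)
  dt <- attr(pt, "dt")
  d_arc <- arc_distance(pt)
  cp <- suppressWarnings(detect_change_points(v, config))
  # pass 1: refine raw detections, classify, merge; pass 2: re-refine the
  # merged boundaries with a wider window (more context on both sides) and
  # re-classify on the sharpened windows
  idx <- refine_boundaries(v, cp$indices, config$refine_window,
                           config$min_segment_length)
  r <- classify_and_merge(v, d_arc, dt, idx, config)
  idx <- refine_boundaries(v, utils::head(r$ends, -1L),
                           2L * config$refine_window,
                           config$min_segment_length)
  r <- classify_and_merge(v, d_arc, dt, idx, config)
  jmp <- jump_breaks(d_arc, r, config)
  jmp <- jmp[jmp >= 1L & jmp < n]
  if (length(jmp)) {
    idx <- sort(unique(c(utils::head(r$ends, -1L), jmp)))
    r <- classify_and_merge(v, d_arc, dt, idx, config)
  }
  starts <- r$starts; ends <- r$ends
  labels <- r$labels; mean_v <- r$mean_v
  t_end <- pt$t[nrow(pt)]
  start_h <- pt$t[starts]
  end_h <- pt$t[ends + 1L]
  out <- data.frame(track_id = attr(pt, "track_id") %||% "track",
                    start_idx = starts, end_idx = ends + 1L,
                    start_h = start_h, end_h = end_h,
                    label = labels, mean_v = mean_v,
                    duration_h = end_h - start_h,
                    censored = start_h > t_end - config$censor_window,
                    stringsAsFactors = FALSE)
  class(out) <- c("state_segments", "data.frame")
  out
}

#' Segment every track of a set
#'
#' @param ts a [track_set()] (typically after [filter_tracks()]).
#' @param config a [seg_config()]; the permutation seed of track i is
#'   derived deterministically from `config$seed` and i.
#' @param geometry optional [ring_geometry()] overriding the set's hint;
#'   when neither is given, a circle is fitted per track.
#' @param R_nominal radius used for velocities (defaults to the hinted
#'   geometry's radius, or the per-track fitted radius).
#' @return A `state_segments` data frame over all tracks, with attribute
#'   `polar` (the list of polar tracks, for downstream use).
#' @export
segment_tracks <- function(ts, config = seg_config(), geometry = NULL,
                           R_nominal = NULL) {
  stopifnot(inherits(ts, "track_set"))
  geometry <- geometry %||% ts$geometry
  ids <- names(ts$tracks)
  polar <- vector("list", length(ids))
  segs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- ts$tracks[[i]]
    g <- geometry %||% fit_circle(tr$x, tr$y)
    pt <- to_polar(tr, g, R_nominal %||% (if (!is.null(geometry)) geometry$radius))
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    polar[[i]] <- pt
    segs[[i]] <- segment_track(pt, cfg_i)
  }
  names(polar) <- ids
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("state_segments", "data.frame")
  attr(out, "polar") <- polar
  out
}

#' Per-frame state labels implied by a segmentation
#'
#' Frame f (1-based) inherits the label of the segment owning the interval
#' starting at f; the final frame inherits the last segment's label.
#'
#' @param segs `state_segments` of one track.
#' @param n_frames number of frames of the track.
#' @return Character vector of length `n_frames` of `"run"`/`"rest"`.
#' @export
frame_states <- function(segs, n_frames) {
  lab <- rep(NA_character_, n_frames)
  for (j in seq_len(nrow(segs)))
    lab[segs$start_idx[j]:(segs$end_idx[j] - 1L)] <- segs$label[j]
  lab[n_frames] <- segs$label[nrow(segs)]
  lab
}
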