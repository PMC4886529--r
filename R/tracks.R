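# Track containers, delimited-text I/O and quality filtering.
#
# A "track" is the time-ordered sequence of nucleus-centroid positions of one
# cell (columns t [h], x [um], y [um]); a "track_set" bundles the tracks of
# one experimental condition together with optional geometry and barrier
# hints. Tracks are assumed pre-truncated at cell division or pattern exit,
# as produced by manual curation of the time-lapse data.

#' Construct a set of cell tracks
#'
#' @param tracks named list of data frames, each with numeric columns `t`
#'   (hours), `x` and `y` (micrometres), one row per frame and time strictly
#'   increasing. Names are the track ids.
#' @param condition label of the experimental condition (cell line,
#'   treatment, ...).
#' @param geometry optional [ring_geometry()] hint shared by all tracks.
#' @param barrier optional [barrier_spec()] describing a PEGylated gap in the
#'   lane.
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, condition = "unnamed", geometry = NULL,
                      barrier = NULL) {
  if (is.null(names(tracks)) || anyDuplicated(names(tracks)))
    stopf("tracks must be a named list with unique track ids")
  tracks <- lapply(names(tracks), function(id) validate_track(tracks[[id]], id))
  names(tracks) <- vapply(tracks, function(tr) attr(tr, "track_id"), "")
  structure(list(tracks = tracks, condition = condition,
                 geometry = geometry, barrier = barrier),
            class = "track_set")
}

validate_track <- function(df, id) {
  if (!all(c("t", "x", "y") %in% names(df)))
    stopf("track '%s': columns t, x, y are required", id)
  df <- df[order(df$t), c("t", "x", "y")]
  if (nrow(df) < 2L)
    stopf("track '%s': at least 2 frames are required", id)
  dt <- diff(df$t)
  if (any(dt <= 0))
    stopf("track '%s': time not strictly increasing (duplicated or unordered frames)", id)
  if (diff(range(dt)) > 1e-6)
    stopf("track '%s': frame spacing not uniform (range %.3g h)", id, diff(range(dt)))
  rownames(df) <- NULL
  attr(df, "track_id") <- as.character(id)
  attr(df, "dt") <- mean(dt)
  df
}

#' @export
print.track_set <- function(x, ...) {
  nf <- vapply(x$tracks, nrow, 0L)
  cat(sprintf("track_set '%s': %d tracks, %d-%d frames each\n",
              x$condition, length(x$tracks),
              if (length(nf)) min(nf) else 0L, if (length(nf)) max(nf) else 0L))
  if (!is.null(x$geometry))
    cat(sprintf("  ring geometry: center (%.1f, %.1f) um, R = %.1f um\n",
                x$geometry$center[1], x$geometry$center[2], x$geometry$radius))
  if (!is.null(x$barrier))
    cat(sprintf("  barrier: gap %.1f um at %.1f rad\n",
                x$barrier$d_gap, x$barrier$angle))
  ex <- attr(x, "exclusions")
  if (!is.null(ex) && nrow(ex))
    cat(sprintf("  %d tracks excluded by filtering\n", nrow(ex)))
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' Default column mapping and unit conversion for track files
#'
#' @param id,t,x,y column names in the file holding the track id, time and
#'   positions.
#' @param sep field delimiter (`","` for CSV, `"\t"` for TSV).
#' @param t_scale multiplier converting the file's time unit to hours.
#' @param pos_scale multiplier converting the file's position unit to
#'   micrometres.
#' @return A list understood by [read_tracks()].
#' @export
track_format <- function(id = "track_id", t = "t_h", x = "x_um", y = "y_um",
                         sep = ",", t_scale = 1, pos_scale = 1) {
  list(id = id, t = t, x = x, y = y, sep = sep,
       t_scale = t_scale, pos_scale = pos_scale)
}

#' Read cell tracks from a delimited text file
#'
#' Reads a headered delimited file of nucleus-centroid positions and returns
#' a validated [track_set()]. Column names and units are mapped through a
#' format configuration, which may also be loaded from a YAML file.
#'
#' @param path path to the file.
#' @param format a [track_format()] list, or the path to a YAML file holding
#'   the same fields.
#' @param condition condition label attached to the set.
#' @param geometry,barrier optional hints, see [track_set()].
#' @return A `track_set`.
#' @export
read_tracks <- function(path, format = track_format(), condition = "unnamed",
                        geometry = NULL, barrier = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.character(format) && length(format) == 1L)
    format <- utils::modifyList(track_format(), yaml::read_yaml(format))
  raw <- utils::read.table(path, header = TRUE, sep = format$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(format$id, format$t, format$x, format$y)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))
  df <- data.frame(id = as.character(raw[[format$id]]),
                   t = as.numeric(raw[[format$t]]) * format$t_scale,
                   x = as.numeric(raw[[format$x]]) * format$pos_scale,
                   y = as.numeric(raw[[format$y]]) * format$pos_scale)
  tracks <- split(df[c("t", "x", "y")], df$id)
  for (id in names(tracks)) {
    if (anyDuplicated(tracks[[id]]$t))
      stopf("track '%s': duplicated time points", id)
  }
  track_set(tracks, condition = condition, geometry = geometry,
            barrier = barrier)
}

#' Write a track set to a delimited text file
#'
#' @param ts a [track_set()].
#' @param path output path.
#' @param format a [track_format()]; unit scales are applied in reverse so
#'   that a write/read cycle is the identity.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path, format = track_format()) {
  rows <- lapply(names(ts$tracks), function(id) {
    tr <- ts$tracks[[id]]
    out <- data.frame(id, tr$t / format$t_scale, tr$x / format$pos_scale,
                      tr$y / format$pos_scale)
    names(out) <- c(format$id, format$t, format$x, format$y)
    out
  })
  utils::write.table(do.call(rbind, rows), path, sep = format$sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter tracks by duration and motility
#'
#' Tracks shorter than `min_duration` (default 18 h) are excluded, as are
#' "non-moving" tracks, operationalized as a total path length below
#' `min_path_length` over the whole track (default 50 um). The exclusion
#' report is attached as attribute `"exclusions"`.
#'
#' @param ts a [track_set()].
#' @param min_duration minimum track duration in hours.
#' @param min_path_length minimum total path length in micrometres.
#' @return The filtered `track_set`, with attribute `exclusions`, a data
#'   frame of `track_id` and `reason` (`"duration"` or `"non-moving"`).
#' @export
filter_tracks <- function(ts, min_duration = 18, min_path_length = 50) {
  stopifnot(inherits(ts, "track_set"), min_duration >= 0)
  reason <- vapply(ts$tracks, function(tr) {
    if (diff(range(tr$t)) < min_duration) return("duration")
    path <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
    if (path < min_path_length) return("non-moving")
    ""
  }, "")
  keep <- reason == ""
  out <- ts
  out$tracks <- ts$tracks[keep]
  attr(out, "exclusions") <- data.frame(
    track_id = names(ts$tracks)[!keep],
    reason = unname(reason[!keep]),
    stringsAsFactors = FALSE)
  if (!any(keep)) warnf("no tracks passed the filter")
  out
}
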