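# The migratory fingerprint: {v_run, tau_run, tau_rest, P_turn(8),
# P_turn(0)} for one condition, and its radar-chart rendering.
#
# P_turn(8) = 1 - P_trans(8), the reversal probability at the standardized
# 8-um gap, complements the three trajectory parameters with two barrier
# parameters; together they form a characteristic polygon on a radar chart.

#' Assemble a migratory fingerprint
#'
#' Deterministic assembly of the five-parameter signature of one condition
#' from the trajectory statistics and (optionally) the barrier statistics.
#' Without barrier data the fingerprint is flagged partial.
#'
#' @param label condition name.
#' @param velocity a [run_velocity()] list.
#' @param tau_run,tau_rest [fit_exponential_tail()] fits of the run and
#'   rest survival tails.
#' @param p_turn_8 a [turning_probability()] list at the 8-um gap, or
#'   `NULL`.
#' @param p_turn_0 a [spontaneous_turning()] list, or `NULL`.
#' @param n_cells number of cells behind the estimates.
#' @return A list of class `fingerprint` with fields `label`, `v_run`,
#'   `v_run_sem`, `tau_run`, `tau_run_ci`, `tau_rest`, `tau_rest_ci`,
#'   `p_turn_8`, `p_turn_8_ci`, `p_turn_0`, `p_turn_0_ci`, `n_cells`,
#'   `partial`.
#' @export
fingerprint <- function(label, velocity, tau_run, tau_rest, p_turn_8 = NULL,
                        p_turn_0 = NULL, n_cells = NA_integer_) {
  if (is.null(tau_run) || is.null(tau_rest))
    stopf("fingerprint requires both persistence-time fits")
  fp <- list(label = label,
             v_run = velocity$v_run, v_run_sem = velocity$v_run_sem,
             tau_run = tau_run$tau, tau_run_ci = tau_run$ci,
             tau_rest = tau_rest$tau, tau_rest_ci = tau_rest$ci,
             p_turn_8 = if (!is.null(p_turn_8)) p_turn_8$p_turn else NA_real_,
             p_turn_8_ci = if (!is.null(p_turn_8)) p_turn_8$ci else c(NA, NA),
             p_turn_0 = if (!is.null(p_turn_0)) p_turn_0$p_turn0 else NA_real_,
             p_turn_0_ci = if (!is.null(p_turn_0)) p_turn_0$ci else c(NA, NA),
             n_cells = n_cells,
             partial = is.null(p_turn_8) || is.null(p_turn_0))
  structure(fp, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("migratory fingerprint '%s'%s:\n", x$label,
              if (x$partial) " (partial: no barrier data)" else ""))
  cat(sprintf("  v_run    = %6.2f +/- %.2f um/h\n", x$v_run, x$v_run_sem))
  cat(sprintf("  tau_run  = %6.2f h  (CI %.2f-%.2f)\n",
              x$tau_run, x$tau_run_ci[1], x$tau_run_ci[2]))
  cat(sprintf("  tau_rest = %6.2f h  (CI %.2f-%.2f)\n",
              x$tau_rest, x$tau_rest_ci[1], x$tau_rest_ci[2]))
  if (!x$partial) {
    cat(sprintf("  P_turn(8)= %6.3f     (CI %.3f-%.3f)\n",
                x$p_turn_8, x$p_turn_8_ci[1], x$p_turn_8_ci[2]))
    cat(sprintf("  P_turn(0)= %6.3f     (CI %.3f-%.3f)\n",
                x$p_turn_0, x$p_turn_0_ci[1], x$p_turn_0_ci[2]))
  }
  invisible(x)
}

# Axis order and orientation of the radar chart. v_run and tau_run point
# upward (larger = vertex farther out on an upper axis); tau_rest and the
# turning probabilities sit on downward axes with inverted scale, so that a
# more motile condition forms a polygon shifted towards the top.
fp_axes <- function() {
  data.frame(
    name = c("v_run", "tau_run", "tau_rest", "p_turn_8", "p_turn_0"),
    # angles: two upward axes flanking 12 o'clock, three downward
    angle = c(pi / 2 + 2 * pi / 5, pi / 2 - 2 * pi / 5, pi / 2 - 4 * pi / 5,
              pi / 2 + 4 * pi / 5, pi / 2),
    invert = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Radar-chart vertex coordinates of fingerprints
#'
#' Shared axis normalization across all fingerprints: each axis maps
#' [0, limit] linearly to radius [0, 1], with limit 1.25 x the maximum
#' observed value (or from `axis_limits`). Axes carrying tau_rest and the
#' turning probabilities are inverted (radius = 1 - scaled value) so that
#' higher motility shifts the polygon upward.
#'
#' @param fps a `fingerprint` or list of fingerprints.
#' @param axis_limits optional named numeric vector of axis maxima
#'   (`v_run`, `tau_run`, `tau_rest`, `p_turn_8`, `p_turn_0`).
#' @return Data frame: `label`, `axis`, `value`, `radius`, `x`, `y`.
#' @export
fingerprint_vertices <- function(fps, axis_limits = NULL) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  ax <- fp_axes()
  vals <- sapply(fps, function(f)
    c(f$v_run, f$tau_run, f$tau_rest, f$p_turn_8, f$p_turn_0))
  if (any(!is.finite(vals)))
    stopf("non-finite fingerprint parameter; cannot place vertices")
  lims <- 1.25 * apply(vals, 1, max)
  lims[lims <= 0] <- 1
  names(lims) <- ax$name
  if (!is.null(axis_limits))
    lims[names(axis_limits)] <- axis_limits
  rows <- lapply(seq_along(fps), function(i) {
    scaled <- pmin(vals[, i] / lims, 1)
    radius <- ifelse(ax$invert, 1 - scaled, scaled)
    data.frame(label = fps[[i]]$label %||% paste0("fp", i),
               axis = ax$name, value = vals[, i], radius = radius,
               x = radius * cos(ax$angle), y = radius * sin(ax$angle),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render fingerprints as a radar chart
#'
#' Writes a vector-graphics radar chart (SVG or PDF by file extension) and
#' a machine-readable JSON of the vertex coordinates next to it, so charts
#' can be tested without image comparison.
#'
#' @param fps a `fingerprint` or list of fingerprints.
#' @param path output path ending in `.svg` or `.pdf`; `NULL` draws on the
#'   current device.
#' @param axis_limits see [fingerprint_vertices()].
#' @param write_json logical; also write `<path>.json` with the vertices.
#' @return The vertex data frame, invisibly.
#' @export
radar_chart <- function(fps, path = NULL, axis_limits = NULL,
                        write_json = !is.null(path)) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  verts <- fingerprint_vertices(fps, axis_limits)
  ax <- fp_axes()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           svg = grDevices::svg(path, width = 7, height = 7),
           pdf = grDevices::pdf(path, width = 7, height = 7),
           stopf("unsupported extension '%s' (use svg or pdf)", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot.new()
  graphics::plot.window(c(-1.4, 1.4), c(-1.4, 1.4), asp = 1)
  for (rr in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(rr * cos(ax$angle), rr * sin(ax$angle),
                      border = "grey85")
  graphics::segments(0, 0, cos(ax$angle), sin(ax$angle), col = "grey70")
  lab <- c(expression(v[run]), expression(tau[run]), expression(tau[rest]),
           expression(P[turn](8)), expression(P[turn](0)))
  graphics::text(1.22 * cos(ax$angle), 1.22 * sin(ax$angle), lab)
  cols <- grDevices::hcl.colors(max(3, length(fps)), "Dark 3")
  for (i in seq_along(fps)) {
    vi <- verts[verts$label == (fps[[i]]$label %||% paste0("fp", i)), ]
    graphics::polygon(vi$x, vi$y, border = cols[i],
                      col = grDevices::adjustcolor(cols[i], 0.2), lwd = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols[seq_along(fps)],
                   legend = vapply(fps, function(f) f$label, ""))
  if (isTRUE(write_json) && !is.null(path))
    jsonlite::write_json(verts, paste0(path, ".json"), digits = NA,
                         dataframe = "rows")
  invisible(verts)
}

#' Write a fingerprint to JSON
#'
#' @param fp a [fingerprint()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  jsonlite::write_json(unclass(fp), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fingerprint from JSON
#'
#' @param path path written by [write_fingerprint()].
#' @return A `fingerprint`.
#' @export
read_fingerprint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "fingerprint")
}
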