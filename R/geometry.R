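# Ring geometry: circle fit, polar projection, tangential velocity.
#
# Cells are confined to a ring-shaped lane of mean radius R (50 um in the
# standard assay). All dynamics are analyzed along the tangential direction:
# with phi_i the unwrapped angular position at frame i, the per-frame arc
# displacement is R * (phi_{i+1} - phi_i), reported here as a velocity in
# um/h by dividing by the frame interval.

#' Ring geometry
#'
#' @param center numeric length-2, ring center (x, y) in micrometres.
#' @param radius ring radius in micrometres; must be positive.
#' @return An object of class `ring_geometry`.
#' @export
ring_geometry <- function(center, radius) {
  stopifnot(length(center) == 2, is.finite(radius), radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("ring: center (%.3f, %.3f) um, radius %.3f um\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Fit a circle to points by algebraic least squares
#'
#' Kasa-style linear least squares: minimizes the algebraic residual of
#' x^2 + y^2 + D x + E y + F = 0, which has a closed-form solution and is
#' accurate at the noise level of nucleus-centroid tracks on a 50-um ring.
#' Used to locate the center of the lane from the cell positions themselves.
#'
#' @param x,y point coordinates in micrometres (or `x` a 2-column matrix /
#'   data frame with columns x, y).
#' @return A [ring_geometry()] with the fitted center and radius.
#' @export
fit_circle <- function(x, y = NULL) {
  if (is.null(y)) {
    p <- as.data.frame(x)
    x <- p[[1]]; y <- p[[2]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("circle fit needs at least 3 points")
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) stopf("degenerate (collinear) points: circle fit failed")
  coefs <- qr.coef(qrA, b)
  cx <- coefs[1] / 2
  cy <- coefs[2] / 2
  r2 <- coefs[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) stopf("degenerate points: circle fit failed")
  ring_geometry(c(cx, cy), sqrt(r2))
}

#' Project a track to polar coordinates around the ring center
#'
#' Computes the radial distance r and the unwrapped angular position phi of
#' every frame. The unwrapping picks, at each step, the angular increment in
#' (-pi, pi], so that multiple revolutions accumulate in phi.
#'
#' @param track a track data frame (columns t, x, y) as stored in a
#'   [track_set()].
#' @param geometry a [ring_geometry()]; typically from [fit_circle()] or the
#'   set's geometry hint.
#' @param R_nominal radius used for arc lengths and velocities downstream.
#'   Defaults to the design radius of the micropattern when known (pass
#'   `geometry$radius` to use the fitted one instead).
#' @return An object of class `polar_track`: data frame with columns `t`,
#'   `r`, `phi`, and attributes `geometry`, `R` (the effective radius),
#'   `track_id`, `dt`.
#' @export
to_polar <- function(track, geometry, R_nominal = NULL) {
  stopifnot(inherits(geometry, "ring_geometry"))
  dx <- track$x - geometry$center[1]
  dy <- track$y - geometry$center[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0))
    stopf("track '%s': frame coincides with the ring center; angle undefined",
          attr(track, "track_id") %||% "?")
  phi_raw <- atan2(dy, dx)
  phi <- phi_raw[1] + c(0, cumsum(wrap_angle(diff(phi_raw))))
  out <- data.frame(t = track$t, r = r, phi = phi)
  attr(out, "geometry") <- geometry
  attr(out, "R") <- R_nominal %||% geometry$radius
  attr(out, "track_id") <- attr(track, "track_id") %||% "track"
  attr(out, "dt") <- attr(track, "dt") %||% mean(diff(track$t))
  class(out) <- c("polar_track", "data.frame")
  out
}

#' Tangential velocity series of a polar track
#'
#' The signed tangential velocity over frame interval i is
#' `v_i = R * (phi_{i+1} - phi_i) / dt` in um/h; counterclockwise motion is
#' positive. `v_i` is assigned to the interval starting at frame i.
#'
#' @param pt a [to_polar()] track.
#' @return Data frame of class `velocity_series` with columns `t_mid`
#'   (interval midpoint, hours) and `v` (um/h); attributes `R`, `dt`,
#'   `track_id`, `t0` (time of the first frame).
#' @export
tangential_velocity <- function(pt) {
  stopifnot(inherits(pt, "polar_track"), nrow(pt) >= 2)
  R <- attr(pt, "R")
  dt <- diff(pt$t)
  v <- R * diff(pt$phi) / dt
  out <- data.frame(t_mid = pt$t[-nrow(pt)] + dt / 2, v = v)
  attr(out, "R") <- R
  attr(out, "dt") <- attr(pt, "dt")
  attr(out, "t0") <- pt$t[1]
  attr(out, "track_id") <- attr(pt, "track_id")
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Arc-length position along the lane
#'
#' Tangential position relative to the first frame, `d_arc_i = R * (phi_i -
#' phi_0)`; one full revolution spans the ring perimeter 2*pi*R (314 um for
#' R = 50 um).
#'
#' @param pt a [to_polar()] track.
#' @return Numeric vector of arc positions in micrometres, first element 0.
#' @export
arc_distance <- function(pt) {
  stopifnot(inherits(pt, "polar_track"))
  attr(pt, "R") * (pt$phi - pt$phi[1])
}
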