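# Shared fixtures built in code.

# Track circling the origin at constant angular speed; v_tang = omega * R.
circle_track <- function(n = 60, R = 50, v = 30, dt = 1 / 6,
                         center = c(0, 0), noise = 0, phi0 = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  phi <- phi0 + v * t / R
  data.frame(t = t,
             x = center[1] + R * cos(phi) + rnorm(n, 0, noise),
             y = center[2] + R * sin(phi) + rnorm(n, 0, noise))
}

# Track built from a prescribed arc-length position series on a ring.
arc_track <- function(s, R = 50, dt = 1 / 6) {
  phi <- s / R
  data.frame(t = (seq_along(s) - 1) * dt, x = R * cos(phi), y = R * sin(phi))
}

as_set <- function(..., condition = "test", geometry = NULL) {
  trs <- list(...)
  names(trs) <- paste0("tr", seq_along(trs))
  track_set(trs, condition = condition, geometry = geometry)
}

# Exhaustive least-squares single-split oracle, applied greedily/recursively:
# returns the k split indices that successively maximize the drop in the
# residual sum of squares about segment means.
ls_split_oracle <- function(x, k, min_len = 3) {
  best_split <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_len) return(NULL)
    seg <- x[lo:hi]
    rss0 <- sum((seg - mean(seg))^2)
    cand <- min_len:(n - min_len)
    rss <- vapply(cand, function(b) {
      l <- seg[1:b]; r <- seg[(b + 1):n]
      sum((l - mean(l))^2) + sum((r - mean(r))^2)
    }, 0)
    b <- cand[which.min(rss)]
    list(idx = lo + b - 1, gain = rss0 - min(rss))
  }
  splits <- integer(0)
  open <- list(c(1L, length(x)))
  for (i in seq_len(k)) {
    props <- lapply(open, function(r) best_split(r[1], r[2]))
    ok <- !vapply(props, is.null, TRUE)
    if (!any(ok)) break
    gains <- vapply(props[ok], function(p) p$gain, 0)
    pick <- which(ok)[which.max(gains)]
    b <- props[[pick]]$idx
    rng <- open[[pick]]
    open[[pick]] <- NULL
    open <- c(open, list(c(rng[1], b)), list(c(b + 1L, rng[2])))
    splits <- c(splits, b)
  }
  sort(splits)
}
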