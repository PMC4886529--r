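test_that("circle fit recovers exact and noisy circles", {
  g <- fit_circle(c(50, 0, -50, 0), c(0, 50, 0, -50))
  expect_equal(g$center, c(0, 0), tolerance = 1e-9)
  expect_equal(g$radius, 50, tolerance = 1e-9)

  # noisy ring vs full nonlinear geometric least squares oracle
  set.seed(42)
  th <- runif(200, 0, 2 * pi)
  x <- 10 + 50 * cos(th) + rnorm(200)
  y <- -5 + 50 * sin(th) + rnorm(200)
  g2 <- fit_circle(x, y)
  oracle <- optim(c(mean(x), mean(y), 50), function(p)
    sum((sqrt((x - p[1])^2 + (y - p[2])^2) - p[3])^2),
    method = "BFGS")$par
  expect_lt(sqrt(sum((g2$center - oracle[1:2])^2)), 0.5)
  expect_lt(abs(g2$radius - oracle[3]), 0.5)

  expect_error(fit_circle(1:10, 2 * (1:10) + 3), "collinear")
})

test_that("polar projection is exact and invertible", {
  tr <- circle_track(n = 200, v = 31, noise = 0.5, seed = 2)
  g <- ring_geometry(c(0, 0), 50)
  pt <- to_polar(tr, g)
  # inverse transform reproduces the input to 1e-9 um
  expect_equal(pt$r * cos(pt$phi), tr$x, tolerance = 1e-9)
  expect_equal(pt$r * sin(pt$phi), tr$y, tolerance = 1e-9)
  # unwrapping continuity
  expect_true(all(abs(diff(pt$phi)) < pi))

  # one full revolution spans 2*pi in phi and the 314-um perimeter in arc
  n_rev <- ceiling(2 * pi * 50 / (30 / 6)) + 1
  tr2 <- circle_track(n = n_rev, v = 30)
  pt2 <- to_polar(tr2, g)
  expect_equal(abs(pt2$phi[n_rev] - pt2$phi[1]), 2 * pi,
               tolerance = 0.02)
  expect_equal(max(abs(arc_distance(pt2))), 2 * pi * 50, tolerance = 1)

  # a frame at the center has no defined angle
  bad <- data.frame(t = c(0, 1 / 6), x = c(0, 1), y = c(0, 0))
  expect_error(to_polar(bad, g), "center")
})

test_that("tangential velocity implements v = R * dphi / dt", {
  g <- ring_geometry(c(0, 0), 50)
  # hand evaluation: dphi = 0.01 rad per 10-min frame at R = 50 -> 3 um/h
  s <- cumsum(c(0, rep(0.01 * 50, 10)))
  vs <- tangential_velocity(to_polar(arc_track(s), g, R_nominal = 50))
  expect_equal(vs$v, rep(3, 10), tolerance = 1e-9)

  # uniform rotation at 30 um/h
  tr <- circle_track(n = 100, v = 30)
  vs2 <- tangential_velocity(to_polar(tr, g, R_nominal = 50))
  expect_equal(vs2$v, rep(30, 99), tolerance = 1e-9)

  # stationary cell
  still <- arc_track(rep(5, 20))
  expect_equal(tangential_velocity(to_polar(still, g))$v, rep(0, 19),
               tolerance = 1e-9)
})

test_that("arc distance telescopes the velocity and starts at zero", {
  g <- ring_geometry(c(0, 0), 50)
  set.seed(3)
  s <- cumsum(rnorm(150, 0, 3))
  pt <- to_polar(arc_track(s - s[1]), g, R_nominal = 50)
  d <- arc_distance(pt)
  v <- tangential_velocity(pt)$v
  expect_equal(d[1], 0)
  expect_equal(diff(d), v * (1 / 6), tolerance = 1e-9)
})

test_that("velocity is invariant under rigid rotation about the center", {
  g <- ring_geometry(c(0, 0), 50)
  tr <- circle_track(n = 80, v = 25, noise = 0.3, seed = 9)
  v0 <- tangential_velocity(to_polar(tr, g, R_nominal = 50))$v
  for (a in c(0.7, 2.1, -1.3)) {
    rot <- data.frame(t = tr$t,
                      x = tr$x * cos(a) - tr$y * sin(a),
                      y = tr$x * sin(a) + tr$y * cos(a))
    va <- tangential_velocity(to_polar(rot, g, R_nominal = 50))$v
    expect_equal(va, v0, tolerance = 1e-9)
  }
})
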