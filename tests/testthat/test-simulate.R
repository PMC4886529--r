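test_that("degenerate parameters give a stationary track", {
  p <- sim_params(v_run = 0, D = 0, noise = 0, seed = 2, duration = 6)
  s <- simulate_track(p)
  expect_equal(diff(range(s$track$x)), 0, tolerance = 1e-12)
  expect_equal(diff(range(s$track$y)), 0, tolerance = 1e-12)
})

test_that("same seed and parameters reproduce tracks bit-exactly", {
  p <- sim_params(seed = 99, duration = 12)
  a <- simulate_tracks(p, 4)
  b <- simulate_tracks(p, 4)
  expect_identical(a$tracks$tracks, b$tracks$tracks)
  expect_identical(a$truth, b$truth)
  # per-track substreams: requesting more tracks preserves earlier ones
  c6 <- simulate_tracks(p, 6)
  expect_identical(c6$tracks$tracks[["sim3"]], a$tracks$tracks[["sim3"]])
  # invasion depths likewise
  expect_identical(simulate_invasion_depths(5, seed = 7),
                   simulate_invasion_depths(5, seed = 7))
})

test_that("time spent running matches the renewal-theory fraction", {
  p <- sim_params(seed = 23, duration = 48)
  s <- simulate_tracks(p, 500)
  frac <- mean(unlist(s$frame_state) == "run")
  expected <- 13.6 / (13.6 + 6.5)
  # 3 standard errors over the track ensemble
  per_track <- vapply(s$frame_state, function(z) mean(z == "run"), 0)
  se <- sd(per_track) / sqrt(length(per_track))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("generated dwell times are exponential (KS at alpha = 0.01)", {
  p <- sim_params(seed = 31, duration = 400)
  s <- simulate_tracks(p, 40)
  dw <- do.call(rbind, s$truth)
  run_dwell <- dw$dwell_h[dw$label == "run"]
  rest_dwell <- dw$dwell_h[dw$label == "rest"]
  expect_gt(length(run_dwell), 300)
  expect_gt(ks.test(run_dwell, "pexp", 1 / 13.6)$p.value, 0.01)
  expect_gt(ks.test(rest_dwell, "pexp", 1 / 6.5)$p.value, 0.01)
})

test_that("default acquisition matches the assay: 10-min frames, 50-um ring", {
  p <- sim_params(seed = 1)
  expect_equal(p$dt, 1 / 6)
  expect_equal(p$R, 50)
  s <- simulate_track(p)
  expect_equal(diff(s$track$t)[1], 1 / 6, tolerance = 1e-9)
  r <- sqrt(s$track$x^2 + s$track$y^2)
  expect_lt(abs(median(r) - 50), 2)
})

test_that("barrier encounters follow the configured transit mechanism", {
  # open gap with no spontaneous turning: every encounter is a transit
  p <- sim_params(seed = 3, noise = 0.5)
  bd0 <- simulate_barrier_dataset(p, d_gap = 0,
                                  mech = mechanism_bernoulli(8.3, 0),
                                  n_encounters = 50)
  expect_true(all(bd0$outcomes == "transit"))

  # Bernoulli mechanism at d_gap = 8: transit fraction within the
  # Clopper-Pearson CI of the model probability
  bd <- simulate_barrier_dataset(p, d_gap = 8,
                                 mech = mechanism_bernoulli(8.3, 0.2),
                                 n_encounters = 300)
  k <- sum(bd$outcomes == "transit")
  ci <- binom.test(k, length(bd$outcomes))$conf.int
  expected <- 0.8 * exp(-8 / 8.3)
  expect_true(ci[1] <= expected && expected <= ci[2])

  # cells meet the barrier repeatedly
  b <- bd$barrier
  g <- bd$tracks$geometry
  n_enc <- vapply(bd$tracks$tracks, function(tr)
    nrow(detect_encounters(to_polar(tr, g, 50), b)), 0L)
  expect_gt(max(n_enc), 1)
})

test_that("invasion depth sampler respects its support and survival law", {
  d <- simulate_invasion_depths(5000, 11.8, seed = 12)
  expect_gte(min(d), 2)
  expect_lte(max(d), 30)
  # survival at interior points matches s0 * exp(-d / mu) within 3 SE
  for (x in c(5, 10, 20)) {
    p_hat <- mean(d > x)
    p_true <- exp(-x / 11.8)
    expect_lt(abs(p_hat - p_true),
              3 * sqrt(p_true * (1 - p_true) / 5000))
  }
})
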