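polar_from_arc <- function(s, R = 50) {
  to_polar(arc_track(s, R = R), ring_geometry(c(0, 0), R), R)
}

test_that("encounters open, close and classify at the 50-um zone", {
  b <- barrier_spec(angle = 0, d_gap = 0, zone_half_width = 50)
  # never approaches the zone (stays near the antipode)
  far <- polar_from_arc(seq(140, 160, length.out = 30))
  expect_equal(nrow(detect_encounters(far, b)), 0)

  # monotone crossing: one encounter, transit
  cross <- polar_from_arc(seq(-80, 80, by = 5))
  enc <- detect_encounters(cross, b)
  expect_equal(nrow(enc), 1)
  expect_identical(enc$outcome, "transit")
  expect_true(enc$entry_side != enc$exit_side)

  # scripted: two reversals then a transit, in order
  path <- c(seq(-150, -30, by = 5), seq(-35, -150, by = -5),
            seq(-145, -20, by = 5), seq(-25, -150, by = -5),
            seq(-145, 150, by = 5))
  enc3 <- detect_encounters(polar_from_arc(path), b)
  expect_identical(enc3$outcome, c("reversal", "reversal", "transit"))

  # track ending inside the zone leaves a censored encounter
  stop_in <- polar_from_arc(seq(-80, -10, by = 5))
  encc <- detect_encounters(stop_in, b)
  expect_identical(encc$outcome, "censored")
  expect_true(is.na(encc$exit_frame))
})

test_that("turning probability uses the exact Clopper-Pearson interval", {
  mk <- function(k, n) data.frame(outcome = rep(c("reversal", "transit"),
                                                c(k, n - k)))
  tp0 <- turning_probability(mk(0, 10))
  expect_equal(tp0$p_turn, 0)
  # independent beta-quantile form of the Clopper-Pearson bounds
  expect_equal(tp0$ci, c(0, qbeta(0.975, 1, 10)), tolerance = 1e-6)
  expect_equal(tp0$ci[2], 0.308, tolerance = 2e-3)

  tp5 <- turning_probability(mk(5, 10))
  expect_equal(tp5$p_turn, 0.5)
  expect_equal(tp5$ci,
               c(qbeta(0.025, 5, 6), qbeta(0.975, 6, 5)), tolerance = 1e-6)
  expect_equal(tp5$ci, c(0.187, 0.813), tolerance = 2e-3)

  # point estimate always inside the interval; censored excluded
  enc <- rbind(mk(3, 9), data.frame(outcome = "censored"))
  tp <- turning_probability(enc)
  expect_equal(tp$n, 9)
  expect_true(tp$ci[1] <= tp$p_turn && tp$p_turn <= tp$ci[2])
  expect_error(turning_probability(data.frame(outcome = "censored")),
               "no non-censored")
})

test_that("Clopper-Pearson intervals reach nominal coverage at n = 20", {
  set.seed(77)
  for (p in c(0.1, 0.5, 0.9)) {
    k <- rbinom(2000, 20, p)
    cis <- vapply(k, function(ki)
      as.numeric(binom.test(ki, 20)$conf.int), numeric(2))
    cover <- mean(cis[1, ] <= p & p <= cis[2, ])
    expect_gte(cover, 0.95)
  }
})

test_that("spontaneous turning is zero for ballistic cells and pools 8 zones", {
  # three full revolutions, never reversing
  n <- ceiling(3 * 2 * pi * 50 / 5) + 1
  ball <- polar_from_arc(seq(0, by = 5, length.out = n))
  st <- spontaneous_turning(list(ball))
  expect_equal(st$p_turn0, 0)
  expect_equal(nrow(st$per_region), 8)
  expect_true(all(st$per_region$n > 0))
  expect_lt(st$ci[1], 1e-9)
})

test_that("scripted zone reversal probability is recovered within its CI", {
  p <- sim_params(seed = 13, noise = 0.5)
  bd <- simulate_barrier_dataset(p, d_gap = 0,
                                 mech = mechanism_bernoulli(8.3, 0.3),
                                 n_encounters = 150)
  expect_gte(length(bd$outcomes), 150)
  tp <- binom.test(sum(bd$outcomes == "reversal"), length(bd$outcomes))
  expect_true(tp$conf.int[1] <= 0.3 && 0.3 <= tp$conf.int[2])
})

test_that("transit decay length is recovered exactly from noiseless data", {
  d <- c(3, 8, 13, 19)
  tc <- structure(data.frame(d_gap = d, n = 1000,
                             n_transits = NA, p_trans = 0.8 * exp(-d / 8),
                             ci_lo = NA, ci_hi = NA),
                  class = c("transit_curve", "data.frame"))
  fit <- fit_transit_decay(tc, p_turn0 = 0.2)
  expect_equal(fit$mu_trans, 8, tolerance = 1e-6)
  # fitted model is strictly decreasing in the gap width
  pr <- (1 - 0.2) * exp(-seq(0, 30, 5) / fit$mu_trans)
  expect_true(all(diff(pr) < 0))
  # two-parameter variant agrees on exact data
  fit2 <- fit_transit_decay(tc, p_turn0 = 0.2, fixed_intercept = FALSE)
  expect_equal(fit2$mu_trans, 8, tolerance = 1e-4)
  expect_error(fit_transit_decay(transform(tc, p_trans = 0), 0.2),
               "zero")
})

test_that("P_turn and P_trans are complementary at every width", {
  mech <- mechanism_bernoulli(8.3, 0.2)
  sim <- simulate_encounter_outcomes(c(3, 8, 13, 19), 200, mech, seed = 21)
  tc <- transit_curve(sim)
  for (i in seq_len(nrow(tc))) {
    tp <- 1 - tc$p_trans[i]
    expect_equal(tp + tc$p_trans[i], 1)
  }
  expect_true(all(tc$p_trans >= 0 & tc$p_trans <= 1))
})

test_that("state occupancy near a barrier favours rests", {
  # all-run tracks: run frequency 1 in every bin
  b <- barrier_spec(0, 8, 50)
  tr <- circle_track(n = 150, v = 30, noise = 0.2, seed = 31)
  pt <- to_polar(tr, ring_geometry(c(0, 0), 50), 50)
  seg <- segment_track(pt, seg_config(seed = 1))
  attr(pt, "track_id") <- seg$track_id[1]
  prof <- state_occupancy_profile(seg, setNames(list(pt), seg$track_id[1]), b)
  expect_true(all(prof$f_run == 1))
  expect_true(all(abs(prof$f_run + prof$f_rest - 1) < 1e-9))

  # barrier dataset: reversals rest at the barrier, enriching rests nearby
  p <- sim_params(seed = 41, noise = 0.5)
  bd <- simulate_barrier_dataset(p, d_gap = 13,
                                 mech = mechanism_bernoulli(8.3, 0.2),
                                 n_encounters = 60)
  segb <- segment_tracks(bd$tracks)
  profb <- state_occupancy_profile(segb, attr(segb, "polar"), bd$barrier,
                                   bin_width = 25)
  near <- profb$dist_mid < 50
  expect_gt(mean(profb$f_rest[near]), mean(profb$f_rest[!near]))
  expect_true(all(abs(profb$f_run + profb$f_rest - 1) < 1e-9))
})

test_that("invasion-depth survival fit recovers exact and sampled laws", {
  # noiseless grid: empirical survival lies exactly on s0 * exp(-d / mu)
  n <- 200
  d <- c(-11.8 * log((n - (1:(n - 1))) / n), -11.8 * log(0.5 / n))
  fit <- fit_invasion_survival(d)
  expect_equal(fit$mu_inv, 11.8, tolerance = 1e-6)
  expect_equal(fit$s0, 1, tolerance = 1e-6)

  depths <- simulate_invasion_depths(5000, 11.8, seed = 5)
  expect_true(all(depths >= 2 & depths <= 30))
  fit2 <- fit_invasion_survival(depths)
  expect_lt(abs(fit2$mu_inv - 11.8) / 11.8, 0.05)

  expect_error(fit_invasion_survival(rep(5, 20)), "degenerate")
  expect_error(fit_invasion_survival(1:5), "at least 10")
})

test_that("invasion mechanism links transit probability to depth survival", {
  mech <- mechanism_invasion(11.8, s0 = 1)
  sim <- simulate_encounter_outcomes(c(3, 8, 13, 19), 400, mech, seed = 8)
  tc <- transit_curve(sim)
  for (i in seq_len(nrow(tc))) {
    expected <- exp(-tc$d_gap[i] / 11.8)   # P(d_inv > d_gap)
    expect_true(tc$ci_lo[i] <= expected && expected <= tc$ci_hi[i])
  }
})
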