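test_that("delimited track files are parsed, validated and round-tripped", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(track_id = rep(c("a", "b"), each = 10),
                   t_h = rep((0:9) / 6, 2),
                   x_um = c(50 * cos((0:9) / 10), 50 * cos((0:9) / 8)),
                   y_um = c(50 * sin((0:9) / 10), 50 * sin((0:9) / 8)))
  write.csv(df, f, row.names = FALSE)
  ts <- read_tracks(f)
  expect_s3_class(ts, "track_set")
  expect_length(ts, 2)
  expect_equal(nrow(ts$tracks[["a"]]), 10)
  expect_equal(ts$tracks[["b"]]$x, df$x_um[11:20])

  # missing column is a configuration error
  expect_error(read_tracks(f, track_format(x = "xpos")), "missing column")

  # duplicated (id, t) row is a validation error naming the track
  bad <- rbind(df, df[1, ])
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_tracks(f2), "'a'.*duplicated")

  # write -> read reproduces positions to 1e-9 um
  sim <- simulate_tracks(sim_params(seed = 4, duration = 6), 3)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, f3)
  back <- read_tracks(f3)
  for (id in names(sim$tracks$tracks)) {
    expect_equal(back$tracks[[id]]$x, sim$tracks$tracks[[id]]$x,
                 tolerance = 1e-9)
    expect_equal(back$tracks[[id]]$y, sim$tracks$tracks[[id]]$y,
                 tolerance = 1e-9)
  }
})

test_that("YAML format configuration maps columns and units", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(cell = "c1", time_min = (0:5) * 10,
                   X = 1:6, Y = rep(2, 6))
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- withr::local_tempfile(fileext = ".yaml")
  # note the quoting: bare y/Y are YAML 1.1 booleans
  writeLines(c("id: cell", "t: time_min", "x: X", "\"y\": \"Y\"",
               "sep: \"\\t\"", "t_scale: 0.016666666666666666"), cfg)
  ts <- read_tracks(f, cfg)
  expect_equal(ts$tracks[["c1"]]$t, (0:5) / 6, tolerance = 1e-9)
  expect_equal(ts$tracks[["c1"]]$x, 1:6)
})

test_that("filtering excludes short and non-moving tracks with reasons", {
  short <- circle_track(n = floor(17.9 * 6) + 1, v = 30)      # 17.9 h < 18 h
  still <- data.frame(t = (0:288) / 6, x = rep(10, 289), y = rep(0, 289))
  good <- circle_track(n = 289, v = 30)                        # 48 h mover
  ts <- track_set(list(short = short, still = still, good = good))
  out <- filter_tracks(ts)
  ex <- attr(out, "exclusions")
  expect_setequal(names(out$tracks), "good")
  expect_equal(ex$reason[ex$track_id == "short"], "duration")
  expect_equal(ex$reason[ex$track_id == "still"], "non-moving")
  # retained + excluded = input
  expect_equal(length(out) + nrow(ex), length(ts))
  # idempotent
  out2 <- filter_tracks(out)
  expect_identical(names(out2$tracks), names(out$tracks))
  expect_equal(nrow(attr(out2, "exclusions")), 0)
})

test_that("simulated motile 48-h tracks all pass the default filter", {
  sim <- simulate_tracks(sim_params(seed = 11), 100)
  out <- filter_tracks(sim$tracks)
  expect_length(out, 100)
  expect_equal(nrow(attr(out, "exclusions")), 0)
})

test_that("track validation enforces the invariants", {
  expect_error(track_set(list(a = data.frame(t = 0, x = 1, y = 1))),
               "at least 2 frames")
  expect_error(
    track_set(list(a = data.frame(t = c(0, 1 / 6, 1 / 6 + 0.01),
                                  x = 1:3, y = 1:3))),
    "not uniform")
  expect_warning(filter_tracks(as_set(circle_track(n = 10)), 18), "no tracks")
})
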