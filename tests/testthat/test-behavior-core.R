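test_that("behavior_session validates its invariants", {
  s <- behavior_session(time = c(0, 1, 2) / 30, position = c(0, 5, 10),
                        velocity = c(150, 150, 150))
  expect_s3_class(s, "behavior_session")
  expect_equal(s$n_frames, 3L)
  expect_equal(nrow(s$events), 0L)

  t_bad <- (0:19) / 30
  t_bad[10] <- t_bad[8]
  expect_error(
    behavior_session(t_bad, position = rep(1, 20), velocity = rep(1, 20)),
    "frame 10")
  expect_error(
    behavior_session(c(0, 1), position = c(0, 300), velocity = c(1, 1)),
    "position")
})

test_that("read_session applies schemas and reports missing columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("t,x,v,ctx", "0,0,10,A", "0.033,1,10,A", "0.066,2,10,A"), f)
  s <- read_session(f, schema = list(time = "t", position = "x",
                                     velocity = "v", context = "ctx"))
  expect_equal(s$n_frames, 3L)
  expect_equal(s$context_id, "A")
  expect_error(read_session(f, schema = list(position = "x",
                                             velocity = "v",
                                             context = "ctx")),
               "schema error.*time")

  # schema supplied as a YAML mapping file, with an event channel
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("T,P,V,C,SH", "0,0,10,A,0", "0.033,1,10,A,1",
               "0.066,2,0,A,0"), f2)
  y <- tempfile(fileext = ".yml")
  writeLines(c("time: T", "position: P", "velocity: V", "context: C",
               "shock: SH"), y)
  s2 <- read_session(f2, schema = y)
  expect_equal(s2$n_frames, 3L)
  expect_equal(s2$events$frame[s2$events$kind == "shock"], 2L)
})

test_that("write_session / read_session round-trips a synthetic session", {
  p <- behavior_sim_params(session_duration = 60,
                           shock_times = c(20, 30), seed = 101)
  s <- simulate_session(p)$session
  f <- tempfile(fileext = ".csv")
  write_session(s, f)
  s2 <- read_session(f, frame_rate = s$frame_rate)
  expect_equal(s2$time, s$time, tolerance = 1e-9)
  expect_equal(s2$position, s$position, tolerance = 1e-9)
  expect_equal(s2$velocity, s$velocity, tolerance = 1e-9)
  expect_equal(s2$context_id, s$context_id)
  expect_equal(s2$events[order(s2$events$kind, s2$events$frame), ],
               s$events[order(s$events$kind, s$events$frame), ],
               ignore_attr = TRUE)
})

test_that("segment_laps counts completed traversals and excludes the pause", {
  s <- make_sawtooth_session(n_laps = 3, lap_frames = 120,
                             pause_frames = 45)
  laps <- segment_laps(s, teleport_pause = 1.5)
  expect_equal(nrow(laps), 3L)
  expect_equal(laps$n_frames, rep(120L, 3))
  expect_equal(laps$duration_s, rep(119 / 30, 3), tolerance = 1e-9)
  expect_true(all(diff(laps$start_frame) == 165L))

  # incomplete final traversal is not a lap
  s2 <- make_sawtooth_session(n_laps = 2, lap_frames = 120)
  half <- behavior_session(s2$time[1:180], s2$position[1:180],
                           s2$velocity[1:180], frame_rate = 30)
  l2 <- segment_laps(half, teleport_pause = 0)
  expect_equal(nrow(l2), 1L)
  expect_gt(attr(l2, "incomplete_frames"), 0L)

  # no position change: empty table, not an error
  flat <- behavior_session((0:99) / 30, rep(50, 100), rep(0, 100))
  expect_equal(nrow(segment_laps(flat)), 0L)
})

test_that("a 10-minute session with 31 laps runs at 3.1 laps per minute", {
  # the training criterion for advancement was >3 laps per minute
  lap_frames <- 575L
  s <- make_sawtooth_session(n_laps = 31, lap_frames = lap_frames,
                             pause_frames = 5)
  stopifnot(s$n_frames == 31 * 580)  # 17980 frames ~ 10 min at 30 Hz
  laps <- segment_laps(s, teleport_pause = 5 / 30)
  m <- session_metrics(s, laps, detect_freezing(s))
  expect_equal(m$n_laps, 31L)
  expect_equal(m$laps_per_minute, 31 / (s$n_frames / 30 / 60),
               tolerance = 1e-9)
  expect_equal(round(m$laps_per_minute, 1), 3.1)
  expect_gt(m$laps_per_minute, 3)
})

test_that("lap segmentation matches the brute-force scan on random walks", {
  set.seed(401)
  for (rep in 1:25) {
    pos <- pmin(pmax(cumsum(rnorm(600, mean = 2, sd = 8)), 0), 200)
    s <- behavior_session((seq_along(pos) - 1) / 30, pos,
                          velocity = c(0, diff(pos)) * 30)
    laps <- segment_laps(s, teleport_pause = 0)
    expect_equal(nrow(laps), oracle_lap_count(pos))
  }
})

test_that("freezing detection follows the velocity definition exactly", {
  s <- behavior_session((0:4) / 30, rep(1, 5), c(0, 0.2, 0, -3, 0))
  expect_equal(detect_freezing(s, epsilon = 0),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
  szero <- behavior_session((0:9) / 30, rep(1, 10), rep(0, 10))
  expect_true(all(detect_freezing(szero)))
  set.seed(402)
  v <- rnorm(500, 0, 0.1)
  sr <- behavior_session((seq_along(v) - 1) / 30, rep(1, 500), v)
  expect_equal(detect_freezing(sr, epsilon = 0.05), abs(v) <= 0.05)
})

test_that("freezing epochs are strictly longer than the minimum duration", {
  m30 <- c(rep(FALSE, 5), rep(TRUE, 30), rep(FALSE, 5))
  expect_equal(nrow(freezing_epochs(m30, 30)), 0L)  # exactly 1.0 s
  m31 <- c(rep(FALSE, 5), rep(TRUE, 31), rep(FALSE, 5))
  ep <- freezing_epochs(m31, 30)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start_frame, 6L)
  expect_equal(ep$duration_s, 31 / 30)
  expect_equal(nrow(freezing_epochs(rep(FALSE, 100), 30)), 0L)
})

test_that("freezing epochs match the run-length oracle on random masks", {
  set.seed(403)
  for (rep in 1:25) {
    mask <- runif(400) < 0.6
    expect_equal(freezing_epochs(mask, 30),
                 oracle_epochs(mask, 30), ignore_attr = TRUE)
  }
  # invariant: padding with non-freezing frames changes nothing
  mask <- runif(200) < 0.5
  expect_equal(freezing_epochs(c(rep(FALSE, 17), mask, rep(FALSE, 9)), 30)$duration_s,
               freezing_epochs(mask, 30)$duration_s)
})

test_that("session metrics implement the per-lap freezing formula", {
  # one lap of 300 frames with 30 freezing frames -> 10%
  ramp <- seq(0, 200, length.out = 300)
  v <- rep(20, 300); v[101:130] <- 0
  s <- behavior_session((0:299) / 30, ramp, v)
  laps <- segment_laps(s, teleport_pause = 0)
  m <- session_metrics(s, laps, detect_freezing(s))
  expect_equal(m$n_laps, 1L)
  expect_equal(m$first_lap_freezing_pct, 10)
  # single lap: averages equal first-lap values
  expect_equal(m$avg_freezing_pct, m$first_lap_freezing_pct)
  expect_equal(m$avg_lap_time, m$first_lap_time)

  # zero laps: undefined, not zero
  flat <- behavior_session((0:99) / 30, rep(50, 100), rep(0, 100))
  mf <- session_metrics(flat, segment_laps(flat), detect_freezing(flat))
  expect_false(mf$defined)
  expect_true(is.na(mf$avg_freezing_pct))
})

test_that("simulated sessions recover the ground-truth freezing fraction", {
  r <- freezing_rates(0.2)
  p <- behavior_sim_params(session_duration = 600,
                           p_run_to_freeze = r$p_run_to_freeze,
                           p_freeze_to_run = r$p_freeze_to_run,
                           backward_prob = 0, seed = 404)
  sim <- simulate_session(p)
  laps <- segment_laps(sim$session)
  mask <- detect_freezing(sim$session)
  m <- session_metrics(sim$session, laps, mask)
  # frame-weighted freezing within laps matches the latent state fraction
  frame_weighted <- 100 * sum(m$per_lap$freezing_frames) /
    sum(m$per_lap$n_frames)
  expect_lt(abs(frame_weighted - 100 * sim$truth$freezing_fraction), 1)
  # per-lap freezing frames never exceed the mask total
  expect_lte(sum(m$per_lap$freezing_frames), sum(mask))
})

test_that("discrimination delta is the CFC-minus-neutral difference", {
  mk <- function(x) structure(list(avg_freezing_pct = x, defined = TRUE),
                              class = "session_metrics")
  expect_equal(discrimination_delta(mk(5), mk(5)), 0)
  expect_equal(discrimination_delta(mk(21.15), mk(20.54)), 0.61)
  set.seed(405)
  for (i in 1:10) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    expect_equal(discrimination_delta(mk(a), mk(b)), a - b)
  }
  undef <- structure(list(avg_freezing_pct = NA_real_, defined = FALSE),
                     class = "session_metrics")
  expect_true(is.na(discrimination_delta(undef, mk(1))))
})

test_that("lap counts are invariant to uniform time rescaling", {
  p <- behavior_sim_params(session_duration = 120, seed = 406)
  s <- simulate_session(p)$session
  laps <- segment_laps(s, teleport_pause = 1.5)
  s2 <- behavior_session(s$time * 2, s$position, s$velocity,
                         frame_rate = s$frame_rate / 2)
  laps2 <- segment_laps(s2, teleport_pause = 3)
  expect_equal(nrow(laps2), nrow(laps))
  expect_equal(laps2$duration_s, laps$duration_s * 2, tolerance = 1e-9)
})

test_that("shock responses quantify the post-shock sprint", {
  # constant velocity: all differences zero, not responsive
  ev <- data.frame(frame = c(301L, 601L), kind = "shock")
  s <- behavior_session((0:899) / 30, rep(1, 900), rep(10, 900),
                        events = ev)
  sr <- shock_response(s, window = 5)
  expect_equal(nrow(sr), 2L)
  expect_equal(sr$speed_change, c(0, 0))
  expect_false(attr(sr, "responsive"))

  # a shock too close to the session edge is excluded with a warning
  ev2 <- data.frame(frame = c(30L, 450L), kind = "shock")
  s2 <- behavior_session((0:899) / 30, rep(1, 900), rep(10, 900),
                         events = ev2)
  expect_warning(sr2 <- shock_response(s2, window = 5), "excluded")
  expect_equal(nrow(sr2), 1L)
  expect_equal(attr(sr2, "n_excluded"), 1L)

  expect_error(shock_response(make_sawtooth_session()), "no shock")
})

test_that("six shocks at one-minute intervals yield six sprint records", {
  shocks <- 120 + 60 * (0:5)
  p <- behavior_sim_params(session_duration = 600, shock_times = shocks,
                           shock_sprint_amplitude = 20,
                           shock_sprint_decay = 1, seed = 407)
  sim <- simulate_session(p)
  sr <- shock_response(sim$session, window = 5)
  expect_equal(nrow(sr), 6L)
  expect_true(attr(sr, "responsive"))
  # mean speed change reflects the configured sprint amplitude: the mean of
  # a 20 cm/s sprint decaying with tau = 1 s over a 5 s window is ~20/5
  expected <- 20 * 1 * (1 - exp(-5)) / 5
  expect_lt(abs(mean(sr$speed_change) - expected) / expected, 0.5)
})
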