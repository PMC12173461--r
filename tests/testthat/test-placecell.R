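# deterministic multi-lap session shared by several blocks
pc_session <- function(n_laps = 10, lap_frames = 200, pause_frames = 15) {
  make_sawtooth_session(n_laps = n_laps, lap_frames = lap_frames,
                        pause_frames = pause_frames)
}

test_that("position binning follows the half-open 5 cm convention", {
  s <- pc_session(n_laps = 2)
  laps <- segment_laps(s, teleport_pause = 0.5)
  dff <- matrix(s$position / 200, 1)  # trace encodes position
  map <- bin_activity(dff, s, laps)
  expect_equal(map$bin_width, 5)
  # position 7.5 cm falls in bin index 1 (0-based); 200 cm in bin 39
  bw <- map$bin_width
  bin_of <- function(p) pmin(floor(p / bw), 39) # 0-based
  expect_equal(bin_of(7.5), 1)
  expect_equal(bin_of(200), 39)
  # the final closed bin is observed on every lap (position reaches 200)
  expect_true(all(is.finite(map$map[1, , 40])))
})

test_that("binning a constant trace yields the constant everywhere observed", {
  s <- pc_session(n_laps = 3)
  laps <- segment_laps(s, teleport_pause = 0.5)
  map <- bin_activity(matrix(0.7, 2, s$n_frames), s, laps)
  obs <- !is.na(map$map)
  expect_true(all(abs(map$map[obs] - 0.7) < 1e-12))
  # occupancy sums to the speed-included frame count within laps
  included <- sum(vapply(seq_len(nrow(laps)), function(i) {
    fr <- laps$start_frame[i]:laps$end_frame[i]
    sum(abs(s$velocity[fr]) >= 1)
  }, numeric(1)))
  expect_equal(sum(map$occupancy), included)
})

test_that("binned maps equal the brute-force per-(cell,lap,bin) oracle", {
  set.seed(601)
  s <- pc_session(n_laps = 4, lap_frames = 150)
  laps <- segment_laps(s, teleport_pause = 0.5)
  for (rep in 1:3) {
    dff <- matrix(rnorm(3 * s$n_frames), 3)
    map <- bin_activity(dff, s, laps, n_bins = 8)
    oracle <- oracle_bin_activity(dff, s, laps, n_bins = 8,
                                  speed_threshold = 1)
    expect_equal(map$map, oracle, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("immobile-frame activity cannot influence the map", {
  p <- behavior_sim_params(session_duration = 120, seed = 602)
  s <- simulate_session(p)$session
  laps <- segment_laps(s)
  set.seed(603)
  dff <- matrix(rnorm(2 * s$n_frames), 2)
  map1 <- bin_activity(dff, s, laps)
  dff2 <- dff
  immobile <- abs(s$velocity) < 1
  dff2[, immobile] <- dff2[, immobile] + matrix(rnorm(2 * sum(immobile), 0, 50),
                                                2)
  map2 <- bin_activity(dff2, s, laps)
  expect_identical(map1$map, map2$map)
})

test_that("transient detection finds injected events and ignores flat traces", {
  fr <- 30
  x <- numeric(900)
  x[300:330] <- exp(-(0:30) / (0.5 * fr))  # amplitude 1, decay 0.5 s
  noise <- numeric(900)
  tr <- detect_transients(rbind(x, noise), fr)
  tr <- tr[tr$cell == 1, ]
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$onset_frame, 300L)
  expect_equal(tr$peak_dff, 1)
  expect_equal(nrow(detect_transients(matrix(0, 1, 900), fr)), 0L)
})

test_that("false transient rate on pure noise stays below 0.02 events/s", {
  set.seed(604)
  n_cells <- 40; n_frames <- 3000
  dff <- matrix(rnorm(n_cells * n_frames, 0, 0.2), n_cells)
  tr <- detect_transients(dff, 30, k = 2, min_dur = 0.5)
  rate <- nrow(tr) / (n_cells * n_frames / 30)
  expect_lt(rate, 0.02)
})

test_that("transient onsets are recovered from simulated event traces", {
  p <- behavior_sim_params(session_duration = 240, seed = 605)
  s <- simulate_session(p)$session
  # non-place cells emit instant-rise/exponential-decay events: SNR 5
  cp <- calcium_sim_params(30, frac_place_cells = 0, amplitude = 1,
                           noise_sd = 0.2, reliability = 0.3, seed = 606)
  sim <- simulate_traces(s, cp)
  det <- detect_transients(sim$dff, s$frame_rate)
  truth <- sim$truth$events
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    d <- det[det$cell == truth$cell[i], ]
    any(abs(d$onset_frame - truth$onset_frame[i]) <= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("candidate fields are contiguous supra-baseline runs", {
  expect_equal(nrow(candidate_fields(rep(0.5, 40))), 0L)  # flat map
  g1 <- 0.1 + 3 * exp(-((1:40) - 20)^2 / (2 * 4^2))
  c1 <- candidate_fields(g1)
  expect_equal(nrow(c1), 1L)
  expect_true(c1$start_bin <= 20 && c1$end_bin >= 20)
  g2 <- 0.1 + 3 * exp(-((1:40) - 10)^2 / 8) + 2 * exp(-((1:40) - 30)^2 / 8)
  c2 <- candidate_fields(g2)
  expect_equal(nrow(c2), 2L)  # multiple fields treated independently
  expect_lt(c2$end_bin[1], c2$start_bin[2])
})

test_that("the bootstrap p-value has the add-one floor and a fixed-seed value", {
  # perfect noiseless field: no rotation can match the observed contrast
  lap_maps <- matrix(0, 20, 40)
  lap_maps[, 18:22] <- 1
  bt <- bootstrap_field_test(lap_maps, list(start_bin = 18, end_bin = 22),
                             n_shuffles = 500, seed = 607)
  expect_equal(bt$boot_p, 1 / 501)
  # determinism
  bt2 <- bootstrap_field_test(lap_maps, list(start_bin = 18, end_bin = 22),
                              n_shuffles = 500, seed = 607)
  expect_identical(bt$boot_p, bt2$boot_p)
  # a candidate spanning the whole track is undefined
  expect_true(is.na(bootstrap_field_test(lap_maps,
                                         list(start_bin = 1, end_bin = 40),
                                         n_shuffles = 100)$boot_p))
})

test_that("bootstrap matches a direct rotate-and-recompute implementation", {
  set.seed(608)
  lap_maps <- matrix(rnorm(8 * 10), 8, 10)
  cand <- list(start_bin = 3, end_bin = 5)
  bt <- bootstrap_field_test(lap_maps, cand, n_shuffles = 100, seed = 609)
  # brute force with the same RNG stream: rotate each lap, pool, difference
  set.seed(609)
  fb <- 3:5
  stat <- function(m) mean(m[, fb]) - mean(m[, -fb])
  offs <- matrix(sample.int(10, 8 * 100, replace = TRUE) - 1L, 8, 100)
  null <- vapply(seq_len(100), function(si) {
    m <- t(vapply(seq_len(8), function(l) {
      o <- offs[l, si]
      if (o == 0) lap_maps[l, ] else
        lap_maps[l, c((10 - o + 1):10, 1:(10 - o))]
    }, numeric(10)))
    stat(m)
  }, numeric(1))
  p_manual <- (1 + sum(null >= stat(lap_maps) - 1e-12)) / 101
  expect_equal(bt$boot_p, p_manual)
})

test_that("field parameters: COM, width and out/in ratio", {
  prof <- rep(0, 40)
  prof[16:24] <- c(1:4, 5, 4:1) / 5  # symmetric triangle peaking at bin 20
  fp <- field_parameters(prof, 16, 24, baseline = 0, bin_width = 5)
  expect_equal(fp$com, 97.5)  # centre of bin 20 (1-based) = 97.5 cm
  expect_equal(fp$out_in_ratio, 0)  # zero activity outside the field
  expect_gte(fp$width, 5)
  # COM lies inside the field's extent
  expect_true(fp$com >= 15 * 5 && fp$com <= 24 * 5)
})

test_that("reliability must strictly exceed 30% of laps", {
  # square activity pulses at mid-track on exactly 3 of 10 laps (30%):
  # rejected; on 4 laps (40%): accepted
  s <- pc_session(n_laps = 10, lap_frames = 200, pause_frames = 15)
  laps <- segment_laps(s, teleport_pause = 0.5)
  make_dff <- function(active_laps) {
    x <- numeric(s$n_frames)
    for (l in active_laps) {
      fr <- laps$start_frame[l]:laps$end_frame[l]
      sel <- fr[s$position[fr] >= 95 & s$position[fr] <= 110]
      x[sel] <- 1
    }
    x <- x + rnorm(s$n_frames, 0, 0.02)
    rbind(x)
  }
  set.seed(610)
  f3 <- detect_place_fields(make_dff(c(2, 5, 8)), s, laps,
                            n_shuffles = 200, seed = 611)
  expect_equal(nrow(f3), 0L)
  rej <- attr(f3, "rejections")
  expect_true("reliability" %in% rej$reason)
  expect_true(any(abs(rej$reliability - 0.3) < 1e-9))
  f4 <- detect_place_fields(make_dff(c(2, 5, 8, 10)), s, laps,
                            n_shuffles = 200, seed = 611)
  expect_equal(nrow(f4), 1L)
  expect_equal(f4$reliability, 0.4)
})

test_that("fields truncated at the track start fail the rising-phase rule", {
  s <- pc_session(n_laps = 10)
  laps <- segment_laps(s, teleport_pause = 0.5)
  set.seed(612)
  x <- numeric(s$n_frames)
  for (l in seq_len(nrow(laps))) {
    fr <- laps$start_frame[l]:laps$end_frame[l]
    sel <- fr[s$position[fr] <= 20]  # active from the very first bin
    x[sel] <- 1
  }
  x <- x + rnorm(s$n_frames, 0, 0.02)
  f <- detect_place_fields(rbind(x), s, laps, n_shuffles = 200, seed = 613)
  expect_equal(nrow(f), 0L)
  expect_true("rising_phase" %in% attr(f, "rejections")$reason)
})

test_that("detection is invariant to multiplicative trace rescaling", {
  p <- behavior_sim_params(session_duration = 180, seed = 614)
  s <- simulate_session(p)$session
  cp <- calcium_sim_params(20, frac_place_cells = 0.5, seed = 615)
  sim <- simulate_traces(s, cp)
  f1 <- detect_place_fields(sim$dff, s, n_shuffles = 200, seed = 616)
  f2 <- detect_place_fields(sim$dff * 3.7, s, n_shuffles = 200, seed = 616)
  expect_equal(f1$cell, f2$cell)
  expect_equal(f1$com, f2$com, tolerance = 1e-9)
  expect_equal(f1$width, f2$width, tolerance = 1e-9)
  expect_equal(f1$boot_p, f2$boot_p)
  expect_equal(f1$out_in_ratio, f2$out_in_ratio, tolerance = 1e-9)
})

test_that("place-cell fraction counts cells, not fields", {
  f <- data.frame(cell = c(1, 1, 3))
  expect_equal(place_cell_fraction(f, n_cells = 10), 20)
  expect_equal(place_cell_fraction(data.frame(cell = integer(0)),
                                   n_cells = 5), 0)
  expect_true(is.na(place_cell_fraction(f, n_cells = 0)))
})
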