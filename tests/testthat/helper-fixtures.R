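# Deterministic fixtures used across test files.

# Sawtooth session: n_laps identical laps of `lap_frames` frames each,
# position ramping 0 -> 200, constant velocity, optional pause frames
# (velocity 0, position 0) between laps.
make_sawtooth_session <- function(n_laps = 3, lap_frames = 120,
                                  pause_frames = 0, frame_rate = 30,
                                  track_length = 200) {
  ramp <- seq(0, track_length, length.out = lap_frames)
  v_run <- track_length / ((lap_frames - 1) / frame_rate)
  pos <- c(); vel <- c()
  for (l in seq_len(n_laps)) {
    pos <- c(pos, ramp, rep(0, pause_frames))
    vel <- c(vel, rep(v_run, lap_frames), rep(0, pause_frames))
  }
  n <- length(pos)
  behavior_session(time = (seq_len(n) - 1) / frame_rate, position = pos,
                   velocity = vel, context_id = "Fix",
                   frame_rate = frame_rate, track_length = track_length)
}

# Brute-force lap counter: single-pass state machine counting
# track-end arrivals with re-arming once the animal is back on the early
# half of the track (the independent oracle for segment_laps).
oracle_lap_count <- function(pos, track_length = 200) {
  armed <- pos[1] < track_length
  laps <- 0L
  for (i in seq_along(pos)) {
    if (armed && pos[i] >= track_length - 1e-9) {
      laps <- laps + 1L
      armed <- FALSE
    } else if (!armed && pos[i] < track_length / 2) {
      armed <- TRUE
    }
  }
  laps
}

# Run-length-encoding epoch oracle: frame-by-frame scan collecting runs of
# TRUE longer than min_duration.
oracle_epochs <- function(mask, frame_rate, min_duration = 1) {
  out <- NULL
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if ((j - i + 1L) / frame_rate > min_duration) {
        out <- rbind(out, c(i, j, (j - i + 1L) / frame_rate))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0)))
  }
  data.frame(start_frame = as.integer(out[, 1]),
             end_frame = as.integer(out[, 2]), duration_s = out[, 3])
}

# Brute-force spatial binning oracle: explicit per-(cell, lap, bin) loops.
oracle_bin_activity <- function(dff, session, laps, n_bins,
                                speed_threshold) {
  nc <- nrow(dff); nl <- nrow(laps)
  bw <- session$track_length / n_bins
  arr <- array(NA_real_, c(nc, nl, n_bins))
  for (l in seq_len(nl)) {
    fr <- laps$start_frame[l]:laps$end_frame[l]
    fr <- fr[abs(session$velocity[fr]) >= speed_threshold]
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * bw; hi <- b * bw
      in_bin <- if (b < n_bins) {
        fr[session$position[fr] >= lo & session$position[fr] < hi]
      } else {
        fr[session$position[fr] >= lo & session$position[fr] <= hi]
      }
      if (length(in_bin) > 0) {
        for (ci in seq_len(nc)) arr[ci, l, b] <- mean(dff[ci, in_bin])
      }
    }
  }
  arr
}
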