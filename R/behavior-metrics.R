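#' Segment a session into completed laps
#'
#' A lap is one completed 0 -> 200 cm traversal of the virtual linear track:
#' it ends on the frame where the animal first reaches the track end, which
#' in the experiment triggers the reward/teleport sequence. After each
#' completed lap the VR pauses for `teleport_pause` seconds before the next
#' lap begins; by default those imposed pause frames belong to no lap, so
#' lap durations and per-lap freezing denominators reflect behavior only.
#' An incomplete traversal in progress at the end of the session is reported
#' in the `incomplete_frames` attribute, never as a lap.
#'
#' @param session a [behavior_session()].
#' @param teleport_pause duration in seconds of the end-of-lap VR pause
#'   (default 1.5); frames within this window after the teleport reset are
#'   excluded from laps. Set to 0 for logs without a pause.
#' @param end_threshold position (cm) that completes a lap; defaults to the
#'   session's track length.
#' @param include_pause if `TRUE`, pause frames are appended to the lap that
#'   triggered them (durations then include the pause).
#'
#' @return a `lap_table`: a data frame with one row per completed lap and
#'   columns `lap`, `start_frame`, `end_frame`, `n_frames`, `start_s`,
#'   `end_s`, `duration_s`, `is_first_lap`; attribute `incomplete_frames`
#'   counts trailing frames of an unfinished traversal.
#' @export
segment_laps <- function(session, teleport_pause = 1.5,
                         end_threshold = NULL, include_pause = FALSE) {
  pos <- session$position
  t <- session$time
  n <- session$n_frames
  thr <- end_threshold %||% session$track_length
  half <- thr / 2
  tol <- 1 / (2 * session$frame_rate)

  # precomputed crossings + forward pointer walks keep this O(n) even for
  # sessions with many laps
  at_end <- pos >= thr - 1e-9
  cross_up <- which(at_end & c(FALSE, !at_end[-n]))   # reaches track end
  below_half <- pos < half
  H <- which(below_half)                              # early-half frames
  tH <- t[H]

  starts <- integer(0); ends <- integer(0)
  s <- if (pos[1L] < thr) 1L else if (length(H)) H[1L] else NA_integer_
  ie <- 1L; ih <- 1L
  while (!is.na(s) && s <= n) {
    while (ie <= length(cross_up) && cross_up[ie] < s) ie <- ie + 1L
    e <- if (at_end[s]) s else if (ie <= length(cross_up)) cross_up[ie] else NA_integer_
    if (is.na(e)) break
    starts <- c(starts, s); ends <- c(ends, e)
    if (e >= n) { s <- NA_integer_; break }
    while (ih <= length(H) && H[ih] <= e) ih <- ih + 1L
    if (ih > length(H)) { s <- NA_integer_; break }
    reset <- H[ih]
    target <- t[reset] + teleport_pause - tol
    while (ih <= length(H) && tH[ih] < target) ih <- ih + 1L
    s <- if (ih <= length(H)) H[ih] else NA_integer_
  }

  nl <- length(ends)
  end_ext <- ends
  if (include_pause && nl > 0L) {
    nxt_start <- c(starts[-1L] - 1L, NA_integer_)
    end_ext <- ifelse(is.na(nxt_start), ends, pmax(ends, nxt_start))
  }
  out <- data.frame(
    lap = seq_len(nl),
    start_frame = starts[seq_len(nl)],
    end_frame = end_ext[seq_len(nl)],
    n_frames = end_ext[seq_len(nl)] - starts[seq_len(nl)] + 1L,
    start_s = t[starts[seq_len(nl)]],
    end_s = t[end_ext[seq_len(nl)]],
    duration_s = t[end_ext[seq_len(nl)]] - t[starts[seq_len(nl)]],
    is_first_lap = seq_len(nl) == 1L)
  if (nl == 0L) {
    out <- data.frame(lap = integer(0), start_frame = integer(0),
                      end_frame = integer(0), n_frames = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), is_first_lap = logical(0))
  }
  incomplete <- if (!is.na(s) && s <= n) n - s + 1L else 0L
  structure(out, incomplete_frames = incomplete,
            track_length = session$track_length,
            class = c("lap_table", "data.frame"))
}

#' Detect freezing frames from instantaneous velocity
#'
#' Freezing is defined as frames whose instantaneous treadmill velocity is
#' zero; `epsilon` admits encoder quantization noise (|v| <= epsilon counts
#' as freezing). Backward movement (negative velocity) is movement, not
#' freezing.
#'
#' @param session a [behavior_session()].
#' @param epsilon non-negative velocity tolerance in cm/s. The faithful
#'   definition is `0`; `0.05` is a reasonable setting for noisy logs.
#' @return logical vector, one element per frame, `TRUE` where frozen.
#' @export
detect_freezing <- function(session, epsilon = 0) {
  stopifnot(epsilon >= 0)
  abs(session$velocity) <= epsilon
}

#' Extract freezing epochs from a freezing mask
#'
#' A freezing epoch is a maximal run of consecutive freezing frames whose
#' duration strictly exceeds `min_duration` (default 1 s): at 30 Hz a run of
#' exactly 30 frames (1.0 s) is not an epoch, 31 frames is.
#'
#' @param mask logical per-frame freezing mask (from [detect_freezing()]).
#' @param frame_rate sampling rate in Hz.
#' @param min_duration minimum epoch duration in seconds (strict).
#' @return data frame with columns `start_frame`, `end_frame`,
#'   `duration_s`; zero rows if no run qualifies.
#' @export
freezing_epochs <- function(mask, frame_rate, min_duration = 1) {
  stopifnot(min_duration > 0, frame_rate > 0)
  if (length(mask) == 0L || !any(mask)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0)))
  }
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / frame_rate > min_duration)
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             duration_s = r$lengths[keep] / frame_rate)
}

#' Per-session behavioral metrics
#'
#' Computes the per-lap and session-level freezing and lap-time metrics.
#' Per-lap freezing percent is the number of freezing frames in the lap
#' divided by the lap's total frame count, times 100; the session average is
#' the mean of per-lap values (laps weigh equally regardless of length).
#'
#' @param session a [behavior_session()].
#' @param laps a `lap_table` from [segment_laps()] on the same session.
#' @param mask logical freezing mask from [detect_freezing()] on the same
#'   session.
#' @return an object of class `session_metrics`: a list with
#'   `avg_freezing_pct`, `first_lap_freezing_pct`, `avg_lap_time`,
#'   `first_lap_time`, `n_laps`, `laps_per_minute`, `defined` (FALSE when
#'   the session has no completed lap, in which case metrics are `NA`), and
#'   a `per_lap` data frame.
#' @export
session_metrics <- function(session, laps, mask) {
  stopifnot(length(mask) == session$n_frames)
  nl <- nrow(laps)
  dur_min <- session$n_frames / session$frame_rate / 60
  if (nl == 0L) {
    return(structure(list(avg_freezing_pct = NA_real_,
                          first_lap_freezing_pct = NA_real_,
                          avg_lap_time = NA_real_, first_lap_time = NA_real_,
                          n_laps = 0L, laps_per_minute = 0,
                          defined = FALSE,
                          per_lap = cbind(laps, freezing_frames = integer(0),
                                          freezing_pct = numeric(0))),
                     class = "session_metrics"))
  }
  cm <- cumsum(as.logical(mask))
  prev <- laps$start_frame - 1L
  fr_frames <- cm[laps$end_frame] -
    c(0L, cm)[prev + 1L] # cumulative count just before each lap start
  pct <- 100 * fr_frames / laps$n_frames
  per_lap <- cbind(as.data.frame(laps), freezing_frames = fr_frames,
                   freezing_pct = pct)
  structure(list(avg_freezing_pct = mean(pct),
                 first_lap_freezing_pct = pct[1L],
                 avg_lap_time = mean(laps$duration_s),
                 first_lap_time = laps$duration_s[1L],
                 n_laps = nl,
                 laps_per_minute = nl / dur_min,
                 defined = TRUE, per_lap = per_lap),
            class = "session_metrics")
}

#' @exportS3Method base::print
print.session_metrics <- function(x, ...) {
  if (!x$defined) {
    cat("<session_metrics> no completed laps; metrics undefined\n")
  } else {
    cat(sprintf(paste0("<session_metrics> %d laps (%.2f laps/min); ",
                       "freezing avg %.1f%% (first lap %.1f%%); ",
                       "lap time avg %.1f s (first %.1f s)\n"),
                x$n_laps, x$laps_per_minute, x$avg_freezing_pct,
                x$first_lap_freezing_pct, x$avg_lap_time, x$first_lap_time))
  }
  invisible(x)
}

#' Context-discrimination delta
#'
#' Freezing (or any session metric) in the shock-paired context minus the
#' same metric in the neutral context. A positive delta indicates correct
#' contextual discrimination.
#'
#' @param metrics_cfc,metrics_neutral `session_metrics` for the shock-paired
#'   and neutral contexts of the same mouse and day.
#' @param metric which field to difference (default `"avg_freezing_pct"`).
#' @return signed numeric delta; `NA` if either input is undefined.
#' @export
discrimination_delta <- function(metrics_cfc, metrics_neutral,
                                 metric = "avg_freezing_pct") {
  a <- metrics_cfc[[metric]]; b <- metrics_neutral[[metric]]
  if (is.null(a) || is.null(b)) stop("unknown metric: ", metric)
  if (!isTRUE(metrics_cfc$defined) || !isTRUE(metrics_neutral$defined)) {
    return(NA_real_)
  }
  a - b
}

#' Shock-evoked running response
#'
#' For each tail-shock event, compares mean running speed (|velocity|) in a
#' pre-shock window against the matching post-shock window. Shocks whose
#' windows extend beyond the session are excluded and counted. The session
#' is flagged responsive when the post-shock speed exceeds the pre-shock
#' speed for at least `majority` of the evaluated shocks (a QC flag: the
#' expected unconditioned response is a transient sprint).
#'
#' @param session a [behavior_session()] containing shock events.
#' @param window window length in seconds on each side (default 5).
#' @param majority fraction of shocks that must show a positive speed change
#'   for the responsive flag (default 2/3).
#' @return data frame with one row per evaluated shock (`shock_frame`,
#'   `t_shock`, `pre_mean_speed`, `post_mean_speed`, `speed_change`);
#'   attributes `responsive` (logical) and `n_excluded`.
#' @export
shock_response <- function(session, window = 5, majority = 2 / 3) {
  sh <- session$events$frame[session$events$kind == "shock"]
  if (length(sh) == 0L) stop("session contains no shock events")
  t <- session$time; spd <- abs(session$velocity)
  t0 <- t[1L]; t1 <- t[session$n_frames]
  rows <- lapply(sh, function(f) {
    ts <- t[f]
    if (ts - window < t0 - 1e-9 || ts + window > t1 + 1e-9) return(NULL)
    pre <- spd[t >= ts - window & t < ts]
    post <- spd[t > ts & t <= ts + window]
    data.frame(shock_frame = f, t_shock = ts,
               pre_mean_speed = mean(pre), post_mean_speed = mean(post),
               speed_change = mean(post) - mean(pre))
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_excl <- sum(!keep)
  if (n_excl > 0L) {
    warning(sprintf("%d shock(s) too close to the session edge; excluded",
                    n_excl))
  }
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(shock_frame = integer(0), t_shock = numeric(0),
               pre_mean_speed = numeric(0), post_mean_speed = numeric(0),
               speed_change = numeric(0))
  responsive <- nrow(out) > 0L && mean(out$speed_change > 0) >= majority
  structure(out, responsive = responsive, n_excluded = n_excl)
}
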