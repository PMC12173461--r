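#' Parameters for the behavior simulator
#'
#' Bundles and validates the parameters of [simulate_session()]. The
#' generator is a two-state (run/freeze) Markov chain sampled per frame,
#' with two deterministic overlays: an exponentially decaying sprint after
#' each tail shock, and the imposed end-of-lap teleport pause. Defaults
#' emulate a well-trained head-fixed mouse on a 2 m virtual track sampled
#' at 30 frames/s: run speeds around 20 cm/s give ~4-5 laps/min, above the
#' >3 laps/min training criterion, and the default transition rates give a
#' baseline freezing fraction near 10% with ~2 s freezing bouts.
#'
#' @param frame_rate sampling rate, Hz.
#' @param track_length track length, cm.
#' @param session_duration session length, seconds.
#' @param run_speed_mean,run_speed_sd running-speed distribution (cm/s),
#'   Normal truncated at 0.
#' @param p_run_to_freeze,p_freeze_to_run per-frame transition
#'   probabilities of the run/freeze chain.
#' @param backward_prob per-frame probability that a running frame's
#'   velocity is negated (brief backward movement).
#' @param shock_times times (s) of tail shocks within the session.
#' @param shock_sprint_amplitude peak speed increase after a shock, cm/s.
#' @param shock_sprint_decay exponential decay time of the sprint, s.
#' @param teleport_pause imposed VR pause after each completed lap, s.
#' @param rewarded whether lap completions emit reward events.
#' @param seed integer seed fixing the whole output stream, or `NULL` to
#'   use the ambient RNG state.
#' @return a validated list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(frame_rate = 30, track_length = 200,
                                session_duration = 600,
                                run_speed_mean = 20, run_speed_sd = 5,
                                p_run_to_freeze = 0.002,
                                p_freeze_to_run = 1 / 60,
                                backward_prob = 0.01,
                                shock_times = numeric(0),
                                shock_sprint_amplitude = 20,
                                shock_sprint_decay = 1,
                                teleport_pause = 1.5,
                                rewarded = FALSE, seed = NULL) {
  p <- list(frame_rate = frame_rate, track_length = track_length,
            session_duration = session_duration,
            run_speed_mean = run_speed_mean, run_speed_sd = run_speed_sd,
            p_run_to_freeze = p_run_to_freeze,
            p_freeze_to_run = p_freeze_to_run,
            backward_prob = backward_prob, shock_times = shock_times,
            shock_sprint_amplitude = shock_sprint_amplitude,
            shock_sprint_decay = shock_sprint_decay,
            teleport_pause = teleport_pause, rewarded = rewarded,
            seed = seed)
  stopifnot(frame_rate > 0, track_length > 0, session_duration > 0,
            run_speed_mean >= 0, run_speed_sd > 0,
            p_run_to_freeze >= 0, p_run_to_freeze <= 1,
            p_freeze_to_run >= 0, p_freeze_to_run <= 1,
            backward_prob >= 0, backward_prob <= 1,
            shock_sprint_decay > 0, teleport_pause >= 0)
  class(p) <- "behavior_sim_params"
  p
}

#' Markov transition rates for a target freezing fraction
#'
#' Inverts the stationary distribution of the run/freeze chain: the
#' long-run freezing fraction is `p_rf / (p_rf + p_fr)`. Given a target
#' fraction and a mean freezing-bout duration, returns the per-frame rates.
#'
#' @param target_fraction long-run freezing fraction in `[0, 1)`.
#' @param mean_epoch_s mean freezing-bout duration, seconds (default 2).
#' @param frame_rate sampling rate, Hz.
#' @return list with `p_run_to_freeze` and `p_freeze_to_run`.
#' @export
freezing_rates <- function(target_fraction, mean_epoch_s = 2,
                           frame_rate = 30) {
  stopifnot(target_fraction >= 0, target_fraction < 1, mean_epoch_s > 0)
  p_fr <- 1 / (mean_epoch_s * frame_rate)
  list(p_run_to_freeze = target_fraction * p_fr / (1 - target_fraction),
       p_freeze_to_run = p_fr)
}

# Alternating geometric dwell times of the two-state chain, as a per-frame
# integer state vector (1 = run, 2 = freeze) of length >= n.
.sim_states <- function(n, p_rf, p_fr) {
  if (p_rf <= 0) return(rep.int(1L, n))
  if (p_fr <= 0) {
    first <- stats::rgeom(1L, p_rf) + 1L
    return(c(rep.int(1L, min(first, n)), rep.int(2L, max(0L, n - first))))
  }
  states <- integer(0)
  while (length(states) < n) {
    k <- max(16L, ceiling(n * (p_rf * p_fr / (p_rf + p_fr))) + 16L)
    runs <- stats::rgeom(k, p_rf) + 1
    frz <- stats::rgeom(k, p_fr) + 1
    lens <- as.vector(rbind(runs, frz))
    states <- c(states, rep.int(rep.int(c(1L, 2L), k), times = lens))
  }
  states[seq_len(n)]
}

# sum of sprint overlays at the given times
.sprint_overlay <- function(t, shock_times, amp, decay) {
  ov <- numeric(length(t))
  for (ts in shock_times) {
    w <- t >= ts & t <= ts + 8 * decay
    if (any(w)) ov[w] <- ov[w] + amp * exp(-(t[w] - ts) / decay)
  }
  ov
}

#' Simulate one behavior session with ground truth
#'
#' Runs the two-state Markov generator described in
#' [behavior_sim_params()]: running frames draw a truncated-Normal speed
#' (negated with probability `backward_prob`), freezing frames have
#' velocity exactly 0, shocks inject an exponentially decaying sprint, and
#' position integrates velocity with a clamp at the track start, a teleport
#' reset at the track end, and a `teleport_pause` of frozen VR (zero
#' velocity, position 0) after each completed lap. The output is fully
#' reproducible from the seed.
#'
#' @param params a [behavior_sim_params()].
#' @param context_id,session_label metadata stored on the session.
#' @return list with `session` (a [behavior_session()]) and `truth`, the
#'   generator-side latents: per-frame `state` (`"run"`, `"freeze"`,
#'   `"sprint"`, `"pause"`), `freezing_fraction` (freeze-state frames over
#'   non-pause frames), `lap_starts`/`lap_ends` (frame indices of completed
#'   laps), and the generating `params`.
#' @export
simulate_session <- function(params, context_id = "VR",
                             session_label = "unknown") {
  stopifnot(inherits(params, "behavior_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  fr <- params$frame_rate
  n <- as.integer(round(params$session_duration * fr))
  time <- (seq_len(n) - 1L) / fr

  base_state <- .sim_states(n, params$p_run_to_freeze, params$p_freeze_to_run)
  base_vel <- numeric(n)
  run_idx <- which(base_state == 1L)
  if (length(run_idx) > 0L) {
    lo <- stats::pnorm(0, params$run_speed_mean, params$run_speed_sd)
    v <- stats::qnorm(stats::runif(length(run_idx), lo, 1),
                      params$run_speed_mean, params$run_speed_sd)
    bk <- stats::runif(length(run_idx)) < params$backward_prob
    v[bk] <- -v[bk]
    base_vel[run_idx] <- v
  }

  pause_frames <- as.integer(round(params$teleport_pause * fr))
  vel <- numeric(n); pos <- numeric(n); state <- integer(n) # 4 = pause
  lap_starts <- integer(0); lap_ends <- integer(0)
  teleport_ev <- integer(0); reward_ev <- integer(0)
  has_shock <- length(params$shock_times) > 0L
  emit_lap <- function(k, idx_o, idx_b, v, p) {
    # emit a completed lap ending at output frame o + k - 1, then the pause
    vel[idx_o] <<- v[seq_len(k)]
    pos[idx_o] <<- pmin(pmax(p[seq_len(k)], 0), params$track_length)
    pos[o + k - 1L] <<- params$track_length
    state[idx_o] <<- base_state[idx_b]
    lap_starts <<- c(lap_starts, lap_open_at)
    lap_ends <<- c(lap_ends, o + k - 1L)
    if (params$rewarded) reward_ev <<- c(reward_ev, o + k - 1L)
    o <<- o + k; b <<- b + k
    q <- min(pause_frames, n - o + 1L)
    if (q > 0L) {
      idx_p <- o:(o + q - 1L)
      vel[idx_p] <<- 0; pos[idx_p] <<- 0; state[idx_p] <<- 4L
      teleport_ev <<- c(teleport_ev, o)
      o <<- o + q
    }
    lap_open_at <<- o
  }
  clamp_wall <- function(p, v, len) {
    guard <- 0L
    while (any(p < -1e-9) && guard < 1024L) {
      i <- which(p < -1e-9)[1L]
      dv <- -p[i]
      p[i:len] <- p[i:len] + dv
      v[i] <- v[i] + dv * fr
      guard <- guard + 1L
    }
    list(p = p, v = v)
  }
  o <- 1L; b <- 1L; lap_open_at <- 1L

  if (!has_shock) {
    # fast path: crossings located on the cumulative distance via cummax +
    # binary search; no per-chunk scanning
    D <- cumsum(base_vel / fr)
    cmD <- cummax(D)
    off <- 0
    while (o <= n) {
      e <- findInterval(off + params$track_length - 1e-9, cmD) + 1L
      k_base <- if (e > n) n - b + 1L else e - b + 1L
      k <- min(k_base, n - o + 1L)
      idx_o <- o:(o + k - 1L); idx_b <- b:(b + k - 1L)
      p <- D[idx_b] - off
      v <- base_vel[idx_b]
      if (any(p < -1e-9)) { # wall clamp shifts the crossing; redo locally
        cw <- clamp_wall(p, v, k)
        p <- cw$p; v <- cw$v
        kc <- which(p >= params$track_length - 1e-9)
        k_cross <- if (length(kc)) kc[1L] else NA_integer_
      } else {
        k_cross <- if (e <= n && k == k_base) k else NA_integer_
      }
      if (!is.na(k_cross)) {
        k <- k_cross
        emit_lap(k, o:(o + k - 1L), b:(b + k - 1L), v, p)
        off <- D[b - 1L]
      } else { # session ends mid-traversal
        vel[idx_o] <- v
        pos[idx_o] <- pmin(pmax(p, 0), params$track_length)
        state[idx_o] <- base_state[idx_b]
        o <- o + k; b <- b + k
        if (b <= n) off <- D[b - 1L]
      }
    }
  } else {
    # shock sessions: the sprint overlay depends on wall-clock time, which
    # shifts with every inserted pause, so integrate chunk by chunk
    chunk0 <- max(256L, as.integer(4 * fr * params$track_length /
                                     max(params$run_speed_mean, 1)))
    cur <- 0
    while (o <= n) {
      L <- min(chunk0, n - o + 1L)
      repeat {
        idx_o <- o:(o + L - 1L); idx_b <- b:(b + L - 1L)
        v_eff <- base_vel[idx_b] +
          .sprint_overlay(time[idx_o], params$shock_times,
                          params$shock_sprint_amplitude,
                          params$shock_sprint_decay)
        p <- cur + cumsum(v_eff / fr)
        cw <- clamp_wall(p, v_eff, L)
        p <- cw$p; v_eff <- cw$v
        k <- which(p >= params$track_length - 1e-9)
        if (length(k) > 0L || o + L - 1L >= n || b + L - 1L >= n) break
        L <- min(2L * L, n - o + 1L)
      }
      if (length(k) == 0L) { # no more completed laps; emit the rest
        vel[idx_o] <- v_eff
        pos[idx_o] <- pmin(pmax(p, 0), params$track_length)
        state[idx_o] <- base_state[idx_b]
        o <- o + L; b <- b + L; cur <- p[L]
        next
      }
      k <- k[1L]
      emit_lap(k, o:(o + k - 1L), b:(b + k - 1L), v_eff, p)
      cur <- 0
    }
  }

  # sprint state: non-pause frames within the decaying-sprint window
  if (has_shock) {
    for (ts in params$shock_times) {
      w <- which(time >= ts & time <= ts + 3 * params$shock_sprint_decay &
                   state != 4L)
      state[w] <- 3L
    }
  }
  shock_ev <- integer(0)
  if (has_shock) {
    shock_ev <- as.integer(round(params$shock_times * fr)) + 1L
    shock_ev <- shock_ev[shock_ev >= 1L & shock_ev <= n]
  }
  ev <- data.frame(
    frame = c(reward_ev, shock_ev, teleport_ev),
    kind = c(rep("reward", length(reward_ev)),
             rep("shock", length(shock_ev)),
             rep("teleport", length(teleport_ev))))
  session <- behavior_session(time = time, position = pos, velocity = vel,
                              context_id = context_id,
                              session_label = session_label, events = ev,
                              frame_rate = fr,
                              track_length = params$track_length)
  lab <- c("run", "freeze", "sprint", "pause")[state]
  non_pause <- state != 4L
  truth <- list(state = lab,
                freezing_fraction = mean(state[non_pause] == 2L),
                freezing_fraction_all = mean(state == 2L),
                lap_starts = lap_starts, lap_ends = lap_ends,
                params = params)
  list(session = session, truth = truth)
}

#' Simulate a multi-mouse, multi-day fear-conditioning cohort
#'
#' Generates the full session sequence of one of the three experimental
#' paradigms with a controllable contextual-fear effect:
#' \describe{
#'   \item{Paradigm 1}{Day 0: 10 min pre-conditioning exploration of the
#'     trained (Familiar) context and of the novel shock-paired (CFC)
#'     context, followed by a conditioning block in the CFC context with
#'     six 1 s shocks at 60 s intervals; recall days: 5 min per context,
#'     no tail-coat.}
#'   \item{Paradigm 2}{adds a Day -1 habituation to two novel contexts
#'     (Control and CFC), conditioning as in Paradigm 1; recall without the
#'     tail-coat.}
#'   \item{Paradigm 3}{as Paradigm 2 but with shorter shock intervals
#'     (22.5 s) and the tail-coat worn during recall.}
#' }
#' Recall-day freezing in the shock-paired context is elevated by `effect`
#' percentage points over `baseline_freeze_pct`; per-mouse offsets (sd
#' `between_sd`) are shared across contexts and per-session noise (sd
#' `pair_sd / sqrt(2)`) makes the CFC-minus-neutral difference have sd
#' about `pair_sd` across mice. Context order on recall days alternates
#' with mouse parity (counterbalancing).
#'
#' @param paradigm 1, 2 or 3.
#' @param n_mice number of mice (>= 2).
#' @param effect recall-day freezing elevation in the shock-paired context,
#'   percentage points; scalar or one value per recall day.
#' @param seed integer seed for the whole cohort.
#' @param n_recall_days number of recall days (default 1).
#' @param baseline_freeze_pct recall-day freezing (%) in the neutral
#'   context (default 16).
#' @param day0_freeze_pct pre-conditioning freezing (%) (default 8).
#' @param between_sd,pair_sd between-mouse and within-pair sd of the
#'   freezing targets, percentage points.
#' @param explore_duration,recall_duration session lengths, seconds
#'   (default 600 and 600; recall tests ran 10 min per context).
#' @param frame_rate sampling rate, Hz.
#' @param stages `"full"` (default) generates every session of the
#'   paradigm; `"recall_only"` generates just the recall-day sessions
#'   (the latent per-mouse targets are drawn identically), for analyses
#'   that use recall behavior only.
#' @return object of class `behavior_cohort`: list with `sessions` (list
#'   of `simulate_session()` results) and `meta`, a data frame with one
#'   row per session (`mouse`, `day`, `context_role`, `context_id`,
#'   `session_label`, `tailcoat`, `order`, `target_freeze_pct`).
#' @export
simulate_cohort <- function(paradigm, n_mice, effect = 8, seed = NULL,
                            n_recall_days = 1, baseline_freeze_pct = 16,
                            day0_freeze_pct = 8, between_sd = 5,
                            pair_sd = 4, explore_duration = 600,
                            recall_duration = 600, frame_rate = 30,
                            stages = c("full", "recall_only")) {
  if (!paradigm %in% 1:3) stop("unknown paradigm: ", paradigm)
  stages <- match.arg(stages)
  full <- stages == "full"
  stopifnot(n_mice >= 2)
  if (!is.null(seed)) set.seed(seed)
  effect <- rep_len(effect, n_recall_days)
  neutral_name <- if (paradigm == 1) "Familiar" else "Control"
  isi <- if (paradigm == 3) 22.5 else 60
  conditioning_duration <- 360
  shock_times <- 30 + isi * (0:5)
  shock_times <- shock_times[shock_times < conditioning_duration - 1]

  sess <- list(); meta <- NULL
  clamp <- function(x) pmin(90, pmax(0.5, x)) / 100
  one <- function(target_pct, dur, shocks, ctx, label) {
    r <- freezing_rates(clamp(target_pct), frame_rate = frame_rate)
    p <- behavior_sim_params(frame_rate = frame_rate,
                             session_duration = dur,
                             p_run_to_freeze = r$p_run_to_freeze,
                             p_freeze_to_run = r$p_freeze_to_run,
                             shock_times = shocks)
    simulate_session(p, context_id = ctx, session_label = label)
  }
  add <- function(s, mouse, day, role, ctx, label, tailcoat, ord, target) {
    sess[[length(sess) + 1L]] <<- s
    meta <<- rbind(meta, data.frame(
      mouse = mouse, day = day, context_role = role, context_id = ctx,
      session_label = label, tailcoat = tailcoat, order = ord,
      target_freeze_pct = target))
  }

  for (m in seq_len(n_mice)) {
    a <- stats::rnorm(1, 0, between_sd)
    cfc_first <- m %% 2L == 1L
    if (paradigm >= 2) {
      for (role in c("neutral", "cfc")) {
        ctx <- if (role == "cfc") "CFC" else neutral_name
        tgt <- day0_freeze_pct + a + stats::rnorm(1, 0, pair_sd / sqrt(2))
        if (full) {
          add(one(tgt, explore_duration, numeric(0), ctx, "habituation"),
              m, -1L, role, ctx, "habituation", TRUE, NA_integer_, tgt)
        }
      }
    }
    for (role in c("neutral", "cfc")) { # pre-conditioning exploration
      ctx <- if (role == "cfc") "CFC" else neutral_name
      tgt <- day0_freeze_pct + a + stats::rnorm(1, 0, pair_sd / sqrt(2))
      if (full) {
        add(one(tgt, explore_duration, numeric(0), ctx, "before_cfc"),
            m, 0L, role, ctx, "before_cfc", TRUE, NA_integer_, tgt)
      }
    }
    tgt_c <- day0_freeze_pct + a + stats::rnorm(1, 0, pair_sd / sqrt(2))
    if (full) {
      add(one(tgt_c, conditioning_duration, shock_times, "CFC",
              "during_cfc"),
          m, 0L, "cfc", "CFC", "during_cfc", TRUE, NA_integer_, tgt_c)
    }
    for (d in seq_len(n_recall_days)) {
      roles <- if (cfc_first) c("cfc", "neutral") else c("neutral", "cfc")
      for (i in seq_along(roles)) {
        role <- roles[i]
        ctx <- if (role == "cfc") "CFC" else neutral_name
        tgt <- baseline_freeze_pct + (role == "cfc") * effect[d] + a +
          stats::rnorm(1, 0, pair_sd / sqrt(2))
        add(one(tgt, recall_duration, numeric(0), ctx,
                paste0("recall_day_", d)),
            m, d, role, ctx, paste0("recall_day_", d),
            paradigm == 3, i, tgt)
      }
    }
  }
  row.names(meta) <- NULL
  structure(list(sessions = sess, meta = meta, paradigm = paradigm,
                 effect = effect, seed = seed),
            class = "behavior_cohort")
}

#' Behavioral metrics for every session of a cohort
#'
#' Runs the standard behavioral pipeline (freezing mask, lap segmentation,
#' [session_metrics()]) over each session of a [simulate_cohort()] result
#' and returns one row per session.
#'
#' @param cohort a `behavior_cohort`.
#' @param epsilon freezing velocity tolerance, cm/s.
#' @param teleport_pause pause length passed to [segment_laps()].
#' @return the cohort's `meta` data frame with metric columns appended
#'   (`avg_freezing_pct`, `first_lap_freezing_pct`, `avg_lap_time`,
#'   `first_lap_time`, `n_laps`, `laps_per_minute`).
#' @export
cohort_metrics <- function(cohort, epsilon = 0, teleport_pause = 1.5) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  rows <- lapply(cohort$sessions, function(s) {
    ses <- s$session
    laps <- segment_laps(ses, teleport_pause = teleport_pause)
    m <- session_metrics(ses, laps, detect_freezing(ses, epsilon))
    data.frame(avg_freezing_pct = m$avg_freezing_pct,
               first_lap_freezing_pct = m$first_lap_freezing_pct,
               avg_lap_time = m$avg_lap_time,
               first_lap_time = m$first_lap_time,
               n_laps = m$n_laps, laps_per_minute = m$laps_per_minute)
  })
  cbind(cohort$meta, do.call(rbind, rows))
}
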