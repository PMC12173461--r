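#' Parameters for the calcium-trace simulator
#'
#' Controls the synthetic dF/F generator of [simulate_traces()] and
#' [simulate_two_sessions()]. Place cells have Gaussian spatial tuning
#' (center uniform on the track, width `field_sigma`) gated per lap by a
#' Bernoulli activation with probability `reliability`; non-place cells
#' emit randomly timed transients with instantaneous rise and exponential
#' decay (`decay_tau`, GCaMP6f-like) at an event rate matched to the place
#' cells' per-lap rate, so detection cannot separate the two populations
#' by rate alone. White Gaussian noise of sd `noise_sd` is added
#' throughout; the nominal SNR is `amplitude / noise_sd`.
#'
#' @param n_cells number of cells.
#' @param frac_place_cells fraction of cells given spatial tuning.
#' @param field_sigma tuning-curve sd in cm; scalar or one per place cell.
#' @param amplitude peak dF/F of a transient / tuning curve.
#' @param reliability per-lap activation probability of a place cell.
#' @param decay_tau transient decay time constant, s.
#' @param noise_sd additive noise sd (dF/F units).
#' @param remap_fraction fraction of place cells assigned new random
#'   centers in session 2 ([simulate_two_sessions()]).
#' @param width_scale_session2 multiplier on all tuning widths in session
#'   2 (< 1 models field narrowing).
#' @param seed integer seed, or `NULL`.
#' @return validated list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_cells, frac_place_cells = 0.4,
                               field_sigma = 10, amplitude = 1,
                               reliability = 0.8, decay_tau = 0.5,
                               noise_sd = 0.2, remap_fraction = 0,
                               width_scale_session2 = 1, seed = NULL) {
  p <- list(n_cells = as.integer(n_cells),
            frac_place_cells = frac_place_cells,
            field_sigma = field_sigma, amplitude = amplitude,
            reliability = reliability, decay_tau = decay_tau,
            noise_sd = noise_sd, remap_fraction = remap_fraction,
            width_scale_session2 = width_scale_session2, seed = seed)
  stopifnot(p$n_cells >= 1,
            frac_place_cells >= 0, frac_place_cells <= 1,
            reliability >= 0, reliability <= 1,
            remap_fraction >= 0, remap_fraction <= 1,
            all(field_sigma > 0), decay_tau > 0, noise_sd >= 0,
            amplitude >= 0, width_scale_session2 > 0)
  class(p) <- "calcium_sim_params"
  p
}

# Draw the latent tuning of a cell population.
.draw_tuning <- function(params, track_length) {
  n <- params$n_cells
  npc <- round(params$frac_place_cells * n)
  is_place <- rep(FALSE, n)
  if (npc > 0) is_place[sample.int(n, npc)] <- TRUE
  center <- rep(NA_real_, n)
  sigma <- rep(NA_real_, n)
  if (npc > 0) {
    center[is_place] <- stats::runif(npc, 0, track_length)
    sigma[is_place] <- rep_len(params$field_sigma, npc)
  }
  data.frame(cell = seq_len(n), is_place = is_place, center = center,
             sigma = sigma)
}

#' Simulate a dF/F trace set with ground-truth tuning
#'
#' Generates one session of calcium traces aligned to a behavior session.
#' On each lap where a place cell activates (probability `reliability`),
#' the cell's noiseless signal is its Gaussian tuning curve evaluated at
#' the animal's position, peaking at `amplitude` when the animal crosses
#' the field center; inactive laps, frames outside laps, and sessions with
#' no movement produce no place signal (the drive is spatially gated).
#' Non-place cells receive Poisson-distributed discrete transients
#' (instant rise to `amplitude`, exponential decay `decay_tau`) at times
#' uniform over lap frames, with per-lap event rate equal to
#' `reliability`. Gaussian noise is added last. Fully reproducible from
#' the seed.
#'
#' @param session a [behavior_session()].
#' @param params a [calcium_sim_params()].
#' @param laps optional precomputed `lap_table`.
#' @param tuning optional tuning data frame (from a previous call's
#'   `truth$tuning`) to reuse latent fields across sessions.
#' @return list with `dff` (cells x frames matrix) and `truth`: `tuning`
#'   (per-cell `is_place`, `center`, `sigma`), `activation` (cells x laps
#'   logical, `NA` for non-place cells), and `events` (data frame of true
#'   transient onsets of non-place cells: `cell`, `onset_frame`).
#' @export
simulate_traces <- function(session, params, laps = NULL, tuning = NULL) {
  stopifnot(inherits(params, "calcium_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(laps)) laps <- segment_laps(session)
  nl <- nrow(laps)
  n <- params$n_cells
  nf <- session$n_frames
  fr <- session$frame_rate
  pos <- session$position
  if (is.null(tuning)) tuning <- .draw_tuning(params, session$track_length)
  stopifnot(nrow(tuning) == n)

  lap_of <- rep(NA_integer_, nf)
  for (i in seq_len(nl)) lap_of[laps$start_frame[i]:laps$end_frame[i]] <- i

  dff <- matrix(0, n, nf)
  activation <- matrix(NA, n, max(nl, 1L))
  events <- list()
  decay_len <- max(1L, ceiling(8 * params$decay_tau * fr))
  kernel <- exp(-(seq_len(decay_len) - 1L) / (params$decay_tau * fr))
  lap_frames <- which(!is.na(lap_of))

  for (ci in seq_len(n)) {
    if (tuning$is_place[ci] && nl > 0L) {
      act <- stats::runif(nl) < params$reliability
      activation[ci, seq_len(nl)] <- act
      if (any(act)) {
        on <- !is.na(lap_of) & act[ifelse(is.na(lap_of), 1L, lap_of)]
        g <- numeric(nf)
        g[on] <- params$amplitude *
          exp(-(pos[on] - tuning$center[ci])^2 / (2 * tuning$sigma[ci]^2))
        dff[ci, ] <- g
      }
    } else if (!tuning$is_place[ci] && length(lap_frames) > 0L) {
      n_ev <- stats::rpois(1L, params$reliability * max(nl, 1L))
      if (n_ev > 0L) {
        t0 <- sort(sample(lap_frames, n_ev, replace = TRUE))
        x <- numeric(nf)
        for (f0 in t0) {
          idx <- f0:min(nf, f0 + decay_len - 1L)
          x[idx] <- x[idx] + params$amplitude * kernel[seq_along(idx)]
        }
        dff[ci, ] <- x
        events[[length(events) + 1L]] <- data.frame(cell = ci,
                                                    onset_frame = t0)
      }
    }
  }
  if (params$noise_sd > 0) {
    dff <- dff + matrix(stats::rnorm(n * nf, 0, params$noise_sd), n, nf)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(cell = integer(0), onset_frame = integer(0))
  list(dff = dff,
       truth = list(tuning = tuning, activation = activation, events = ev))
}

#' Simulate a matched pair of sessions with controlled remapping
#'
#' Session 2 copies session 1's latent tuning except that a
#' `remap_fraction` subset of the place cells draws new centers uniformly
#' on the track, and every tuning width is multiplied by
#' `width_scale_session2` (< 1 models across-day field narrowing). Lap
#' activations and noise are drawn independently per session. The
#' returned identity map plays the role of the cross-day cell-matching
#' table produced by image alignment in a real experiment.
#'
#' @param behavior_a,behavior_b behavior sessions for the two days (a
#'   single session may be passed twice).
#' @param params a [calcium_sim_params()] (its `remap_fraction` and
#'   `width_scale_session2` are used unless overridden).
#' @param remap_fraction,width_scale_session2 optional overrides.
#' @return list with `a` and `b` (each a [simulate_traces()] result),
#'   `match` (data frame `cell_a`, `cell_b`), and `remapped` (logical per
#'   cell).
#' @export
simulate_two_sessions <- function(behavior_a, behavior_b, params,
                                  remap_fraction = params$remap_fraction,
                                  width_scale_session2 =
                                    params$width_scale_session2) {
  stopifnot(inherits(params, "calcium_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  tun_a <- .draw_tuning(params, behavior_a$track_length)
  a <- simulate_traces(behavior_a,
                       calcium_sim_params_noseed(params), tuning = tun_a)
  tun_b <- tun_a
  pc <- which(tun_a$is_place)
  remapped <- rep(FALSE, params$n_cells)
  n_remap <- round(remap_fraction * length(pc))
  if (n_remap > 0L) {
    sel <- pc[sample.int(length(pc), n_remap)]
    tun_b$center[sel] <- stats::runif(n_remap, 0, behavior_b$track_length)
    remapped[sel] <- TRUE
  }
  tun_b$sigma <- tun_b$sigma * width_scale_session2
  b <- simulate_traces(behavior_b,
                       calcium_sim_params_noseed(params), tuning = tun_b)
  list(a = a, b = b,
       match = data.frame(cell_a = seq_len(params$n_cells),
                          cell_b = seq_len(params$n_cells)),
       remapped = remapped)
}

# copy of params with seed removed, so nested calls share one RNG stream
calcium_sim_params_noseed <- function(params) {
  params$seed <- NULL
  params
}
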