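#' Candidate place fields from a mean spatial profile
#'
#' Candidates are maximal contiguous runs of bins whose session-mean dF/F
#' exceeds the cell's baseline by more than 10%. The baseline is a low
#' quantile (default the 20th percentile) of the cell's 40-bin mean map, a
#' statistic robust to the field's own occupancy of the map; the threshold
#' is `baseline + 0.10 * |baseline|`, which reduces to 110% of the baseline
#' for the usual positive baselines. Runs may not span unobserved bins.
#' Multiple candidates per cell are returned and treated independently
#' downstream.
#'
#' @param profile numeric vector of per-bin session-mean dF/F (one cell).
#' @param baseline_quantile quantile defining the baseline (default 0.2).
#' @return data frame with columns `start_bin`, `end_bin` (1-based,
#'   inclusive) and `n_bins`; attribute `baseline`.
#' @export
candidate_fields <- function(profile, baseline_quantile = 0.2) {
  obs <- !is.na(profile)
  if (!any(obs)) stop("profile has no observed bin")
  baseline <- stats::quantile(profile[obs], baseline_quantile, names = FALSE)
  thr <- baseline + 0.10 * abs(baseline)
  above <- obs & !is.na(profile) & profile > thr
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start_bin = starts[keep], end_bin = ends[keep],
                    n_bins = r$lengths[keep])
  structure(out, baseline = baseline)
}

#' Bootstrap significance test for a candidate field
#'
#' Tests spatial tuning of a candidate bin range against a shuffle null
#' that preserves within-lap structure: each lap's bin vector is
#' independently circularly rotated by a uniform random offset. The
#' statistic is the mean dF/F over in-candidate (lap, bin) entries minus
#' the mean over out-of-candidate entries; the p-value uses the add-one
#' estimator `(1 + #{null >= observed}) / (1 + n_shuffles)`, so the
#' smallest attainable p is `1/(n_shuffles + 1)` and p is never 0.
#'
#' @param lap_maps numeric matrix, laps x bins, of one cell's binned dF/F
#'   (`NA` = unobserved).
#' @param candidate list or one-row data frame with `start_bin`,
#'   `end_bin` (1-based, inclusive).
#' @param n_shuffles number of random rotations (default 1000, minimum
#'   100).
#' @param seed optional integer seed for reproducibility.
#' @return list with `boot_p`, `stat_obs`, and `n_shuffles`.
#' @export
bootstrap_field_test <- function(lap_maps, candidate, n_shuffles = 1000,
                                 seed = NULL) {
  stopifnot(n_shuffles >= 100)
  if (!is.null(seed)) set.seed(seed)
  lap_maps <- as.matrix(lap_maps)
  L <- nrow(lap_maps); B <- ncol(lap_maps)
  fb <- seq(candidate$start_bin, candidate$end_bin)
  if (length(fb) >= B) {
    return(list(boot_p = NA_real_, stat_obs = NA_real_,
                n_shuffles = n_shuffles))
  }
  f <- numeric(B); f[fb] <- 1
  V <- lap_maps; V[is.na(V)] <- 0
  O <- (!is.na(lap_maps)) * 1
  # Fmat[b, r] = f[(b - 1 + r - 1) %% B + 1]: in-field sums for every
  # rotation offset come from one matrix product per cell.
  Fmat <- matrix(f[(outer(seq_len(B) - 1L, seq_len(B) - 1L, `+`) %% B) + 1L],
                 B, B)
  S <- V %*% Fmat
  Cn <- O %*% Fmat
  tot_sum <- sum(V); tot_cnt <- sum(O)
  stat_at <- function(off) { # off: integer vector length L of 0-based offsets
    idx <- cbind(seq_len(L), off + 1L)
    in_sum <- sum(S[idx]); in_cnt <- sum(Cn[idx])
    out_cnt <- tot_cnt - in_cnt
    if (in_cnt == 0 || out_cnt == 0) return(NA_real_)
    in_sum / in_cnt - (tot_sum - in_sum) / out_cnt
  }
  obs <- stat_at(rep.int(0L, L))
  offs <- matrix(sample.int(B, L * n_shuffles, replace = TRUE) - 1L,
                 L, n_shuffles)
  null <- vapply(seq_len(n_shuffles), function(s) stat_at(offs[, s]),
                 numeric(1))
  p <- (1 + sum(null >= obs - 1e-12, na.rm = TRUE)) / (1 + n_shuffles)
  list(boot_p = p, stat_obs = obs, n_shuffles = n_shuffles)
}

# width at 25% of (peak - baseline) above baseline, linearly interpolated
# between bin centers; NA bins terminate the search. Returns width in cm,
# clamped below at one bin width.
.field_width <- function(profile, peak_bin, baseline, bin_width,
                         track_length) {
  thr <- baseline + 0.25 * (profile[peak_bin] - baseline)
  B <- length(profile)
  ctr <- function(b) (b - 0.5) * bin_width
  # walk left
  b <- peak_bin
  while (b > 1L && !is.na(profile[b - 1L]) && profile[b - 1L] >= thr) b <- b - 1L
  left <- if (b == 1L || is.na(profile[b - 1L])) {
    if (b == 1L) 0 else ctr(b) - bin_width / 2
  } else {
    ctr(b) - bin_width * (profile[b] - thr) / (profile[b] - profile[b - 1L])
  }
  b <- peak_bin
  while (b < B && !is.na(profile[b + 1L]) && profile[b + 1L] >= thr) b <- b + 1L
  right <- if (b == B || is.na(profile[b + 1L])) {
    if (b == B) track_length else ctr(b) + bin_width / 2
  } else {
    ctr(b) + bin_width * (profile[b] - thr) / (profile[b] - profile[b + 1L])
  }
  max(right - left, bin_width)
}

#' Parameters of an accepted place field
#'
#' Computes the center of mass (COM: activity-weighted mean position over
#' the field's bins), the field width (contiguous extent around the field
#' peak where the mean profile stays at least 25% of the peak-minus-
#' baseline above baseline, linearly interpolated between bin centers and
#' never smaller than one bin), the out/in-field firing ratio (mean dF/F
#' outside the field bins over mean inside, negative outside means clamped
#' to 0), and the mean in-field dF/F.
#'
#' @param profile per-bin session-mean dF/F of the cell.
#' @param start_bin,end_bin field bin range (1-based, inclusive).
#' @param baseline the cell's baseline (from [candidate_fields()]).
#' @param bin_width bin width, cm.
#' @param track_length track length, cm.
#' @return list with `com`, `width`, `out_in_ratio`, `mean_infield_dff`.
#' @export
field_parameters <- function(profile, start_bin, end_bin, baseline,
                             bin_width, track_length = 200) {
  fb <- start_bin:end_bin
  w <- profile[fb]
  com <- sum(((fb - 0.5) * bin_width) * w) / sum(w)
  peak_bin <- fb[which.max(w)]
  width <- .field_width(profile, peak_bin, baseline, bin_width,
                        track_length)
  outside <- profile[-fb]
  mean_out <- mean(outside, na.rm = TRUE)
  if (!is.finite(mean_out)) mean_out <- 0
  mean_in <- mean(w, na.rm = TRUE)
  ratio <- if (mean_in > 0) max(mean_out, 0) / mean_in else NA_real_
  list(com = com, width = width, out_in_ratio = ratio,
       mean_infield_dff = mean_in)
}

#' Detect place fields in a session
#'
#' The full detection pipeline. Candidates from [candidate_fields()] are
#' accepted as place fields only if all four criteria hold:
#' \enumerate{
#'   \item mean in-field dF/F exceeds the cell's baseline by more than 10%
#'     (built into candidate construction);
#'   \item the cell shows significant calcium transients on more than
#'     `reliability_min` (strictly; default 30%) of laps inside the field
#'     during running;
#'   \item the rising flank of the spatial profile begins on the track:
#'     candidates touching the first bin (where the teleport deposits the
#'     animal) are rejected as boundary-truncated;
#'   \item the lap-rotation bootstrap p-value ([bootstrap_field_test()])
#'     is below `alpha` (default 0.05).
#' }
#' Multiple fields per cell are evaluated independently. Rejections carry
#' the first failed criterion.
#'
#' @param dff cells x frames dF/F matrix aligned to `session`.
#' @param session a [behavior_session()].
#' @param laps a `lap_table`; computed from `session` if `NULL`.
#' @param n_bins,speed_threshold passed to [bin_activity()].
#' @param baseline_quantile passed to [candidate_fields()].
#' @param transient_k,transient_min_dur passed to [detect_transients()].
#' @param reliability_min strict lower bound on field reliability.
#' @param n_shuffles,alpha bootstrap settings.
#' @param seed optional integer seed governing all shuffles.
#' @param map optionally, a precomputed `spatial_map` for `dff`.
#' @return data frame of accepted fields with columns `cell`, `cell_id`,
#'   `bin_start`, `bin_end` (0-based, inclusive), `com`, `width`,
#'   `reliability`, `out_in_ratio`, `boot_p`, `mean_infield_dff`;
#'   attributes `rejections` (data frame with `reason`), `n_cells`, and
#'   `map`.
#' @export
detect_place_fields <- function(dff, session, laps = NULL, n_bins = 40,
                                speed_threshold = 1,
                                baseline_quantile = 0.2, transient_k = 2,
                                transient_min_dur = 0.25,
                                reliability_min = 0.3, n_shuffles = 1000,
                                alpha = 0.05, seed = NULL, map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dff <- as.matrix(dff)
  if (is.null(laps)) laps <- segment_laps(session)
  if (is.null(map)) {
    map <- bin_activity(dff, session, laps, n_bins = n_bins,
                        speed_threshold = speed_threshold)
  }
  nc <- nrow(dff); nl <- map$n_laps; bw <- map$bin_width
  tr <- detect_transients(dff, session$frame_rate, k = transient_k,
                          min_dur = transient_min_dur)
  # annotate onsets with lap, bin and running status
  lap_of <- rep(NA_integer_, session$n_frames)
  for (i in seq_len(nrow(laps))) {
    lap_of[laps$start_frame[i]:laps$end_frame[i]] <- i
  }
  # plain vectors per transient onset; data-frame subsetting in the cell
  # loop is too slow for population-sized trace sets
  tr_cell <- tr$cell
  tr_lap <- if (nrow(tr) > 0L) lap_of[tr$onset_frame] else integer(0)
  tr_bin <- if (nrow(tr) > 0L) {
    pmin(floor(session$position[tr$onset_frame] / bw), n_bins - 1L) + 1L
  } else integer(0)
  tr_ok <- !is.na(tr_lap) &
    abs(session$velocity[tr$onset_frame]) >= speed_threshold
  by_cell <- split(which(tr_ok), tr_cell[tr_ok])

  acc <- list(cell = integer(0), sb = integer(0), eb = integer(0),
              com = numeric(0), width = numeric(0), rel = numeric(0),
              ratio = numeric(0), bp = numeric(0), infield = numeric(0))
  rej <- list(cell = integer(0), sb = integer(0), eb = integer(0),
              rel = numeric(0), bp = numeric(0), reason = character(0))
  for (ci in seq_len(nc)) {
    prof <- mean_profile(map, ci)
    if (!any(!is.na(prof))) next
    cand <- candidate_fields(prof, baseline_quantile)
    if (nrow(cand) == 0L) next
    baseline <- attr(cand, "baseline")
    idx <- by_cell[[as.character(ci)]]
    ev_lap <- tr_lap[idx]; ev_bin <- tr_bin[idx]
    lap_maps <- matrix(map$map[ci, , ], nl, n_bins)
    for (j in seq_len(nrow(cand))) {
      sb <- cand$start_bin[j]; eb <- cand$end_bin[j]
      rel <- if (length(ev_lap)) {
        length(unique(ev_lap[ev_bin >= sb & ev_bin <= eb])) / nl
      } else 0
      reason <- NULL
      if (rel <= reliability_min) {
        reason <- "reliability"
      } else if (sb <= 1L) {
        reason <- "rising_phase"
      }
      bp <- NA_real_
      if (is.null(reason)) {
        bt <- bootstrap_field_test(lap_maps,
                                   list(start_bin = sb, end_bin = eb),
                                   n_shuffles = n_shuffles)
        bp <- bt$boot_p
        if (!is.finite(bp) || bp >= alpha) reason <- "bootstrap"
      }
      if (is.null(reason)) {
        fp <- field_parameters(prof, sb, eb, baseline, bw,
                               map$track_length)
        acc$cell <- c(acc$cell, ci); acc$sb <- c(acc$sb, sb)
        acc$eb <- c(acc$eb, eb); acc$com <- c(acc$com, fp$com)
        acc$width <- c(acc$width, fp$width); acc$rel <- c(acc$rel, rel)
        acc$ratio <- c(acc$ratio, fp$out_in_ratio)
        acc$bp <- c(acc$bp, bp)
        acc$infield <- c(acc$infield, fp$mean_infield_dff)
      } else {
        rej$cell <- c(rej$cell, ci); rej$sb <- c(rej$sb, sb)
        rej$eb <- c(rej$eb, eb); rej$rel <- c(rej$rel, rel)
        rej$bp <- c(rej$bp, bp); rej$reason <- c(rej$reason, reason)
      }
    }
  }
  res <- data.frame(cell = acc$cell,
                    cell_id = as.character(map$cell_ids[acc$cell]),
                    bin_start = acc$sb - 1L, bin_end = acc$eb - 1L,
                    com = acc$com, width = acc$width,
                    reliability = acc$rel, out_in_ratio = acc$ratio,
                    boot_p = acc$bp, mean_infield_dff = acc$infield,
                    stringsAsFactors = FALSE)
  row.names(res) <- NULL
  rej <- data.frame(cell = rej$cell, bin_start = rej$sb - 1L,
                    bin_end = rej$eb - 1L, reliability = rej$rel,
                    boot_p = rej$bp, reason = rej$reason,
                    stringsAsFactors = FALSE)
  structure(res, rejections = rej, n_cells = nc, map = map,
            class = c("place_field_table", "data.frame"))
}

#' Fraction of recorded cells with a place field
#'
#' Cells with at least one accepted place field divided by the total
#' number of recorded cells, as a percentage.
#'
#' @param fields a `place_field_table` from [detect_place_fields()] (or
#'   any data frame with a `cell` column).
#' @param n_cells total number of recorded cells; defaults to the table's
#'   `n_cells` attribute.
#' @return percent in `[0, 100]`; `NA` when `n_cells` is 0.
#' @export
place_cell_fraction <- function(fields, n_cells = attr(fields, "n_cells")) {
  if (is.null(n_cells)) stop("n_cells not supplied")
  if (n_cells == 0) return(NA_real_)
  100 * length(unique(fields$cell)) / n_cells
}
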