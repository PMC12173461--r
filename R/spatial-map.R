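#' Bin calcium activity into a spatial activity map
#'
#' Divides the track into `n_bins` equal position bins (default 40 bins of
#' 5 cm on a 2 m track) and averages each cell's dF/F per lap and bin over
#' the running frames only: frames where the animal is immobile
#' (|velocity| < `speed_threshold`, default 1 cm/s) are excluded, so place
#' coding is estimated from active exploration and never from freezing
#' bouts. Bins are half-open `[k*w, (k+1)*w)` with the last bin closed at
#' the track end. Lap/bin combinations with no included frame are
#' unobserved (`NA` in the map, 0 occupancy).
#'
#' @param dff numeric matrix of dF/F traces, cells x frames, aligned
#'   frame-by-frame to `session`.
#' @param session the aligned [behavior_session()].
#' @param laps a `lap_table` from [segment_laps()] on `session`.
#' @param n_bins number of position bins (default 40).
#' @param speed_threshold immobility cutoff in cm/s (default 1).
#' @param cell_ids optional cell labels (default row names or indices).
#' @return object of class `spatial_map`: list with `map` (cells x laps x
#'   bins array of mean dF/F, `NA` where unobserved), `occupancy` (laps x
#'   bins included-frame counts), `n_bins`, `bin_width`, `speed_threshold`,
#'   `cell_ids`, `n_laps`, `track_length`.
#' @export
bin_activity <- function(dff, session, laps, n_bins = 40,
                         speed_threshold = 1, cell_ids = NULL) {
  dff <- as.matrix(dff)
  if (ncol(dff) != session$n_frames) {
    stop("dff has ", ncol(dff), " frames but the session has ",
         session$n_frames)
  }
  if (anyNA(dff)) stop("dff contains missing values")
  if (nrow(laps) == 0L) stop("lap table is empty")
  nc <- nrow(dff); nl <- nrow(laps)
  bw <- session$track_length / n_bins
  if (is.null(cell_ids)) cell_ids <- rownames(dff) %||% as.character(seq_len(nc))

  lap_of <- rep(NA_integer_, session$n_frames)
  for (i in seq_len(nl)) {
    lap_of[laps$start_frame[i]:laps$end_frame[i]] <- i
  }
  inc <- !is.na(lap_of) & abs(session$velocity) >= speed_threshold
  bin <- pmin(floor(session$position / bw), n_bins - 1L) + 1L
  grp <- (lap_of - 1L) * n_bins + bin

  map <- array(NA_real_, dim = c(nc, nl, n_bins),
               dimnames = list(cell_ids, NULL, NULL))
  occ <- matrix(0L, nl, n_bins)
  if (any(inc)) {
    g <- grp[inc]
    cnt <- tabulate(g, nbins = nl * n_bins)
    sums <- rowsum(t(dff[, inc, drop = FALSE]), group = g)
    ids <- as.integer(rownames(sums))
    flat <- matrix(NA_real_, nl * n_bins, nc) # [(lap-1)*n_bins + bin, cell]
    flat[ids, ] <- sums / cnt[ids]
    map <- aperm(array(flat, dim = c(n_bins, nl, nc)), c(3L, 2L, 1L))
    dimnames(map) <- list(cell_ids, NULL, NULL)
    occ[] <- matrix(cnt, nl, n_bins, byrow = TRUE)
  }
  structure(list(map = map, occupancy = occ, n_bins = n_bins,
                 bin_width = bw, speed_threshold = speed_threshold,
                 cell_ids = cell_ids, n_laps = nl,
                 track_length = session$track_length),
            class = "spatial_map")
}

#' @exportS3Method base::print
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %d cells x %d laps x %d bins (%.0f cm bins); %.1f%% bins observed\n",
              dim(x$map)[1L], x$n_laps, x$n_bins, x$bin_width,
              100 * mean(x$occupancy > 0)))
  invisible(x)
}

#' Session-mean spatial profile of one cell
#'
#' Mean over laps of the cell's binned dF/F, ignoring unobserved bins.
#'
#' @param map a `spatial_map`.
#' @param cell cell index or id.
#' @return numeric vector of length `n_bins` (`NA` where never observed).
#' @export
mean_profile <- function(map, cell) {
  m <- map$map[cell, , , drop = FALSE]
  prof <- colMeans(matrix(m, map$n_laps, map$n_bins), na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  prof
}

#' Activity-weighted center of mass of a spatial profile
#'
#' @param profile numeric vector of per-bin mean dF/F.
#' @param bin_width bin width in cm.
#' @param bins optional subset of bin indices to use (default all
#'   non-`NA`).
#' @return COM in cm.
#' @export
profile_com <- function(profile, bin_width, bins = NULL) {
  if (is.null(bins)) bins <- which(!is.na(profile))
  w <- profile[bins]
  centers <- (bins - 0.5) * bin_width
  sum(centers * w) / sum(w)
}
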