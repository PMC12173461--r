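#' Within-session split-half map correlation
#'
#' Stability control for remapping analyses: for each cell, correlates the
#' mean spatial profile of the first half of laps with that of the second
#' half (odd lap counts give the extra lap to the first half). Bins
#' unobserved in either half are dropped pairwise; cells with fewer than
#' 4 laps or fewer than `min_common_bins` common bins are undefined.
#'
#' @param map a `spatial_map`.
#' @param cells cell indices (default all).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_common_bins minimum number of pairwise-observed bins
#'   (default 10).
#' @return named numeric vector of correlations (`NA` where undefined).
#' @export
split_half_correlation <- function(map, cells = NULL, method = "pearson",
                                   min_common_bins = 10) {
  if (is.null(cells)) cells <- seq_len(dim(map$map)[1L])
  nl <- map$n_laps
  h1 <- seq_len(ceiling(nl / 2))
  h2 <- setdiff(seq_len(nl), h1)
  r <- vapply(cells, function(ci) {
    if (nl < 4L) return(NA_real_)
    m <- matrix(map$map[ci, , ], nl, map$n_bins)
    p1 <- colMeans(m[h1, , drop = FALSE], na.rm = TRUE)
    p2 <- colMeans(m[h2, , drop = FALSE], na.rm = TRUE)
    ok <- is.finite(p1) & is.finite(p2)
    if (sum(ok) < min_common_bins) return(NA_real_)
    suppressWarnings(stats::cor(p1[ok], p2[ok], method = method))
  }, numeric(1))
  names(r) <- map$cell_ids[cells]
  r
}

#' Across-session map correlation for matched cells
#'
#' Correlates each matched cell's session-mean spatial profile in a
#' reference session (A) with its profile in a comparison session (B).
#' When a place-field table for session A is supplied, the analysis is
#' restricted to cells holding an accepted field in the reference session
#' (fields "defined on day 0"), and the COM columns report the reference
#' field's COM and the COM of session B's profile over the same bins;
#' otherwise COMs are whole-profile. Unmatched or undefined cells are
#' skipped and counted.
#'
#' @param map_a,map_b `spatial_map`s of the two sessions.
#' @param match data frame with columns `cell_a`, `cell_b`; defaults to
#'   the identity map when both sessions have equal cell counts.
#' @param fields_a optional `place_field_table` for session A.
#' @param method,min_common_bins as in [split_half_correlation()].
#' @return data frame with `cell_a`, `cell_b`, `r`, `com_a`, `com_b`;
#'   attribute `n_skipped`.
#' @export
across_session_correlation <- function(map_a, map_b, match = NULL,
                                       fields_a = NULL,
                                       method = "pearson",
                                       min_common_bins = 10) {
  na_cells <- dim(map_a$map)[1L]; nb_cells <- dim(map_b$map)[1L]
  if (is.null(match)) {
    if (na_cells != nb_cells) {
      stop("sessions have different cell counts; a match map is required")
    }
    match <- data.frame(cell_a = seq_len(na_cells),
                        cell_b = seq_len(na_cells))
  }
  stopifnot(!anyDuplicated(match$cell_a), !anyDuplicated(match$cell_b))
  skipped <- sum(match$cell_a > na_cells | match$cell_b > nb_cells)
  match <- match[match$cell_a <= na_cells & match$cell_b <= nb_cells, ,
                 drop = FALSE]
  if (!is.null(fields_a)) {
    match <- match[match$cell_a %in% fields_a$cell, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(match)), function(i) {
    ca <- match$cell_a[i]; cb <- match$cell_b[i]
    pa <- mean_profile(map_a, ca)
    pb <- mean_profile(map_b, cb)
    ok <- is.finite(pa) & is.finite(pb)
    r <- if (sum(ok) < min_common_bins) NA_real_ else
      suppressWarnings(stats::cor(pa[ok], pb[ok], method = method))
    if (!is.null(fields_a)) {
      fld <- fields_a[fields_a$cell == ca, ][1L, ]
      bins <- (fld$bin_start:fld$bin_end) + 1L
      com_a <- fld$com
      com_b <- if (all(is.na(pb[bins]))) NA_real_ else
        profile_com(pb, map_b$bin_width, bins[!is.na(pb[bins])])
    } else {
      com_a <- if (any(ok)) profile_com(pa, map_a$bin_width, which(is.finite(pa))) else NA_real_
      com_b <- if (any(ok)) profile_com(pb, map_b$bin_width, which(is.finite(pb))) else NA_real_
    }
    data.frame(cell_a = ca, cell_b = cb, r = r, com_a = com_a,
               com_b = com_b)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_a = integer(0), cell_b = integer(0), r = numeric(0),
               com_a = numeric(0), com_b = numeric(0))
  structure(out, n_skipped = skipped)
}

#' Compare place-field populations between two sessions
#'
#' Paired comparison of field parameters (width, reliability, out/in
#' ratio) between two analyzed sessions. Inference is at the mouse level
#' to avoid pseudoreplication: per-mouse means are formed and compared
#' with a paired t-test across the mice present in both sessions; pooled
#' per-cell medians are reported descriptively alongside. With a single
#' mouse (or no `mouse` column) only descriptives are returned. Direction
#' flags report field narrowing (significant width decrease in B) and a
#' place-cell count increase.
#'
#' @param fields_a,fields_b `place_field_table`s (optionally with a
#'   `mouse` column).
#' @return list of class `field_population_comparison`: `tests` (data
#'   frame: parameter, per-mouse means, mean difference B-A, t, p, n
#'   mice), `pooled` (per-parameter medians and field/cell counts),
#'   `narrowing`, `fraction_increase`.
#' @export
compare_field_populations <- function(fields_a, fields_b) {
  pars <- c("width", "reliability", "out_in_ratio")
  pooled <- data.frame(
    parameter = pars,
    median_a = vapply(pars, function(p) stats::median(fields_a[[p]]), numeric(1)),
    median_b = vapply(pars, function(p) stats::median(fields_b[[p]]), numeric(1)),
    row.names = NULL)
  counts <- c(n_fields_a = nrow(fields_a), n_fields_b = nrow(fields_b),
              n_cells_a = length(unique(fields_a$cell)),
              n_cells_b = length(unique(fields_b$cell)))

  tests <- NULL
  has_mice <- !is.null(fields_a$mouse) && !is.null(fields_b$mouse) &&
    length(intersect(unique(fields_a$mouse), unique(fields_b$mouse))) >= 2L
  if (has_mice) {
    mice <- sort(intersect(unique(fields_a$mouse), unique(fields_b$mouse)))
    tests <- do.call(rbind, lapply(pars, function(p) {
      ma <- vapply(mice, function(m) mean(fields_a[[p]][fields_a$mouse == m]),
                   numeric(1))
      mb <- vapply(mice, function(m) mean(fields_b[[p]][fields_b$mouse == m]),
                   numeric(1))
      pt <- paired_test(mb, ma)
      data.frame(parameter = p, mean_a = mean(ma), mean_b = mean(mb),
                 mean_diff = pt$mean_diff, t = pt$t, p = pt$p,
                 n_mice = length(mice))
    }))
  }
  narrowing <- if (!is.null(tests)) {
    w <- tests[tests$parameter == "width", ]
    isTRUE(w$mean_diff < 0 && w$p < 0.05)
  } else {
    pooled$median_b[pooled$parameter == "width"] <
      pooled$median_a[pooled$parameter == "width"]
  }
  structure(list(tests = tests, pooled = pooled, counts = counts,
                 narrowing = narrowing,
                 fraction_increase =
                   counts["n_cells_b"] > counts["n_cells_a"]),
            class = "field_population_comparison")
}

#' @exportS3Method base::print
print.field_population_comparison <- function(x, ...) {
  cat("<field_population_comparison>\n")
  print(x$pooled)
  if (!is.null(x$tests)) {
    cat("mouse-level paired tests (B - A):\n")
    print(x$tests)
  } else {
    cat("(single session group: descriptives only)\n")
  }
  cat(sprintf("narrowing: %s; place-cell count increase: %s\n",
              x$narrowing, x$fraction_increase))
  invisible(x)
}
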