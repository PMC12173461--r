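#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of an end-to-end synthetic run (simulate ->
#' behavior -> place cells -> remapping -> stats) in one validated list.
#' All randomness flows from the named seeds, which are recorded in the
#' run manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param paradigm experimental paradigm, 1, 2 or 3.
#' @param n_mice,n_recall_days,effect cohort settings
#'   (see [simulate_cohort()]).
#' @param epsilon freezing velocity tolerance, cm/s.
#' @param min_epoch_s minimum freezing-epoch duration, s.
#' @param n_bins,bin_width_cm spatial binning; their product must equal
#'   `track_length`.
#' @param speed_threshold immobility cutoff for binning, cm/s.
#' @param n_shuffles bootstrap shuffles for field detection.
#' @param n_cells cells in the synthetic imaging session.
#' @param track_length track length, cm.
#' @param seeds named list with integer `behavior`, `imaging`,
#'   `detection` seeds.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir, paradigm = 1, n_mice = 6,
                       n_recall_days = 1, effect = 8, epsilon = 0,
                       min_epoch_s = 1, n_bins = 40, bin_width_cm = 5,
                       speed_threshold = 1, n_shuffles = 200,
                       n_cells = 60, track_length = 200,
                       seeds = list(behavior = 1L, imaging = 2L,
                                    detection = 3L)) {
  if (abs(n_bins * bin_width_cm - track_length) > 1e-9) {
    stop("n_bins * bin_width_cm must equal track_length")
  }
  stopifnot(paradigm %in% 1:3, n_mice >= 2, epsilon >= 0,
            min_epoch_s > 0, n_shuffles >= 100, n_cells >= 1)
  for (s in c("behavior", "imaging", "detection")) {
    if (is.null(seeds[[s]])) stop("missing seed: ", s)
  }
  structure(list(out_dir = out_dir, paradigm = paradigm, n_mice = n_mice,
                 n_recall_days = n_recall_days, effect = effect,
                 epsilon = epsilon, min_epoch_s = min_epoch_s,
                 n_bins = n_bins, bin_width_cm = bin_width_cm,
                 speed_threshold = speed_threshold,
                 n_shuffles = n_shuffles, n_cells = n_cells,
                 track_length = track_length,
                 seeds = lapply(seeds, as.integer)),
            class = "run_config")
}

# deterministic polynomial hash of the JSON-serialized config
.config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: cohort simulation, behavioral metrics, the
#' behavioral statistics (recall-day paired tests, discrimination delta,
#' paired Cohen's d, per-context extinction LME), synthetic imaging of a
#' pre-conditioning vs recall session pair for the first mouse,
#' place-field detection on both sessions, and remapping statistics.
#' Every stage writes its tables (CSV) and a summary report plus a run
#' manifest (JSON) into `config$out_dir`; re-running with the same config
#' reproduces all outputs byte for byte. A stage failure stops the run
#' with the stage named, retaining the outputs already written.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `report`, `manifest` and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate-behavior", simulate_cohort(
    config$paradigm, config$n_mice, effect = config$effect,
    seed = config$seeds$behavior, n_recall_days = config$n_recall_days))

  metrics <- stage("analyze-behavior", {
    m <- cohort_metrics(cohort, epsilon = config$epsilon)
    utils::write.csv(m, pth("session_metrics.csv"), row.names = FALSE)
    s1 <- cohort$sessions[[1L]]$session
    laps1 <- segment_laps(s1)
    sm1 <- session_metrics(s1, laps1, detect_freezing(s1, config$epsilon))
    pl <- sm1$per_lap
    utils::write.csv(
      data.frame(lap_index = pl$lap, start_s = pl$start_s,
                 end_s = pl$end_s, duration_s = pl$duration_s,
                 freezing_pct = pl$freezing_pct),
      pth("laps_mouse1.csv"), row.names = FALSE)
    m
  })

  beh_stats <- stage("stats", {
    r1 <- metrics[metrics$day == 1L, ]
    cfc <- r1[r1$context_role == "cfc", ]
    cfc <- cfc[order(cfc$mouse), ]
    neu <- r1[r1$context_role == "neutral", ]
    neu <- neu[order(neu$mouse), ]
    pt_avg <- paired_test(cfc$avg_freezing_pct, neu$avg_freezing_pct)
    pt_first <- paired_test(cfc$first_lap_freezing_pct,
                            neu$first_lap_freezing_pct)
    long <- .metrics_to_long(metrics)
    lme_list <- lapply(unique(long$vr_context), function(ctx) {
      fit <- fit_lme_freezing(long, ctx, metric = "average")
      data.frame(context = ctx, fit$coef)
    })
    lme_tab <- do.call(rbind, lme_list)
    utils::write.csv(lme_tab, pth("lme_average_freezing.csv"),
                     row.names = FALSE)
    list(delta_avg_freezing = pt_avg$mean_diff,
         p_avg_freezing = pt_avg$p,
         d_avg_freezing = cohens_d_paired(cfc$avg_freezing_pct,
                                          neu$avg_freezing_pct),
         delta_first_lap = pt_first$mean_diff,
         p_first_lap = pt_first$p,
         d_first_lap = cohens_d_paired(cfc$first_lap_freezing_pct,
                                       neu$first_lap_freezing_pct),
         lme = lme_tab)
  })

  imaging <- stage("simulate-imaging", {
    meta <- cohort$meta
    ia <- which(meta$mouse == 1L & meta$session_label == "before_cfc" &
                  meta$context_role == "cfc")[1L]
    ib <- which(meta$mouse == 1L & meta$day == 1L &
                  meta$context_role == "cfc")[1L]
    set.seed(config$seeds$imaging)
    params <- calcium_sim_params(config$n_cells)
    two <- simulate_two_sessions(cohort$sessions[[ia]]$session,
                                 cohort$sessions[[ib]]$session, params)
    list(two = two, sess_a = cohort$sessions[[ia]]$session,
         sess_b = cohort$sessions[[ib]]$session)
  })

  remap <- stage("analyze-placecells", {
    fa <- detect_place_fields(imaging$two$a$dff, imaging$sess_a,
                              n_bins = config$n_bins,
                              speed_threshold = config$speed_threshold,
                              n_shuffles = config$n_shuffles,
                              seed = config$seeds$detection)
    fb <- detect_place_fields(imaging$two$b$dff, imaging$sess_b,
                              n_bins = config$n_bins,
                              speed_threshold = config$speed_threshold,
                              n_shuffles = config$n_shuffles,
                              seed = config$seeds$detection + 1L)
    utils::write.csv(as.data.frame(fa), pth("fields_day0.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fb), pth("fields_recall.csv"),
                     row.names = FALSE)
    map_a <- attr(fa, "map"); map_b <- attr(fb, "map")
    r_within <- split_half_correlation(map_a)
    acr <- across_session_correlation(map_a, map_b,
                                      match = imaging$two$match,
                                      fields_a = fa)
    stab <- data.frame(cell = acr$cell_a,
                       r_within = r_within[acr$cell_a],
                       r_across = acr$r, com_a = acr$com_a,
                       com_b = acr$com_b)
    utils::write.csv(stab, pth("stability.csv"), row.names = FALSE)
    ks <- if (sum(is.finite(stab$r_within)) > 0 &&
                sum(is.finite(stab$r_across)) > 0) {
      ks_two_sample(stab$r_within, stab$r_across)
    } else list(statistic = NA_real_, p = NA_real_)
    list(fraction_a = place_cell_fraction(fa),
         fraction_b = place_cell_fraction(fb),
         comparison = compare_field_populations(fa, fb),
         ks_within_vs_across = ks)
  })

  report <- list(
    behavior = beh_stats[setdiff(names(beh_stats), "lme")],
    lme_day_terms = beh_stats$lme,
    place_cell_fraction_day0 = remap$fraction_a,
    place_cell_fraction_recall = remap$fraction_b,
    median_width_day0 =
      remap$comparison$pooled$median_a[remap$comparison$pooled$parameter == "width"],
    median_width_recall =
      remap$comparison$pooled$median_b[remap$comparison$pooled$parameter == "width"],
    ks_within_vs_across = remap$ks_within_vs_across)
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  manifest <- list(package = "fearfield",
                   version = as.character(utils::packageVersion("fearfield")),
                   config = unclass(config),
                   config_hash = .config_hash(config))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(report = report, manifest = manifest,
                 out_dir = config$out_dir))
}

# reshape cohort metrics into the long extinction-table format:
# Day0 = pre-conditioning exploration, RecallK = recall day K
.metrics_to_long <- function(metrics) {
  keep <- metrics$session_label == "before_cfc" | metrics$day >= 1L
  m <- metrics[keep, , drop = FALSE]
  day <- ifelse(m$session_label == "before_cfc", "Day0",
                paste0("Recall", m$day))
  rbind(
    data.frame(mouse_id = paste0("m", m$mouse), vr_context = m$context_id,
               day = day, freezing_pct = m$avg_freezing_pct,
               metric = "average"),
    data.frame(mouse_id = paste0("m", m$mouse), vr_context = m$context_id,
               day = day, freezing_pct = m$first_lap_freezing_pct,
               metric = "first_lap"))
}
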