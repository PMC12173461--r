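#' Paired t-test with mean difference and 95% CI
#'
#' Two-sided paired t-test between two conditions measured on the same
#' mice, reporting the mean difference (a - b) and its t-distribution 95%
#' confidence interval. If all differences are identical the test is
#' degenerate: t is 0 (and p 1) when the common difference is zero,
#' otherwise signed infinite with p 0, and `degenerate` is flagged.
#'
#' @param a,b numeric vectors of per-mouse values, equal length >= 2.
#' @param conf_level confidence level (default 0.95).
#' @return list with `t`, `df`, `p`, `mean_diff`, `ci` (length 2), `n`,
#'   `degenerate`.
#' @export
paired_test <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("paired test requires n >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    md <- mean(d)
    t <- if (md == 0) 0 else sign(md) * Inf
    return(list(t = t, df = n - 1L, p = if (md == 0) 1 else 0,
                mean_diff = md, ci = c(md, md), n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate),
       ci = as.numeric(ht$conf.int), n = n, degenerate = FALSE)
}

#' Paired Cohen's d
#'
#' Effect size for a within-subject comparison. The default variant is
#' d_z = mean(differences) / sd(differences), the natural paired choice;
#' `"dav"` divides instead by the average of the two condition standard
#' deviations. Zero-variance differences make d_z undefined (`NA` with a
#' warning).
#'
#' @param a,b numeric vectors of paired values, equal length >= 2.
#' @param variant `"dz"` (default) or `"dav"`.
#' @return numeric effect size.
#' @export
cohens_d_paired <- function(a, b, variant = c("dz", "dav")) {
  variant <- match.arg(variant)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (variant == "dz") {
    s <- stats::sd(d)
    if (s == 0) {
      warning("zero-variance differences: Cohen's d undefined")
      return(NA_real_)
    }
    mean(d) / s
  } else {
    s <- (stats::sd(a) + stats::sd(b)) / 2
    if (s == 0) {
      warning("zero-variance samples: Cohen's d undefined")
      return(NA_real_)
    }
    mean(d) / s
  }
}

#' Bonferroni correction
#'
#' Adjusted p-values `min(1, p * m)`. Unlike [stats::p.adjust()], `m` may
#' exceed the number of p-values supplied (e.g. when only a subset of a
#' larger comparison family is being reported).
#'
#' @param p numeric vector of p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return adjusted p-values, clamped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= length(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * m)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Classical two-tailed two-sample KS statistic with the asymptotic
#' p-value, used to compare correlation or parameter distributions
#' between conditions.
#'
#' @param x,y numeric samples (nonempty; `NA` dropped).
#' @return list with `statistic` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Fit the extinction linear mixed-effects model
#'
#' Models freezing across recall days for one virtual context:
#' `freezing_pct ~ day + (1 | mouse_id)` with the pre-conditioning Day 0
#' session as the reference level, so each day coefficient estimates the
#' freezing elevation over baseline on that recall day. Estimation is by
#' REML via \pkg{lme4}; p-values are Wald normal approximations. Singular
#' fits (degenerate mouse-intercept variance) are flagged but estimates
#' are still returned.
#'
#' @param table long-format data frame with columns `mouse_id`,
#'   `vr_context`, `day`, `freezing_pct`, `metric`.
#' @param context which `vr_context` to model (one context per model).
#' @param metric which `metric` rows to use (default `"average"`).
#' @param baseline the `day` level serving as reference (default
#'   `"Day0"`).
#' @return object of class `lme_freezing`: list with `coef` (data frame:
#'   `term`, `estimate`, `se`, `p`), `random_intercept_sd`,
#'   `residual_sd`, `singular`, `n_mice`, `n_obs`, `context`, `metric`,
#'   and the fitted `model`.
#' @export
fit_lme_freezing <- function(table, context, metric = "average",
                             baseline = "Day0") {
  d <- table[table$vr_context == context & table$metric == metric, ,
             drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for context ", context)
  d$day <- stats::relevel(factor(d$day), ref = baseline)
  if (nlevels(d$day) < 2L) stop("need at least 2 days")
  if (length(unique(d$mouse_id)) < 3L) stop("need at least 3 mice")
  fit <- lme4::lmer(freezing_pct ~ day + (1 | mouse_id), data = d,
                    REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- fe / se
  coef_tab <- data.frame(term = sub("^day", "", names(fe)),
                         estimate = unname(fe), se = unname(se),
                         p = unname(2 * stats::pnorm(-abs(z))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coef = coef_tab,
                 random_intercept_sd =
                   vc$sdcor[vc$grp == "mouse_id"][1L],
                 residual_sd = vc$sdcor[vc$grp == "Residual"][1L],
                 singular = lme4::isSingular(fit),
                 n_mice = length(unique(d$mouse_id)), n_obs = nrow(d),
                 context = context, metric = metric, model = fit),
            class = "lme_freezing")
}

#' @exportS3Method base::print
print.lme_freezing <- function(x, ...) {
  cat(sprintf("<lme_freezing> context %s, metric %s: %d mice, %d obs%s\n",
              x$context, x$metric, x$n_mice, x$n_obs,
              if (x$singular) " [singular fit]" else ""))
  tab <- x$coef
  tab$summary <- sprintf("%.2f±%.2f, p=%.3g", tab$estimate, tab$se,
                         tab$p)
  print(tab[, c("term", "summary")], row.names = FALSE)
  cat(sprintf("mouse intercept sd %.2f, residual sd %.2f\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Simulate a long-format extinction freezing table
#'
#' Gaussian generator for testing [fit_lme_freezing()]: per-mouse random
#' intercepts (sd `mouse_sd`) plus day effects plus residual noise (sd
#' `resid_sd`), one observation per mouse and day, clamped to [0, 100].
#'
#' @param n_mice number of mice.
#' @param day_effects named numeric vector of freezing elevations over
#'   baseline, one per recall day (names become `day` levels).
#' @param baseline_mean Day-0 baseline freezing percent.
#' @param mouse_sd,resid_sd random-intercept and residual sds.
#' @param context,metric labels for the generated rows.
#' @param seed optional integer seed.
#' @return data frame in the [fit_lme_freezing()] input format.
#' @export
simulate_extinction_table <- function(n_mice,
                                      day_effects = c(Recall1 = 10),
                                      baseline_mean = 10, mouse_sd = 3,
                                      resid_sd = 4, context = "CFC",
                                      metric = "average", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  days <- c("Day0", names(day_effects))
  eff <- c(0, unname(day_effects))
  a <- stats::rnorm(n_mice, 0, mouse_sd)
  rows <- expand.grid(mouse_id = paste0("m", seq_len(n_mice)),
                      day = days, stringsAsFactors = FALSE)
  rows$vr_context <- context
  rows$metric <- metric
  rows$freezing_pct <- pmin(100, pmax(0,
    baseline_mean + eff[match(rows$day, days)] +
      a[match(rows$mouse_id, paste0("m", seq_len(n_mice)))] +
      stats::rnorm(nrow(rows), 0, resid_sd)))
  rows[, c("mouse_id", "vr_context", "day", "freezing_pct", "metric")]
}
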