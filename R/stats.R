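# Cohort-level statistical analysis: linearity tests against the
# constant-rate reference ratio 0.8, bundle-branch-block group comparisons,
# and moderation models for the activation-time ratios.

#' One-sample t-test of activation ratios against a reference value
#'
#' Tests whether a set of time-to-fraction ratios (e.g. per-patient
#' RV80/QRS values) differs from the constant-rate reference 0.8: under a
#' linear activation-versus-time function, 80% of the chamber surface is
#' activated within 80% of the QRS duration, so a mean ratio away from 0.8
#' indicates temporally variable activation.
#'
#' @param values numeric vector of ratios (n >= 2, finite).
#' @param mu0 reference value (default 0.8).
#' @return an object of class `htest` (two-sided one-sample t-test).
#' @export
one_sample_t_vs <- function(values, mu0 = 0.8) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    crt_stop("need at least 2 values for a one-sample t-test",
             "crt80_sample_size_error")
  if (anyNA(values) || any(!is.finite(values)))
    crt_stop("values must be finite", "crt80_validation_error")
  if (stats::sd(values) == 0) {
    # degenerate sample: t is 0/0 when every ratio equals the reference
    # (report t = 0, p = 1), +/-Inf otherwise
    t0 <- if (mean(values) == mu0) 0 else sign(mean(values) - mu0) * Inf
    return(structure(list(
      statistic = c(t = t0), parameter = c(df = length(values) - 1L),
      p.value = if (t0 == 0) 1 else 0,
      estimate = c(`mean of x` = mean(values)),
      null.value = c(mean = mu0), alternative = "two.sided",
      method = "One Sample t-test", data.name = "values"
    ), class = "htest"))
  }
  stats::t.test(values, mu = mu0)
}

# resolve a metric column like "lv80_intrinsic" from (metric, setting)
metric_column <- function(cohort, metric, setting) {
  col <- paste0(tolower(metric), "_", tolower(setting))
  if (!col %in% names(cohort))
    crt_stop(sprintf("column '%s' not present in cohort table", col),
             "crt80_validation_error")
  col
}

#' Per-group regression slopes of an activation time on QRS duration
#'
#' Fits `metric ~ QRS` separately in the LBBB and RBBB groups by ordinary
#' least squares and tests the group difference in slope via the
#' `group x QRS` interaction term of the pooled model
#' `metric ~ bbb * qrs_ms`. The per-group slopes approximate the average
#' metric/QRS ratio in each group.
#'
#' @param cohort cohort data frame with columns `bbb` (`"LBBB"`/`"RBBB"`),
#'   `qrs_ms`, and the metric column `<metric>_<setting>`.
#' @param metric `"LV80"`, `"RV80"` or `"BIV80"` (any fraction tag present
#'   in the table works, e.g. `"LV70"`).
#' @param setting pacing setting whose metrics to use.
#' @return list with `slopes` (named, per group), `se`, `interaction_p`,
#'   the per-group `fits` and the `pooled` interaction model.
#' @export
slope_by_group <- function(cohort, metric = "LV80", setting = "INTRINSIC") {
  col <- metric_column(cohort, metric, setting)
  d <- cohort[stats::complete.cases(cohort[, c(col, "qrs_ms", "bbb")]), ]
  groups <- c("LBBB", "RBBB")
  ng <- table(factor(d$bbb, levels = groups))
  if (any(ng < 3L))
    crt_stop(sprintf("each group needs >= 3 patients (LBBB %d, RBBB %d)",
                     ng["LBBB"], ng["RBBB"]), "crt80_sample_size_error")
  fits <- lapply(groups, function(g)
    stats::lm(stats::reformulate("qrs_ms", col), d[d$bbb == g, ]))
  names(fits) <- groups
  slopes <- vapply(fits, function(f) unname(stats::coef(f)["qrs_ms"]), 0)
  ses <- vapply(fits, function(f)
    summary(f)$coefficients["qrs_ms", "Std. Error"], 0)
  pooled <- stats::lm(stats::reformulate("bbb * qrs_ms", col), d)
  cf <- summary(pooled)$coefficients
  int_row <- grep(":qrs_ms$|^qrs_ms:", rownames(cf))
  list(slopes = slopes, se = ses,
       interaction_coef = unname(cf[int_row, "Estimate"]),
       interaction_p = unname(cf[int_row, "Pr(>|t|)"]),
       fits = fits, pooled = pooled, n = as.vector(ng))
}

#' Moderation models for activation-time ratios
#'
#' Regresses a ratio (e.g. LV80/QRS) on bundle-branch-block status, then
#' adds one `bbb x moderator` interaction at a time to ask whether the
#' LBBB-RBBB difference depends on scar (late gadolinium enhancement),
#' ischemic etiology, Q-LV time or QRS duration.
#'
#' @param cohort cohort data frame.
#' @param ratio ratio name in the form `"LV80/QRS"`, `"RV80/QRS"` or
#'   `"BIV80/QRS"`.
#' @param setting pacing setting whose metric enters the numerator.
#' @param moderators character vector among
#'   `c("lge_present", "ischemic", "qlv_ms", "qrs_ms")` (default none).
#' @return list with `base` fit (ratio ~ bbb), `bbb_coef`, `bbb_p`, and per
#'   moderator the interaction coefficient and p-value.
#' @export
ratio_model <- function(cohort, ratio = "LV80/QRS", setting = "INTRINSIC",
                        moderators = character()) {
  metric <- sub("/QRS$", "", ratio)
  col <- metric_column(cohort, metric, setting)
  miss <- setdiff(moderators, names(cohort))
  if (length(miss) > 0L)
    crt_stop(paste("moderators not in cohort:", paste(miss, collapse = ", ")),
             "crt80_validation_error")
  d <- cohort
  d$.ratio <- d[[col]] / d$qrs_ms
  base <- stats::lm(.ratio ~ bbb, d)
  cfb <- summary(base)$coefficients
  bbb_row <- grep("^bbb", rownames(cfb))
  inter <- lapply(moderators, function(m) {
    f <- stats::lm(stats::reformulate(paste0("bbb * ", m), ".ratio"), d)
    cf <- summary(f)$coefficients
    row <- grep(":", rownames(cf))
    list(moderator = m, coef = unname(cf[row, "Estimate"]),
         p = unname(cf[row, "Pr(>|t|)"]), fit = f)
  })
  names(inter) <- moderators
  list(base = base,
       bbb_coef = unname(cfb[bbb_row, "Estimate"]),
       bbb_p = unname(cfb[bbb_row, "Pr(>|t|)"]),
       interactions = inter)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, non-zero variance).
#' @return list with `r`, `p` and `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    crt_stop("need at least 3 complete pairs", "crt80_sample_size_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    crt_stop("correlation undefined for zero-variance input",
             "crt80_domain_error")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare a variable between bundle-branch-block groups
#'
#' Kruskal-Wallis for continuous variables, Fisher's exact test on the
#' 2 x k contingency table for categorical ones; Shapiro-Wilk normality
#' p-values per group are returned as a diagnostic for continuous
#' variables.
#'
#' @param cohort cohort data frame with a `bbb` column.
#' @param variable column to compare.
#' @param kind `"continuous"` or `"categorical"`.
#' @return list with `p`, the underlying `test` object, and (continuous
#'   only) `shapiro_p` per group.
#' @export
group_compare <- function(cohort, variable,
                          kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!variable %in% names(cohort))
    crt_stop(sprintf("column '%s' not in cohort", variable),
             "crt80_validation_error")
  d <- cohort[!is.na(cohort[[variable]]), ]
  ng <- table(factor(d$bbb, levels = c("LBBB", "RBBB")))
  if (any(ng == 0L))
    crt_stop("both bundle-branch-block groups must be non-empty",
             "crt80_sample_size_error")
  if (kind == "continuous") {
    test <- stats::kruskal.test(d[[variable]], factor(d$bbb))
    sh <- vapply(split(d[[variable]], d$bbb), function(v) {
      if (length(unique(v)) < 3L || length(v) < 3L) return(NA_real_)
      stats::shapiro.test(v)$p.value
    }, 0)
    list(p = test$p.value, test = test, shapiro_p = sh)
  } else {
    tab <- table(d$bbb, d[[variable]])
    test <- stats::fisher.test(tab)
    list(p = test$p.value, test = test, table = tab)
  }
}
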