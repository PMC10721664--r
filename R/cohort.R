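# Synthetic cohort generation: per-patient activation maps across the five
# pacing settings, electrical metrics, and outcomes linearly coupled to the
# electrical predictors.

#' Default outcome-coupling model for synthetic cohorts
#'
#' Each CRT response outcome is generated as
#' `intercept + slope * predictor + Normal(0, noise_sd)`, with the
#' predictors the ones the response models use downstream:
#' |LV80 - RV80| under LVP and RVP for the LVESVI fractional change, LV80
#' under BIVP for post-CRT log BNP, the RV80 fractional change under BIVP
#' for the change in peak VO2, and (cross-sectionally) the intrinsic RV80
#' for the pre-CRT RV ejection fraction.
#'
#' Defaults are scaled to clinically plausible magnitudes: e.g. a 40 ms
#' interventricular difference costs about 0.24 of LV remodelling response
#' at slope 0.006/ms, and log BNP rises ~0.018 per ms of LV80.
#'
#' @return named list; each element has `predictor`, `intercept`, `slope`
#'   and `noise_sd`.
#' @export
cohort_outcome_model <- function() {
  list(
    lvesvi_fc_lvp = list(predictor = "lvrvdiff_lvp",
                         intercept = -0.35, slope = 0.006, noise_sd = 0.10),
    lvesvi_fc_rvp = list(predictor = "lvrvdiff_rvp",
                         intercept = -0.30, slope = 0.006, noise_sd = 0.10),
    log_bnp_post = list(predictor = "lv80_bivp",
                        intercept = 3.2, slope = 0.018, noise_sd = 0.55),
    delta_peak_vo2 = list(predictor = "rv80_fc_bivp",
                          intercept = 0.8, slope = -2.5, noise_sd = 0.8),
    rvef = list(predictor = "rv80_intrinsic",
                intercept = 48, slope = -0.12, noise_sd = 5)
  )
}

# 80%-time from a pre-sorted scope: infimum of the cumulative-area step.
step_t80 <- function(ts, ca) {
  ts[which(ca / ca[length(ca)] >= 0.8 - 1e-12)[1L]]
}

# prep extension for fast repeated simulation + metric computation
cohort_prep <- function(mesh) {
  prep <- mesh_prep(mesh)
  prep$tri_is_lv <- mesh$labels == "LV"
  prep$tr <- mesh$triangles
  prep$e_lv <- which(prep$edges$class == "LV")
  prep$e_rv <- which(prep$edges$class == "RV")
  prep$e_seam <- which(prep$edges$class == "SEAM")
  pool <- unique(as.vector(mesh$triangles))
  lm <- prep$landmarks
  prep$cand <- list(
    lv_free_wall = nearest_vertices(mesh, lm$lv_free_wall, pool, 5L),
    rv_free_wall = nearest_vertices(mesh, lm$rv_free_wall, pool, 5L),
    rv_apex = nearest_vertices(mesh, lm$rv_apex, pool, 5L)
  )
  prep
}

# Lean jittered preset draw used by the cohort loop: same parameter
# distributions as preset_config(jitter = TRUE), no validation overhead.
fast_preset_draw <- function(prep, preset) {
  base <- 0.8 * stats::runif(1L, 0.85, 1.15)
  intrinsic <- preset %in% c("LBBB", "RBBB")
  seam <- if (intrinsic) stats::runif(1L, 0.18, 0.32)
          else stats::runif(1L, 0.5, 0.7)
  cs_lv <- stats::runif(1L, 0.9, 1.1)
  cs_rv <- stats::runif(1L, 0.9, 1.1)
  if (intrinsic) {
    if (preset == "LBBB") { cs_rv <- cs_rv * 1.5; cs_lv <- cs_lv * 0.8 }
    else { cs_lv <- cs_lv * 1.5; cs_rv <- cs_rv * 0.8 }
  } else {
    base <- base * 0.85
  }
  pick <- function(role) {
    cand <- prep$cand[[role]]
    cand[sample.int(length(cand), 1L)]
  }
  sites <- switch(preset,
    LBBB = pick("rv_free_wall"), RBBB = pick("lv_free_wall"),
    RVP = pick("rv_apex"), LVP = pick("lv_free_wall"),
    BIVP = c(pick("lv_free_wall"), pick("rv_apex")),
    BIVP_LV30 = c(pick("lv_free_wall"), pick("rv_apex")))
  delays <- switch(preset, BIVP = c(0, 0), BIVP_LV30 = c(0, 30), 0)
  vel <- numeric(length(prep$edges$length))
  vel[prep$e_lv] <- base * cs_lv
  vel[prep$e_rv] <- base * cs_rv
  vel[prep$e_seam] <- base * seam
  list(sites = sites, delays = delays, weights = prep$edges$length / vel)
}

fast_metrics <- function(prep, vtimes) {
  tr <- prep$tr
  tt <- (vtimes[tr[, 1L]] + vtimes[tr[, 2L]] + vtimes[tr[, 3L]]) / 3
  o <- order(tt)
  ts <- tt[o]
  as <- prep$areas[o]
  lv <- prep$tri_is_lv[o]
  c(lv80 = step_t80(ts[lv], cumsum(as[lv])),
    rv80 = step_t80(ts[!lv], cumsum(as[!lv])),
    biv80 = step_t80(ts, cumsum(as)),
    biv100 = ts[length(ts)])
}

#' Simulate a synthetic CRT cohort
#'
#' Generates `n_patients` patients: bundle-branch-block type drawn with
#' probability `prop_lbbb` of LBBB, activation maps for the intrinsic
#' rhythm (the patient's BBB preset) and the four paced settings with
#' jittered conduction velocities and breakthrough sites, electrical
#' metrics (LV80/RV80/BIV80 and the paced-completion QRS analogue per
#' setting, measured baseline QRS, Q-LV at the LV pacing site), and
#' outcomes drawn from the linear coupling model (see
#' [cohort_outcome_model()]).
#'
#' All randomness flows from the single integer `seed` through one RNG
#' stream, so a fixed seed reproduces the cohort bitwise.
#'
#' @param mesh a [tri_mesh]; defaults to `biv_shell_mesh(2)`.
#' @param n_patients number of patients (study-sized default 30).
#' @param prop_lbbb proportion with LBBB (default 2/3, as in a typical CRT
#'   referral population).
#' @param outcome_model outcome coupling list, see [cohort_outcome_model()].
#' @param noise_sd optional override of the residual scales: a single value
#'   or a named vector by outcome (0 gives exactly linear outcomes).
#' @param seed integer seed.
#' @return data frame of class `cohort_table`, one row per patient, with
#'   identifier, group and moderator columns, `lv80`/`rv80`/`biv80`/`qrsd`
#'   per setting, derived predictors (`lvrvdiff_lvp`, `lvrvdiff_rvp`,
#'   `rv80_fc_bivp`) and outcomes. The generating parameters are attached
#'   as attribute `"params"`.
#' @export
simulate_cohort <- function(mesh = NULL, n_patients = 30, prop_lbbb = 2 / 3,
                            outcome_model = cohort_outcome_model(),
                            noise_sd = NULL, seed = 1) {
  if (!is_count(n_patients) || n_patients < 1)
    crt_stop("n_patients must be a positive integer", "crt80_validation_error")
  if (prop_lbbb < 0 || prop_lbbb > 1)
    crt_stop("prop_lbbb must lie in [0, 1]", "crt80_validation_error")
  if (!is.null(noise_sd)) {
    if (any(noise_sd < 0))
      crt_stop("noise_sd must be >= 0", "crt80_validation_error")
    for (nm in names(outcome_model))
      outcome_model[[nm]]$noise_sd <-
        unname(if (length(noise_sd) == 1L) noise_sd
               else noise_sd[[nm]] %||% outcome_model[[nm]]$noise_sd)
  }
  mesh <- mesh %||% biv_shell_mesh(2L)
  prep <- cohort_prep(mesh)
  set.seed(as.integer(seed))
  bbb <- ifelse(stats::runif(n_patients) < prop_lbbb, "LBBB", "RBBB")
  settings <- c("INTRINSIC", "RVP", "LVP", "BIVP", "BIVP_LV30")
  met <- array(NA_real_, c(n_patients, length(settings), 4L),
               dimnames = list(NULL, settings,
                               c("lv80", "rv80", "biv80", "biv100")))
  qlv <- numeric(n_patients)
  for (i in seq_len(n_patients)) {
    for (s in settings) {
      preset <- if (s == "INTRINSIC") bbb[i] else s
      draw <- fast_preset_draw(prep, preset)
      t <- sim_raw_times(prep, draw$sites, draw$delays, draw$weights)
      t <- t - min(t)
      met[i, s, ] <- fast_metrics(prep, t)
      if (s == "INTRINSIC") qlv[i] <- t[prep$landmarks$lv_free_wall]
    }
  }
  out <- data.frame(id = sprintf("P%03d", seq_len(n_patients)), bbb = bbb)
  # measured baseline QRS: intrinsic biventricular completion plus a small
  # surface-ECG measurement discrepancy
  out$qrs_ms <- met[, "INTRINSIC", "biv100"] *
    stats::runif(n_patients, 0.98, 1.05)
  out$qlv_ms <- qlv
  out$lge_present <- stats::runif(n_patients) < 1 / 3
  out$ischemic <- stats::runif(n_patients) < 1 / 3
  out$lv_lead_position <- sample(c("lateral", "posterolateral", "anterior"),
                                 n_patients, replace = TRUE,
                                 prob = c(0.5, 0.3, 0.2))
  for (s in settings) {
    suf <- tolower(s)
    out[[paste0("lv80_", suf)]] <- met[, s, "lv80"]
    out[[paste0("rv80_", suf)]] <- met[, s, "rv80"]
    out[[paste0("biv80_", suf)]] <- met[, s, "biv80"]
    out[[paste0("qrsd_", suf)]] <- met[, s, "biv100"]
  }
  out$lvrvdiff_lvp <- abs(out$lv80_lvp - out$rv80_lvp)
  out$lvrvdiff_rvp <- abs(out$lv80_rvp - out$rv80_rvp)
  out$rv80_fc_bivp <- fractional_change(out$rv80_bivp, out$rv80_intrinsic)
  for (nm in names(outcome_model)) {
    m <- outcome_model[[nm]]
    out[[nm]] <- m$intercept + m$slope * out[[m$predictor]] +
      stats::rnorm(n_patients, 0, m$noise_sd)
  }
  attr(out, "params") <- list(n_patients = n_patients, prop_lbbb = prop_lbbb,
                              outcome_model = outcome_model, seed = seed)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as flat CSV
#'
#' @param cohort a cohort data frame.
#' @param path CSV path.
#' @return the path (write) or the data frame (read), invisibly/visibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    crt_stop(sprintf("cohort file not found: %s", path), "crt80_io_error")
  d <- utils::read.csv(path)
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Standard cohort analysis
#'
#' Runs the analysis battery over a cohort table: one-sample t-tests of the
#' intrinsic LV80/QRS, RV80/QRS and BIV80/QRS ratios against the
#' constant-rate reference 0.8 within each bundle-branch-block group,
#' per-group slopes of each metric on QRS duration with the group
#' interaction test, the robust response models, and the RV-function
#' correlations.
#'
#' @param cohort cohort data frame (see [simulate_cohort()] for the column
#'   dictionary).
#' @param method regression method for the response models.
#' @return list of class `cohort_analysis` with elements `ratio_tests`,
#'   `slopes`, `response_models`, `rv_function`.
#' @export
analyze_cohort <- function(cohort, method = c("huber", "ols")) {
  method <- match.arg(method)
  metrics <- c("LV80", "RV80", "BIV80")
  rt <- do.call(rbind, lapply(metrics, function(m) {
    col <- metric_column(cohort, m, "INTRINSIC")
    do.call(rbind, lapply(c("LBBB", "RBBB"), function(g) {
      v <- cohort[[col]][cohort$bbb == g] / cohort$qrs_ms[cohort$bbb == g]
      if (length(v) < 2L)
        return(data.frame(metric = m, group = g, mean_ratio = NA, t = NA,
                          df = NA, p = NA))
      tt <- one_sample_t_vs(v, 0.8)
      data.frame(metric = m, group = g, mean_ratio = mean(v),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }))
  sl <- do.call(rbind, lapply(metrics, function(m) {
    s <- slope_by_group(cohort, m, "INTRINSIC")
    data.frame(metric = m, slope_lbbb = unname(s$slopes["LBBB"]),
               slope_rbbb = unname(s$slopes["RBBB"]),
               interaction_p = s$interaction_p)
  }))
  models <- list(
    lvesvi_fc_lvp = robust_regress(cohort, "lvesvi_fc_lvp", "lvrvdiff_lvp", method),
    lvesvi_fc_rvp = robust_regress(cohort, "lvesvi_fc_rvp", "lvrvdiff_rvp", method),
    log_bnp_post = robust_regress(cohort, "log_bnp_post", "lv80_bivp", method),
    delta_peak_vo2 = robust_regress(cohort, "delta_peak_vo2", "rv80_fc_bivp", method)
  )
  rvf <- if ("rvef" %in% names(cohort)) list(
    rv80 = pearson_corr(cohort$rv80_intrinsic, cohort$rvef),
    rv80_qrs = pearson_corr(cohort$rv80_intrinsic / cohort$qrs_ms, cohort$rvef)
  ) else NULL
  structure(list(ratio_tests = rt, slopes = sl, response_models = models,
                 rv_function = rvf),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("== Intrinsic ratios vs constant-rate reference 0.8 ==\n")
  print(x$ratio_tests, row.names = FALSE, digits = 3)
  cat("\n== Per-group slopes of activation time on QRS duration ==\n")
  print(x$slopes, row.names = FALSE, digits = 3)
  cat("\n== Response models (", x$response_models[[1]]$method, ") ==\n", sep = "")
  for (nm in names(x$response_models)) {
    m <- x$response_models[[nm]]
    cat(sprintf("%s: R^2 = %.3f (model p = %.3g), n = %d\n",
                nm, m$r_squared, m$model_p, m$n_used))
  }
  if (!is.null(x$rv_function))
    cat(sprintf("\nRV function: r(RV80, RVEF) = %.2f (p = %.3g); r(RV80/QRS, RVEF) = %.2f (p = %.3g)\n",
                x$rv_function$rv80$r, x$rv_function$rv80$p,
                x$rv_function$rv80_qrs$r, x$rv_function$rv80_qrs$p))
  invisible(x)
}
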