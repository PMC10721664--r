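#' Chamber activation metrics: the LVx/RVx/BIVx family
#'
#' Computes, for each chamber scope (LV, RV, BIV) and each fraction `f`, the
#' time at which `f` of the scope's epicardial surface is activated, plus
#' the ratios of those times to the QRS duration and the interventricular
#' synchrony score |LV80 - RV80|. Fractions default to 0.7, 0.8, 0.9 and
#' 1.0; the 0.8 column gives LV80, RV80 and BIV80.
#'
#' The QRS duration used for the ratios is either derived from the map
#' (biventricular completion time, `qrs_source = "map_derived"`) or supplied
#' from a 12-lead measurement (`qrs_source = "supplied"`, which may differ
#' from the map's completion time).
#'
#' @param map an [activation_map].
#' @param fractions activation fractions to evaluate; must include 0.8 for
#'   the synchrony score.
#' @param qrs_source `"map_derived"` or `"supplied"`.
#' @param qrs_ms QRS duration in ms, required when `qrs_source = "supplied"`.
#' @param weighting passed to [activation_curve()].
#' @return object of class `chamber_metrics`: a list with `times` (scope x
#'   fraction matrix, ms), `ratios` (times / QRS), `qrs_ms`, `lvrv_diff_ms`
#'   (per fraction), and the pacing `setting`.
#' @export
chamber_metrics <- function(map, fractions = c(0.7, 0.8, 0.9, 1.0),
                            qrs_source = c("map_derived", "supplied"),
                            qrs_ms = NULL, weighting = c("area", "count")) {
  qrs_source <- match.arg(qrs_source)
  weighting <- match.arg(weighting)
  if (any(fractions <= 0 | fractions > 1))
    crt_stop("fractions must lie in (0, 1]", "crt80_domain_error")
  fractions <- sort(unique(fractions))
  curves <- lapply(c(LV = "LV", RV = "RV", BIV = "BIV"), function(sc)
    activation_curve(map, sc, weighting))
  times <- vapply(fractions, function(f)
    vapply(curves, time_to_fraction, numeric(1L), f = f), numeric(3L))
  dimnames(times) <- list(c("LV", "RV", "BIV"),
                          vapply(fractions, format, ""))
  if (qrs_source == "supplied") {
    if (is.null(qrs_ms))
      crt_stop("qrs_source = 'supplied' requires qrs_ms", "crt80_config_error")
    if (qrs_ms <= 0)
      crt_stop("qrs_ms must be > 0", "crt80_validation_error")
    qrs <- qrs_ms
  } else {
    qrs <- time_to_fraction(curves$BIV, 1)  # biventricular completion time
  }
  lvrv <- abs(times["LV", ] - times["RV", ])
  structure(list(times = times, ratios = times / qrs, qrs_ms = qrs,
                 qrs_source = qrs_source, lvrv_diff_ms = lvrv,
                 fractions = fractions, setting = map$setting,
                 weighting = weighting),
            class = "chamber_metrics")
}

#' Interventricular synchrony score |LVx - RVx|
#'
#' Absolute difference of the LV and RV time-to-fraction statistics; at the
#' default `f = 0.8` this is |LV80 - RV80|, the electrical interventricular
#' synchrony measure used to compare pacing settings and predict LV
#' remodelling response.
#'
#' @param metrics a [chamber_metrics] object.
#' @param f fraction at which to take the difference (must be among the
#'   metrics' fractions).
#' @return absolute difference in ms (symmetric in the two chambers).
#' @export
lvrv_diff <- function(metrics, f = 0.8) {
  stopifnot(inherits(metrics, "chamber_metrics"))
  col <- match(format(f), colnames(metrics$times))
  if (is.na(col))
    crt_stop(sprintf("fraction %s not present in metrics", format(f)),
             "crt80_domain_error")
  unname(abs(metrics$times["LV", col] - metrics$times["RV", col]))
}

#' Fractional change (post - pre) / pre
#'
#' The relative-change statistic used for both the LV remodelling response
#' (LVESVI fractional change; negative = improvement) and the RV80
#' fractional change under biventricular pacing.
#'
#' @param post,pre numeric values (vectorised); `pre` must be non-zero.
#' @return `(post - pre) / pre`, dimensionless.
#' @export
fractional_change <- function(post, pre) {
  if (any(pre == 0))
    crt_stop("fractional change undefined for pre = 0", "crt80_domain_error")
  (post - pre) / pre
}

#' @export
print.chamber_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("<chamber_metrics> setting %s, QRS %.1f ms (%s)\n",
              x$setting, x$qrs_ms, x$qrs_source))
  cat("times (ms):\n"); print(round(x$times, 1))
  cat("ratios to QRS:\n"); print(round(x$ratios, digits))
  cat(sprintf("|LV80 - RV80| = %.1f ms\n",
              x$lvrv_diff_ms[match("0.8", colnames(x$times))]))
  invisible(x)
}

#' @export
as.data.frame.chamber_metrics <- function(x, ...) {
  fr <- colnames(x$times)
  tag <- as.character(round(as.numeric(fr) * 100))  # "0.8" -> "80"
  out <- list(setting = x$setting, qrs_ms = x$qrs_ms)
  for (k in seq_along(fr)) {
    for (sc in c("LV", "RV", "BIV"))
      out[[paste0(tolower(sc), tag[k])]] <- x$times[sc, k]
    out[[paste0("lvrvdiff", tag[k])]] <- unname(x$lvrv_diff_ms[k])
  }
  for (k in seq_along(fr))
    for (sc in c("LV", "RV", "BIV"))
      out[[paste0(tolower(sc), tag[k], "_qrs")]] <- x$ratios[sc, k]
  as.data.frame(out)
}
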