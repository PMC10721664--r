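# Per-patient comparison of electrical synchrony across pacing settings:
# the data behind "pacing configuration plots", setting recommendation,
# and response classification.

#' Per-patient pacing session
#'
#' Collects one patient's chamber metrics across the available pacing
#' settings. The intrinsic rhythm must be present (it is the reference every
#' paced setting is compared against) and no setting may appear twice.
#'
#' @param id patient identifier.
#' @param metrics either a named list of [chamber_metrics] objects (names =
#'   setting tags) or a data frame with columns `setting`, `lv80`, `rv80`,
#'   `biv80` (ms).
#' @return object of class `pacing_session` holding a per-setting table
#'   with `lv80`, `rv80`, `biv80` and `lvrvdiff` columns.
#' @export
pacing_session <- function(id, metrics) {
  if (is.data.frame(metrics)) {
    need <- c("setting", "lv80", "rv80", "biv80")
    if (!all(need %in% names(metrics)))
      crt_stop("session data frame needs columns setting, lv80, rv80, biv80",
               "crt80_validation_error")
    tab <- metrics[, need]
  } else {
    stopifnot(all(vapply(metrics, inherits, TRUE, "chamber_metrics")))
    tab <- data.frame(
      setting = names(metrics),
      lv80 = vapply(metrics, function(m) m$times["LV", "0.8"], 0),
      rv80 = vapply(metrics, function(m) m$times["RV", "0.8"], 0),
      biv80 = vapply(metrics, function(m) m$times["BIV", "0.8"], 0)
    )
  }
  if (!all(tab$setting %in% PACING_SETTINGS))
    crt_stop(sprintf("unknown setting(s): %s",
                     paste(setdiff(tab$setting, PACING_SETTINGS), collapse = ", ")),
             "crt80_validation_error")
  if (anyDuplicated(tab$setting))
    crt_stop("duplicate pacing settings in session", "crt80_validation_error")
  if (!"INTRINSIC" %in% tab$setting)
    crt_stop("session must include the INTRINSIC reference setting",
             "crt80_session_error")
  tab$lvrvdiff <- abs(tab$lv80 - tab$rv80)
  rownames(tab) <- NULL
  structure(list(id = id, table = tab), class = "pacing_session")
}

#' Pacing configuration table
#'
#' One row per available setting with LV80, RV80, BIV80, |LVRVDIFF| and the
#' deltas of each metric relative to the intrinsic rhythm — how much each
#' pacing mode shortens or lengthens chamber activation. This is the data
#' product behind the pacing configuration plot.
#'
#' @param session a [pacing_session].
#' @return data frame with columns `setting`, `lv80`, `rv80`, `biv80`,
#'   `lvrvdiff` and `d_lv80`, `d_rv80`, `d_biv80`, `d_lvrvdiff` (setting
#'   minus intrinsic).
#' @export
config_table <- function(session) {
  stopifnot(inherits(session, "pacing_session"))
  tab <- session$table
  ref <- tab[tab$setting == "INTRINSIC", ]
  for (col in c("lv80", "rv80", "biv80", "lvrvdiff"))
    tab[[paste0("d_", col)]] <- tab[[col]] - ref[[col]]
  tab
}

#' Recommend the pacing setting with best interventricular synchrony
#'
#' Among the paced settings, picks the one minimizing |LV80 - RV80| (the
#' interventricular electrical synchrony score, the quantity most strongly
#' tied to LV functional response). Exact ties are broken by the smaller
#' BIV80, then by the fixed preference order BIVP, BIVP_LV30, LVP, RVP.
#'
#' @param session a [pacing_session] with at least two paced settings.
#' @return list of class `pacing_recommendation` with `setting`, the
#'   `rationale` table of candidates (sorted best first) and the criteria
#'   used.
#' @export
recommend_setting <- function(session) {
  stopifnot(inherits(session, "pacing_session"))
  tab <- session$table
  paced <- tab[tab$setting != "INTRINSIC", ]
  if (nrow(paced) == 0L)
    crt_stop("session contains only the intrinsic rhythm: nothing to recommend",
             "crt80_insufficient_settings_error")
  if (nrow(paced) < 2L)
    crt_stop("need at least two paced settings to compare",
             "crt80_insufficient_settings_error")
  pref <- c(BIVP = 1L, BIVP_LV30 = 2L, LVP = 3L, RVP = 4L)
  ord <- order(paced$lvrvdiff, paced$biv80, pref[paced$setting])
  paced <- paced[ord, ]
  rownames(paced) <- NULL
  structure(list(
    setting = paced$setting[1L],
    rationale = paced,
    criteria = c("minimal |LV80 - RV80|", "tie: minimal BIV80",
                 "tie: order BIVP, BIVP_LV30, LVP, RVP"),
    id = session$id
  ), class = "pacing_recommendation")
}

#' @export
print.pacing_recommendation <- function(x, ...) {
  cat(sprintf("<pacing_recommendation> patient %s: %s\n", x$id, x$setting))
  print(x$rationale, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classify CRT response from outcome values
#'
#' Responder thresholds ("at least" read inclusively): LV remodelling
#' response is a >= 5% LVESV reduction, i.e. fractional change <= -0.05;
#' functional response is a peak VO2 improvement >= 1 mL/kg/min. Flags are
#' `NA` (absent, not `FALSE`) when the underlying outcome is missing.
#'
#' @param lvesvi_fc LVESVI fractional change (dimensionless), or `NULL`/`NA`.
#' @param delta_peak_vo2 change in peak VO2 (mL/kg/min), or `NULL`/`NA`.
#' @return list with logical flags `lvesv_responder` and `vo2_responder`.
#' @export
classify_response <- function(lvesvi_fc = NULL, delta_peak_vo2 = NULL) {
  flag <- function(x, test) {
    if (is.null(x) || length(x) == 0L || is.na(x)) NA else test(x)
  }
  list(
    lvesv_responder = flag(lvesvi_fc, function(x) x <= -0.05),
    vo2_responder = flag(delta_peak_vo2, function(x) x >= 1)
  )
}

#' @describeIn pacing_session pacing configuration plot: LV80 and RV80 per
#'   setting, connected to show how each mode redistributes chamber
#'   activation.
#' @param x a `pacing_session`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pacing_session <- function(x, ...) {
  tab <- x$table
  ordidx <- order(match(tab$setting, PACING_SETTINGS))
  tab <- tab[ordidx, ]
  graphics::matplot(seq_len(nrow(tab)), cbind(tab$lv80, tab$rv80, tab$biv80),
                    type = "b", pch = c(19, 17, 1), lty = c(1, 1, 2),
                    col = c("firebrick", "navy", "grey40"),
                    xaxt = "n", xlab = "pacing setting",
                    ylab = "time to 80% activation (ms)",
                    main = sprintf("Pacing configuration plot - patient %s", x$id),
                    ...)
  graphics::axis(1, at = seq_len(nrow(tab)), labels = tab$setting, las = 2)
  graphics::legend("topright", c("LV80", "RV80", "BIV80"),
                   pch = c(19, 17, 1), lty = c(1, 1, 2),
                   col = c("firebrick", "navy", "grey40"), bty = "n")
  invisible(x)
}

#' @export
print.pacing_session <- function(x, ...) {
  cat(sprintf("<pacing_session> patient %s, settings: %s\n",
              x$id, paste(x$table$setting, collapse = ", ")))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
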