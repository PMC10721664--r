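#' Pacing settings
#'
#' The five pacing configurations compared by the analysis: intrinsic rhythm,
#' RV-only pacing, synchronized LV-only pacing, simultaneous biventricular
#' pacing, and biventricular pacing with the LV stimulated 30 ms first.
#'
#' @format character vector of setting tags.
#' @export
PACING_SETTINGS <- c("INTRINSIC", "RVP", "LVP", "BIVP", "BIVP_LV30")

#' LV-first offset of a pacing setting
#'
#' @param setting one of [PACING_SETTINGS].
#' @return offset in ms by which the LV site is stimulated before the RV
#'   site: 30 for `BIVP_LV30`, 0 otherwise.
#' @export
lv_offset_ms <- function(setting) {
  setting <- match.arg(setting, PACING_SETTINGS)
  if (setting == "BIVP_LV30") 30 else 0
}

#' Per-vertex activation-time map
#'
#' Holds one activation map: the time (ms from QRS onset) at which each mesh
#' vertex was electrically activated, under one pacing setting. Times are
#' referenced to the earliest ventricular activation, so the minimum vertex
#' time is 0. A triangle's activation time is the arithmetic mean of its
#' three vertex times; this is the element time used by the area-weighted
#' activation curves.
#'
#' By default a map whose minimum time is positive is re-referenced to 0
#' (with a message reporting the shift); `strict = TRUE` turns this into an
#' error instead.
#'
#' @param mesh the [tri_mesh] the times live on.
#' @param times numeric vector of activation times (ms), one per vertex;
#'   finite and non-negative.
#' @param setting pacing setting tag, one of [PACING_SETTINGS].
#' @param strict error (rather than shift) when the minimum time is not 0.
#' @return object of class `activation_map`.
#' @export
activation_map <- function(mesh, times, setting = "INTRINSIC", strict = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  setting <- match.arg(setting, PACING_SETTINGS)
  times <- as.numeric(times)
  if (length(times) != nrow(mesh$vertices))
    crt_stop(sprintf("expected %d vertex times, got %d",
                     nrow(mesh$vertices), length(times)),
             "crt80_shape_error")
  if (anyNA(times) || any(!is.finite(times)))
    crt_stop("activation times must all be finite", "crt80_validation_error")
  if (any(times < 0))
    crt_stop("negative activation time", "crt80_validation_error")
  m <- min(times)
  if (m > 0) {
    if (strict)
      crt_stop(sprintf("minimum activation time is %g ms, not 0 (strict mode)", m),
               "crt80_validation_error")
    message(sprintf("re-referencing activation map: shifting all times by -%g ms", m))
    times <- times - m
  }
  structure(list(mesh = mesh, times = times, setting = setting),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> setting %s, %d vertices, range 0 - %.1f ms\n",
              x$setting, length(x$times), max(x$times)))
  invisible(x)
}

# Mean of the three vertex times, per triangle: the element activation time.
triangle_times <- function(map, mesh = map$mesh) {
  tr <- mesh$triangles
  (map$times[tr[, 1L]] + map$times[tr[, 2L]] + map$times[tr[, 3L]]) / 3
}
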