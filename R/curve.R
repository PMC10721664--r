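#' Activation-fraction curve for a chamber scope
#'
#' The chamber's activation-versus-time function: the cumulative fraction of
#' the scope's epicardial surface activated by each time point. Triangles
#' (element time = mean of the three vertex times) are sorted by activation
#' time; coincident times are merged into single events, so the curve is a
#' right-continuous non-decreasing step function ending at 1.
#'
#' With `weighting = "area"` (default) each triangle contributes its area;
#' `weighting = "count"` weights every surface element equally (the two
#' agree exactly on uniform-area meshes).
#'
#' @param map an [activation_map].
#' @param scope `"LV"`, `"RV"` or `"BIV"` (both chambers; equal to the
#'   area-weighted mixture of the LV and RV curves).
#' @param weighting `"area"` or `"count"`.
#' @return object of class `activation_curve` with `event_times` (ms,
#'   strictly increasing) and `cum_fraction`.
#' @export
activation_curve <- function(map, scope = c("BIV", "LV", "RV"),
                             weighting = c("area", "count")) {
  stopifnot(inherits(map, "activation_map"))
  scope <- match.arg(scope)
  weighting <- match.arg(weighting)
  mesh <- map$mesh
  keep <- if (scope == "BIV") rep(TRUE, length(mesh$labels)) else mesh$labels == scope
  if (!any(keep))
    crt_stop(sprintf("scope %s is empty on this mesh", scope),
             "crt80_validation_error")
  tt <- triangle_times(map)[keep]
  w <- if (weighting == "area") triangle_areas(mesh, check = FALSE)[keep]
       else rep(1, sum(keep))
  ord <- order(tt)
  tt <- tt[ord]; w <- w[ord]
  # merge exactly tied element times into single events
  grp <- cumsum(!duplicated(tt))
  et <- tt[!duplicated(tt)]
  cw <- as.vector(cumsum(rowsum(w, grp)[, 1L]) / sum(w))
  structure(list(scope = scope, weighting = weighting,
                 event_times = et, cum_fraction = cw,
                 total_weight = sum(w)),
            class = "activation_curve")
}

#' Time to a given activation fraction
#'
#' The smallest event time at which the cumulative activation fraction
#' reaches `f` (step-function infimum; no interpolation between surface
#' elements).
#'
#' @param curve an [activation_curve].
#' @param f target fraction in (0, 1]; `f = 0.8` gives the LV80/RV80/BIV80
#'   family, `f = 1` the scope completion time.
#' @return time in ms.
#' @export
time_to_fraction <- function(curve, f) {
  stopifnot(inherits(curve, "activation_curve"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    crt_stop("fraction must lie in (0, 1]", "crt80_domain_error")
  idx <- which(curve$cum_fraction >= f - 1e-12)[1L]
  curve$event_times[idx]
}

#' @export
print.activation_curve <- function(x, ...) {
  cat(sprintf("<activation_curve> scope %s (%s-weighted), %d events, 0 - %.1f ms\n",
              x$scope, x$weighting, length(x$event_times), max(x$event_times)))
  invisible(x)
}

#' @describeIn activation_curve step plot of the cumulative activation
#'   fraction versus time.
#' @param x an `activation_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.activation_curve <- function(x, ...) {
  graphics::plot(c(0, x$event_times), c(0, x$cum_fraction), type = "s",
                 xlab = "time from QRS onset (ms)",
                 ylab = "cumulative activation fraction",
                 main = sprintf("%s activation", x$scope), ylim = c(0, 1), ...)
  graphics::abline(h = 0.8, lty = 3)
  invisible(x)
}
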