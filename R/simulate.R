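#' Wavefront simulation configuration
#'
#' Describes one synthetic activation sequence: breakthrough (earliest
#' activation) sites with onset delays, a base conduction velocity, per
#' chamber velocity multipliers, a multiplier for edges straddling the
#' LV/RV seam, and optional slow-conducting scar patches.
#'
#' @param breakthrough data frame (or 2-column matrix) with columns
#'   `vertex` (1-based vertex index) and `delay_ms` (onset delay, >= 0).
#' @param base_velocity conduction speed in mm/ms (epicardial muscle is
#'   roughly 0.3-1 mm/ms).
#' @param chamber_scale named multipliers `c(LV = , RV = )` applied to edges
#'   lying entirely within one chamber.
#' @param seam_scale multiplier (> 0) for edges bordering both chambers;
#'   values well below 1 emulate slow trans-septal conduction.
#' @param scar_patches list of `list(vertex =, radius_mm =, scale =)`;
#'   edges whose midpoint lies within `radius_mm` (Euclidean) of the patch
#'   seed vertex have their velocity multiplied by `scale` (< 1).
#' @param seed optional integer recorded with the configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(breakthrough, base_velocity = 0.8,
                       chamber_scale = c(LV = 1, RV = 1), seam_scale = 1,
                       scar_patches = list(), seed = NULL) {
  breakthrough <- as.data.frame(breakthrough)
  if (ncol(breakthrough) == 2L && !all(c("vertex", "delay_ms") %in% names(breakthrough)))
    names(breakthrough) <- c("vertex", "delay_ms")
  if (nrow(breakthrough) < 1L)
    crt_stop("at least one breakthrough site is required", "crt80_validation_error")
  if (any(breakthrough$delay_ms < 0))
    crt_stop("breakthrough onset delays must be >= 0", "crt80_validation_error")
  if (!is.numeric(base_velocity) || base_velocity <= 0)
    crt_stop("base_velocity must be > 0", "crt80_validation_error")
  if (!all(c("LV", "RV") %in% names(chamber_scale)) || any(chamber_scale <= 0))
    crt_stop("chamber_scale must be positive and named c(LV=, RV=)",
             "crt80_validation_error")
  if (seam_scale <= 0)
    crt_stop("seam_scale must be > 0", "crt80_validation_error")
  for (p in scar_patches)
    if (is.null(p$vertex) || is.null(p$radius_mm) || is.null(p$scale) ||
        p$scale <= 0)
      crt_stop("each scar patch needs vertex, radius_mm and a positive scale",
               "crt80_validation_error")
  structure(list(breakthrough = breakthrough, base_velocity = base_velocity,
                 chamber_scale = chamber_scale, seam_scale = seam_scale,
                 scar_patches = scar_patches, seed = seed),
            class = "sim_config")
}

# Edge traversal times for a configuration: length / local velocity.
edge_weights <- function(prep, config) {
  e <- prep$edges
  scale <- ifelse(e$class == "SEAM", config$seam_scale,
                  unname(config$chamber_scale[e$class]))
  vel <- config$base_velocity * scale
  for (p in config$scar_patches) {
    seedxyz <- prep$mesh$vertices[p$vertex, ]
    d2 <- (e$midpoint[, 1L] - seedxyz[1L])^2 +
      (e$midpoint[, 2L] - seedxyz[2L])^2 +
      (e$midpoint[, 3L] - seedxyz[3L])^2
    hit <- d2 <= p$radius_mm^2
    vel[hit] <- vel[hit] * p$scale
  }
  e$length / vel
}

# Single-source Dijkstra on the precomputed adjacency lists (dense scan;
# meshes here are small, so O(V^2) with vectorised relaxation is fast).
dijkstra_times <- function(prep, source, weights) {
  n <- length(prep$adj_nbr)
  d <- rep(Inf, n)
  d[source] <- 0
  active <- d
  for (iter in seq_len(n)) {
    u <- which.min(active)
    du <- active[u]
    if (!is.finite(du)) break
    active[u] <- Inf
    nb <- prep$adj_nbr[[u]]
    nd <- du + weights[prep$adj_eidx[[u]]]
    upd <- nd < d[nb]
    if (any(upd)) {
      vv <- nb[upd]
      d[vv] <- nd[upd]
      active[vv] <- nd[upd]
    }
  }
  d
}

# Arrival times from the breakthrough sites; not re-referenced.
sim_raw_times <- function(prep, sites, delays, weights) {
  t <- dijkstra_times(prep, sites[1L], weights) + delays[1L]
  if (length(sites) > 1L)
    for (k in seq.int(2L, length(sites)))
      t <- pmin(t, dijkstra_times(prep, sites[k], weights) + delays[k])
  t
}

#' Simulate an activation map by wavefront propagation
#'
#' Propagates activation from the breakthrough sites over the mesh edge
#' graph: the activation time of a vertex is the minimum over sites of
#' (onset delay + shortest-path travel time), with edge traversal time
#' `edge length / local velocity`. The local velocity is the base velocity
#' scaled per chamber, reduced on seam-straddling edges, and reduced again
#' inside scar patches. The resulting map is re-referenced so the earliest
#' vertex activates at 0 ms.
#'
#' This shortest-path propagation is exactly reproducible by an independent
#' Dijkstra implementation, which makes the simulator testable to machine
#' precision.
#'
#' @param mesh a [tri_mesh].
#' @param config a [sim_config].
#' @param setting pacing setting tag for the resulting map.
#' @param prep optional precomputed `mesh_prep()` (internal reuse).
#' @return an [activation_map].
#' @export
simulate_activation <- function(mesh, config, setting = "INTRINSIC",
                                prep = NULL) {
  stopifnot(inherits(config, "sim_config"))
  prep <- prep %||% mesh_prep(mesh)
  sites <- config$breakthrough$vertex
  if (any(sites < 1L | sites > nrow(prep$mesh$vertices)))
    crt_stop("breakthrough vertex outside mesh", "crt80_validation_error")
  t <- sim_raw_times(prep, sites, config$breakthrough$delay_ms,
                     edge_weights(prep, config))
  if (any(!is.finite(t)))
    crt_stop("unreachable vertex: mesh edge graph is disconnected",
             "crt80_simulation_error")
  m <- activation_map(prep$mesh, t - min(t), setting = setting)
  attr(m, "config") <- config
  m
}

#' Synthetic biventricular shell mesh
#'
#' Builds a closed surface from two ellipsoidal half-shells sharing the
#' semi-axes of the short (`y`) and long (`z`) axes and joined along the
#' `x = 0` seam: the `x < 0` half (semi-axis `lv_axis`) is labelled LV, the
#' `x > 0` half (`rv_axis`) RV. The surface is an octahedron subdivided
#' `n_subdiv` times with vertices projected onto the composite ellipsoid,
#' so the triangle count is `8 * 4^n_subdiv`.
#'
#' Default dimensions approximate a dilated adult heart: LV half-width
#' 45 mm, RV half-width 30 mm, short axis 35 mm, apex-base half-length
#' 60 mm (apex at negative `z`).
#'
#' @param n_subdiv subdivision level (>= 0).
#' @param lv_axis,rv_axis,short_axis,long_axis ellipsoid semi-axes in mm.
#' @return a [tri_mesh].
#' @export
biv_shell_mesh <- function(n_subdiv = 2L, lv_axis = 45, rv_axis = 30,
                           short_axis = 35, long_axis = 60) {
  if (!is_count(n_subdiv))
    crt_stop("n_subdiv must be a non-negative integer", "crt80_validation_error")
  if (any(c(lv_axis, rv_axis, short_axis, long_axis) <= 0))
    crt_stop("ellipsoid semi-axes must be positive (degenerate geometry)",
             "crt80_validation_error")
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (lev in seq_len(n_subdiv)) {
    midcache <- new.env(parent = emptyenv())
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midcache[[key]]
      if (is.null(idx)) {
        p <- (v[i, ] + v[j, ]) / 2
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        idx <- nrow(v)
        midcache[[key]] <- idx
      }
      idx
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c_ <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4L * k - 3L, ] <- c(a, ab, ca)
      nf[4L * k - 2L, ] <- c(ab, b, bc)
      nf[4L * k - 1L, ] <- c(bc, c_, ca)
      nf[4L * k, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2))
  cx <- (v[f[, 1L], 1L] + v[f[, 2L], 1L] + v[f[, 3L], 1L]) / 3
  labels <- ifelse(cx < 0, "LV", "RV")
  xs <- ifelse(v[, 1L] < 0, lv_axis, rv_axis)
  vertices <- cbind(x = v[, 1L] * xs, y = v[, 2L] * short_axis,
                    z = v[, 3L] * long_axis)
  tri_mesh(vertices, f, labels)
}

# ---- bundle-branch-block / pacing presets ----------------------------------

PRESETS <- c("LBBB", "RBBB", "RVP", "LVP", "BIVP", "BIVP_LV30")

# Draw a preset configuration. Uses the current RNG stream when jitter=TRUE.
# Nominal physiology: base conduction 0.8 mm/ms; intrinsic bundle-branch
# block = single contralateral free-wall breakthrough, Purkinje-backed
# chamber conducting faster, strongly slowed trans-seam conduction; paced
# rhythms = point stimulation without Purkinje support (slightly slower
# tissue, milder seam slowing).
preset_config <- function(prep, preset, jitter = FALSE) {
  lm <- prep$landmarks
  jit <- function(lo, hi, nominal) if (jitter) stats::runif(1L, lo, hi) else nominal
  pick_site <- function(vertex) {
    if (!jitter) return(vertex)
    pool <- unique(as.vector(prep$mesh$triangles))
    cand <- nearest_vertices(prep$mesh, vertex, pool, k = 5L)
    cand[sample.int(length(cand), 1L)]
  }
  base <- 0.8 * jit(0.85, 1.15, 1)
  intrinsic <- preset %in% c("LBBB", "RBBB")
  seam <- if (intrinsic) jit(0.18, 0.32, 0.25) else jit(0.5, 0.7, 0.6)
  cs <- c(LV = jit(0.9, 1.1, 1), RV = jit(0.9, 1.1, 1))
  sites <- switch(
    preset,
    LBBB = data.frame(vertex = pick_site(lm$rv_free_wall), delay_ms = 0),
    RBBB = data.frame(vertex = pick_site(lm$lv_free_wall), delay_ms = 0),
    RVP = data.frame(vertex = pick_site(lm$rv_apex), delay_ms = 0),
    LVP = data.frame(vertex = pick_site(lm$lv_free_wall), delay_ms = 0),
    BIVP = data.frame(vertex = c(pick_site(lm$lv_free_wall),
                                 pick_site(lm$rv_apex)),
                      delay_ms = c(0, 0)),
    BIVP_LV30 = data.frame(vertex = c(pick_site(lm$lv_free_wall),
                                      pick_site(lm$rv_apex)),
                           delay_ms = c(0, 30)),
    crt_stop(sprintf("unknown preset '%s'", preset), "crt80_config_error")
  )
  if (intrinsic) {
    fast <- if (preset == "LBBB") "RV" else "LV"
    slow <- setdiff(c("LV", "RV"), fast)
    cs[fast] <- cs[fast] * 1.5
    cs[slow] <- cs[slow] * 0.8
  } else {
    base <- base * 0.85  # no His-Purkinje capture under point pacing
  }
  sim_config(sites, base_velocity = base, chamber_scale = cs,
             seam_scale = seam)
}

#' Preset activation maps: bundle branch block and pacing configurations
#'
#' Generates an activation map with the qualitative structure of a left or
#' right bundle branch block (`"LBBB"`, `"RBBB"`) or of one of the paced
#' settings (`"RVP"`, `"LVP"`, `"BIVP"`, `"BIVP_LV30"`). LBBB places the
#' breakthrough on the RV free wall with slowed trans-seam conduction, so
#' the LV is reached late and LV80 > RV80 with a long LV tail; RBBB is the
#' mirror image. Paced presets stimulate the designated RV-apex / LV
#' free-wall sites, with the RV site delayed 30 ms under `"BIVP_LV30"`
#' (LV-first offset).
#'
#' With a `seed`, velocities and site placement are jittered to produce
#' patient-to-patient variability; the bundle-branch ordering guarantees
#' (LBBB: LV80 > RV80; RBBB: RV80 > LV80) hold for every seed.
#'
#' @param mesh a [tri_mesh].
#' @param preset one of `"LBBB"`, `"RBBB"`, `"RVP"`, `"LVP"`, `"BIVP"`,
#'   `"BIVP_LV30"`.
#' @param seed optional integer; when given, parameters are jittered
#'   reproducibly.
#' @param prep optional precomputed mesh preparation (internal reuse).
#' @return an [activation_map]; the generating [sim_config] is attached as
#'   attribute `"config"`. Bundle-branch presets are tagged as setting
#'   `"INTRINSIC"`, paced presets by their own tag.
#' @export
preset_activation_map <- function(mesh, preset, seed = NULL, prep = NULL) {
  if (!preset %in% PRESETS)
    crt_stop(sprintf("unknown preset '%s' (expected one of %s)",
                     preset, paste(PRESETS, collapse = ", ")),
             "crt80_config_error")
  prep <- prep %||% mesh_prep(mesh)
  jitter <- !is.null(seed)
  if (jitter) set.seed(as.integer(seed))
  config <- preset_config(prep, preset, jitter = jitter)
  setting <- if (preset %in% c("LBBB", "RBBB")) "INTRINSIC" else preset
  simulate_activation(mesh, config, setting = setting, prep = prep)
}

# ---- linear (constant-rate) activation maps --------------------------------

#' Activation map with a linear activation-versus-time function
#'
#' Assigns vertex times such that the cumulative area fraction of each
#' chamber in `scope` increases linearly from 0 to `duration` ms, up to the
#' granularity of a single triangle. In this constant-rate limit the time to
#' 80% activation divided by the completion time equals 0.8 for every scope
#' - the reference value against which observed LV80/QRS, RV80/QRS and
#' BIV80/QRS ratios are tested.
#'
#' Each in-scope triangle is given a target time at its area-cumulative
#' position along an apex-to-base sweep (increasing centroid `z`; both
#' chambers swept in the same direction so their targets agree near the
#' seam): the k-th triangle of a chamber, in sweep order, targets
#' `duration * (A_1 + ... + A_{k-1} + A_k/2) / A_chamber`. Because a
#' triangle's activation time is the mean of its three vertex times, the
#' vertex times are then solved in least squares to reproduce the
#' per-triangle targets, and the map is shifted so the earliest vertex
#' activates at 0.
#'
#' @param mesh a [tri_mesh].
#' @param scope `"BIV"` (both chambers linear, the default), `"LV"` or `"RV"`.
#' @param duration total activation duration in ms (> 0).
#' @return an [activation_map] (setting `"INTRINSIC"`).
#' @export
linear_activation_map <- function(mesh, scope = c("BIV", "LV", "RV"),
                                  duration = 150) {
  scope <- match.arg(scope)
  if (!is.numeric(duration) || duration <= 0)
    crt_stop("duration must be > 0", "crt80_validation_error")
  chambers <- if (scope == "BIV") c("LV", "RV") else scope
  v <- mesh$vertices; tr <- mesh$triangles
  areas <- triangle_areas(mesh, check = FALSE)
  n <- nrow(v)
  # apex-to-base sweep coordinate: triangle centroid z
  cz <- (v[tr[, 1L], "z"] + v[tr[, 2L], "z"] + v[tr[, 3L], "z"]) / 3
  rows <- integer(0); target <- numeric(0)
  for (ch in chambers) {
    tri_c <- which(mesh$labels == ch)
    if (length(tri_c) == 0L)
      crt_stop(sprintf("chamber %s has no triangles", ch),
               "crt80_validation_error")
    ord <- tri_c[order(cz[tri_c], tri_c)]
    a <- areas[ord]
    tgt <- duration * (cumsum(a) - a / 2) / sum(a)
    rows <- c(rows, ord); target <- c(target, tgt)
  }
  # least squares for vertex times: mean of the three vertex times of each
  # in-scope triangle should match its target
  member <- sort(unique(as.vector(tr[rows, ])))
  colidx <- match(as.vector(tr[rows, ]), member)
  M <- Matrix::sparseMatrix(i = rep(seq_along(rows), 3L), j = colidx,
                            x = 1 / 3,
                            dims = c(length(rows), length(member)))
  G <- Matrix::crossprod(M)
  Mt_tgt <- Matrix::crossprod(M, target)
  # weak prior anchoring each vertex at its incident-triangle mean target:
  # suppresses the oscillatory modes the data term leaves undetermined
  deg <- Matrix::colSums(M > 0)
  t0 <- 3 * as.numeric(Mt_tgt) / deg
  lambda <- 1e-4 * mean(Matrix::diag(G))
  tmem <- as.numeric(Matrix::solve(
    G + lambda * Matrix::Diagonal(length(member)),
    Mt_tgt + lambda * t0))
  tmem <- tmem - min(if (scope == "BIV") min(tmem) else 0, min(tmem))
  times <- numeric(n)
  times[member] <- tmem
  m <- activation_map(mesh, times, setting = "INTRINSIC")
  attr(m, "duration") <- duration
  attr(m, "scope") <- scope
  m
}
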