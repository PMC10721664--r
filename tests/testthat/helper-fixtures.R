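# Fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smallest valid mesh: unit square split into one LV and one RV triangle.
two_tri_mesh <- function() {
  tri_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    triangles = rbind(c(1, 2, 3), c(2, 4, 3)),
    labels = c("LV", "RV")
  )
}

# Triangle strip with prescribed element activation times: triangle i has
# vertices (i, i+1, i+2); vertex times are solved so each triangle's mean
# vertex time equals targets[i] exactly. All triangles have area 0.5.
strip_fixture <- function(targets, labels) {
  k <- length(targets)
  n <- k + 2L
  v <- cbind(x = 0.5 * seq_len(n), y = seq_len(n) %% 2, z = 0)
  tr <- cbind(seq_len(k), seq_len(k) + 1L, seq_len(k) + 2L)
  w <- numeric(n)
  w[1L] <- 0
  w[2L] <- 1.5 * targets[1L]
  for (i in seq_len(k)) w[i + 2L] <- 3 * targets[i] - w[i] - w[i + 1L]
  stopifnot(all(w >= 0), min(w) == 0)
  mesh <- tri_mesh(v, tr, labels)
  list(mesh = mesh, map = activation_map(mesh, w))
}

# Jittered rectangular grid mesh (~nx*ny vertices), left half LV.
random_grid_mesh <- function(nx, ny, seed) {
  set.seed(seed)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  v <- cbind(x = g$i + runif(nrow(g), -0.2, 0.2),
             y = g$j + runif(nrow(g), -0.2, 0.2),
             z = runif(nrow(g), -0.2, 0.2))
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
      tris[[length(tris) + 1L]] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
  }
  tr <- do.call(rbind, tris)
  cx <- (v[tr[, 1L], 1L] + v[tr[, 2L], 1L] + v[tr[, 3L], 1L]) / 3
  tri_mesh(v, tr, ifelse(cx <= stats::median(cx), "LV", "RV"))
}

# Independent per-triangle area oracle via Heron's formula.
heron_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  elen <- function(a, b) sqrt(rowSums((v[a, , drop = FALSE] - v[b, , drop = FALSE])^2))
  a <- elen(tr[, 1L], tr[, 2L])
  b <- elen(tr[, 2L], tr[, 3L])
  c_ <- elen(tr[, 3L], tr[, 1L])
  s <- (a + b + c_) / 2
  sqrt(s * (s - a) * (s - b) * (s - c_))
}

# Independent activation-time oracle: edge weights recomputed from the
# configuration rules, then Bellman-Ford sweeps to the unique fixpoint of
# d[v] = min_u(d[u] + w(u,v)).
oracle_activation_times <- function(mesh, config) {
  tr <- mesh$triangles
  n <- nrow(mesh$vertices)
  e_all <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  lab_all <- rep(mesh$labels, 3L)
  key <- paste(pmin(e_all[, 1L], e_all[, 2L]), pmax(e_all[, 1L], e_all[, 2L]))
  seam_keys <- unique(key)[vapply(unique(key), function(k)
    length(unique(lab_all[key == k])) > 1L, TRUE)]
  keep <- !duplicated(key)
  ei <- pmin(e_all[keep, 1L], e_all[keep, 2L])
  ej <- pmax(e_all[keep, 1L], e_all[keep, 2L])
  ecls <- ifelse(key[keep] %in% seam_keys, "SEAM", lab_all[keep])
  v <- mesh$vertices
  len <- sqrt(rowSums((v[ei, , drop = FALSE] - v[ej, , drop = FALSE])^2))
  vel <- ifelse(ecls == "SEAM", config$base_velocity * config$seam_scale,
                config$base_velocity * config$chamber_scale[ecls])
  mid <- (v[ei, , drop = FALSE] + v[ej, , drop = FALSE]) / 2
  for (p in config$scar_patches) {
    d2 <- rowSums((mid - matrix(v[p$vertex, ], length(ei), 3L, byrow = TRUE))^2)
    hit <- d2 <= p$radius_mm^2
    vel[hit] <- vel[hit] * p$scale
  }
  w <- len / vel
  dist_from <- function(src) {
    d <- rep(Inf, n)
    d[src] <- 0
    repeat {
      cand_t <- c(ej, ei)
      cand_v <- c(d[ei] + w, d[ej] + w)
      m <- tapply(cand_v, cand_t, min)
      nd <- d
      at <- as.integer(names(m))
      nd[at] <- pmin(nd[at], m)
      if (identical(nd, d)) break
      d <- nd
    }
    d
  }
  t <- rep(Inf, n)
  for (k in seq_len(nrow(config$breakthrough)))
    t <- pmin(t, dist_from(config$breakthrough$vertex[k]) +
                config$breakthrough$delay_ms[k])
  t - min(t)
}

# Thomsen's approximation to the ellipsoid surface area (p = 1.6075).
ellipsoid_area <- function(a, b, c_) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c_)^p + (b * c_)^p) / 3)^(1 / p)
}

# Step-function lookup: curve value at time t (right-continuous).
curve_value_at <- function(curve, t) {
  idx <- which(curve$event_times <= t + 1e-12)
  if (length(idx) == 0L) 0 else curve$cum_fraction[max(idx)]
}
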