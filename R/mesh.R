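#' Labelled biventricular surface mesh
#'
#' Constructs a triangulated epicardial surface with a per-triangle chamber
#' label (`"LV"` or `"RV"`). This is the geometric substrate for activation
#' maps: coordinates are in millimetres, and the activation-fraction curves
#' weight each triangle by its area.
#'
#' A valid mesh must reference existing vertices only, contain no degenerate
#' (zero-area) triangles, carry at least one triangle of each chamber label,
#' and form a single connected edge graph (required by the wavefront
#' simulator, which propagates along mesh edges).
#'
#' @param vertices numeric matrix or data frame with columns `x`, `y`, `z`
#'   (mm), one row per vertex.
#' @param triangles integer matrix or data frame with three columns of
#'   1-based vertex indices, one row per triangle.
#' @param labels character vector, one of `"LV"`/`"RV"` per triangle.
#' @param validate logical; skip validation only for internal callers that
#'   have already validated.
#' @return an object of class `tri_mesh` with elements `vertices` (n x 3
#'   matrix), `triangles` (m x 3 integer matrix) and `labels` (character).
#' @examples
#' m <- tri_mesh(
#'   vertices = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(3, 4, 0)),
#'   triangles = rbind(c(1, 2, 3), c(2, 4, 3)),
#'   labels = c("LV", "RV")
#' )
#' triangle_areas(m)
#' @export
tri_mesh <- function(vertices, triangles, labels, validate = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || !is.numeric(vertices))
    crt_stop("`vertices` must be a numeric n x 3 matrix (x, y, z in mm)",
             "crt80_validation_error")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y", "z")

  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L)
    crt_stop("`triangles` must have three vertex-index columns",
             "crt80_validation_error")
  storage.mode(triangles) <- "integer"
  colnames(triangles) <- c("v1", "v2", "v3")

  labels <- as.character(labels)
  mesh <- structure(
    list(vertices = vertices, triangles = triangles, labels = labels),
    class = "tri_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' @rdname tri_mesh
#' @param mesh a `tri_mesh`.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles; lab <- mesh$labels
  n <- nrow(v); m <- nrow(tr)
  if (m < 1L) crt_stop("mesh has no triangles", "crt80_validation_error")
  if (length(lab) != m)
    crt_stop(sprintf("expected %d chamber labels, got %d", m, length(lab)),
             "crt80_validation_error")
  if (!all(lab %in% c("LV", "RV")))
    crt_stop("chamber labels must be 'LV' or 'RV'", "crt80_validation_error")
  if (anyNA(tr) || any(tr < 1L) || any(tr > n))
    crt_stop(sprintf(
      "triangle vertex indices must lie in 1..%d (offending triangle %d)",
      n, which(apply(tr, 1L, function(r) anyNA(r) || any(r < 1L | r > n)))[1L]
    ), "crt80_validation_error")
  if (any(tr[, 1L] == tr[, 2L] | tr[, 2L] == tr[, 3L] | tr[, 1L] == tr[, 3L]))
    crt_stop("triangle with repeated vertex index", "crt80_validation_error")
  a <- triangle_areas(mesh, check = FALSE)
  if (any(a <= 0))
    crt_stop(sprintf("degenerate (zero-area) triangle at row %d",
                     which(a <= 0)[1L]), "crt80_validation_error")
  if (!all(c("LV", "RV") %in% lab))
    crt_stop("mesh must carry at least one LV and one RV triangle",
             "crt80_validation_error")
  g <- mesh_igraph(mesh)
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    small <- which(comp$membership == which.min(comp$csize))[1L]
    crt_stop(sprintf(
      "mesh edge graph is disconnected (%d components; e.g. vertex %d isolated from vertex 1)",
      comp$no, small), "crt80_validation_error")
  }
  invisible(mesh)
}

#' Triangle areas of a surface mesh
#'
#' Area of each triangle as half the magnitude of the cross product of two
#' edge vectors, in mm^2.
#'
#' @param mesh a [tri_mesh].
#' @param check validate that all areas are strictly positive.
#' @return numeric vector of per-triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh, check = TRUE) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  a <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (check && any(a <= 0))
    crt_stop(sprintf("degenerate (zero-area) triangle at row %d",
                     which(a <= 0)[1L]), "crt80_validation_error")
  a
}

#' @export
print.tri_mesh <- function(x, ...) {
  a <- triangle_areas(x, check = FALSE)
  cat(sprintf(
    "<tri_mesh> %d vertices, %d triangles (LV %d / RV %d), area %.1f mm^2\n",
    nrow(x$vertices), nrow(x$triangles),
    sum(x$labels == "LV"), sum(x$labels == "RV"), sum(a)))
  invisible(x)
}

# ---- internal edge-graph machinery -----------------------------------------

# Unique undirected edges with lengths, chamber class and midpoints.
# Edge class is "LV"/"RV" when every incident triangle carries that label,
# "SEAM" when the edge borders both chambers.
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  lab3 <- rep(mesh$labels, 3L)
  lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  is_lv <- tabulate(idx[lab3 == "LV"], nbins = sum(first)) > 0L
  is_rv <- tabulate(idx[lab3 == "RV"], nbins = sum(first)) > 0L
  cls <- ifelse(is_lv & is_rv, "SEAM", ifelse(is_lv, "LV", "RV"))
  i <- lo[first]; j <- hi[first]
  v <- mesh$vertices
  d <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  mid <- (v[i, , drop = FALSE] + v[j, , drop = FALSE]) / 2
  list(i = i, j = j, length = len, class = cls, midpoint = mid)
}

mesh_igraph <- function(mesh, edges = NULL) {
  edges <- edges %||% mesh_edges(mesh)
  igraph::make_graph(as.vector(t(cbind(edges$i, edges$j))),
                     n = nrow(mesh$vertices), directed = FALSE)
}

# One-off per-mesh preparation reused across many simulations (cohorts).
mesh_prep <- function(mesh) {
  edges <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  # adjacency lists: neighbours of each vertex and the edge index used
  both_v <- c(edges$i, edges$j)
  both_n <- c(edges$j, edges$i)
  both_e <- rep(seq_along(edges$i), 2L)
  o <- order(both_v)
  runs <- rle(both_v[o])
  adj_nbr <- split(both_n[o], rep(seq_along(runs$values), runs$lengths))
  adj_eidx <- split(both_e[o], rep(seq_along(runs$values), runs$lengths))
  nbr <- vector("list", n); eidx <- vector("list", n)
  nbr[runs$values] <- adj_nbr
  eidx[runs$values] <- adj_eidx
  list(
    mesh = mesh,
    edges = edges,
    adj_nbr = nbr,
    adj_eidx = eidx,
    areas = triangle_areas(mesh, check = FALSE),
    landmarks = mesh_landmarks(mesh)
  )
}

# Anatomical landmark vertices used by the pacing/bundle-branch presets.
# Convention of biv_shell_mesh(): LV occupies x < 0, RV x > 0, long axis z
# with the apex at negative z.
mesh_landmarks <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  in_lv <- unique(as.vector(tr[mesh$labels == "LV", ]))
  in_rv <- unique(as.vector(tr[mesh$labels == "RV", ]))
  lv_only <- setdiff(in_lv, in_rv)
  rv_only <- setdiff(in_rv, in_lv)
  if (length(lv_only) == 0L) lv_only <- in_lv
  if (length(rv_only) == 0L) rv_only <- in_rv
  lv_free <- lv_only[which.min(v[lv_only, "x"])]
  rv_free <- rv_only[which.max(v[rv_only, "x"])]
  # RV apical free wall: low on the long axis but on the free wall proper,
  # where an RV lead tip sits (not the polar tip shared with the LV)
  xr <- v[rv_only, "x"]; zr <- v[rv_only, "z"]
  rv_apex <- rv_only[which.min(zr / max(abs(zr)) - xr / max(abs(xr)))]
  list(lv_free_wall = lv_free, rv_free_wall = rv_free, rv_apex = rv_apex)
}

# k nearest same-set vertices to a landmark (site-jitter candidates).
nearest_vertices <- function(mesh, vertex, pool, k = 5L) {
  v <- mesh$vertices
  d <- sqrt(rowSums((v[pool, , drop = FALSE] -
                       matrix(v[vertex, ], length(pool), 3L, byrow = TRUE))^2))
  pool[order(d)][seq_len(min(k, length(pool)))]
}
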