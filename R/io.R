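#' Read and write labelled surface meshes
#'
#' Two plain-text dialects are supported:
#' * `"csv"` — a CSV pair `<path>_vertices.csv` (`id,x,y,z`) and
#'   `<path>_triangles.csv` (`id,v1,v2,v3,label`), 1-based indices and
#'   `LV`/`RV` labels;
#' * `"ply"` — ASCII PLY whose faces carry an extra integer `label`
#'   property (0 = LV, 1 = RV).
#'
#' Coordinates are written with 17 significant digits so an ASCII
#' round-trip is bit-exact.
#'
#' @param mesh a [tri_mesh].
#' @param path file path; for `"csv"` a prefix to which
#'   `_vertices.csv`/`_triangles.csv` are appended.
#' @param format `"csv"`, `"ply"`, or `"auto"` (by extension, read only).
#' @return `read_mesh()` a validated [tri_mesh]; `write_mesh()` the path,
#'   invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("csv", "ply")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  if (format == "csv") {
    vf <- paste0(path, "_vertices.csv"); tf <- paste0(path, "_triangles.csv")
    writeLines(c("id,x,y,z",
                 sprintf("%d,%s,%s,%s", seq_len(nrow(v)),
                         fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L]))),
               vf)
    writeLines(c("id,v1,v2,v3,label",
                 sprintf("%d,%d,%d,%d,%s", seq_len(nrow(tr)),
                         tr[, 1L], tr[, 2L], tr[, 3L], mesh$labels)),
               tf)
  } else {
    lab01 <- ifelse(mesh$labels == "LV", 0L, 1L)
    writeLines(c(
      "ply", "format ascii 1.0",
      "comment labelled biventricular epicardial surface (label: 0=LV, 1=RV)",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(tr)),
      "property list uchar int vertex_indices",
      "property int label",
      "end_header",
      sprintf("%s %s %s", fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L])),
      sprintf("3 %d %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L, tr[, 3L] - 1L, lab01)
    ), path)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = c("auto", "csv", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "csv"
  if (format == "csv") read_mesh_csv(path) else read_mesh_ply(path)
}

read_mesh_csv <- function(path) {
  vf <- paste0(path, "_vertices.csv"); tf <- paste0(path, "_triangles.csv")
  for (f in c(vf, tf))
    if (!file.exists(f))
      crt_stop(sprintf("mesh file not found: %s", f), "crt80_io_error")
  v <- utils::read.csv(vf, colClasses = "numeric")
  tr <- utils::read.csv(tf)
  if (!all(c("x", "y", "z") %in% names(v)))
    crt_stop("vertices file must have columns id,x,y,z", "crt80_format_error")
  if (!all(c("v1", "v2", "v3") %in% names(tr)))
    crt_stop("triangles file must have columns id,v1,v2,v3,label",
             "crt80_format_error")
  if (!"label" %in% names(tr))
    crt_stop("triangles file is missing the chamber 'label' column",
             "crt80_format_error")
  tri_mesh(as.matrix(v[, c("x", "y", "z")]),
           as.matrix(tr[, c("v1", "v2", "v3")]),
           as.character(tr$label))
}

read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply" ||
      !grepl("^format ascii", trimws(lines[2L])))
    crt_stop("not an ASCII PLY file", "crt80_format_error")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) crt_stop("PLY header not terminated", "crt80_format_error")
  hdr <- trimws(lines[seq_len(end)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L)
    crt_stop("PLY must declare one vertex and one face element",
             "crt80_format_error")
  # face properties after the face element declaration
  fi <- grep("^element face ", hdr)
  face_props <- grep("^property", hdr[seq.int(fi + 1L, length(hdr))], value = TRUE)
  if (!any(grepl("label$", face_props)))
    crt_stop("PLY faces carry no 'label' property (0=LV, 1=RV expected)",
             "crt80_format_error")
  body <- lines[seq.int(end + 1L, length.out = nv + nf)]
  vtx <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), nv, byrow = TRUE)
  if (ncol(vtx) != 3L)
    crt_stop("PLY vertex rows must have exactly x y z", "crt80_format_error")
  fr <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE), nf, byrow = TRUE)
  if (ncol(fr) != 5L || any(fr[, 1L] != 3))
    crt_stop("PLY faces must be triangles with a trailing label",
             "crt80_format_error")
  tri_mesh(vtx, fr[, 2:4] + 1L, ifelse(fr[, 5L] == 0, "LV", "RV"))
}

#' Read and write activation maps
#'
#' Activation maps are stored as CSV with header `vertex_id,time_ms`, one
#' row per mesh vertex, times in ms from QRS onset. Times round-trip to
#' better than 1e-6 ms (17 significant digits are written). On load the
#' vertex count must match the mesh, and maps whose minimum time is positive
#' are re-referenced to 0 (or rejected with `strict = TRUE`).
#'
#' @param map an [activation_map].
#' @param path CSV file path.
#' @param mesh the [tri_mesh] the map belongs to.
#' @param setting pacing setting tag to attach on load.
#' @param strict passed to [activation_map()].
#' @return `read_activation_map()` an [activation_map]; `write_activation_map()`
#'   the path, invisibly.
#' @export
write_activation_map <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  writeLines(c("vertex_id,time_ms",
               sprintf("%d,%s", seq_along(map$times), fmt_num(map$times))),
             path)
  invisible(path)
}

#' @rdname write_activation_map
#' @export
read_activation_map <- function(path, mesh, setting = "INTRINSIC",
                                strict = FALSE) {
  if (!file.exists(path))
    crt_stop(sprintf("activation map file not found: %s", path),
             "crt80_io_error")
  d <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("vertex_id", "time_ms") %in% names(d)))
    crt_stop("activation map CSV must have header vertex_id,time_ms",
             "crt80_format_error")
  if (nrow(d) != nrow(mesh$vertices))
    crt_stop(sprintf("map has %d rows but mesh has %d vertices",
                     nrow(d), nrow(mesh$vertices)), "crt80_shape_error")
  times <- d$time_ms[order(d$vertex_id)]
  if (any(times < 0))
    crt_stop("negative activation time in file", "crt80_validation_error")
  activation_map(mesh, times, setting = setting, strict = strict)
}
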