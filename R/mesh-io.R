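#' Read a triangle mesh from an ascii file
#'
#' Supported formats: OFF, ascii PLY and ascii VTK (legacy POLYDATA).  The
#' format is inferred from the file extension unless given explicitly.
#' Coordinates are kept exactly as printed (ascii round trips are bit-exact
#' up to the writer's formatting precision).
#'
#' @param path path to the mesh file.
#' @param format one of `"off"`, `"ply"`, `"vtk"`; default guesses from the
#'   extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply", vtk = "vtk",
                     stop("cannot infer mesh format from extension '.",
                          ext, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  switch(format,
         off = parse_off(lines, path),
         ply = parse_ply(lines, path),
         vtk = parse_vtk(lines, path))
}

fields_num <- function(line) {
  as.numeric(strsplit(trimws(line), "\\s+")[[1]])
}

parse_face_rows <- function(lines, start, n_faces, path) {
  faces <- matrix(NA_integer_, n_faces, 3)
  li <- start
  for (k in seq_len(n_faces)) {
    v <- fields_num(lines[li])
    if (length(v) < 1 || v[1] != 3 || length(v) < 4)
      stop(sprintf("%s: line %d: only triangular faces supported (got '%s')",
                   path, li, lines[li]))
    faces[k, ] <- as.integer(v[2:4]) + 1L   # files are 0-based
    li <- li + 1L
  }
  faces
}

parse_off <- function(lines, path) {
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF")
    stop(path, ": line 1: missing OFF header")
  cnt <- fields_num(lines[2])
  if (length(cnt) < 2 || anyNA(cnt[1:2]))
    stop(path, ": line 2: expected 'n_vertices n_faces n_edges'")
  nv <- cnt[1]; nf <- cnt[2]
  verts <- t(vapply(lines[3:(2 + nv)], fields_num, numeric(3),
                    USE.NAMES = FALSE))
  faces <- parse_face_rows(lines, 3L + nv, nf, path)
  triangle_mesh(verts, faces)
}

parse_ply <- function(lines, path) {
  if (trimws(lines[1]) != "ply") stop(path, ": line 1: missing ply header")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop(path, ": no end_header line")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop(path, ": only ascii PLY is supported")
  el <- regmatches(hdr, regexec("^element\\s+(\\w+)\\s+(\\d+)", trimws(hdr)))
  el <- el[vapply(el, length, 1L) == 3]
  names(el) <- vapply(el, `[`, "", 2)
  nv <- as.integer(el[["vertex"]][3])
  nf <- as.integer(el[["face"]][3])
  verts <- t(vapply(lines[hdr_end + seq_len(nv)],
                    function(l) fields_num(l)[1:3], numeric(3),
                    USE.NAMES = FALSE))
  faces <- parse_face_rows(lines, hdr_end + nv + 1L, nf, path)
  triangle_mesh(verts, faces)
}

parse_vtk <- function(lines, path) {
  pts_i <- grep("^POINTS\\s", lines)[1]
  if (is.na(pts_i)) stop(path, ": no POINTS section")
  nv <- as.integer(strsplit(trimws(lines[pts_i]), "\\s+")[[1]][2])
  # POINTS data may wrap lines arbitrarily: gather 3*nv numbers
  vals <- numeric(0); li <- pts_i + 1L
  while (length(vals) < 3 * nv) {
    vals <- c(vals, fields_num(lines[li])); li <- li + 1L
  }
  verts <- matrix(vals[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  pol_i <- grep("^POLYGONS\\s", lines)[1]
  if (is.na(pol_i)) stop(path, ": no POLYGONS section")
  nf <- as.integer(fields_num(sub("^POLYGONS", "", lines[pol_i]))[1])
  faces <- parse_face_rows(lines, pol_i + 1L, nf, path)
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh to an ascii file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"off"`, `"ply"` or `"vtk"`; default from extension.
#' @param point_data optional named list of per-vertex numeric vectors,
#'   written as VTK `POINT_DATA` scalar arrays (VTK format only).
#' @param digits printing precision (default 17, lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply", "vtk"),
                       point_data = NULL, digits = 17) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply", vtk = "vtk",
                     stop("cannot infer mesh format from extension"))
  }
  v <- mesh$vertices; f <- mesh$faces
  vtxt <- apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  ftxt <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  out <- switch(format,
    off = c("OFF", paste(nrow(v), nrow(f), 0), vtxt, ftxt),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(v)),
            "property float x", "property float y", "property float z",
            paste("element face", nrow(f)),
            "property list uchar int vertex_indices",
            "end_header", vtxt, ftxt),
    vtk = {
      hdr <- c("# vtk DataFile Version 3.0", "surfmorph mesh", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(v), "double"), vtxt,
               paste("POLYGONS", nrow(f), 4 * nrow(f)), ftxt)
      if (!is.null(point_data)) {
        hdr <- c(hdr, paste("POINT_DATA", nrow(v)))
        for (nm in names(point_data)) {
          hdr <- c(hdr,
                   paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default",
                   formatC(point_data[[nm]], digits = digits, format = "g"))
        }
      }
      hdr
    })
  writeLines(out, path)
  invisible(path)
}

#' Write a per-vertex scalar field as CSV
#'
#' Two columns: `vertex_index` (1-based) and `value`.
#'
#' @param values numeric vector, one value per vertex.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vertex_field_csv <- function(values, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(values),
                              value = values),
                   path, row.names = FALSE)
  invisible(path)
}
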