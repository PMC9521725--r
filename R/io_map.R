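# Map export/import: legacy ASCII VTK polydata and ASCII PLY for the mesh
# with per-vertex voltage scalars, plus a plain CSV sphere table. Values are
# written with 9 significant digits (re-import agrees to >= 6 significant
# digits as the formats' text precision allows).

fmt_map <- function(x) formatC(x, digits = 9, format = "g")

#' Export a voltage map and decrement spheres to open formats
#'
#' Writes the chamber mesh with per-vertex bipolar voltage as geometry
#' (`<basename>.vtk` legacy ASCII polydata, or `<basename>.ply` ASCII PLY
#' with a per-vertex `voltage` property) plus the sphere table as
#' `<basename>_spheres.csv`. No-data vertices are written as -1 mV (VTK has
#' no native NA) and restored to `NA` on import. Colour thresholds
#' (scar/border, mV) travel as metadata comments.
#'
#' @param voltage_map A [build_voltage_map()] result.
#' @param spheres A [place_deep_spheres()] result (may have zero rows).
#' @param path Output basename (extensions are appended).
#' @param format `"vtk"` or `"ply"`; anything else is an error listing the
#'   supported formats.
#' @return Named character vector of the files written, invisibly.
#' @export
export_map <- function(voltage_map, spheres, path, format = c("vtk", "ply")) {
  if (!is.character(format) || !format[1] %in% c("vtk", "ply")) {
    stop_typed("unsupported_format",
               sprintf("unsupported format '%s'; supported: vtk, ply",
                       format[1]))
  }
  format <- format[1]
  mesh <- voltage_map$mesh
  v <- voltage_map$vertex_voltage
  v_out <- ifelse(is.na(v), -1, v)

  geom_path <- paste0(path, ".", format)
  if (format == "vtk") {
    nv <- nrow(mesh$vertices)
    nf <- nrow(mesh$faces)
    lines <- c(
      "# vtk DataFile Version 3.0",
      sprintf("bipolar voltage map; scar<%gmV border<%gmV",
              voltage_map$scar_mv, voltage_map$border_mv),
      "ASCII",
      "DATASET POLYDATA",
      sprintf("POINTS %d float", nv),
      apply(mesh$vertices, 1L, function(p) paste(fmt_map(p), collapse = " ")),
      sprintf("POLYGONS %d %d", nf, 4L * nf),
      apply(mesh$faces, 1L, function(f) paste(c(3L, f - 1L), collapse = " ")),
      sprintf("POINT_DATA %d", nv),
      "SCALARS voltage float 1",
      "LOOKUP_TABLE default",
      fmt_map(v_out)
    )
    writeLines(lines, geom_path)
  } else {
    nv <- nrow(mesh$vertices)
    nf <- nrow(mesh$faces)
    lines <- c(
      "ply",
      "format ascii 1.0",
      sprintf("comment bipolar voltage map; scar<%gmV border<%gmV",
              voltage_map$scar_mv, voltage_map$border_mv),
      sprintf("element vertex %d", nv),
      "property float x", "property float y", "property float z",
      "property float voltage",
      sprintf("element face %d", nf),
      "property list uchar int vertex_indices",
      "end_header",
      vapply(seq_len(nv), function(i) {
        paste(c(fmt_map(mesh$vertices[i, ]), fmt_map(v_out[i])),
              collapse = " ")
      }, character(1)),
      apply(mesh$faces, 1L, function(f) paste(c(3L, f - 1L), collapse = " "))
    )
    writeLines(lines, geom_path)
  }
  sph_path <- paste0(path, "_spheres.csv")
  utils::write.csv(
    data.frame(channel = spheres$channel,
               cx = spheres$cx, cy = spheres$cy, cz = spheres$cz,
               radius_mm = spheres$radius_mm, deep_ms = spheres$deep_ms),
    sph_path, row.names = FALSE, quote = FALSE)
  invisible(c(geometry = geom_path, spheres = sph_path))
}

#' Re-import an exported map
#'
#' @param path Basename used at export time.
#' @param format `"vtk"` or `"ply"`.
#' @return A list with `vertices`, `faces`, `vertex_voltage` (no-data
#'   restored to `NA`) and `spheres`.
#' @export
import_map <- function(path, format = c("vtk", "ply")) {
  if (!is.character(format) || !format[1] %in% c("vtk", "ply")) {
    stop_typed("unsupported_format",
               sprintf("unsupported format '%s'; supported: vtk, ply",
                       format[1]))
  }
  format <- format[1]
  lines <- readLines(paste0(path, ".", format))
  if (format == "vtk") {
    ip <- grep("^POINTS", lines)
    nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    verts <- do.call(rbind, lapply(lines[(ip + 1):(ip + nv)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    ifc <- grep("^POLYGONS", lines)
    nf <- as.integer(strsplit(lines[ifc], "\\s+")[[1]][2])
    faces <- do.call(rbind, lapply(lines[(ifc + 1):(ifc + nf)], function(l) {
      as.integer(strsplit(trimws(l), "\\s+")[[1]][-1]) + 1L
    }))
    isc <- grep("^LOOKUP_TABLE", lines)[1]
    volt <- as.numeric(lines[(isc + 1):(isc + nv)])
  } else {
    hd_end <- grep("^end_header", lines)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    vl <- lines[(hd_end + 1):(hd_end + nv)]
    vm <- do.call(rbind, lapply(vl, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    verts <- vm[, 1:3, drop = FALSE]
    volt <- vm[, 4]
    fl <- lines[(hd_end + nv + 1):(hd_end + nv + nf)]
    faces <- do.call(rbind, lapply(fl, function(l) {
      as.integer(strsplit(trimws(l), "\\s+")[[1]][-1]) + 1L
    }))
  }
  volt[volt == -1] <- NA_real_
  colnames(verts) <- c("x", "y", "z")
  spheres <- utils::read.csv(paste0(path, "_spheres.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(channel = "character"))
  list(vertices = verts, faces = faces, vertex_voltage = volt,
       spheres = spheres)
}
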