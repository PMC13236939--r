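# ASCII PLY / STL readers and writers.
#
# PLY carries per-vertex density as a scalar property; STL cannot, so a
# sidecar CSV of vertex densities (in template vertex order) is written
# alongside.  All numbers are printed with enough digits for exact textual
# round-tripping at double precision.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a surface mesh as ASCII PLY
#'
#' Vertex coordinates (and, when present, per-vertex density as a scalar
#' `density` property) plus 0-based face indices.  Reading a truncated or
#' malformed file raises a parse error naming the offending line.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_d <- !is.null(mesh$vertex_density)
  hdr <- c("ply", "format ascii 1.0",
           paste0("comment body ", mesh$body),
           paste0("element vertex ", nv),
           "property double x", "property double y", "property double z",
           if (has_d) "property double density",
           paste0("element face ", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vl <- apply(mesh$vertices, 1, function(r) paste(fmt_num(r), collapse = " "))
  if (has_d) vl <- paste(vl, fmt_num(mesh$vertex_density))
  fl <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' @rdname write_ply
#' @param body body label to assign (default: the label stored in the file
#'   comment, falling back to `"femur"`).
#' @export
read_ply <- function(path, body = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("not a PLY file: ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("PLY parse error: missing end_header")
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY parse error: missing element counts")
  has_d <- any(grepl("^property double density", hdr))
  cmt <- grep("^comment body ", hdr, value = TRUE)
  if (is.null(body))
    body <- if (length(cmt)) sub("comment body ", "", cmt[1]) else "femur"
  if (length(lines) < endh + nv + nf)
    stop("PLY parse error: truncated at line ", length(lines) + 1L,
         " (expected ", endh + nv + nf, " lines)")
  vparts <- strsplit(lines[endh + seq_len(nv)], " ", fixed = TRUE)
  ncols <- 3L + has_d
  if (any(lengths(vparts) != ncols))
    stop("PLY parse error: malformed vertex at line ",
         endh + which(lengths(vparts) != ncols)[1])
  vnum <- matrix(as.numeric(unlist(vparts)), ncol = ncols, byrow = TRUE)
  fparts <- strsplit(lines[endh + nv + seq_len(nf)], " ", fixed = TRUE)
  if (any(lengths(fparts) != 4L) ||
      any(vapply(fparts, function(p) p[1] != "3", logical(1))))
    stop("PLY parse error: only triangular faces are supported")
  fnum <- matrix(as.integer(unlist(fparts)), ncol = 4L, byrow = TRUE)[, 2:4] + 1L
  surface_mesh(vnum[, 1:3], fnum,
               vertex_density = if (has_d) vnum[, 4], body = body)
}

#' Write / read a surface mesh as ASCII STL (with density sidecar)
#'
#' STL stores independent triangles and carries no vertex attributes; when
#' the mesh has densities a sidecar CSV (`<path>.density.csv`, columns
#' x/y/z/density in template vertex order) is written.  On read, vertices
#' are re-unified by exact coordinate text; if the sidecar is supplied its
#' row order defines the vertex order, reconstructing the density exactly.
#'
#' @inheritParams write_ply
#' @export
write_stl <- function(mesh, path) {
  fv <- face_vertex_array(mesh)
  nrm <- mesh_face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", mesh$body), con)
  for (i in seq_len(nrow(mesh$faces))) {
    writeLines(c(paste("facet normal", paste(fmt_num(nrm[i, ]), collapse = " ")),
                 " outer loop",
                 paste("  vertex", paste(fmt_num(fv$a[i, ]), collapse = " ")),
                 paste("  vertex", paste(fmt_num(fv$b[i, ]), collapse = " ")),
                 paste("  vertex", paste(fmt_num(fv$c[i, ]), collapse = " ")),
                 " endloop", "endfacet"), con)
  }
  writeLines(paste("endsolid", mesh$body), con)
  if (!is.null(mesh$vertex_density)) {
    side <- data.frame(x = fmt_num(mesh$vertices[, 1]),
                       y = fmt_num(mesh$vertices[, 2]),
                       z = fmt_num(mesh$vertices[, 3]),
                       density = fmt_num(mesh$vertex_density))
    utils::write.csv(side, paste0(path, ".density.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_stl
#' @param density_csv optional sidecar CSV path.
#' @export
read_stl <- function(path, density_csv = NULL, body = "femur") {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "solid"))
    stop("not an ASCII STL file: ", path)
  vlines <- grep("^\\s*vertex ", lines)
  if (length(vlines) %% 3L != 0L)
    stop("STL parse error: vertex count not a multiple of 3 (truncated file?)")
  if (!any(startsWith(lines, "endsolid")))
    stop("STL parse error: missing endsolid (truncated file?)")
  toks <- sub("^\\s*vertex\\s+", "", lines[vlines])
  corner_key <- gsub("\\s+", " ", toks)
  coords <- matrix(as.numeric(unlist(strsplit(corner_key, " ", fixed = TRUE))),
                   ncol = 3, byrow = TRUE)
  if (!is.null(density_csv)) {
    side <- utils::read.csv(density_csv, colClasses = "character")
    vkey <- paste(side$x, side$y, side$z)
    idx <- match(corner_key, vkey)
    if (anyNA(idx))
      stop("density sidecar does not match STL vertices")
    verts <- cbind(as.numeric(side$x), as.numeric(side$y), as.numeric(side$z))
    dens <- as.numeric(side$density)
  } else {
    first <- !duplicated(corner_key)
    verts <- coords[first, , drop = FALSE]
    idx <- match(corner_key, corner_key[first])
    dens <- NULL
  }
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, vertex_density = dens, body = body)
}

#' Write a cohort to disk with a manifest
#'
#' One PLY per body per specimen plus a manifest CSV (animal id, acquired
#' side, mirrored flag, file paths).
#'
#' @param cohort a `knee_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    paths <- vapply(specimen_bodies(), function(b) {
      p <- file.path(dir, sprintf("limb%02d_%s.ply", i, b))
      write_ply(s[[b]], p)
      p
    }, character(1))
    rows[[i]] <- data.frame(limb = i, animal_id = s$animal_id,
                            side_as_acquired = s$side_as_acquired,
                            is_mirrored = s$is_mirrored,
                            femur = paths[1], tibia_fibula = paths[2],
                            patella = paths[3], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
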