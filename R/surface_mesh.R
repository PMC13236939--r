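#' Triangle surface mesh with per-vertex density
#'
#' The basic geometric container of the package: a shared-topology triangle
#' mesh describing one bone surface.  All meshes generated for the same body
#' within one cohort share an identical face array (template topology), which
#' is what makes vertex-wise correspondence, and hence the statistical
#' shape-appearance model, well defined without any registration step.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#'   (File formats such as PLY store 0-based indices; the readers/writers
#'   convert.)
#' @param vertex_density optional numeric vector of length n, per-vertex
#'   equivalent mineral density in g/cm^3 (finite, non-negative).
#' @param face_region optional character vector of length m with labels in
#'   `"medial"`, `"lateral"`, `"other"`.
#' @param body body label, one of `"femur"`, `"tibia_fibula"`, `"patella"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_density = NULL,
                         face_region = NULL, body = "femur") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > n))
    stop("face indices out of range [1, n_vertices]")
  if (!is.null(vertex_density)) {
    vertex_density <- as.numeric(vertex_density)
    if (length(vertex_density) != n)
      stop("vertex_density must have one value per vertex")
    if (any(!is.finite(vertex_density)) || any(vertex_density < 0))
      stop("vertex_density must be finite and >= 0")
  }
  if (!is.null(face_region)) {
    face_region <- as.character(face_region)
    if (length(face_region) != nrow(faces))
      stop("face_region must have one label per face")
    bad <- setdiff(unique(face_region), c("medial", "lateral", "other"))
    if (length(bad)) stop("unknown face_region label: ", paste(bad, collapse = ", "))
  }
  body <- match.arg(body, c("femur", "tibia_fibula", "patella"))
  structure(list(vertices = vertices, faces = faces,
                 vertex_density = vertex_density,
                 face_region = face_region, body = body),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %s, %d vertices, %d faces%s>\n", x$body,
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$vertex_density)) "" else ", with density"))
  invisible(x)
}

# Per-face geometry ---------------------------------------------------------

face_vertex_array <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas, centroids and normals
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_face_areas` gives the triangle areas (mm^2); `mesh_area`
#'   their sum; `mesh_face_centroids` an m x 3 matrix; `mesh_face_normals`
#'   unit normals oriented by the face winding.
#' @export
mesh_face_areas <- function(mesh) {
  fv <- face_vertex_array(mesh)
  cr <- cross3(fv$b - fv$a, fv$c - fv$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname mesh_face_areas
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_face_areas
#' @export
mesh_face_centroids <- function(mesh) {
  fv <- face_vertex_array(mesh)
  (fv$a + fv$b + fv$c) / 3
}

#' @rdname mesh_face_areas
#' @export
mesh_face_normals <- function(mesh) {
  fv <- face_vertex_array(mesh)
  cr <- cross3(fv$b - fv$a, fv$c - fv$a)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

# Structured-grid meshing ----------------------------------------------------
#
# All synthetic bodies are built from rectangular parameter grids with a
# fixed, cohort-wide resolution, so every specimen shares the template
# topology by construction.

grid_faces <- function(nu, nv) {
  # nu x nv vertex grid, vertex id = (i - 1) * nv + j
  idx <- function(i, j) (i - 1L) * nv + j
  i <- rep(seq_len(nu - 1L), each = nv - 1L)
  j <- rep(seq_len(nv - 1L), times = nu - 1L)
  v00 <- idx(i, j); v01 <- idx(i, j + 1L)
  v10 <- idx(i + 1L, j); v11 <- idx(i + 1L, j + 1L)
  rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))
}

grid_mesh <- function(u, v, fpos) {
  nu <- length(u); nv <- length(v)
  uu <- rep(u, each = nv)
  vv <- rep(v, times = nu)
  verts <- fpos(uu, vv)
  list(vertices = verts, faces = grid_faces(nu, nv), u = uu, v = vv)
}

# Mirroring ------------------------------------------------------------------

#' Reflect a mesh across the sagittal plane (x = 0)
#'
#' Used to convert between left- and right-side representations.  The face
#' winding is flipped so that outward orientation is preserved; anatomical
#' region labels are invariant under reflection.
#'
#' @param mesh a [surface_mesh()].
#' @return the reflected `surface_mesh` (identical topology).
#' @export
mirror_mesh <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

# Rigid transforms -----------------------------------------------------------

rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

transform_points <- function(p, R, origin = c(0, 0, 0), translation = c(0, 0, 0)) {
  p <- as.matrix(p)
  sweep(sweep(p, 2, origin) %*% t(R), 2, origin + translation, "+")
}
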