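# Point-cloud and triangle-mesh containers. Coordinates in mm.

as_xyz <- function(x) {
  m <- if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3, byrow = TRUE)
       else as.matrix(x)
  if (ncol(m) != 3L) stopf("expected 3-column coordinates, got %d", ncol(m))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Point cloud
#'
#' N x 3 coordinates in mm with optional per-point source labels
#' (e.g. `"skin"`, `"sleeve"`, `"outlier"`) and optional unit normals.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param labels Optional character vector of length N.
#' @param normals Optional N x 3 matrix of unit vectors.
#' @return A `point_cloud` object.
#' @export
point_cloud <- function(points = matrix(numeric(0), 0, 3),
                        labels = NULL, normals = NULL) {
  pts <- as_xyz(points)
  if (any(!is.finite(pts))) stopf("point cloud contains non-finite coordinates")
  n <- nrow(pts)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stopf("labels length %d != %d points", length(labels), n)
  }
  if (!is.null(normals)) {
    normals <- as_xyz(normals)
    if (nrow(normals) != n) stopf("normals rows != points")
    if (n > 0) {
      len <- sqrt(rowSums(normals^2))
      if (any(abs(len - 1) > 1e-6)) stopf("normals must be unit length (tol 1e-6)")
    }
  }
  structure(list(points = pts, labels = labels, normals = normals),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points", nrow(x$points)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  if (!is.null(x$normals)) cat(", with normals")
  cat("\n")
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A `point_cloud`.
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

# Subset a point cloud by index, keeping labels and normals aligned.
cloud_subset <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              normals = if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE])
}

#' Apply a rigid transform to a point cloud
#'
#' Points are mapped by the full transform; normals, when present, are
#' rotated only. Labels are carried over unchanged.
#'
#' @param t A `rigid_transform`.
#' @param cloud A `point_cloud`.
#' @return The transformed `point_cloud`.
#' @export
transform_points <- function(t, cloud) {
  stopifnot(inherits(t, "rigid_transform"), inherits(cloud, "point_cloud"))
  point_cloud(apply_rigid(t, cloud$points),
              labels = cloud$labels,
              normals = if (!is.null(cloud$normals)) apply_rotation(t, cloud$normals))
}

#' Triangle mesh
#'
#' Vertices in mm with 1-based triangular face indices. `watertight` is a
#' recorded flag for solids built by the phantom generator (closed, manifold
#' by construction); it is not recomputed from arbitrary input.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param watertight Logical flag recorded on the mesh.
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces, watertight = FALSE) {
  V <- as_xyz(vertices)
  Fm <- as.matrix(faces)
  if (ncol(Fm) != 3L) stopf("faces must have 3 columns")
  storage.mode(Fm) <- "integer"
  dimnames(Fm) <- NULL
  if (nrow(Fm) > 0 && (min(Fm) < 1L || max(Fm) > nrow(V)))
    stopf("face index out of range [1, %d]", nrow(V))
  structure(list(vertices = V, faces = Fm, watertight = isTRUE(watertight)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$watertight) ", watertight" else ""))
  invisible(x)
}

# Outward-facing (as-wound) unit normals per face.
face_normals <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  a <- V[Fm[, 1], , drop = FALSE]
  n <- cross3(V[Fm[, 2], , drop = FALSE] - a, V[Fm[, 3], , drop = FALSE] - a)
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# Row-wise cross product of Nx3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_areas <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  a <- V[Fm[, 1], , drop = FALSE]
  n <- cross3(V[Fm[, 2], , drop = FALSE] - a, V[Fm[, 3], , drop = FALSE] - a)
  0.5 * sqrt(rowSums(n^2))
}

#' Apply a rigid transform to a triangle mesh
#' @param t A `rigid_transform`.
#' @param mesh A `triangle_mesh`.
#' @return The transformed mesh.
#' @export
transform_mesh <- function(t, mesh) {
  stopifnot(inherits(t, "rigid_transform"), inherits(mesh, "triangle_mesh"))
  triangle_mesh(apply_rigid(t, mesh$vertices), mesh$faces, mesh$watertight)
}

#' Ray
#'
#' Origin plus unit direction, used for visibility and entry/exit geometry.
#'
#' @param origin length-3 point (mm).
#' @param direction length-3 vector; must be unit length within `1e-9`.
#' @return A `ray` object.
#' @export
ray <- function(origin, direction) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stopf("ray direction must be unit length")
  structure(list(origin = origin, direction = direction), class = "ray")
}

normalize3 <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalise a zero vector")
  v / n
}

#' Ray/mesh intersections
#'
#' All intersections of a ray with a mesh, ordered by increasing ray
#' parameter. For a watertight mesh and a ray whose origin lies outside,
#' the number of hits is even.
#'
#' @param r A `ray`.
#' @param mesh A `triangle_mesh`.
#' @return A data.frame with columns `t`, `x`, `y`, `z`, `face` (1-based);
#'   zero rows when the ray misses.
#' @export
ray_mesh_intersections <- function(r, mesh) {
  stopifnot(inherits(r, "ray"), inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stopf("mesh has no faces")
  h <- cpp_ray_mesh_hits(r$origin, r$direction, mesh$vertices, mesh$faces - 1L)
  data.frame(t = h[, 1], x = h[, 2], y = h[, 3], z = h[, 4],
             face = as.integer(h[, 5]) + 1L)
}
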