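# Rigid-body transforms between the preoperative image frame and the
# structured-light camera (world) frame. All lengths in millimetres;
# reported angles in degrees, internal angles in radians.

#' Rigid transform
#'
#' A 4x4 homogeneous rigid-body transform (rotation + translation, no scale).
#' The rotation block must be orthonormal with determinant +1 and the bottom
#' row exactly `c(0, 0, 0, 1)`.
#'
#' @param matrix A 4x4 numeric matrix.
#' @param tol Orthonormality tolerance (default `1e-9`).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix, tol = 1e-9) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !all(dim(m) == c(4L, 4L)) || any(!is.finite(m)))
    stopf("a rigid transform must be a finite 4x4 numeric matrix")
  if (!all(m[4, ] == c(0, 0, 0, 1)))
    stopf("bottom row of a rigid transform must be exactly [0,0,0,1]")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stopf("rotation block is not orthonormal (tolerance %g)", tol)
  if (det(R) < 0)
    stopf("rotation block has negative determinant (reflection, not rotation)")
  structure(list(matrix = m), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm):\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity rigid transform
#' @return A `rigid_transform`.
#' @export
rigid_identity <- function() rigid_transform(diag(4))

#' Build a rigid transform from rotation and translation
#'
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation in mm (default zero).
#' @return A `rigid_transform`.
#' @export
rigid_from_rt <- function(R = diag(3), t = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  rigid_transform(m)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n == 0) stopf("rotation axis must be non-zero")
  a <- a / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `rigid_compose(a, b)` applies `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rigid_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$matrix %*% b$matrix, tol = 1e-8)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return A `rigid_transform` such that composing with `t` yields identity.
#' @export
rigid_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- t$matrix[1:3, 1:3]
  tr <- t$matrix[1:3, 4]
  rigid_from_rt(t(R), -crossprod(R, tr))
}

# Apply a rigid transform to an Nx3 coordinate matrix.
apply_rigid <- function(t, pts) {
  pts <- as_xyz(pts)
  if (nrow(pts) == 0L) return(pts)
  R <- t$matrix[1:3, 1:3]
  tr <- t$matrix[1:3, 4]
  sweep(pts %*% t(R), 2, -tr)
}

# Rotate direction vectors only (no translation).
apply_rotation <- function(t, v) {
  v <- as_xyz(v)
  v %*% t(t$matrix[1:3, 1:3])
}

#' Undirected angle between two lines
#'
#' The angle between the lines spanned by `u` and `v`, folded into
#' \[0, 90\] degrees; the sign of either direction vector is irrelevant.
#'
#' @param u,v length-3 direction vectors (need not be unit length).
#' @return Angle in degrees in \[0, 90\].
#' @export
angle_between_lines <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("angle_between_lines: zero direction vector")
  c_ <- abs(sum(u * v)) / (nu * nv)
  acos(min(1, c_)) * 180 / pi
}

#' Serialise a rigid transform to JSON (row-major 16 floats)
#' @param t A `rigid_transform`.
#' @param path Output file path.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(list(matrix = as.vector(t(t$matrix))), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON (row-major 16 floats)
#' @param path Input file path.
#' @return A `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(as.numeric(x$matrix), 4, 4, byrow = TRUE))
}
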