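# Seeded parametric phantom: a rigid multi-vertebra "cervical spine" stand-in
# (capped elliptical-cylinder bodies with bilateral pedicle corridors) under a
# smooth offset "skin" surface mimicking a ~20 mm soft-tissue layer, plus the
# 25 mm drill-sleeve cylinder. Geometry is deliberately analytic, not
# anatomical: accuracy metrics depend only on surfaces and corridor axes.
#
# Image-frame conventions: spine axis along x, lateral along y, posterior
# (toward the camera) along +z.

#' Phantom specification
#'
#' Parameters of the synthetic spine phantom. All lengths in mm.
#'
#' @param seed Integer seed controlling all per-vertebra jitter.
#' @param n_vertebrae Number of vertebrae (default 7).
#' @param body_half_axes Half-axes `c(ax, ay, az)` of a vertebral body:
#'   half-length along the spine and elliptical half-axes laterally /
#'   antero-posteriorly. A single triple is jittered per vertebra; an
#'   `n x 3` matrix fixes each vertebra exactly.
#' @param pedicle_corridor_radius Safe-corridor radius (default 3).
#' @param pedicle_length Axial span of the corridor used for breach grading
#'   (default 24).
#' @param cortical_margin Minimum clearance demanded between the corridor
#'   surface and the bone surface over the central half of the span
#'   (default 1.5).
#' @param skin_offset Soft-tissue layer thickness (default 20).
#' @param inter_vertebra_spacing Gap between adjacent bodies (default 5).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(seed = 1L, n_vertebrae = 7L,
                         body_half_axes = c(9, 25, 20),
                         pedicle_corridor_radius = 3.0,
                         pedicle_length = 24,
                         cortical_margin = 1.5,
                         skin_offset = 20,
                         inter_vertebra_spacing = 5) {
  if (pedicle_corridor_radius <= 1.0)
    stopf("corridor radius must exceed the 1 mm wire radius")
  if (skin_offset <= 0) stopf("skin_offset must be positive")
  if (inter_vertebra_spacing <= 0)
    stopf("inter_vertebra_spacing must be positive (bodies would overlap)")
  if (any(body_half_axes <= 0) || pedicle_length <= 0 || cortical_margin < 0)
    stopf("all phantom dimensions must be positive")
  ha <- if (is.matrix(body_half_axes)) body_half_axes
        else matrix(body_half_axes, n_vertebrae, 3, byrow = TRUE)
  if (nrow(ha) != n_vertebrae || ncol(ha) != 3)
    stopf("body_half_axes must be a triple or an n_vertebrae x 3 matrix")
  structure(list(seed = as.integer(seed), n_vertebrae = as.integer(n_vertebrae),
                 body_half_axes = ha,
                 jitter_half_axes = !is.matrix(body_half_axes),
                 pedicle_corridor_radius = pedicle_corridor_radius,
                 pedicle_length = pedicle_length,
                 cortical_margin = cortical_margin,
                 skin_offset = skin_offset,
                 inter_vertebra_spacing = inter_vertebra_spacing),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %d vertebrae, corridor r=%.1f mm, skin offset %.1f mm, seed %d\n",
              x$n_vertebrae, x$pedicle_corridor_radius, x$skin_offset, x$seed))
  invisible(x)
}

# Per-vertebra derived parameters, deterministic in (seed, index).
vertebra_params <- function(spec, index) {
  with_seed(spec$seed * 1000L + index, {
    ha <- spec$body_half_axes[index, ]
    if (spec$jitter_half_axes) ha <- ha * runif(3, 0.94, 1.06)
    list(half_axes = ha,
         conv_angle_deg = 25 + runif(2, -4, 4),      # left/right convergence
         lateral_frac = 0.30 + runif(2, -0.04, 0.04)) # entry-side lateral offset
  })
}

# Closed lofted surface of an elliptic cylinder along x:
# stations xs, half-axes A(x), B(x), n_theta angular segments.
loft_ellipse_mesh <- function(xs, A, B, n_theta = 48L) {
  m <- length(xs)
  phi <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  V <- do.call(rbind, lapply(seq_len(m), function(j)
    cbind(xs[j], A[j] * cos(phi), B[j] * sin(phi))))
  idx <- function(j, k) (j - 1L) * n_theta + ((k - 1L) %% n_theta) + 1L
  faces <- list()
  for (j in seq_len(m - 1L)) {
    k <- seq_len(n_theta)
    faces[[length(faces) + 1L]] <- cbind(idx(j, k), idx(j + 1L, k), idx(j + 1L, k + 1L))
    faces[[length(faces) + 1L]] <- cbind(idx(j, k), idx(j + 1L, k + 1L), idx(j, k + 1L))
  }
  c0 <- nrow(V) + 1L; c1 <- nrow(V) + 2L
  V <- rbind(V, c(xs[1], 0, 0), c(xs[m], 0, 0))
  k <- seq_len(n_theta)
  faces[[length(faces) + 1L]] <- cbind(c0, idx(1L, k + 1L), idx(1L, k))
  faces[[length(faces) + 1L]] <- cbind(c1, idx(m, k), idx(m, k + 1L))
  ensure_outward(triangle_mesh(V, do.call(rbind, faces), watertight = TRUE))
}

# Flip all faces if the signed volume is negative (normals inward).
ensure_outward <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  a <- V[Fm[, 1], , drop = FALSE]; b <- V[Fm[, 2], , drop = FALSE]
  cc <- V[Fm[, 3], , drop = FALSE]
  vol <- sum(rowSums(a * cross3(b, cc))) / 6
  if (vol < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

mesh_volume <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  a <- V[Fm[, 1], , drop = FALSE]; b <- V[Fm[, 2], , drop = FALSE]
  cc <- V[Fm[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, cc))) / 6
}

#' Is a point inside a watertight mesh?
#'
#' Ray-parity test along a fixed oblique direction.
#'
#' @param p length-3 point (mm).
#' @param mesh A watertight `triangle_mesh`.
#' @return Logical.
#' @export
point_in_mesh <- function(p, mesh) {
  d <- normalize3(c(0.2394875, 0.5830127, 0.7764932))  # oblique, avoids edges
  h <- ray_mesh_intersections(ray(as.numeric(p), d), mesh)
  nrow(h[h$t > 1e-9, , drop = FALSE]) %% 2L == 1L
}

# Distance from an interior 2D point to an ellipse boundary (dense polygon).
ellipse_clearance <- function(y, z, a, b, n = 1440L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  min(sqrt((a * cos(phi) - y)^2 + (b * sin(phi) - z)^2))
}

#' Build one synthetic vertebra and its two pedicle corridors
#'
#' The body is a watertight capped elliptic cylinder centred at the origin
#' (axis along x); bilateral corridors run in its mid cross-section from
#' postero-lateral entry toward an antero-medial exit. Construction fails if
#' a corridor cannot keep `cortical_margin` clearance from the cortex over
#' the central half of its grading span.
#'
#' @param spec A `phantom_spec`.
#' @param index Vertebra index in `1:n_vertebrae`.
#' @param n_theta Angular mesh resolution (default 64).
#' @return List with `mesh` (a `triangle_mesh`) and `corridors`
#'   (list of two corridor definitions, sides `"L"`/`"R"`).
#' @export
make_vertebra <- function(spec, index, n_theta = 64L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$pedicle_corridor_radius <= 0) stopf("corridor radius must be positive")
  p <- vertebra_params(spec, index)
  ax <- p$half_axes[1]; ay <- p$half_axes[2]; az <- p$half_axes[3]
  if (spec$pedicle_corridor_radius >= min(ay, az))
    stopf("corridor radius %.1f exceeds body half-axes", spec$pedicle_corridor_radius)
  mesh <- loft_ellipse_mesh(c(-ax, ax), c(ay, ay), c(az, az), n_theta = n_theta)
  corridors <- lapply(1:2, function(s) {
    sgn <- if (s == 1L) 1 else -1                 # +y = left side
    th <- p$conv_angle_deg[s] * pi / 180
    axis_point <- c(0, sgn * p$lateral_frac[s] * ay, 0)
    axis_dir <- normalize3(c(0, -sgn * sin(th), -cos(th)))  # tip-ward: posterior -> anterior
    half <- spec$pedicle_length / 2
    for (t in seq(-half / 2, half / 2, length.out = 9)) {   # central half of span
      q <- axis_point + t * axis_dir
      cl <- ellipse_clearance(q[2], q[3], ay, az)
      if (cl < spec$pedicle_corridor_radius + spec$cortical_margin)
        stopf("corridor %s of vertebra %d too close to cortex (clearance %.2f mm)",
              c("L", "R")[s], index, cl)
    }
    list(vertebra = index, side = c("L", "R")[s],
         axis_point = axis_point, axis_dir = axis_dir,
         radius = spec$pedicle_corridor_radius, span = spec$pedicle_length)
  })
  list(mesh = mesh, corridors = corridors)
}

#' Assemble the full phantom scene
#'
#' Stacks `n_vertebrae` bodies along x with the configured spacing, wraps
#' them in a smooth watertight offset "skin" (elliptic loft with gentle
#' axial modulation so registration is well-posed), attaches ground-truth
#' planned trajectories coaxial with every corridor, and designates
#' landmark points on the posterior skin surface for rough registration.
#'
#' @param spec A `phantom_spec`.
#' @param n_theta_bone,n_theta_skin Angular mesh resolutions.
#' @return A `phantom_scene`: `skin`, `bones`, `corridors`,
#'   `truth_trajectories`, `landmarks`, `frame = "image"`.
#' @export
make_scene <- function(spec, n_theta_bone = 64L, n_theta_skin = 48L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_vertebrae
  parts <- lapply(seq_len(n), make_vertebra, spec = spec, n_theta = n_theta_bone)
  axs <- vapply(seq_len(n), function(i) vertebra_params(spec, i)$half_axes[1], 0)
  # centre positions along x: consecutive bodies separated by the spacing
  gaps <- spec$inter_vertebra_spacing
  centers <- numeric(n)
  for (i in seq_len(n)[-1])
    centers[i] <- centers[i - 1] + axs[i - 1] + gaps + axs[i]
  centers <- centers - (min(centers - axs) + max(centers + axs)) / 2
  bones <- vector("list", n); corridors <- list(); truth <- list()
  for (i in seq_len(n)) {
    sh <- rigid_from_rt(t = c(centers[i], 0, 0))
    bones[[i]] <- transform_mesh(sh, parts[[i]]$mesh)
    for (cor in parts[[i]]$corridors) {
      cor$axis_point <- cor$axis_point + c(centers[i], 0, 0)
      corridors[[length(corridors) + 1L]] <- cor
      entry_lead <- 80   # channel origin sits well above the skin
      truth[[length(truth) + 1L]] <-
        channel(origin = cor$axis_point - entry_lead * cor$axis_dir,
                direction = cor$axis_dir, radius = 1.0, length = 300,
                label = sprintf("V%d%s", cor$vertebra, cor$side))
    }
  }
  ay_max <- max(vapply(seq_len(n), function(i) vertebra_params(spec, i)$half_axes[2], 0))
  az_max <- max(vapply(seq_len(n), function(i) vertebra_params(spec, i)$half_axes[3], 0))
  x_lo <- min(centers - axs) - spec$skin_offset
  x_hi <- max(centers + axs) + spec$skin_offset
  xs <- seq(x_lo, x_hi, length.out = 33L)
  wob <- function(x, ph) 1 + 0.12 * (1 + sin(2 * pi * (x - x_lo) / (x_hi - x_lo) * 1.5 + ph)) / 2
  A <- (ay_max + spec$skin_offset + 1.5) * wob(xs, 0.3)
  B <- (az_max + spec$skin_offset + 1.5) * wob(xs, 2.1)
  skin <- loft_ellipse_mesh(xs, A, B, n_theta = n_theta_skin)
  # landmarks: posterior-surface skin vertices spread along x, alternating
  # left/right of the midline so the landmark set is well-conditioned
  lv <- skin$vertices
  pick_x <- seq(x_lo + 15, x_hi - 15, length.out = 6L)
  landmarks <- t(vapply(seq_along(pick_x), function(k) {
    phi_t <- pi / 2 + (if (k %% 2L == 0L) 0.6 else -0.6)
    target <- c(pick_x[k], mean(A) * cos(phi_t), mean(B) * sin(phi_t))
    cand <- lv[lv[, 3] > 0, , drop = FALSE]
    cand[which.min(colSums((t(cand) - target)^2)), ]
  }, numeric(3)))
  structure(list(skin = skin, bones = bones, corridors = corridors,
                 truth_trajectories = truth, landmarks = landmarks,
                 spec = spec, frame = "image"),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("Phantom scene (%s frame): %d bones, %d corridors, %d planned trajectories\n",
              x$frame, length(x$bones), length(x$corridors),
              length(x$truth_trajectories)))
  invisible(x)
}

#' Drill-sleeve mesh
#'
#' The navigation drill sleeve: an aluminium tube of outer diameter 25 mm
#' and length 200 mm. Only the scannable outer surface is modelled (closed
#' with end caps); the 6.05 mm bore is invisible to the camera. In the pose
#' frame the axis is +z with the tail at the origin.
#'
#' @param pose A `rigid_transform` placing the sleeve in its scene.
#' @param n_theta Angular resolution (default 96).
#' @return A watertight `triangle_mesh`.
#' @export
make_drill_sleeve <- function(pose = rigid_identity(), n_theta = 96L) {
  stopifnot(inherits(pose, "rigid_transform"))
  r <- 12.5; len <- 200
  m <- loft_ellipse_mesh(c(0, len), c(r, r), c(r, r), n_theta = n_theta)
  # loft builds along x; swap to +z axis
  to_z <- rigid_from_rt(R = matrix(c(0, 0, 1,  0, 1, 0,  -1, 0, 0), 3, 3), t = c(0, 0, 0))
  transform_mesh(pose, transform_mesh(to_z, m))
}

#' Export a phantom scene to STL files plus a JSON manifest
#'
#' @param scene A `phantom_scene`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
export_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(scene$skin, file.path(dir, "skin.stl"))
  for (i in seq_along(scene$bones))
    write_mesh(scene$bones[[i]], file.path(dir, sprintf("bone_%02d.stl", i)))
  manifest <- list(
    frame = scene$frame,
    corridors = lapply(scene$corridors, function(cr)
      list(vertebra = cr$vertebra, side = cr$side,
           axis_point = cr$axis_point, axis_dir = cr$axis_dir,
           radius = cr$radius, span = cr$span)),
    truth_trajectories = lapply(scene$truth_trajectories, unclass),
    landmarks = scene$landmarks)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
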