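# Simulated structured-light camera: pinhole perspective grid of rays,
# first-hit visibility, working-range and grazing-incidence culling,
# Gaussian depth noise along the viewing ray, and uniform box outliers.

#' Structured-light camera model
#'
#' Pinhole camera whose frustum half-angles derive from the reference field
#' of view at the reference standoff (800 x 605.8 mm at 1500 mm). The
#' camera looks along its own +z axis; `pose` places it in the world frame.
#'
#' @param pose Camera-in-world `rigid_transform`.
#' @param fov_mm Reference field of view `c(width, height)` in mm.
#' @param fov_standoff_mm Standoff at which `fov_mm` applies (default 1500).
#' @param working_range Valid depth range in mm (default `c(900, 2900)`).
#' @param grid Sample resolution `c(rows, cols)` (default `c(150, 200)`).
#' @param max_incidence_deg Grazing-angle cutoff in degrees (default 80).
#' @return A `camera_model`.
#' @export
camera_model <- function(pose = rigid_identity(),
                         fov_mm = c(800, 605.8), fov_standoff_mm = 1500,
                         working_range = c(900, 2900),
                         grid = c(150L, 200L), max_incidence_deg = 80) {
  stopifnot(inherits(pose, "rigid_transform"))
  if (any(grid < 1)) stopf("camera grid dimensions must be positive")
  if (working_range[1] <= 0 || working_range[2] <= working_range[1])
    stopf("invalid working range")
  structure(list(pose = pose, fov_mm = fov_mm, fov_standoff_mm = fov_standoff_mm,
                 working_range = working_range, grid = as.integer(grid),
                 max_incidence_deg = max_incidence_deg),
            class = "camera_model")
}

#' Place a camera looking at a target point
#'
#' @param position Camera centre in world (mm).
#' @param target Point the optical axis passes through.
#' @param up Approximate up direction used to fix roll.
#' @param ... Passed on to [camera_model()].
#' @return A `camera_model`.
#' @export
camera_look_at <- function(position, target, up = c(1, 0, 0), ...) {
  z <- normalize3(as.numeric(target) - as.numeric(position))
  x <- normalize3(cross3(matrix(up, 1), matrix(z, 1))[1, ])
  y <- cross3(matrix(z, 1), matrix(x, 1))[1, ]
  camera_model(pose = rigid_from_rt(R = cbind(x, y, z), t = position), ...)
}

#' Depth-noise and outlier configuration
#'
#' @param depth_sigma Gaussian noise sd along the viewing ray (mm).
#' @param outlier_fraction Fraction of scan points appended as outliers.
#' @param outlier_box Edge lengths of the box outliers are drawn in (mm).
#' @param seed Integer seed for all scan randomness.
#' @return A `noise_config`.
#' @export
noise_config <- function(depth_sigma = 0, outlier_fraction = 0,
                         outlier_box = c(400, 400, 400), seed = 1L) {
  if (depth_sigma < 0) stopf("depth_sigma must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stopf("outlier_fraction must lie in [0, 1]")
  structure(list(depth_sigma = depth_sigma, outlier_fraction = outlier_fraction,
                 outlier_box = outlier_box, seed = as.integer(seed)),
            class = "noise_config")
}

# Unit ray directions of the pixel grid, in world coordinates.
camera_rays <- function(camera) {
  tanx <- (camera$fov_mm[1] / 2) / camera$fov_standoff_mm
  tany <- (camera$fov_mm[2] / 2) / camera$fov_standoff_mm
  rows <- camera$grid[1]; cols <- camera$grid[2]
  u <- if (cols > 1) seq(-tanx, tanx, length.out = cols) else 0
  v <- if (rows > 1) seq(-tany, tany, length.out = rows) else 0
  g <- expand.grid(u = u, v = v)
  d <- cbind(g$u, g$v, 1)
  d <- d / sqrt(rowSums(d^2))
  apply_rotation(camera$pose, d)
}

#' Simulate a structured-light scan
#'
#' Casts one ray per grid sample from the camera centre; keeps only the
#' first surface hit (hidden surfaces excluded), drops hits outside the
#' working range or beyond the grazing-angle cutoff, and perturbs each
#' surviving depth with Gaussian noise along the ray. Point labels name the
#' source mesh; normals are the hit facet normals oriented toward the
#' camera. Deterministic given `noise$seed`.
#'
#' @param meshes Named list of `triangle_mesh` objects in world frame.
#' @param camera A `camera_model`.
#' @param noise A `noise_config`.
#' @return A `scan_result` with fields `cloud`, `noise`, `camera`,
#'   `empty` (warning flag).
#' @export
simulate_scan <- function(meshes, camera, noise = noise_config()) {
  stopifnot(inherits(camera, "camera_model"), inherits(noise, "noise_config"))
  if (!length(meshes)) stopf("no meshes to scan")
  if (is.null(names(meshes)) || any(names(meshes) == ""))
    stopf("meshes must be a named list")
  dirs <- camera_rays(camera)
  orig <- camera$pose$matrix[1:3, 4]
  nr <- nrow(dirs)
  best_t <- rep(Inf, nr); best_mesh <- rep(NA_integer_, nr); best_face <- rep(NA_integer_, nr)
  for (mi in seq_along(meshes)) {
    h <- cpp_first_hits(orig, dirs, meshes[[mi]]$vertices, meshes[[mi]]$faces - 1L)
    better <- !is.na(h[, 1]) & h[, 1] < best_t
    best_t[better] <- h[better, 1]
    best_mesh[better] <- mi
    best_face[better] <- as.integer(h[better, 2]) + 1L
  }
  keep <- is.finite(best_t) &
    best_t >= camera$working_range[1] & best_t <= camera$working_range[2]
  # grazing-incidence cutoff against the hit facet normal
  if (any(keep)) {
    idx <- which(keep)
    nrm <- matrix(0, length(idx), 3)
    for (mi in unique(best_mesh[idx])) {
      sel <- best_mesh[idx] == mi
      fn <- face_normals(meshes[[mi]])
      nrm[sel, ] <- fn[best_face[idx][sel], , drop = FALSE]
    }
    cosi <- abs(rowSums(dirs[idx, , drop = FALSE] * nrm))
    ok <- acos(pmin(1, cosi)) * 180 / pi <= camera$max_incidence_deg
    keep[idx[!ok]] <- FALSE
    idx <- idx[ok]; nrm <- nrm[ok, , drop = FALSE]
  } else idx <- integer(0)
  if (!length(idx)) {
    return(structure(list(cloud = point_cloud(), noise = noise, camera = camera,
                          empty = TRUE), class = "scan_result"))
  }
  depth <- best_t[idx]
  depth <- with_seed(noise$seed,
                     depth + if (noise$depth_sigma > 0)
                       rnorm(length(idx), 0, noise$depth_sigma) else 0)
  pts <- sweep(dirs[idx, , drop = FALSE] * depth, 2, orig, `+`)
  # orient facet normals toward the camera
  flip <- rowSums(nrm * dirs[idx, , drop = FALSE]) > 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cloud <- point_cloud(pts, labels = names(meshes)[best_mesh[idx]], normals = nrm)
  structure(list(cloud = cloud, noise = noise, camera = camera, empty = FALSE),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan result: %d points (sigma %.3g mm%s)\n", n_points(x$cloud),
              x$noise$depth_sigma, if (x$empty) ", EMPTY" else ""))
  invisible(x)
}

#' Append uniform box outliers to a scan
#'
#' Appends `floor(outlier_fraction * N)` points drawn uniformly in the
#' configured outlier box centred on the scan centroid, labelled
#' `"outlier"`. Seeded by `noise$seed`.
#'
#' @param scan A `scan_result`.
#' @return The augmented `scan_result`.
#' @export
add_outliers <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  frac <- scan$noise$outlier_fraction
  n <- n_points(scan$cloud)
  m <- floor(frac * n)
  if (m == 0) return(scan)
  ctr <- colMeans(scan$cloud$points)
  box <- scan$noise$outlier_box
  pts <- with_seed(scan$noise$seed + 7919L,
                   sweep(matrix(runif(3 * m, -0.5, 0.5), m, 3) %*% diag(box), 2, ctr, `+`))
  labs <- c(scan$cloud$labels %||% rep("scan", n), rep("outlier", m))
  nrm <- scan$cloud$normals
  if (!is.null(nrm)) {
    # outliers carry a placeholder normal pointing back at the camera
    back <- -apply_rotation(scan$camera$pose, matrix(c(0, 0, 1), 1))
    nrm <- rbind(nrm, matrix(back, m, 3, byrow = TRUE))
  }
  scan$cloud <- point_cloud(rbind(scan$cloud$points, pts), labels = labs, normals = nrm)
  scan
}
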