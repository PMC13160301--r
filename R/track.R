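# Channel planning on the navigational map, fixed-radius RANSAC cylinder
# fitting of the scanned drill sleeve, navigation-channel generation, and
# guidance offsets driving the virtual gimbal alignment.

#' Planned or navigation channel
#'
#' A cylinder with an entry-end axis point, unit direction (tip-ward, i.e.
#' pointing in the insertion direction), radius and length.
#'
#' @param origin Entry-end axis point (mm).
#' @param direction Direction vector (normalised internally).
#' @param radius Radius in mm (planned channels default to 1).
#' @param length Length in mm (planned channels default to 300).
#' @param label Identifier such as `"V3L"`.
#' @param frame Coordinate frame tag, `"image"` or `"world"`.
#' @return A `channel` object.
#' @export
channel <- function(origin, direction, radius = 1.0, length = 300.0,
                    label = "", frame = "image") {
  if (radius <= 0 || length <= 0) stopf("channel radius and length must be positive")
  structure(list(origin = as.numeric(origin), direction = normalize3(direction),
                 radius = radius, length = length, label = label, frame = frame),
            class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("Channel %s (%s): r %.2f mm x %.0f mm at (%.2f, %.2f, %.2f), dir (%.3f, %.3f, %.3f)\n",
              x$label, x$frame, x$radius, x$length,
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

transform_channel <- function(t, ch) {
  ch$origin <- as.numeric(apply_rigid(t, matrix(ch$origin, 1)))
  ch$direction <- as.numeric(apply_rotation(t, matrix(ch$direction, 1)))
  ch$frame <- if (ch$frame == "image") "world" else ch$frame
  ch
}

#' Navigational map
#'
#' The bundled preoperative model: skin surface mesh, bone meshes and the
#' planned channels, all sharing one frame tag and moved as one rigid body.
#'
#' @param skin A `triangle_mesh`.
#' @param bones List of `triangle_mesh`.
#' @param channels List of `channel`.
#' @param frame `"image"` (preoperative) or `"world"` (camera space).
#' @return A `nav_map`.
#' @export
nav_map <- function(skin, bones = list(), channels = list(), frame = "image") {
  stopifnot(inherits(skin, "triangle_mesh"))
  frame <- match.arg(frame, c("image", "world"))
  structure(list(skin = skin, bones = bones, channels = channels, frame = frame),
            class = "nav_map")
}

#' @export
print.nav_map <- function(x, ...) {
  cat(sprintf("Navigational map (%s frame): skin + %d bones, %d channels\n",
              x$frame, length(x$bones), length(x$channels)))
  invisible(x)
}

#' Add a planned channel to the navigational map
#'
#' The channel axis is the z-axis of `pose`; cloning an existing channel
#' under a new pose reuses its radius and length.
#'
#' @param map A `nav_map` in the image frame.
#' @param pose A `rigid_transform`; origin = entry-end axis point, z-axis =
#'   insertion direction.
#' @param radius Channel radius in mm (default 1).
#' @param length Channel length in mm (default 300).
#' @param label Channel label.
#' @return The map with the channel appended.
#' @export
add_channel <- function(map, pose, radius = 1.0, length = 300.0, label = "") {
  stopifnot(inherits(map, "nav_map"), inherits(pose, "rigid_transform"))
  if (map$frame != "image") stopf("channels are planned in the image frame")
  ch <- channel(origin = pose$matrix[1:3, 4],
                direction = pose$matrix[1:3, 3],
                radius = radius, length = length, label = label,
                frame = "image")
  map$channels <- c(map$channels, list(ch))
  map
}

# Perpendicular foot of point p on the line (a, d); returns the foot point.
line_foot <- function(p, a, d) a + sum((p - a) * d) * d

#' Fit a fixed-radius cylinder to a partial sleeve scan
#'
#' RANSAC over two-point-plus-normal axis hypotheses followed by nonlinear
#' least-squares refinement of the 4-DOF axis with the radius held at the
#' known instrument radius (free-radius mode adds the radius as a fifth
#' parameter for diagnostics). Points with absolute radial residual below
#' `inlier_threshold` are inliers. Insufficient points or angular coverage
#' below `min_arc_deg` yields a fit-failure signal, not an error.
#'
#' @param cloud A `point_cloud` of sleeve-surface points (world frame).
#'   Estimated normals are computed by local PCA when absent.
#' @param fixed_radius Known cylinder radius in mm (default 12.5).
#' @param inlier_threshold Inlier residual bound in mm (default 0.3).
#' @param min_arc_deg Minimum angular coverage of inliers (default 90).
#' @param min_points Minimum usable point count (default 50).
#' @param max_hypotheses RANSAC hypothesis budget (default 200).
#' @param free_radius Also estimate the radius (default FALSE).
#' @param seed RNG seed making the fit deterministic.
#' @return A `cylinder_fit` (`axis_point`, `axis_direction`, `radius`,
#'   `inlier_rms`, `inlier_count`, `arc_coverage_deg`) or a
#'   `cylinder_fit_failure` with a `reason`.
#' @export
fit_cylinder <- function(cloud, fixed_radius = 12.5, inlier_threshold = 0.3,
                         min_arc_deg = 90, min_points = 50L,
                         max_hypotheses = 200L, free_radius = FALSE, seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$points
  if (nrow(P) < min_points)
    return(fit_failure(sprintf("only %d points (need >= %d)", nrow(P), min_points)))
  N <- cloud$normals %||% estimate_normals(P)
  r0 <- fixed_radius
  radial <- function(a, d) {
    w <- sweep(P, 2, a)
    proj <- w - outer(as.numeric(w %*% d), d)
    sqrt(rowSums(proj^2))
  }
  best <- NULL
  with_seed(seed, {
    for (h in seq_len(max_hypotheses)) {
      ij <- sample.int(nrow(P), 2L)
      n1 <- N[ij[1], ]; n2 <- N[ij[2], ]
      d <- cross3(matrix(n1, 1), matrix(n2, 1))[1, ]
      nd <- sqrt(sum(d^2))
      if (nd < 0.05) next
      d <- d / nd
      for (sgn in c(-1, 1)) {          # PCA normals have arbitrary sign
        a <- P[ij[1], ] + sgn * r0 * n1
        res <- abs(radial(a, d) - r0)
        ninl <- sum(res < inlier_threshold)
        if (is.null(best) || ninl > best$ninl)
          best <- list(a = a, d = d, ninl = ninl)
      }
    }
  })
  if (is.null(best) || best$ninl < min_points)
    return(fit_failure("no RANSAC hypothesis reached the minimum inlier count"))
  # refine the 4-DOF axis (plus radius if free) by Levenberg-Marquardt
  d0 <- best$d
  e <- orthobasis(d0)
  inl <- abs(radial(best$a, d0) - r0) < inlier_threshold
  Pi <- P[inl, , drop = FALSE]
  resid_fun <- function(par) {
    a <- best$a + par[1] * e$u + par[2] * e$v
    d <- normalize3(d0 + par[3] * e$u + par[4] * e$v)
    r <- if (free_radius) par[5] else r0
    w <- sweep(Pi, 2, a)
    proj <- w - outer(as.numeric(w %*% d), d)
    sqrt(rowSums(proj^2)) - r
  }
  par0 <- c(0, 0, 0, 0, if (free_radius) r0)
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  par <- fit$par
  a <- best$a + par[1] * e$u + par[2] * e$v
  d <- normalize3(d0 + par[3] * e$u + par[4] * e$v)
  r <- if (free_radius) par[5] else r0
  res <- radial(a, d) - r
  inl <- abs(res) < inlier_threshold
  if (sum(inl) < min_points)
    return(fit_failure("refined fit keeps too few inliers"))
  Pi <- P[inl, , drop = FALSE]
  a <- as.numeric(line_foot(colMeans(Pi), a, d))   # anchor near the data
  cover <- arc_coverage(Pi, a, d, e)
  if (cover < min_arc_deg)
    return(fit_failure(sprintf("angular coverage %.1f deg below minimum %.1f",
                               cover, min_arc_deg)))
  structure(list(axis_point = a, axis_direction = d, radius = r,
                 inlier_rms = sqrt(mean(res[inl]^2)), inlier_count = sum(inl),
                 arc_coverage_deg = cover, fixed_radius = !free_radius),
            class = "cylinder_fit")
}

fit_failure <- function(reason) structure(list(reason = reason),
                                          class = "cylinder_fit_failure")

#' Did a cylinder fit fail?
#' @param x Result of [fit_cylinder()].
#' @return Logical.
#' @export
is_fit_failure <- function(x) inherits(x, "cylinder_fit_failure")

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("Cylinder fit: r %.2f mm, axis (%.2f, %.2f, %.2f) dir (%.4f, %.4f, %.4f)\n",
              x$radius, x$axis_point[1], x$axis_point[2], x$axis_point[3],
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  cat(sprintf("  %d inliers, RMS %.4g mm, arc coverage %.0f deg\n",
              x$inlier_count, x$inlier_rms, x$arc_coverage_deg))
  invisible(x)
}

#' @export
print.cylinder_fit_failure <- function(x, ...) {
  cat("Cylinder fit FAILED:", x$reason, "\n")
  invisible(x)
}

# Orthonormal basis perpendicular to unit vector d.
orthobasis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize3(cross3(matrix(d, 1), matrix(ref, 1))[1, ])
  v <- cross3(matrix(d, 1), matrix(u, 1))[1, ]
  list(u = u, v = v)
}

# Observed angular coverage (deg) of points around an axis: 360 minus the
# largest angular gap.
arc_coverage <- function(P, a, d, e = orthobasis(d)) {
  w <- sweep(P, 2, a)
  ang <- sort(atan2(as.numeric(w %*% e$v), as.numeric(w %*% e$u)))
  if (length(ang) < 2) return(0)
  gaps <- c(diff(ang), 2 * pi - (ang[length(ang)] - ang[1]))
  (2 * pi - max(gaps)) * 180 / pi
}

#' Navigation channel from a cylinder fit
#'
#' A channel coaxial with the fitted sleeve axis (default 2 mm diameter,
#' 800 mm length). When `camera` is supplied the direction is oriented
#' tip-ward, i.e. with positive component along the camera viewing axis.
#'
#' @param fit A `cylinder_fit`.
#' @param diameter Channel diameter in mm (default 2).
#' @param length Channel length in mm (default 800).
#' @param camera Optional `camera_model` fixing the direction sign.
#' @param label Channel label.
#' @return A `channel` in the world frame.
#' @export
channel_from_fit <- function(fit, diameter = 2.0, length = 800.0,
                             camera = NULL, label = "nav") {
  if (is_fit_failure(fit)) stopf("cannot build a channel from a failed fit: %s", fit$reason)
  d <- fit$axis_direction
  if (!is.null(camera)) {
    fwd <- as.numeric(apply_rotation(camera$pose, matrix(c(0, 0, 1), 1)))
    if (sum(d * fwd) < 0) d <- -d
  }
  channel(origin = fit$axis_point, direction = d, radius = diameter / 2,
          length = length, label = label, frame = "world")
}

#' Guidance offset between planned and current channel
#'
#' @param planned,current `channel` objects in the same frame.
#' @return Named numeric: `entry_translation_mm` (perpendicular distance of
#'   the planned origin from the current axis) and `angle_deg`
#'   (undirected axis angle).
#' @export
guidance_offset <- function(planned, current) {
  stopifnot(inherits(planned, "channel"), inherits(current, "channel"))
  if (planned$frame != current$frame)
    stopf("guidance_offset: channels are in different frames (%s vs %s)",
          planned$frame, current$frame)
  foot <- line_foot(planned$origin, current$origin, current$direction)
  c(entry_translation_mm = sqrt(sum((planned$origin - foot)^2)),
    angle_deg = angle_between_lines(planned$direction, current$direction))
}

#' Iteratively align a channel to the plan
#'
#' In-silico stand-in for the manual gimbal-and-rod adjustment: repeatedly
#' applies the guidance correction (a fraction `gain` of the full
#' translation and rotation) until both tolerances are met.
#'
#' @param planned Target `channel`.
#' @param start Starting `channel` (same frame).
#' @param tolerance_mm,tolerance_deg Stopping tolerances (> 0).
#' @param gain Fraction of the correction applied per iteration (default 1).
#' @param max_iterations Safety cap (default 100).
#' @return The aligned `channel`, with an attribute `trace`: a data.frame
#'   of per-iteration offsets.
#' @export
simulate_alignment <- function(planned, start, tolerance_mm = 1e-6,
                               tolerance_deg = 1e-6, gain = 1,
                               max_iterations = 100L) {
  if (tolerance_mm <= 0 || tolerance_deg <= 0) stopf("tolerances must be positive")
  cur <- start
  trace <- list()
  it <- 0L
  repeat {
    off <- guidance_offset(planned, cur)
    trace[[length(trace) + 1L]] <- data.frame(iteration = it,
                                              entry_translation_mm = off[[1]],
                                              angle_deg = off[[2]])
    if ((off[[1]] <= tolerance_mm && off[[2]] <= tolerance_deg) || it >= max_iterations)
      break
    it <- it + 1L
    # translate so the axis passes closer to the planned origin
    foot <- line_foot(planned$origin, cur$origin, cur$direction)
    cur$origin <- cur$origin + gain * (planned$origin - foot)
    # rotate the direction toward the planned axis
    tgt <- if (sum(planned$direction * cur$direction) < 0) -planned$direction
           else planned$direction
    cur$direction <- normalize3(cur$direction + gain * (tgt - cur$direction))
  }
  attr(cur, "trace") <- do.call(rbind, trace)
  cur
}

# Unoriented surface normals by local PCA over k nearest neighbours.
estimate_normals <- function(P, k = 12L) {
  k <- min(k, nrow(P) - 1L)
  idx <- cpp_knn_indices(P, as.integer(k)) + 1L
  t(vapply(seq_len(nrow(P)), function(i) {
    nb <- P[c(i, idx[i, ]), , drop = FALSE]
    ev <- eigen(stats::cov(nb), symmetric = TRUE)
    ev$vectors[, 3]
  }, numeric(3)))
}
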