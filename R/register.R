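# Registration stack: landmark rough alignment (least-squares rigid,
# Kabsch/Umeyama without scale), statistical outlier removal, ICP fine
# registration against the surface model, cloud-to-mesh registration
# accuracy, and inverse-transform motion of the navigational map.

#' Ordered landmark correspondences
#'
#' At least four equivalent point pairs picked on the scan (`source`) and
#' on the preoperative model (`target`).
#'
#' @param source_points,target_points K x 3 matrices (mm), row i of one
#'   corresponding to row i of the other.
#' @return A `landmark_pairs` object.
#' @export
landmark_pairs <- function(source_points, target_points) {
  s <- as_xyz(source_points); t <- as_xyz(target_points)
  if (nrow(s) != nrow(t)) stopf("source and target landmark counts differ")
  if (nrow(s) < 4L)
    stopf("rough registration needs at least 4 equivalent point pairs (got %d)", nrow(s))
  if (anyDuplicated(s) || anyDuplicated(t))
    stopf("duplicate landmark points")
  for (m in list(s, t)) {
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2] < 1e-9 * max(sv[1], 1))
      stopf("landmarks are collinear; rigid alignment is rank-deficient")
  }
  structure(list(source_points = s, target_points = t), class = "landmark_pairs")
}

# One linearised point-to-plane update: minimise sum over correspondences of
# (n_i . (R p_i + t - q_i))^2 with R ~ I + [omega]x, then re-orthonormalise
# by the exponential map. Standard fine-registration update against a surface.
point_to_plane_update <- function(P, Q, N) {
  A <- cbind(cross3(P, N), N)
  b <- -rowSums(N * (P - Q))
  x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                error = function(e) qr.solve(A, b))
  omega <- x[1:3]
  ang <- sqrt(sum(omega^2))
  R <- if (ang < 1e-14) diag(3) else rotation_about_axis(omega, ang * 180 / pi)
  rigid_from_rt(R = R, t = x[4:6])
}

# Least-squares rigid transform mapping P onto Q (row correspondence).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_from_rt(R = R, t = cq - R %*% cp)
}

#' Rough registration from landmark pairs
#'
#' The least-squares rigid transform (rotation + translation, no scaling)
#' minimising the sum of squared landmark mismatches.
#'
#' @param pairs A `landmark_pairs` object.
#' @return A `rigid_transform` mapping scan coordinates into the model frame.
#' @export
rough_register <- function(pairs) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  kabsch(pairs$source_points, pairs$target_points)
}

#' Statistical outlier removal
#'
#' Removes points whose mean distance to their `k` nearest neighbours
#' exceeds the global mean of that statistic by more than
#' `sigma_multiplier` standard deviations. Survivor order is preserved.
#'
#' @param cloud A `point_cloud`.
#' @param k_neighbors Neighbourhood size (default 6).
#' @param sigma_multiplier Threshold multiplier (default 1.0).
#' @return The filtered `point_cloud`.
#' @export
sor_filter <- function(cloud, k_neighbors = 6L, sigma_multiplier = 1.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n <= k_neighbors) {
    warning("SOR: cloud has too few points; returned unchanged")
    return(cloud)
  }
  md <- cpp_knn_mean_dist(cloud$points, as.integer(k_neighbors))
  # absolute epsilon so exactly-tied statistics are not split by fp noise
  thr <- mean(md) + sigma_multiplier * sd(md) + 1e-9
  cloud_subset(cloud, which(md <= thr))
}

#' Fine registration by iterated closest points
#'
#' Starting from an already rough-aligned pose, alternates closest-point
#' correspondence (point to nearest surface point when the target is a
#' mesh) with a least-squares rigid update until the RMS change falls
#' below `tol` or `max_iterations` is reached. The reported RMS is the
#' root-mean-square correspondence distance over *all* source points at
#' the final pose; iterations may run on an evenly-spaced subsample of at
#' most `max_correspondences` points.
#'
#' @param source A `point_cloud` (scan, typically SOR-filtered).
#' @param target A `triangle_mesh` or `point_cloud` reference.
#' @param init Initial `rigid_transform` (the rough registration).
#' @param max_iterations Iteration cap (default 100).
#' @param tol RMS-change convergence threshold in mm (default 1e-6).
#' @param max_correspondences Subsample cap for the iterations (default 5000).
#' @return A `registration_result`: `transform` (composed with `init`),
#'   `rms`, `iterations`, `converged`, `correspondence_count`.
#' @export
icp_refine <- function(source, target, init = rigid_identity(),
                       max_iterations = 100L, tol = 1e-6,
                       max_correspondences = 5000L) {
  stopifnot(inherits(source, "point_cloud"), inherits(init, "rigid_transform"))
  n <- n_points(source)
  if (n == 0L) stopf("ICP: empty source cloud")
  is_mesh <- inherits(target, "triangle_mesh")
  if (!is_mesh && !inherits(target, "point_cloud"))
    stopf("ICP target must be a triangle_mesh or point_cloud")
  tnormals <- if (is_mesh) face_normals(target)
  closest <- function(P) {
    if (is_mesh) {
      h <- cpp_closest_mesh(P, target$vertices, target$faces - 1L)
      list(d = h[, 1], q = h[, 2:4, drop = FALSE],
           n = tnormals[h[, 5] + 1, , drop = FALSE])
    } else {
      h <- cpp_nn_cloud(P, target$points)
      list(d = h[, 1], q = target$points[h[, 2] + 1, , drop = FALSE])
    }
  }
  sub <- if (n > max_correspondences)
    unique(round(seq(1L, n, length.out = max_correspondences))) else seq_len(n)
  P0 <- source$points[sub, , drop = FALSE]
  trans <- init
  rms_prev <- Inf; it <- 0L; converged <- FALSE
  while (it < max_iterations) {
    it <- it + 1L
    P <- apply_rigid(trans, P0)
    cp <- closest(P)
    rms <- sqrt(mean(cp$d^2))
    if (abs(rms_prev - rms) < tol) { converged <- TRUE; rms_prev <- rms; break }
    rms_prev <- rms
    upd <- if (is_mesh) point_to_plane_update(P, cp$q, cp$n) else kabsch(P, cp$q)
    trans <- rigid_compose(upd, trans)
  }
  d_all <- closest(apply_rigid(trans, source$points))$d
  structure(list(transform = trans, rms = sqrt(mean(d_all^2)),
                 iterations = it, converged = converged,
                 correspondence_count = n),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("ICP registration: RMS %.6g mm after %d iteration%s (%sconverged, %d points)\n",
              x$rms, x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "" else "NOT ", x$correspondence_count))
  invisible(x)
}

#' @export
summary.registration_result <- function(object, ...) {
  cat("Fine registration result\n")
  print(object)
  print(object$transform)
  invisible(object)
}

#' Cloud-to-mesh distance report
#'
#' Unsigned distance from every point to its nearest mesh triangle. The
#' mean is the registration-accuracy scalar reported by the pipeline.
#'
#' @param cloud A non-empty `point_cloud`.
#' @param mesh A non-empty `triangle_mesh`.
#' @param keep_per_point Keep the per-point distance vector (default TRUE).
#' @return A `distance_report`: `mean_distance`, `max_distance`, `per_point`.
#' @export
cloud_to_mesh_distance <- function(cloud, mesh, keep_per_point = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(mesh, "triangle_mesh"))
  if (n_points(cloud) == 0L) stopf("empty cloud")
  if (nrow(mesh$faces) == 0L) stopf("empty mesh")
  d <- cpp_closest_mesh(cloud$points, mesh$vertices, mesh$faces - 1L)[, 1]
  structure(list(mean_distance = mean(d), max_distance = max(d),
                 per_point = if (keep_per_point) d),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("Cloud/mesh distance: mean %.6g mm, max %.6g mm\n",
              x$mean_distance, x$max_distance))
  invisible(x)
}

#' Move the navigational map into the camera (world) frame
#'
#' Applies the *inverse* of the scan-to-model registration to every mesh
#' and channel of the map, flipping its frame tag from `"image"` to
#' `"world"`. Rigid relations inside the map are preserved.
#'
#' @param map A `nav_map` in the image frame.
#' @param reg A `registration_result` whose transform maps scan -> model.
#' @return The map in the world frame.
#' @export
register_map <- function(map, reg) {
  stopifnot(inherits(map, "nav_map"), inherits(reg, "registration_result"))
  if (map$frame == "world")
    stopf("navigational map is already in the world frame (double application)")
  inv <- rigid_invert(reg$transform)
  map$skin <- transform_mesh(inv, map$skin)
  map$bones <- lapply(map$bones, transform_mesh, t = inv)
  map$channels <- lapply(map$channels, transform_channel, t = inv)
  map$frame <- "world"
  map
}

#' Write landmark pairs to CSV (sx,sy,sz,tx,ty,tz)
#' @param pairs A `landmark_pairs`.
#' @param path Output path.
#' @export
write_landmarks_csv <- function(pairs, path) {
  df <- data.frame(pairs$source_points, pairs$target_points)
  names(df) <- c("sx", "sy", "sz", "tx", "ty", "tz")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark pairs from CSV (sx,sy,sz,tx,ty,tz)
#' @param path Input path.
#' @return A `landmark_pairs`.
#' @export
read_landmarks_csv <- function(path) {
  df <- read.csv(path)
  landmark_pairs(as.matrix(df[c("sx", "sy", "sz")]),
                 as.matrix(df[c("tx", "ty", "tz")]))
}

#' Serialise a registration result to JSON
#' @param reg A `registration_result`.
#' @param path Output path.
#' @export
write_registration_json <- function(reg, path) {
  jsonlite::write_json(list(matrix = as.vector(t(reg$transform$matrix)),
                            rms = reg$rms, iterations = reg$iterations,
                            converged = reg$converged),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
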