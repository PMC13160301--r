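# Shared fixtures and independent oracles, all built in code.

# Random rigid transform with rotation up to max_deg and translation up to
# max_mm, deterministic in seed.
rand_rigid <- function(seed, max_deg = 180, max_mm = 50) {
  withr::with_seed(seed, {
    axis <- rnorm(3)
    rigid_from_rt(R = rotation_about_axis(axis, runif(1, -max_deg, max_deg)),
                  t = runif(3, -max_mm, max_mm))
  })
}

# Axis-aligned unit cube centred at the origin (12 triangles, outward faces).
unit_cube_mesh <- function(scale = 1) {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5), z = c(-0.5, 0.5))) * scale
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -1/2
    c(5, 6, 7), c(6, 8, 7),   # z = +1/2
    c(1, 2, 5), c(2, 6, 5),   # y = -1/2
    c(3, 7, 4), c(4, 7, 8),   # y = +1/2
    c(1, 5, 3), c(3, 5, 7),   # x = -1/2
    c(2, 4, 6), c(4, 8, 6))   # x = +1/2
  triangle_mesh(v, f, watertight = TRUE)
}

# Latitude/longitude sphere mesh.
uv_sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_lat = 24L, n_lon = 48L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1L)[-c(1L, n_lat + 1L)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  ring <- function(la) cbind(cos(la) * cos(lon), cos(la) * sin(lon), sin(la))
  V <- do.call(rbind, lapply(lat, ring))
  idx <- function(j, k) (j - 1L) * n_lon + ((k - 1L) %% n_lon) + 1L
  faces <- list()
  for (j in seq_len(length(lat) - 1L)) {
    k <- seq_len(n_lon)
    faces[[length(faces) + 1L]] <- cbind(idx(j, k), idx(j, k + 1L), idx(j + 1L, k))
    faces[[length(faces) + 1L]] <- cbind(idx(j + 1L, k), idx(j, k + 1L), idx(j + 1L, k + 1L))
  }
  south <- nrow(V) + 1L; north <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, -1), c(0, 0, 1))
  k <- seq_len(n_lon)
  faces[[length(faces) + 1L]] <- cbind(south, idx(1L, k), idx(1L, k + 1L))
  faces[[length(faces) + 1L]] <- cbind(north, idx(length(lat), k + 1L), idx(length(lat), k))
  m <- triangle_mesh(sweep(V * radius, 2, center, `+`), do.call(rbind, faces),
                     watertight = TRUE)
  pednav:::ensure_outward(m)
}

# Points on a cylinder surface: axis point a, unit direction d, radius r,
# axial extent len, visible arc arc_deg, radial Gaussian noise sigma.
sample_cylinder_cloud <- function(n, a, d, r, len, arc_deg = 360, sigma = 0,
                                  seed = 1L, with_normals = TRUE) {
  withr::with_seed(seed, {
    e <- pednav:::orthobasis(d)
    phi <- runif(n, -arc_deg / 2, arc_deg / 2) * pi / 180
    t <- runif(n, -len / 2, len / 2)
    radial <- outer(cos(phi), e$u) + outer(sin(phi), e$v)
    pts <- matrix(a, n, 3, byrow = TRUE) + outer(t, d) +
      (r + rnorm(n, 0, sigma)) * radial
    point_cloud(pts, normals = if (with_normals) radial)
  })
}

# Independent point-to-triangle distance: exact convex-QP solution found by
# enumerating the simplex faces (interior, three edges, three corners).
bf_point_tri_dist <- function(p, a, b, c) {
  E1 <- b - a; E2 <- c - a; w <- p - a
  G <- rbind(c(sum(E1 * E1), sum(E1 * E2)), c(sum(E2 * E1), sum(E2 * E2)))
  rhs <- c(sum(E1 * w), sum(E2 * w))
  cand <- list(c(0, 0), c(1, 0), c(0, 1))
  uv <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
    cand <- c(cand, list(uv))
  seg <- function(t) pmin(pmax(t, 0), 1)
  cand <- c(cand,
            list(c(seg(rhs[1] / G[1, 1]), 0)),
            list(c(0, seg(rhs[2] / G[2, 2]))))
  # edge b-c: x = b + t (c - b)
  d3 <- c - b
  t3 <- seg(sum((p - b) * d3) / sum(d3 * d3))
  cand <- c(cand, list(c(1 - t3, t3)))
  min(vapply(cand, function(x) {
    q <- a + x[1] * E1 + x[2] * E2
    sqrt(sum((p - q)^2))
  }, 0))
}

# Exhaustive cloud-to-mesh distance over every triangle.
bf_cloud_mesh_dist <- function(P, mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  vapply(seq_len(nrow(P)), function(i) {
    min(vapply(seq_len(nrow(Fm)), function(f)
      bf_point_tri_dist(P[i, ], V[Fm[f, 1], ], V[Fm[f, 2], ], V[Fm[f, 3], ]), 0))
  }, 0)
}

# Brute-force mean k-nearest-neighbour distance via the full distance matrix.
bf_knn_mean <- function(P, k) {
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
}

# A small random (non-manifold) triangle soup for oracle comparisons.
random_triangle_soup <- function(n_tri, seed, extent = 40) {
  withr::with_seed(seed, {
    V <- matrix(runif(n_tri * 9, -extent, extent), n_tri * 3, 3)
    triangle_mesh(V, matrix(seq_len(n_tri * 3), ncol = 3, byrow = TRUE))
  })
}
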