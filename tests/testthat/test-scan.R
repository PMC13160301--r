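# A large plane facing the camera at the reference standoff.
facing_plane <- function(z = 1500, half = 900) {
  triangle_mesh(rbind(c(-half, -half, z), c(half, -half, z),
                      c(half, half, z), c(-half, half, z)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

test_that("a noiseless frontal plane returns one exact point per ray", {
  cam <- camera_model(grid = c(40L, 50L))
  sc <- simulate_scan(list(plane = facing_plane()), cam, noise_config(seed = 1))
  expect_false(sc$empty)
  expect_equal(n_points(sc$cloud), 40L * 50L)
  expect_lt(max(abs(sc$cloud$points[, 3] - 1500)), 1e-9)
  expect_true(all(sc$cloud$labels == "plane"))
})

test_that("surfaces hidden behind the first hit are not reported", {
  occluded <- unit_cube_mesh(scale = 100)
  occluded <- transform_mesh(rigid_from_rt(t = c(0, 0, 2000)), occluded)
  sc <- simulate_scan(list(front = facing_plane(), box = occluded),
                      camera_model(grid = c(30L, 30L)), noise_config(seed = 2))
  expect_equal(sum(sc$cloud$labels == "box"), 0L)
  expect_gt(sum(sc$cloud$labels == "front"), 0L)
  # box alone is visible
  sc2 <- simulate_scan(list(box = occluded), camera_model(grid = c(30L, 30L)),
                       noise_config(seed = 2))
  expect_gt(sum(sc2$cloud$labels == "box"), 0L)
})

test_that("injected depth noise is recovered by a Monte-Carlo estimate", {
  cam <- camera_model(grid = c(100L, 120L))
  sc <- simulate_scan(list(plane = facing_plane()), cam,
                      noise_config(depth_sigma = 0.1, seed = 31))
  expect_gte(n_points(sc$cloud), 1e4)
  # signed distance to the plane = z - 1500; rays are near-normal here
  s_hat <- sd(sc$cloud$points[, 3] - 1500)
  expect_lt(abs(s_hat - 0.1) / 0.1, 0.15)
})

test_that("scans are deterministic given the seed and flag empty frusta", {
  cam <- camera_model(grid = c(25L, 25L))
  a <- simulate_scan(list(p = facing_plane()), cam, noise_config(0.2, seed = 5))
  b <- simulate_scan(list(p = facing_plane()), cam, noise_config(0.2, seed = 5))
  expect_identical(a$cloud$points, b$cloud$points)
  cc <- simulate_scan(list(p = facing_plane()), cam, noise_config(0.2, seed = 6))
  expect_false(identical(a$cloud$points, cc$cloud$points))
  far <- simulate_scan(list(p = facing_plane(z = 5000)), cam, noise_config(seed = 1))
  expect_true(far$empty)
  expect_equal(n_points(far$cloud), 0L)
})

test_that("outlier injection appends the exact count inside the box", {
  cam <- camera_model(grid = c(40L, 25L))
  base <- simulate_scan(list(p = facing_plane()), cam,
                        noise_config(depth_sigma = 0, outlier_fraction = 0, seed = 9))
  expect_identical(add_outliers(base)$cloud$points, base$cloud$points)

  n <- n_points(base$cloud)
  base$noise <- noise_config(0, outlier_fraction = 0.05,
                             outlier_box = c(300, 200, 100), seed = 9)
  out <- add_outliers(base)
  m <- sum(out$cloud$labels == "outlier")
  expect_equal(m, floor(0.05 * n))
  pts <- out$cloud$points[out$cloud$labels == "outlier", , drop = FALSE]
  ctr <- colMeans(base$cloud$points)
  expect_true(all(abs(sweep(pts, 2, ctr)) <= rep(c(150, 100, 50), each = m) + 1e-9))
})

test_that("returned points re-cast to their own first hit (visibility oracle)", {
  scene <- make_scene(phantom_spec(seed = 4))
  cam <- camera_look_at(c(0, 0, 1400), c(0, 0, 0), grid = c(40L, 50L))
  sc <- simulate_scan(list(skin = scene$skin), cam, noise_config(seed = 13))
  orig <- cam$pose$matrix[1:3, 4]
  idx <- withr::with_seed(1, sample(n_points(sc$cloud), 25))
  for (i in idx) {
    p <- sc$cloud$points[i, ]
    d <- pednav:::normalize3(p - orig)
    h <- ray_mesh_intersections(ray(orig, d), scene$skin)
    expect_gt(nrow(h), 0)
    expect_lt(abs(h$t[1] - sqrt(sum((p - orig)^2))), 1e-6)
  }
})
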