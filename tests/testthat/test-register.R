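test_that("landmark alignment recovers exact and known rigid poses", {
  pts <- matrix(c(0, 0, 0, 10, 0, 0, 0, 12, 0, 0, 0, 9, 5, 5, 5), 5, 3, byrow = TRUE)
  same <- rough_register(landmark_pairs(pts, pts))
  expect_lt(max(abs(same$matrix - diag(4))), 1e-9)
  for (s in 1:8) {
    Tr <- rand_rigid(s + 400)
    src <- withr::with_seed(s, matrix(rnorm(12, sd = 30), 4, 3))
    got <- rough_register(landmark_pairs(src, pednav:::apply_rigid(Tr, src)))
    expect_lt(max(abs(got$matrix - Tr$matrix)), 1e-9)
  }
})

test_that("degenerate landmark sets are refused", {
  tri <- matrix(rnorm(9), 3, 3)
  expect_error(landmark_pairs(tri, tri), "at least 4")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(landmark_pairs(line, line + 1), "collinear")
  dup <- rbind(c(1, 1, 1), c(1, 1, 1), c(2, 2, 3), c(4, 5, 6))
  expect_error(landmark_pairs(dup, dup), "duplicate")
})

test_that("SOR removes a gross outlier from a regular ring and is idempotent", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  g <- cbind(40 * cos(th), 40 * sin(th), 0)   # every point statistically equal
  clean <- sor_filter(point_cloud(g), 6, 1.0)
  expect_equal(n_points(clean), nrow(g))
  spiked <- point_cloud(rbind(g, c(1000, 1000, 1000)),
                        labels = c(rep("grid", nrow(g)), "spike"))
  filt <- sor_filter(spiked, 6, 1.0)
  expect_false("spike" %in% filt$labels)
  expect_equal(n_points(filt), nrow(g))
  expect_identical(sor_filter(filt, 6, 1.0)$points, filt$points)
})

test_that("SOR matches the brute-force k-NN statistic on random clouds", {
  for (s in 1:3) {
    P <- withr::with_seed(s, matrix(runif(3 * 400, 0, 100), 400, 3))
    k <- 6; mult <- 1.0
    md <- bf_knn_mean(P, k)
    keep <- md <= mean(md) + mult * sd(md)
    got <- sor_filter(point_cloud(P), k, mult)
    expect_identical(got$points, P[keep, , drop = FALSE])
  }
  tiny <- point_cloud(matrix(rnorm(9), 3))
  expect_warning(out <- sor_filter(tiny, 6), "too few")
  expect_identical(out$points, tiny$points)
})

test_that("ICP leaves an already-aligned noiseless scan in place", {
  scene <- make_scene(phantom_spec(seed = 6))
  cam <- camera_look_at(c(0, 0, 1400), c(0, 0, 0), grid = c(60L, 80L))
  sc <- simulate_scan(list(skin = scene$skin), cam, noise_config(seed = 3))
  reg <- icp_refine(sc$cloud, scene$skin)
  expect_lt(reg$rms, 1e-6)
  expect_lt(max(abs(reg$transform$matrix - diag(4))), 1e-6)
  expect_true(reg$converged)
  expect_error(icp_refine(point_cloud(), scene$skin), "empty")
})

test_that("rough + fine registration recovers a perturbed pose to ground truth", {
  scene <- make_scene(phantom_spec(seed = 2))
  cam <- camera_look_at(c(0, 0, 1400), c(0, 0, 0), grid = c(120L, 160L))
  t_place <- rigid_from_rt(rotation_about_axis(c(0.3, 0.5, 0.8), 5), c(10, -3, 2))
  truth <- rigid_invert(t_place)
  skin_w <- transform_mesh(t_place, scene$skin)
  sc <- simulate_scan(list(skin = skin_w), cam, noise_config(seed = 11))
  lm_src <- pednav:::apply_rigid(t_place, scene$landmarks) +
    withr::with_seed(42, matrix(rnorm(18, 0, 0.5), 6))
  rough <- rough_register(landmark_pairs(lm_src, scene$landmarks))
  reg <- icp_refine(sor_filter(sc$cloud), scene$skin, init = rough)
  expect_lt(reg$rms, 1e-3)
  D <- rigid_compose(reg$transform, rigid_invert(truth))$matrix
  ang <- acos(min(1, (sum(diag(D[1:3, 1:3])) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.01)
  expect_lt(sqrt(sum(D[1:3, 4]^2)), 0.01)
  # the fine stage never ends worse than its first iteration
  d0 <- cloud_to_mesh_distance(transform_points(rough, sor_filter(sc$cloud)),
                               scene$skin)$per_point
  expect_lte(reg$rms, sqrt(mean(d0^2)) + 1e-12)
})

test_that("final RMS tracks the injected depth noise", {
  scene <- make_scene(phantom_spec(seed = 2))
  cam <- camera_look_at(c(0, 0, 1400), c(0, 0, 0), grid = c(120L, 160L))
  t_place <- rigid_from_rt(rotation_about_axis(c(0.3, 0.5, 0.8), 5), c(10, -3, 2))
  skin_w <- transform_mesh(t_place, scene$skin)
  lm_src <- pednav:::apply_rigid(t_place, scene$landmarks) +
    withr::with_seed(42, matrix(rnorm(18, 0, 0.5), 6))
  rough <- rough_register(landmark_pairs(lm_src, scene$landmarks))
  for (s in 1:5) {
    sc <- simulate_scan(list(skin = skin_w), cam, noise_config(0.1, seed = 100 + s))
    reg <- icp_refine(sor_filter(sc$cloud), scene$skin, init = rough)
    expect_gte(reg$rms, 0.05)
    expect_lte(reg$rms, 0.2)
  }
})

test_that("register_map moves the plan into camera space consistently", {
  scene <- make_scene(phantom_spec(seed = 7))
  map <- nav_map(scene$skin, scene$bones, scene$truth_trajectories)
  ident_reg <- icp_refine(point_cloud(scene$skin$vertices[1:200, ]), scene$skin)
  moved <- register_map(map, ident_reg)
  expect_identical(moved$frame, "world")
  expect_equal(moved$skin$vertices, map$skin$vertices, tolerance = 1e-9)
  expect_error(register_map(moved, ident_reg), "already")

  # with a real placement: the unmoved scan matches the moved map exactly as
  # well as the registered scan matched the model
  t_place <- rand_rigid(31, max_deg = 10, max_mm = 30)
  cam <- camera_look_at(c(0, 0, 1400), c(0, 0, 0), grid = c(60L, 80L))
  sc <- simulate_scan(list(skin = transform_mesh(t_place, scene$skin)), cam,
                      noise_config(0.05, seed = 8))
  lm_src <- pednav:::apply_rigid(t_place, scene$landmarks)
  reg <- icp_refine(sc$cloud, scene$skin,
                    init = rough_register(landmark_pairs(lm_src, scene$landmarks)))
  pre <- cloud_to_mesh_distance(transform_points(reg$transform, sc$cloud), scene$skin)
  moved2 <- register_map(map, reg)
  post <- cloud_to_mesh_distance(sc$cloud, moved2$skin)
  expect_equal(post$mean_distance, pre$mean_distance, tolerance = 1e-9)
  # rigid motion preserves inter-channel geometry
  a12 <- angle_between_lines(map$channels[[1]]$direction, map$channels[[2]]$direction)
  b12 <- angle_between_lines(moved2$channels[[1]]$direction, moved2$channels[[2]]$direction)
  expect_equal(a12, b12, tolerance = 1e-9)
})
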