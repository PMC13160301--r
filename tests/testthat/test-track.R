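test_that("planned channels carry the stated defaults and clone cleanly", {
  scene <- make_scene(phantom_spec(seed = 1))
  map <- nav_map(scene$skin, scene$bones)
  pose1 <- rand_rigid(1, max_deg = 30, max_mm = 40)
  pose2 <- rand_rigid(2, max_deg = 30, max_mm = 40)
  map <- add_channel(map, pose1, label = "a")
  map <- add_channel(map, pose2, label = "b")
  ch <- map$channels[[1]]
  expect_equal(ch$radius, 1.0)
  expect_equal(ch$length, 300.0)
  expect_equal(ch$direction, pose1$matrix[1:3, 3], tolerance = 1e-12)
  expect_equal(map$channels[[2]]$radius, map$channels[[1]]$radius)
  expect_gt(angle_between_lines(map$channels[[1]]$direction,
                                map$channels[[2]]$direction), 0)
  expect_error(add_channel(map, pose1, radius = 0), "positive")
  # posed from a truth trajectory, the channel is coaxial with its corridor
  tr <- scene$truth_trajectories[[3]]
  e <- pednav:::orthobasis(tr$direction)
  posed <- add_channel(nav_map(scene$skin), rigid_from_rt(
    R = cbind(e$u, e$v, tr$direction), t = tr$origin))
  expect_equal(angle_between_lines(posed$channels[[1]]$direction,
                                   scene$corridors[[3]]$axis_dir), 0,
               tolerance = 1e-9)
})

test_that("exact cylinder samples are recovered to machine precision", {
  a <- c(10, -5, 3); d <- pednav:::normalize3(c(0.2, -0.1, 0.97))
  cl <- sample_cylinder_cloud(2000, a, d, 12.5, 150, arc_deg = 360, sigma = 0, seed = 99)
  fit <- fit_cylinder(cl, seed = 1)
  expect_s3_class(fit, "cylinder_fit")
  expect_equal(fit$radius, 12.5)
  expect_lt(angle_between_lines(fit$axis_direction, d), 1e-6)
  foot <- pednav:::line_foot(fit$axis_point, a, d)
  expect_lt(sqrt(sum((fit$axis_point - foot)^2)), 1e-6)
  expect_lt(fit$inlier_rms, 1e-9)
})

test_that("a partial noisy arc still localises the axis", {
  a <- c(-4, 8, 2); d <- pednav:::normalize3(c(-0.15, 0.2, 0.97))
  for (s in 1:5) {
    cl <- sample_cylinder_cloud(5000, a, d, 12.5, 150, arc_deg = 120,
                                sigma = 0.05, seed = s)
    fit <- fit_cylinder(cl, seed = s)
    expect_s3_class(fit, "cylinder_fit")
    expect_lt(angle_between_lines(fit$axis_direction, d), 0.2)
    foot <- pednav:::line_foot(fit$axis_point, a, d)
    expect_lt(sqrt(sum((fit$axis_point - foot)^2)), 0.1)
    expect_gte(fit$arc_coverage_deg, 110)
  }
})

test_that("the fit shrugs off 5% outliers and flags degenerate coverage", {
  a <- c(0, 0, 0); d <- c(0, 0, 1)
  cl <- sample_cylinder_cloud(4000, a, d, 12.5, 150, arc_deg = 180,
                              sigma = 0.03, seed = 17)
  junk <- withr::with_seed(18, matrix(runif(3 * 200, -80, 80), 200, 3))
  dirty <- point_cloud(rbind(cl$points, junk))
  fit <- fit_cylinder(dirty, seed = 4)
  expect_s3_class(fit, "cylinder_fit")
  expect_lt(angle_between_lines(fit$axis_direction, d), 0.2)
  foot <- pednav:::line_foot(fit$axis_point, a, d)
  expect_lt(sqrt(sum((fit$axis_point - foot)^2)), 0.1)

  few <- sample_cylinder_cloud(20, a, d, 12.5, 40, arc_deg = 30, seed = 5)
  expect_true(is_fit_failure(fit_cylinder(few, seed = 1)))
  narrow <- sample_cylinder_cloud(500, a, d, 12.5, 80, arc_deg = 30, seed = 6)
  expect_true(is_fit_failure(fit_cylinder(narrow, seed = 1)))
})

test_that("axis recovery degrades as the visible arc shrinks", {
  a <- c(0, 0, 0); d <- pednav:::normalize3(c(0.1, 0.1, 0.99))
  err <- vapply(c(360, 240, 180, 120), function(arc) {
    mean(vapply(1:4, function(s) {
      cl <- sample_cylinder_cloud(1200, a, d, 12.5, 150, arc_deg = arc,
                                  sigma = 0.1, seed = 100 * arc + s)
      fit <- fit_cylinder(cl, seed = s)
      foot <- pednav:::line_foot(fit$axis_point, a, d)
      angle_between_lines(fit$axis_direction, d) +
        sqrt(sum((fit$axis_point - foot)^2))
    }, 0))
  }, 0)
  expect_lt(err[1], err[4])            # full circle beats the narrowest arc
  expect_true(all(err < 0.3))
})

test_that("navigation channels inherit the fitted axis and stated dimensions", {
  a <- c(5, 5, 40); d <- pednav:::normalize3(c(0.3, -0.2, -0.93))
  cl <- sample_cylinder_cloud(3000, a, d, 12.5, 150, arc_deg = 200, seed = 3)
  fit <- fit_cylinder(cl, seed = 2)
  cam <- camera_look_at(c(0, 0, 1400), c(0, 0, 0))
  ch <- channel_from_fit(fit, camera = cam)
  expect_equal(ch$radius, 1.0)
  expect_equal(ch$length, 800.0)
  expect_equal(angle_between_lines(ch$direction, fit$axis_direction), 0,
               tolerance = 1e-9)
  fwd <- as.numeric(pednav:::apply_rotation(cam$pose, matrix(c(0, 0, 1), 1)))
  expect_gt(sum(ch$direction * fwd), 0)   # tip-ward, away from the camera
  expect_error(channel_from_fit(pednav:::fit_failure("x")), "failed fit")
})

test_that("guidance offsets are the perpendicular miss and the axis angle", {
  planned <- channel(c(0, 0, 0), c(0, 0, 1), frame = "world")
  expect_equal(unname(guidance_offset(planned, planned)), c(0, 0))
  shifted <- channel(c(5, 0, -20), c(0, 0, 1), frame = "world")
  expect_equal(unname(guidance_offset(planned, shifted)), c(5, 0), tolerance = 1e-12)
  rotated <- channel(c(0, 0, 0), c(sin(2 * pi / 180), 0, cos(2 * pi / 180)),
                     frame = "world")
  expect_equal(unname(guidance_offset(planned, rotated)), c(0, 2), tolerance = 1e-9)
  expect_error(guidance_offset(planned, channel(c(0, 0, 0), c(0, 0, 1))), "frames")
})

test_that("simulated alignment converges to the plan within tolerance", {
  planned <- channel(c(10, -5, 0), pednav:::normalize3(c(0.2, 0.1, 0.97)),
                     frame = "world")
  done <- simulate_alignment(planned, planned)
  expect_equal(max(attr(done, "trace")$iteration), 0)
  start <- channel(c(18, 3, -4), pednav:::normalize3(c(-0.1, 0.25, 0.96)),
                   frame = "world")
  out <- simulate_alignment(planned, start, tolerance_mm = 1e-9,
                            tolerance_deg = 1e-9)
  off <- guidance_offset(planned, out)
  expect_lt(off[[1]], 1e-9)
  expect_lt(off[[2]], 1e-9)
  expect_lt(angle_between_lines(out$direction, planned$direction), 1e-9)
  # partial-gain corrections still reach tolerance, just more slowly
  slow <- simulate_alignment(planned, start, tolerance_mm = 1e-6,
                             tolerance_deg = 1e-6, gain = 0.5)
  off2 <- guidance_offset(planned, slow)
  expect_lt(off2[[1]], 1e-6)
  expect_gt(nrow(attr(slow, "trace")), nrow(attr(out, "trace")))
})
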