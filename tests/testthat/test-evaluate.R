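test_that("entry/exit points bracket a sphere by its diameter", {
  ctr <- c(2, -1, 4); r <- 9
  sph <- uv_sphere_mesh(radius = r, center = ctr, n_lat = 60, n_lon = 120)
  ch <- channel(ctr - c(0, 0, 50), c(0, 0, 1), length = 300, frame = "image")
  ep <- entry_exit_points(ch, sph)
  sagitta <- 2 * r * (1 - cos(pi / 60))
  expect_lt(abs(sqrt(sum((ep$exit - ep$entry)^2)) - 2 * r), 2 * sagitta)
  expect_equal(ep$direction, c(0, 0, 1), tolerance = 1e-6)
})

test_that("a corridor-coaxial trajectory crosses the vertebra where the ellipse says", {
  spec <- phantom_spec(seed = 3)
  v <- make_vertebra(spec, 1)
  cor <- v$corridors[[1]]
  ch <- channel(cor$axis_point - 50 * cor$axis_dir, cor$axis_dir, length = 300)
  ep <- entry_exit_points(ch, v$mesh)
  # analytic chord of the ellipse (y/ay)^2 + (z/az)^2 = 1 along the axis
  ha <- pednav:::vertebra_params(spec, 1)$half_axes
  p0 <- cor$axis_point; d <- cor$axis_dir
  qa <- (d[2] / ha[2])^2 + (d[3] / ha[3])^2
  qb <- 2 * (p0[2] * d[2] / ha[2]^2 + p0[3] * d[3] / ha[3]^2)
  qc <- (p0[2] / ha[2])^2 + (p0[3] / ha[3])^2 - 1
  ts <- sort((-qb + c(-1, 1) * sqrt(qb^2 - 4 * qa * qc)) / (2 * qa))
  sagitta <- max(ha[2:3]) * (1 - cos(pi / 64)) + 1e-6
  expect_lt(max(abs(ep$entry - (p0 + ts[1] * d))), 2 * sagitta)
  expect_lt(max(abs(ep$exit - (p0 + ts[2] * d))), 2 * sagitta)

  miss <- channel(c(0, 500, 0), c(0, 0, 1))
  expect_error(entry_exit_points(miss, v$mesh), "nearest approach")
})

test_that("trajectory deviations reduce to the expected closed forms", {
  mk <- function(entry, exit) structure(
    list(entry = entry, exit = exit,
         direction = pednav:::normalize3(exit - entry)),
    class = "trajectory_endpoints")
  base <- mk(c(0, 0, 0), c(0, 0, 30))
  self <- trajectory_deviation(base, base)
  expect_equal(self$entry_offset, 0); expect_equal(self$exit_offset, 0)
  expect_equal(self$angle_offset, 0)

  shifted <- trajectory_deviation(base, mk(c(1, 0, 0), c(1, 0, 30)))
  expect_equal(shifted$entry_offset, 1); expect_equal(shifted$exit_offset, 1)
  expect_equal(shifted$angle_offset, 0, tolerance = 1e-9)
  expect_equal(shifted$entry_dx, -1)

  # 1 degree rotation about the shared entry, segment length L = 30:
  # exit offset is the chord 2 L sin(0.5 deg)
  L <- 30; th <- pi / 180
  rot <- mk(c(0, 0, 0), c(L * sin(th), 0, L * cos(th)))
  dv <- trajectory_deviation(base, rot)
  expect_equal(dv$entry_offset, 0)
  expect_equal(dv$angle_offset, 1, tolerance = 1e-9)
  expect_equal(dv$exit_offset, 2 * L * sin(th / 2), tolerance = 1e-6)
})

test_that("Neo grades follow the breach-depth thresholds", {
  cor <- list(axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
              radius = 3.0, span = 24)
  coax <- channel(c(0, 0, -40), c(0, 0, 1), radius = 1, length = 120)
  expect_equal(neo_grade(coax, cor)$grade, 0L)
  off3 <- channel(c(3, 0, -40), c(0, 0, 1), radius = 1, length = 120)
  g3 <- neo_grade(off3, cor)
  expect_equal(g3$breach_depth_mm, 1.0, tolerance = 1e-12)
  expect_equal(g3$grade, 1L)
  expect_equal(neo_grade(channel(c(4, 0, -40), c(0, 0, 1), radius = 1, length = 120),
                         cor)$grade, 2L)
  off65 <- neo_grade(channel(c(6.5, 0, -40), c(0, 0, 1), radius = 1, length = 120), cor)
  expect_equal(off65$breach_depth_mm, 4.5, tolerance = 1e-12)
  expect_equal(off65$grade, 3L)
  outside <- channel(c(0, 0, 100), c(0, 0, 1), radius = 1, length = 20)
  expect_error(neo_grade(outside, cor), "span")
})

test_that("breach depth matches dense sampling of a tilted wire", {
  cor <- list(axis_point = c(1, -2, 0), axis_dir = pednav:::normalize3(c(0.1, 0, 0.995)),
              radius = 3.0, span = 24)
  wire <- channel(c(3.5, -1, -60), pednav:::normalize3(c(-0.03, 0.04, 0.998)),
                  radius = 1, length = 150)
  got <- neo_grade(wire, cor)$breach_depth_mm
  # dense independent evaluation along the wire
  d <- cor$axis_dir; a <- cor$axis_point
  s <- seq(0, wire$length, length.out = 200001)
  pts <- matrix(wire$origin, length(s), 3, byrow = TRUE) + outer(s, wire$direction)
  ax <- as.numeric(sweep(pts, 2, a) %*% d)
  # the axial coordinate is linear in s, so the span boundaries interpolate exactly
  slope <- (ax[2] - ax[1]) / (s[2] - s[1])
  s_b <- (c(-1, 1) * cor$span / 2 - ax[1]) / slope
  s_b <- s_b[s_b >= 0 & s_b <= wire$length]
  keep_s <- c(s[abs(ax) <= cor$span / 2], s_b)
  ptsk <- matrix(wire$origin, length(keep_s), 3, byrow = TRUE) +
    outer(keep_s, wire$direction)
  w <- sweep(ptsk, 2, a)
  perp <- sqrt(rowSums((w - outer(as.numeric(w %*% d), d))^2))
  want <- max(0, max(perp) + wire$radius - cor$radius)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("summary rows reproduce the packaged per-model tables", {
  reg <- read.csv(system.file("extdata", "model_registration.csv", package = "pednav"))
  row_rms <- summarize_metric(reg$rms, "rms")
  expect_lt(abs(row_rms$sd - 0.12), 0.001)
  expect_equal(row_rms$mean, 0.4249, tolerance = 1e-4)
  row_acc <- summarize_metric(reg$registration_accuracy, "accuracy")
  expect_lt(abs(row_acc$mean - 0.010), 0.001)
  dev <- read.csv(system.file("extdata", "model_deviation.csv", package = "pednav"))
  expect_lt(abs(summarize_metric(dev$exit_offset, "exit")$mean - 1.253), 0.001)
  expect_lt(abs(summarize_metric(dev$entry_offset, "entry")$mean - 0.909), 0.001)
  expect_lt(abs(summarize_metric(dev$angle_offset, "angle")$mean - 0.922), 0.001)
  cst <- summarize_metric(rep(2.5, 5), "const")
  expect_equal(cst$sd, 0)
  expect_equal(cst$median, 2.5)
  expect_error(summarize_metric(1), "n >= 2")
})

test_that("paired tests pick the right branch and match the closed-form t", {
  same <- paired_location_test(1:5, 1:5)
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)

  d <- c(1, 2, 3, 4, 5)
  post <- c(10, 11, 12, 13, 14); pre <- post + d
  got <- paired_location_test(pre, post)
  expect_equal(got$test, "t")
  expect_equal(got$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-9)

  heavy_pre <- c(0.1, -0.2, 0.05, 0.12, -0.07, 0.02, 0.08, -0.03, 0.06, 0.01,
                 -0.04, 0.09, 0.03, -0.05, 60, 85, -70, 90, -80, 75)
  got2 <- paired_location_test(heavy_pre, rep(0, 20))
  expect_equal(got2$test, "rank-sum")
  expect_error(paired_location_test(1:4, 1:5), "differ")
})
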