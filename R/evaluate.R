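# Puncture-accuracy analytics: entry/exit points of a trajectory through
# bone, offsets and offset angle against the plan, per-axis coordinate
# differences, Neo breach grading, and the summary statistics / paired
# location tests used to report them.

#' Entry and exit points of a trajectory through a bone
#'
#' Entry is the first axis/mesh intersection along the insertion
#' direction; exit is the last intersection within the channel length
#' (anterior cortex penetration).
#'
#' @param ch A `channel` whose axis intersects the bone.
#' @param bone A `triangle_mesh`.
#' @return A `trajectory_endpoints`: `entry`, `exit`, `direction`.
#' @export
entry_exit_points <- function(ch, bone) {
  stopifnot(inherits(ch, "channel"), inherits(bone, "triangle_mesh"))
  hits <- ray_mesh_intersections(ray(ch$origin, ch$direction), bone)
  hits <- hits[hits$t > 1e-9 & hits$t <= ch$length, , drop = FALSE]
  if (nrow(hits) < 2L) {
    near <- cloud_to_mesh_distance(point_cloud(matrix(ch$origin + (ch$length / 2) * ch$direction, 1)),
                                   bone, keep_per_point = FALSE)
    stopf("trajectory misses the bone (nearest approach about %.2f mm)",
          near$mean_distance)
  }
  entry <- as.numeric(hits[1, c("x", "y", "z")])
  exit <- as.numeric(hits[nrow(hits), c("x", "y", "z")])
  structure(list(entry = entry, exit = exit,
                 direction = normalize3(exit - entry)),
            class = "trajectory_endpoints")
}

#' @export
print.trajectory_endpoints <- function(x, ...) {
  cat(sprintf("Trajectory: entry (%.2f, %.2f, %.2f) -> exit (%.2f, %.2f, %.2f), %.1f mm\n",
              x$entry[1], x$entry[2], x$entry[3], x$exit[1], x$exit[2], x$exit[3],
              sqrt(sum((x$exit - x$entry)^2))))
  invisible(x)
}

#' Deviation between planned and achieved trajectories
#'
#' Entry/exit offsets are Euclidean distances between the corresponding
#' points; the offset angle is the undirected angle between the two axes;
#' per-axis differences are signed, planned minus achieved.
#'
#' @param planned,achieved `trajectory_endpoints` in the same frame.
#' @param label Wire label carried into the record.
#' @return A `deviation_record` (one-row data.frame): `label`,
#'   `entry_offset`, `exit_offset`, `angle_offset`, `entry_dx/dy/dz`,
#'   `exit_dx/dy/dz`.
#' @export
trajectory_deviation <- function(planned, achieved, label = "") {
  stopifnot(inherits(planned, "trajectory_endpoints"),
            inherits(achieved, "trajectory_endpoints"))
  de <- planned$entry - achieved$entry
  dx <- planned$exit - achieved$exit
  out <- data.frame(label = label,
                    entry_offset = sqrt(sum(de^2)),
                    exit_offset = sqrt(sum(dx^2)),
                    angle_offset = angle_between_lines(planned$direction,
                                                      achieved$direction),
                    entry_dx = de[1], entry_dy = de[2], entry_dz = de[3],
                    exit_dx = dx[1], exit_dy = dx[2], exit_dz = dx[3])
  class(out) <- c("deviation_record", class(out))
  out
}

#' Neo breach grade of a wire against its pedicle corridor
#'
#' Breach depth is the largest protrusion of the wire cylinder beyond the
#' corridor cylinder over the overlapping axial span:
#' `max(0, distance-to-corridor-axis + wire radius - corridor radius)`.
#' The radial distance between two straight axes is convex along the span,
#' so the maximum is attained at a span endpoint and is evaluated in
#' closed form. Grades: 0 (no breach), 1 (< 2 mm), 2 (2-4 mm), 3 (>= 4 mm).
#'
#' @param wire A `channel` for the Kirschner wire (radius 1 mm).
#' @param corridor Corridor definition: list with `axis_point`, `axis_dir`,
#'   `radius`, `span` (as produced by the phantom generator).
#' @return List: `grade` (integer 0-3), `breach_depth_mm`.
#' @export
neo_grade <- function(wire, corridor) {
  stopifnot(inherits(wire, "channel"))
  a <- corridor$axis_point; d <- normalize3(corridor$axis_dir)
  half <- corridor$span / 2
  # wire-axis arc length s over which the wire lies within the corridor span
  u <- wire$direction
  t0 <- sum((wire$origin - a) * d)               # axial coord of the wire origin
  c_ <- sum(u * d)
  if (abs(c_) < 1e-9) {
    if (abs(t0) > half) stopf("wire does not traverse the corridor span")
    s_lo <- 0; s_hi <- wire$length
  } else {
    ss <- sort(c((-half - t0) / c_, (half - t0) / c_))
    s_lo <- max(ss[1], 0); s_hi <- min(ss[2], wire$length)
    if (s_lo >= s_hi) stopf("wire does not traverse the corridor span")
  }
  dist_at <- function(s) {
    v <- wire$origin + s * u - a
    perp <- v - sum(v * d) * d
    sqrt(sum(perp^2))
  }
  # squared distance is a convex quadratic in s: max attained at an endpoint
  breach <- max(0, max(dist_at(s_lo), dist_at(s_hi)) + wire$radius - corridor$radius)
  grade <- if (breach == 0) 0L else if (breach < 2) 1L else if (breach < 4) 2L else 3L
  list(grade = grade, breach_depth_mm = breach)
}

#' Summary-statistics row for one metric
#'
#' Sample mean, sd (n-1), median and quartiles, as used in the study
#' report tables.
#'
#' @param values Numeric vector (n >= 2 for the sd).
#' @param metric Metric name carried into the row.
#' @return One-row data.frame: `metric`, `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`.
#' @export
summarize_metric <- function(values, metric = "metric") {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) stopf("values must be finite and non-empty")
  if (length(values) < 2) stopf("need n >= 2 for a sample sd")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75)))
  data.frame(metric = metric, n = length(values), mean = mean(values),
             sd = sd(values), median = q[2], q1 = q[1], q3 = q[3])
}

#' Paired location test with automatic branch selection
#'
#' Assesses normality of the paired differences (Shapiro-Wilk at
#' alpha = 0.05); normal differences get a paired t test, otherwise the
#' Wilcoxon signed-rank test. Two-sided p values throughout.
#'
#' @param pre,post Equal-length numeric vectors (n >= 3).
#' @return List: `test` (`"t"` or `"rank-sum"`), `statistic`, `p_value`,
#'   `normal`, `degenerate`.
#' @export
paired_location_test <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post)) stopf("pre and post lengths differ")
  if (length(pre) < 3) stopf("need n >= 3 pairs")
  d <- pre - post
  if (all(d == 0))
    return(list(test = "degenerate", statistic = 0, p_value = NA_real_,
                normal = NA, degenerate = TRUE))
  normal <- tryCatch(shapiro.test(d)$p.value >= 0.05, error = function(e) FALSE)
  if (normal) {
    ht <- t.test(pre, post, paired = TRUE)
    list(test = "t", statistic = unname(ht$statistic), p_value = ht$p.value,
         normal = TRUE, degenerate = FALSE)
  } else {
    ht <- suppressWarnings(wilcox.test(pre, post, paired = TRUE, exact = FALSE))
    list(test = "rank-sum", statistic = unname(ht$statistic), p_value = ht$p.value,
         normal = FALSE, degenerate = FALSE)
  }
}
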