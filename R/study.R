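# End-to-end virtual study: phantom -> scan -> register -> track -> puncture
# -> evaluate, repeated over models with explicit seeds, producing report
# tables shaped like the physical study's (per-model RMS / registration
# accuracy; per-wire Neo grade and entry/exit/angle offsets).

#' Virtual-study run configuration
#'
#' @param seeds Integer seed per model (default `1:9`, nine models).
#' @param phantom Named list of overrides passed to [phantom_spec()].
#' @param scan_grid Camera grid `c(rows, cols)` for the scene scan.
#' @param sleeve_grid Camera grid for the zoomed sleeve scan.
#' @param camera_standoff_mm Camera height above the phantom (default 1400).
#' @param depth_sigma Scan depth noise sd in mm (default 0).
#' @param outlier_fraction,outlier_box Outlier injection (default none).
#' @param landmark_jitter_mm Sd of the simulated landmark pick error.
#' @param sor_k,sor_multiplier SOR filter parameters.
#' @param icp Named list of overrides for [icp_refine()].
#' @param fit Named list of overrides for [fit_cylinder()].
#' @param align_tolerance_mm,align_tolerance_deg Gimbal alignment stop
#'   tolerances (defaults 1e-9).
#' @param exec_sigma_deg,exec_sigma_mm Execution-noise model: angular and
#'   lateral Gaussian jitter applied to the aligned channel before
#'   "insertion" (defaults 0).
#' @param start_perturb_deg,start_perturb_mm Initial sleeve mis-pose before
#'   alignment (defaults 5 deg, 8 mm).
#' @param out_dir Optional directory for report CSVs.
#' @param verbose Emit `stage=... model=... metric=...` log lines.
#' @return A `run_config`.
#' @export
run_config <- function(seeds = 1:9, phantom = list(),
                       scan_grid = c(120L, 160L), sleeve_grid = c(80L, 80L),
                       camera_standoff_mm = 1400,
                       depth_sigma = 0, outlier_fraction = 0,
                       outlier_box = c(400, 400, 400),
                       landmark_jitter_mm = 0,
                       sor_k = 6L, sor_multiplier = 1.0,
                       icp = list(), fit = list(),
                       align_tolerance_mm = 1e-9, align_tolerance_deg = 1e-9,
                       exec_sigma_deg = 0, exec_sigma_mm = 0,
                       start_perturb_deg = 5, start_perturb_mm = 8,
                       out_dir = NULL, verbose = FALSE) {
  stopifnot(length(seeds) >= 1, all(is.finite(seeds)))
  structure(as.list(environment()), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Virtual-study config: %d models (seeds %s), sigma=%.3g mm, exec=(%.2g deg, %.2g mm)\n",
              length(x$seeds), paste(x$seeds, collapse = ","),
              x$depth_sigma, x$exec_sigma_deg, x$exec_sigma_mm))
  invisible(x)
}

log_stage <- function(cfg, stage, model, ...) {
  if (isTRUE(cfg$verbose)) {
    kv <- c(...)
    message(sprintf("stage=%s model=%d %s", stage, model,
                    paste(sprintf("%s=%s", names(kv), kv), collapse = " ")))
  }
}

# Seeded rigid placement of the phantom on the virtual table.
placement_transform <- function(seed) {
  with_seed(seed + 551L, {
    Rz <- rotation_about_axis(c(0, 0, 1), runif(1, -15, 15))
    Rt <- rotation_about_axis(normalize3(c(runif(2, -1, 1), 0)), runif(1, 0, 5))
    rigid_from_rt(R = Rt %*% Rz, t = c(runif(2, -40, 40), runif(1, -20, 20)))
  })
}

# General channel re-framing by an arbitrary rigid transform.
reframe_channel <- function(t, ch, frame) {
  channel(origin = as.numeric(apply_rigid(t, matrix(ch$origin, 1))),
          direction = as.numeric(apply_rotation(t, matrix(ch$direction, 1))),
          radius = ch$radius, length = ch$length, label = ch$label, frame = frame)
}

reframe_corridor <- function(t, cor) {
  cor$axis_point <- as.numeric(apply_rigid(t, matrix(cor$axis_point, 1)))
  cor$axis_dir <- as.numeric(apply_rotation(t, matrix(cor$axis_dir, 1)))
  cor
}

# Execution noise: lateral shift perpendicular to the axis plus a tilt.
perturb_channel <- function(ch, sigma_deg, sigma_mm, seed) {
  if (sigma_deg == 0 && sigma_mm == 0) return(ch)
  with_seed(seed, {
    e <- orthobasis(ch$direction)
    ch$origin <- ch$origin + rnorm(1, 0, sigma_mm) * e$u + rnorm(1, 0, sigma_mm) * e$v
    tilt <- rnorm(1, 0, sigma_deg)
    phi <- runif(1, 0, 2 * pi)
    axis <- cos(phi) * e$u + sin(phi) * e$v
    R <- rotation_about_axis(axis, tilt)
    ch$direction <- normalize3(as.numeric(R %*% ch$direction))
    ch
  })
}

run_one_model <- function(cfg, model_idx) {
  seed <- as.integer(cfg$seeds[model_idx])
  spec <- do.call(phantom_spec, c(list(seed = seed), cfg$phantom))
  scene <- make_scene(spec)
  t_place <- placement_transform(seed)
  skin_w <- transform_mesh(t_place, scene$skin)
  bones_w <- lapply(scene$bones, transform_mesh, t = t_place)

  cam <- camera_look_at(position = c(0, 0, cfg$camera_standoff_mm),
                        target = c(0, 0, 0), up = c(1, 0, 0),
                        grid = cfg$scan_grid)
  noise <- noise_config(depth_sigma = cfg$depth_sigma,
                        outlier_fraction = cfg$outlier_fraction,
                        outlier_box = cfg$outlier_box, seed = seed * 131L)
  meshes <- c(list(skin = skin_w), stats::setNames(bones_w, sprintf("bone%02d", seq_along(bones_w))))
  scan <- add_outliers(simulate_scan(meshes, cam, noise))
  if (scan$empty) stopf("scene scan is empty")
  log_stage(cfg, "scan", model_idx, points = n_points(scan$cloud))

  lm_src <- apply_rigid(t_place, scene$landmarks)
  if (cfg$landmark_jitter_mm > 0)
    lm_src <- lm_src + with_seed(seed * 17L + 3L,
      matrix(rnorm(length(lm_src), 0, cfg$landmark_jitter_mm), nrow(lm_src)))
  rough <- rough_register(landmark_pairs(lm_src, scene$landmarks))

  filtered <- sor_filter(scan$cloud, cfg$sor_k, cfg$sor_multiplier)
  reg <- do.call(icp_refine, c(list(source = filtered, target = scene$skin,
                                    init = rough), cfg$icp))
  acc <- cloud_to_mesh_distance(transform_points(reg$transform, filtered),
                                scene$skin, keep_per_point = FALSE)
  log_stage(cfg, "register", model_idx,
            rms = sprintf("%.6g", reg$rms),
            accuracy = sprintf("%.6g", acc$mean_distance))

  map <- nav_map(scene$skin, scene$bones, scene$truth_trajectories, frame = "image")
  map_w <- register_map(map, reg)
  t_back <- rigid_invert(t_place)     # world -> image, ground truth (postop CT)

  rows <- vector("list", length(map_w$channels))
  for (k in seq_along(map_w$channels)) {
    planned_w <- map_w$channels[[k]]
    planned_img <- scene$truth_trajectories[[k]]
    cor <- scene$corridors[[k]]
    wseed <- seed * 1000L + k

    # pose the sleeve near the planned path, tail toward the camera
    start <- perturb_channel(planned_w, cfg$start_perturb_deg,
                             cfg$start_perturb_mm, wseed + 11L)
    tail <- start$origin - 60 * start$direction
    e <- orthobasis(start$direction)
    pose <- rigid_from_rt(R = cbind(e$u, e$v, start$direction), t = tail)
    sleeve <- make_drill_sleeve(pose)
    roi_cam <- camera_look_at(position = c(0, 0, cfg$camera_standoff_mm),
                              target = tail + 100 * start$direction,
                              up = c(1, 0, 0),
                              fov_mm = c(120, 120), grid = cfg$sleeve_grid)
    s_scan <- simulate_scan(list(sleeve = sleeve), roi_cam,
                            noise_config(depth_sigma = cfg$depth_sigma,
                                         seed = wseed + 29L))
    if (s_scan$empty) stopf("sleeve scan is empty for wire %s", planned_img$label)
    fit <- do.call(fit_cylinder,
                   c(list(cloud = s_scan$cloud, fixed_radius = 12.5,
                          seed = wseed + 43L), cfg$fit))
    if (is_fit_failure(fit)) stopf("cylinder fit failed for wire %s: %s",
                                   planned_img$label, fit$reason)
    nav_ch <- channel_from_fit(fit, camera = roi_cam, label = planned_img$label)
    aligned <- simulate_alignment(planned_w, nav_ch,
                                  tolerance_mm = cfg$align_tolerance_mm,
                                  tolerance_deg = cfg$align_tolerance_deg)
    achieved_w <- perturb_channel(aligned, cfg$exec_sigma_deg,
                                  cfg$exec_sigma_mm, wseed + 57L)
    achieved_w$radius <- 1.0          # the Kirschner wire
    # ground-truth mapping back to the preoperative frame (postop CT role)
    achieved_img <- reframe_channel(t_back, achieved_w, "image")
    bone <- scene$bones[[cor$vertebra]]
    ep_planned <- entry_exit_points(planned_img, bone)
    ep_achieved <- entry_exit_points(achieved_img, bone)
    dev <- trajectory_deviation(ep_planned, ep_achieved, label = planned_img$label)
    ng <- neo_grade(achieved_img, cor)
    dev$neo_grade <- ng$grade
    dev$breach_depth_mm <- ng$breach_depth_mm
    dev$model <- model_idx
    log_stage(cfg, "wire", model_idx, label = dev$label,
              entry = sprintf("%.4g", dev$entry_offset),
              grade = ng$grade)
    rows[[k]] <- dev
  }
  list(model = model_idx, seed = seed, rms = reg$rms,
       registration_accuracy = acc$mean_distance,
       wires = do.call(rbind, rows))
}

#' Run the end-to-end virtual study
#'
#' For each model seed: build a phantom, place it on the virtual table,
#' simulate a structured-light scene scan, register (landmark rough + SOR +
#' ICP fine), move the navigational map into camera space, then for every
#' planned channel scan and cylinder-fit the drill sleeve, align the
#' navigation channel to the plan, apply execution noise, "insert" the
#' wire, and grade the puncture against ground truth. Deterministic given
#' the configured seeds; any per-model stage failure is recorded and the
#' study continues.
#'
#' @param config A `run_config`.
#' @return A `study_report`: `table1` (per-model rms / registration
#'   accuracy), `table2` (per-wire deviations and Neo grades), `summary`,
#'   `grade0_percent`, `failures`, `config`.
#' @export
run_virtual_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  results <- list(); failures <- list()
  for (i in seq_along(config$seeds)) {
    out <- tryCatch(run_one_model(config, i), error = function(e)
      structure(list(model = i, message = conditionMessage(e)), class = "study_failure"))
    if (inherits(out, "study_failure")) {
      failures[[length(failures) + 1L]] <- data.frame(model = out$model,
                                                      message = out$message)
      log_stage(config, "failure", i, message = out$message)
    } else results[[length(results) + 1L]] <- out
  }
  if (!length(results)) stopf("every model failed; first error: %s", failures[[1]]$message)
  table1 <- do.call(rbind, lapply(results, function(r)
    data.frame(model = r$model, rms = r$rms,
               registration_accuracy = r$registration_accuracy)))
  table2 <- do.call(rbind, lapply(results, function(r) r$wires))
  rownames(table2) <- NULL
  table2 <- table2[c("model", "label", "neo_grade", "breach_depth_mm",
                     "entry_offset", "exit_offset", "angle_offset",
                     "entry_dx", "entry_dy", "entry_dz",
                     "exit_dx", "exit_dy", "exit_dz")]
  metrics <- list(rms = table1$rms,
                  registration_accuracy = table1$registration_accuracy,
                  entry_offset = table2$entry_offset,
                  exit_offset = table2$exit_offset,
                  angle_offset = table2$angle_offset)
  metrics <- metrics[vapply(metrics, length, 1L) >= 2L]
  summ <- do.call(rbind, Map(summarize_metric, metrics, names(metrics)))
  rownames(summ) <- NULL
  report <- structure(list(table1 = table1, table2 = table2, summary = summ,
                           grade0_percent = 100 * mean(table2$neo_grade == 0),
                           n_wires = nrow(table2),
                           failures = if (length(failures)) do.call(rbind, failures)
                                      else data.frame(model = integer(0), message = character(0)),
                           config = config),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Virtual study: %d models, %d wires, %d failure(s)\n",
              nrow(x$table1), x$n_wires, nrow(x$failures)))
  cat(sprintf("  Neo grade 0: %.1f%% of wires\n", x$grade0_percent))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s mean %.4g  sd %.4g  (n=%d)\n",
                s$metric[i], s$mean[i], s$sd[i], s$n[i]))
  invisible(x)
}

#' Write a study report as CSV tables plus a JSON manifest
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
    df
  }
  write.csv(fmt(report$table1), file.path(dir, "table1.csv"), row.names = FALSE, quote = FALSE)
  write.csv(fmt(report$table2), file.path(dir, "table2.csv"), row.names = FALSE, quote = FALSE)
  write.csv(fmt(report$summary), file.path(dir, "summary.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_models = nrow(report$table1),
                            n_wires = report$n_wires,
                            grade0_percent = report$grade0_percent,
                            seeds = report$config$seeds,
                            failures = report$failures),
                       file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Summary statistics of one column of a report table
#'
#' @param path CSV file path.
#' @param column Column name (must be numeric).
#' @return One-row data.frame from [summarize_metric()].
#' @export
table_stats <- function(path, column) {
  df <- read.csv(path)
  if (!column %in% names(df)) stopf("no column '%s' in %s", column, path)
  v <- df[[column]]
  if (!is.numeric(v) || !length(v)) stopf("column '%s' is empty or non-numeric", column)
  summarize_metric(v, column)
}
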