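# Disk formats and end-to-end orchestration: multi-page TIFF per cell plus a
# CSV manifest, JSON configs/reports, and the simulate -> train -> embed ->
# project -> stage -> constrain -> analytics pipeline.

#' Write a trajectory dataset to disk
#'
#' One multi-page 16-bit TIFF per cell plus `manifest.csv` (cell_id, frame,
#' time_min, file, phase, stage, division_flag) and, when the dataset came
#' from the generator, `config.json`.
#'
#' @param dataset List of `cell_trajectory` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_trajectories <- function(dataset, dir) {
  if (inherits(dataset, "cell_trajectory")) dataset <- list(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- trajectory_manifest(dataset)
  files <- character(0)
  for (tr in dataset) {
    fn <- paste0(tr$cell_id, ".tif")
    pages <- lapply(seq_len(dim(tr$images)[3]), function(t) tr$images[, , t])
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 16)
    files <- c(files, rep(fn, dim(tr$images)[3]))
  }
  manifest$file <- files
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- dataset[[1]]$config
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read single-cell trajectories from a manifest
#'
#' Frames are ordered by time within each cell regardless of manifest row
#' order. Pixels outside `[0, 1]` are rescaled by the dataset-wide min-max
#' (recorded in the `pixel_range` attribute); data already in `[0, 1]` are
#' left untouched.
#'
#' @param manifest Path to a manifest CSV with columns `cell_id`, `frame`,
#'   `time_min`, `file` (optional `stage`).
#' @param image_dir Directory holding the TIFF files (default: the manifest's
#'   directory).
#' @return List of `cell_trajectory` objects, with attribute `pixel_range`.
#' @export
read_trajectories <- function(manifest, image_dir = dirname(manifest)) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "time_min", "file")
  if (!all(need %in% names(mf))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  mf <- dplyr::arrange(mf, .data$cell_id, .data$time_min)
  paths <- unique(file.path(image_dir, mf$file))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing image files: ", paste(basename(missing), collapse = ", "))
  }
  pages <- lapply(paths, function(p) tiff::readTIFF(p, all = TRUE))
  names(pages) <- basename(paths)
  out <- lapply(split(mf, mf$cell_id), function(sub) {
    if (any(diff(sub$time_min) <= 0)) {
      stop("non-monotone timestamps for cell ", sub$cell_id[1])
    }
    stk <- pages[[basename(sub$file[1])]]
    if (length(stk) != nrow(sub)) {
      stop("cell ", sub$cell_id[1], ": manifest rows (", nrow(sub),
           ") != TIFF pages (", length(stk), ")")
    }
    p <- nrow(stk[[1]])
    images <- array(unlist(stk), c(p, ncol(stk[[1]]), length(stk)))
    structure(list(images = images, cell_id = sub$cell_id[1],
                   time_min = sub$time_min,
                   stage = if ("stage" %in% names(sub)) sub$stage else NULL,
                   truth = NULL, config = NULL),
              class = "cell_trajectory")
  })
  rng <- range(vapply(out, function(tr) range(tr$images), numeric(2)))
  if (rng[1] < 0 || rng[2] > 1) {
    out <- lapply(out, function(tr) {
      tr$images <- (tr$images - rng[1]) / (rng[2] - rng[1])
      tr
    })
  }
  out <- unname(out[order(match(names(out), unique(mf$cell_id)))])
  attr(out, "pixel_range") <- rng
  out
}

#' Configuration of a full pipeline run
#'
#' Bundles the generator, training, model-size, staging and trajectory
#' parameters of one end-to-end study. Serialisable to/from JSON.
#'
#' @param synthetic A [synthetic_config()].
#' @param schedule A [training_schedule()].
#' @param n_cells Number of simulated cells.
#' @param train_fraction Fraction of trajectories used for training (the rest
#'   are held out for evaluation).
#' @param latent_dim,enc_channels,dense_units,disc_channels Model sizes
#'   (see [manifold_model()]).
#' @param gmm_k Mixture components for staging.
#' @param smoothing_factor B-spline smoothing for the first-axis curve.
#' @param run_window Running-average window (frames) for the second-axis
#'   curve.
#' @param min_prominence Extremum prominence threshold (`NULL` = 0.25 x
#'   range).
#' @param seed Master seed of the run.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            schedule = training_schedule(),
                            n_cells = 24,
                            train_fraction = 0.6,
                            latent_dim = 16,
                            enc_channels = c(32, 64, 128),
                            dense_units = 256,
                            disc_channels = c(32, 64, 128, 256),
                            gmm_k = 8,
                            smoothing_factor = 0.6,
                            run_window = 10,
                            min_prominence = NULL,
                            seed = 1L) {
  stopifnot(n_cells >= 4, train_fraction > 0, train_fraction < 1)
  structure(list(synthetic = synthetic, schedule = schedule,
                 n_cells = as.integer(n_cells),
                 train_fraction = train_fraction,
                 latent_dim = as.integer(latent_dim),
                 enc_channels = enc_channels, dense_units = dense_units,
                 disc_channels = disc_channels, gmm_k = as.integer(gmm_k),
                 smoothing_factor = smoothing_factor,
                 run_window = as.integer(run_window),
                 min_prominence = min_prominence,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / deserialise a pipeline configuration
#'
#' Unknown keys in the JSON are rejected.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  x$synthetic$stage_fractions <- as.list(x$synthetic$stage_fractions)
  x$schedule <- unclass(x$schedule)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) stop("unknown config keys: ", paste(extra, collapse = ", "))
  syn <- x$synthetic
  syn_known <- names(formals(synthetic_config))
  if (length(setdiff(names(syn), syn_known)) > 0) {
    stop("unknown synthetic config keys: ",
         paste(setdiff(names(syn), syn_known), collapse = ", "))
  }
  syn$stage_fractions <- unlist(syn$stage_fractions)
  sch <- x$schedule
  sch_known <- names(formals(training_schedule))
  if (length(setdiff(names(sch), sch_known)) > 0) {
    stop("unknown schedule keys: ",
         paste(setdiff(names(sch), sch_known), collapse = ", "))
  }
  x$synthetic <- do.call(synthetic_config, syn)
  x$schedule <- do.call(training_schedule, sch)
  do.call(pipeline_config, x)
}

#' Scaled-down study configuration
#'
#' The desk-scale counterpart of a full imaging study, used by the package's
#' own evaluation: 16 cells of 64 frames at 5.9-minute intervals with a
#' 48-frame cycle, 32 x 32 patches, an 8-dimensional latent space with
#' narrow conv stacks, and up to 100 epochs per training stage with early
#' stopping. See the methods vignette for the rationale behind each size.
#'
#' @param seed Master seed.
#' @param epochs_per_stage Epoch cap per training stage (default 80).
#' @return A [pipeline_config()].
#' @export
study_config_small <- function(seed = 1L, epochs_per_stage = 80) {
  pipeline_config(
    synthetic = synthetic_config(patch_size = 32, n_frames = 64,
                                 period_frames = 48, frame_interval = 5.9,
                                 period_jitter = 0.03, noise_sigma = 0.02,
                                 seed = seed),
    schedule = training_schedule(epochs_per_stage = epochs_per_stage,
                                 lr = 2e-3, lambda_feat = 0.03,
                                 adv_weight = 0.01, tcc_weight = 0.5,
                                 checkpoint_every = 5,
                                 early_stop_patience = 10,
                                 batch_size = 16, tcc_window = 48,
                                 seed = seed),
    n_cells = 16, latent_dim = 8,
    enc_channels = c(8, 16, 32), dense_units = 64,
    disc_channels = c(8, 16, 32, 64),
    seed = seed)
}

# Analytics for one held-out cell: key events on axis 1; cycle duration from
# the running average of whichever axis carries the once-per-cycle division
# drop (axis 1 for a division-anchored projector, axis 2 otherwise). A NULL
# min_prominence in the config defers to each operation's default.
analyse_cell <- function(proj_cell, config, duration_axis = "proj2") {
  sm1 <- smooth_bspline(proj_cell$proj1, config$smoothing_factor,
                        proj_cell$time_min)
  ra2 <- running_average(proj_cell[[duration_axis]], config$run_window,
                         proj_cell$time_min)
  dt <- diff(proj_cell$time_min[1:2])
  if (is.null(config$min_prominence)) {
    ev <- assign_key_stages(sm1)
    dur <- suppressWarnings(estimate_cycle_duration(ra2, frame_interval = dt))
  } else {
    ev <- assign_key_stages(sm1, min_prominence = config$min_prominence)
    dur <- suppressWarnings(
      estimate_cycle_duration(ra2, frame_interval = dt,
                              min_prominence = config$min_prominence))
  }
  list(events = ev, duration_hours = dur)
}

run_once <- function(config, seed, verbose = FALSE) {
  syn <- config$synthetic
  syn$seed <- as.integer(seed)
  dataset <- simulate_dataset(syn, config$n_cells)
  set.seed(seed)
  n_train <- max(2L, round(config$train_fraction * config$n_cells))
  train_idx <- sort(sample(config$n_cells, n_train))
  train_set <- dataset[train_idx]
  test_set <- dataset[-train_idx]

  schedule <- config$schedule
  schedule$seed <- as.integer(seed)
  model <- train_manifold(train_set, schedule,
                          latent_dim = config$latent_dim,
                          enc_channels = config$enc_channels,
                          dense_units = config$dense_units,
                          disc_channels = config$disc_channels,
                          verbose = verbose)

  lat_train <- embed_dataset(model, train_set)
  lat_test <- embed_dataset(model, test_set)

  # staging: fit on training latents, name components with post hoc labels
  gmm <- fit_gmm(lat_train, k = config$gmm_k, seed = seed)
  comp_train <- gmm_responsibilities(gmm, lat_train)$component
  labels_train <- unlist(lapply(train_set, function(tr) tr$stage))
  mapping <- majority_stage_mapping(comp_train, labels_train, k = config$gmm_k)
  stage_model <- merge_components(gmm, mapping)

  # projection: fit on training latents; axis 1 anchored to division timing
  # when the training trajectories carry division events, otherwise plain
  # principal components oriented by the M calls
  anchor <- unlist(lapply(train_set, function(tr) {
    n <- dim(tr$images)[3]
    divs <- if (!is.null(tr$truth)) tr$truth$division_frames else integer(0)
    if (length(divs) == 0) return(rep(NA_real_, n))
    vapply(seq_len(n), function(j) min(abs(j - divs)), numeric(1))
  }))
  calls_train <- classify_frames(stage_model, lat_train)
  if (sum(is.finite(anchor)) >= 10) {
    projector <- fit_projection(lat_train, anchor = anchor, seed = seed)
    proj_train <- project_latents(projector, lat_train)
  } else {
    projector <- fit_projection(lat_train, seed = seed)
    proj_train <- project_latents(projector, lat_train)
    projector <- orient_projection(projector, proj_train, calls_train == "M")
    proj_train <- project_latents(projector, lat_train)
  }
  proj_test <- project_latents(projector, lat_test)

  calls_raw <- classify_frames(stage_model, lat_test)
  proj_test$stage_raw <- calls_raw

  cells <- split(proj_test, proj_test$cell_id)
  cells <- cells[unique(proj_test$cell_id)]
  analytics <- lapply(cells, analyse_cell, config = config,
                      duration_axis = if (projector$anchored) "proj1" else "proj2")
  constrained <- unlist(lapply(names(cells), function(cid) {
    constrain_stage_calls(cells[[cid]]$stage_raw, analytics[[cid]]$events)
  }))
  proj_test$stage_constrained <- constrained

  truth_test <- trajectory_manifest(test_set)
  proj_test$stage_true <- truth_test$stage
  proj_test$phase <- truth_test$phase

  acc_raw <- confusion_and_accuracy(proj_test$stage_raw, proj_test$stage_true)
  acc_con <- confusion_and_accuracy(proj_test$stage_constrained,
                                    proj_test$stage_true)
  durations <- tibble::tibble(
    cell_id = names(cells),
    duration_hours = vapply(analytics, function(a) a$duration_hours, numeric(1)),
    true_hours = syn$period_frames * syn$frame_interval / 60)

  list(model = model, projector = projector, stage_model = stage_model,
       latents_train = proj_train, frames = proj_test,
       analytics = analytics, durations = durations,
       accuracy_raw = acc_raw$accuracy, accuracy_constrained = acc_con$accuracy,
       confusion_raw = acc_raw$confusion, confusion_constrained = acc_con$confusion,
       test_cells = vapply(test_set, function(tr) tr$cell_id, character(1)),
       seed = seed)
}

#' Run the full annotation-free staging pipeline
#'
#' Simulates a dataset, splits it by trajectory, trains the VAE-GAN with the
#' three-stage schedule, embeds and projects all frames (projection and GMM
#' fit on training cells only), names and merges the mixture components with
#' post hoc labels, classifies held-out frames, applies the per-cycle G1-G2
#' constraint from each cell's inferred late-S time, and estimates cycle
#' durations. With `n_runs > 1` the whole procedure is repeated with shifted
#' seeds and accuracies are reported as mean and SD across runs.
#'
#' @param config A [pipeline_config()].
#' @param n_runs Number of independent train/evaluate repetitions.
#' @param output_dir Optional directory for artifacts (config snapshot,
#'   per-run latents/stage-call CSVs, confusion matrices, report JSON).
#' @param verbose Print training progress.
#' @return A `pipeline_result`: list with `runs` (per-run results) and
#'   `report` (accuracy mean/SD, duration errors).
#' @export
run_pipeline <- function(config = pipeline_config(), n_runs = 1,
                         output_dir = NULL, verbose = FALSE) {
  runs <- lapply(seq_len(n_runs), function(r) {
    run_once(config, seed = config$seed + r - 1L, verbose = verbose)
  })
  acc_raw <- vapply(runs, `[[`, numeric(1), "accuracy_raw")
  acc_con <- vapply(runs, `[[`, numeric(1), "accuracy_constrained")
  durs <- dplyr::bind_rows(lapply(runs, `[[`, "durations"))
  rel_err <- abs(durs$duration_hours - durs$true_hours) / durs$true_hours
  report <- list(n_runs = n_runs,
                 accuracy_raw_mean = mean(acc_raw),
                 accuracy_raw_sd = stats::sd(acc_raw),
                 accuracy_constrained_mean = mean(acc_con),
                 accuracy_constrained_sd = stats::sd(acc_con),
                 accuracy_raw_runs = acc_raw,
                 accuracy_constrained_runs = acc_con,
                 duration_median_hours = stats::median(durs$duration_hours,
                                                       na.rm = TRUE),
                 duration_rel_err_median = stats::median(rel_err, na.rm = TRUE),
                 duration_within_10pct = mean(rel_err <= 0.1, na.rm = TRUE))
  out <- structure(list(runs = runs, report = report, config = config),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_artifacts(out, output_dir)
  out
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(result$config, file.path(dir, "config.json"))
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (r in seq_along(result$runs)) {
    run <- result$runs[[r]]
    rd <- file.path(dir, sprintf("run_%02d", r))
    dir.create(rd, showWarnings = FALSE)
    save_model(run$model, file.path(rd, "model.rds"))
    utils::write.csv(run$frames, file.path(rd, "frames.csv"), row.names = FALSE)
    utils::write.csv(run$model$training_log, file.path(rd, "training_log.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(run$confusion_raw),
                     file.path(rd, "confusion_raw.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(run$confusion_constrained),
                     file.path(rd, "confusion_constrained.csv"),
                     row.names = FALSE)
    utils::write.csv(run$durations, file.path(rd, "durations.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Pipeline result (", r$n_runs, " run(s))\n",
      sprintf("  staging accuracy: %.2f%% raw, %.2f%% constrained\n",
              r$accuracy_raw_mean, r$accuracy_constrained_mean),
      sprintf("  median duration estimate: %.2f h (median rel. err %.1f%%)\n",
              r$duration_median_hours, 100 * r$duration_rel_err_median),
      sep = "")
  invisible(x)
}

#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::as_tibble(x$report[c("n_runs", "accuracy_raw_mean", "accuracy_raw_sd",
                               "accuracy_constrained_mean",
                               "accuracy_constrained_sd",
                               "duration_median_hours",
                               "duration_rel_err_median",
                               "duration_within_10pct")])
}

#' Per-frame stage calls of a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Tibble of held-out frames across runs: projections, raw and
#'   constrained calls, ground truth.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$runs), function(r) {
    dplyr::mutate(x$runs[[r]]$frames, run = r, .before = 1)
  }))
}
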