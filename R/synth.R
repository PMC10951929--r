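#' Canonical cell-cycle stage order
#'
#' Stage vocabulary used throughout the package, in biological order starting
#' at cell birth: G1, early S, mid S, late S, G2, M.
#'
#' @format Character vector of length 6.
#' @export
CYCLE_STAGES <- c("G1", "earlyS", "midS", "lateS", "G2", "M")

#' Configuration for the synthetic nucleus-movie generator
#'
#' Describes a population of simulated single-cell PCNA-like movies: square
#' patches of a centered nucleus whose size, brightness and replication-foci
#' texture follow the cell-cycle phase. Defaults emulate live-cell imaging at
#' 5.9-minute frame intervals with trajectories roughly synchronized near the
#' G2--M boundary.
#'
#' @param patch_size Side of the square patch in pixels (>= 16).
#' @param n_frames Number of frames per trajectory.
#' @param frame_interval Minutes between frames.
#' @param period_frames Frames per full cell cycle (>= 8).
#' @param period_jitter Fractional standard deviation of the per-frame phase
#'   increment (0 = perfectly regular cycle).
#' @param stage_fractions Named numeric vector over [CYCLE_STAGES] giving each
#'   stage's fraction of the cycle; must sum to 1.
#' @param noise_sigma Additive Gaussian pixel noise scale.
#' @param photobleach_rate Per-frame fractional intensity decay.
#' @param initial_phase Mean cycle fraction at the first frame (default 0.85,
#'   i.e. cells start in G2 approaching mitosis).
#' @param initial_phase_sd Cell-to-cell spread of the initial phase.
#' @param seed Integer master seed for [simulate_dataset()].
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(patch_size = 32, n_frames = 64, period_frames = 48)
#' @export
synthetic_config <- function(patch_size = 64,
                             n_frames = 255,
                             frame_interval = 5.9,
                             period_frames = 200,
                             period_jitter = 0.05,
                             stage_fractions = c(G1 = 0.35, earlyS = 0.12,
                                                 midS = 0.12, lateS = 0.12,
                                                 G2 = 0.21, M = 0.08),
                             noise_sigma = 0.02,
                             photobleach_rate = 5e-4,
                             initial_phase = 0.85,
                             initial_phase_sd = 0.03,
                             seed = 1L) {
  stopifnot(patch_size >= 16, n_frames >= 1, frame_interval > 0,
            period_frames >= 8, period_jitter >= 0, noise_sigma >= 0,
            photobleach_rate >= 0, photobleach_rate < 1)
  if (!setequal(names(stage_fractions), CYCLE_STAGES)) {
    stop("stage_fractions must be named by: ", paste(CYCLE_STAGES, collapse = ", "))
  }
  stage_fractions <- stage_fractions[CYCLE_STAGES]
  if (abs(sum(stage_fractions) - 1) > 1e-9) {
    stop("stage_fractions must sum to 1 (got ", sum(stage_fractions), ")")
  }
  if (any(stage_fractions <= 0)) stop("stage_fractions must all be positive")
  structure(list(patch_size = as.integer(patch_size),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 period_frames = as.integer(period_frames),
                 period_jitter = period_jitter,
                 stage_fractions = stage_fractions,
                 noise_sigma = noise_sigma,
                 photobleach_rate = photobleach_rate,
                 initial_phase = initial_phase %% 1,
                 initial_phase_sd = initial_phase_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic movie config: ", x$patch_size, "x", x$patch_size, " px, ",
      x$n_frames, " frames @ ", x$frame_interval, " min, period ",
      x$period_frames, " frames\n", sep = "")
  invisible(x)
}

#' Map a cycle fraction to a cell-cycle stage
#'
#' Partitions the unit interval into half-open stage windows `[lo, hi)`
#' ordered G1 -> early S -> mid S -> late S -> G2 -> M (phase 0 = cell birth)
#' and returns the stage containing each phase.
#'
#' @param phase Numeric vector of cycle fractions in `[0, 1)`.
#' @param stage_fractions Named fractions as in [synthetic_config()].
#' @return Character vector of stage labels.
#' @examples
#' phase_to_stage(c(0, 0.5, 0.97))
#' @export
phase_to_stage <- function(phase,
                           stage_fractions = synthetic_config()$stage_fractions) {
  if (any(!is.finite(phase)) || any(phase < 0) || any(phase >= 1)) {
    stop("phase must lie in [0, 1)")
  }
  stage_fractions <- stage_fractions[CYCLE_STAGES]
  stopifnot(abs(sum(stage_fractions) - 1) < 1e-9)
  breaks <- c(0, cumsum(stage_fractions))
  breaks[length(breaks)] <- 1
  idx <- findInterval(phase, breaks, rightmost.closed = FALSE)
  CYCLE_STAGES[pmin(idx, length(CYCLE_STAGES))]
}

# Within-stage progress in [0,1) plus stage id, vectorised.
stage_progress <- function(phase, stage_fractions) {
  stage <- phase_to_stage(phase, stage_fractions)
  lo <- c(0, cumsum(stage_fractions))[match(stage, CYCLE_STAGES)]
  prog <- (phase - lo) / stage_fractions[stage]
  list(stage = stage, progress = pmin(pmax(prog, 0), 1))
}

# Radial distance map from the patch centre, memoised per size.
.dist_cache <- new.env(parent = emptyenv())
patch_dist <- function(p) {
  key <- as.character(p)
  if (is.null(.dist_cache[[key]])) {
    ax <- seq_len(p) - (p + 1) / 2
    .dist_cache[[key]] <- sqrt(outer(ax^2, ax^2, "+"))
  }
  .dist_cache[[key]]
}

# Continuous appearance model: amplitude, radius and replication-foci
# parameters are piecewise-linear functions of phase anchored at stage
# centres, so consecutive frames change gradually (as in live PCNA movies)
# and the only appearance jump is the division itself.
appearance_at <- function(phase, fractions) {
  breaks <- c(0, cumsum(fractions))        # G1 eS mS lS G2 M boundaries
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  m_start <- breaks[6]
  f_m <- fractions[["M"]]
  # brightness keyframes: dim G1, rising through S to a late-S maximum,
  # dip in G2, condensation burst in early M
  kx <- c(0, centres[1:5], m_start, m_start + 0.4 * f_m, 1)
  ky <- c(0.28, 0.31, 0.44, 0.50, 0.62, 0.50, 0.52, 0.95, 0.95)
  amp <- stats::approx(kx, ky, xout = phase, rule = 2)$y
  # radius: interphase growth, then rapid condensation during early M
  if (phase < m_start) {
    rad <- 0.78 + 0.5 * phase / m_start
  } else {
    q <- (phase - m_start) / f_m
    rad <- 1.28 - (1.28 - 0.62) * min(q / 0.4, 1)
  }
  # replication foci across the whole S window: many-small -> few-large,
  # fading in and out at the S boundaries
  s_lo <- breaks[2]; s_hi <- breaks[5]
  s_prog <- (phase - s_lo) / (s_hi - s_lo)
  foci <- NULL
  if (s_prog > 0 && s_prog < 1) {
    ramp <- min(1, s_prog / 0.12, (1 - s_prog) / 0.12)
    foci <- list(n = round(24 - 18 * s_prog),
                 sigma_frac = 0.030 + 0.055 * s_prog,
                 gain = (0.20 + 0.22 * s_prog) * ramp)
  }
  list(amp = amp, radius_frac = rad, foci = foci)
}

#' Render one synthetic nucleus patch at a given cycle phase
#'
#' Appearance is a deterministic function of phase plus the current RNG
#' state, and evolves continuously along the cycle: the nucleus grows through
#' G1/S/G2 while its brightness rises to a late-S maximum; punctate PCNA-like
#' replication foci appear across S, shifting from many-small (early S)
#' through fewer-larger (mid S) to few-large-bright (late S); during M the
#' nucleus condenses rapidly into a small bright object. Pixels are clamped
#' to `[0, 1]` and quantised to a 16-bit grid.
#'
#' @param phase Cycle fraction in `[0, 1)`.
#' @param config A [synthetic_config()].
#' @param intensity_scale Multiplier applied before noise (used by
#'   [simulate_trajectory()] for photobleaching).
#' @return `patch_size x patch_size` numeric matrix in `[0, 1]`.
#' @export
render_cell <- function(phase, config = synthetic_config(), intensity_scale = 1) {
  if (length(phase) != 1 || !is.finite(phase) || phase < 0 || phase >= 1) {
    stop("phase must be a single value in [0, 1)")
  }
  p <- config$patch_size
  d <- patch_dist(p)
  app <- appearance_at(phase, config$stage_fractions)

  r0 <- 0.22 * p
  radius <- app$radius_frac * r0
  edge <- 0.08 * p
  img <- app$amp / (1 + exp((d - radius) / edge))

  if (!is.null(app$foci)) {
    ctr <- (p + 1) / 2
    ax <- seq_len(p)
    for (i in seq_len(app$foci$n)) {
      rr <- radius * 0.8 * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cx <- ctr + rr * cos(th)
      cy <- ctr + rr * sin(th)
      sg <- app$foci$sigma_frac * p
      g <- outer(exp(-((ax - cx)^2) / (2 * sg^2)),
                 exp(-((ax - cy)^2) / (2 * sg^2)))
      img <- img + app$foci$gain * g
    }
  }

  img <- img * intensity_scale
  if (config$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, config$noise_sigma)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  # quantise to the 16-bit grid of the emulated camera; also makes TIFF
  # round-trips exact
  img <- round(img * 65535) / 65535
  matrix(img, p, p)
}

#' Simulate one single-cell trajectory with ground truth
#'
#' Advances the cycle phase by `1/period_frames` per frame (optionally
#' jittered), renders each frame with [render_cell()], applies photobleaching,
#' and records the ground truth: per-frame phase, stage, division frames
#' (phase wrap-arounds) and the true period in minutes.
#'
#' @param config A [synthetic_config()].
#' @param cell_id Identifier stored in the trajectory.
#' @return A `cell_trajectory`: list with `images` (patch x patch x n_frames
#'   array), `cell_id`, `time_min`, and `truth` (list with `phase`, `stage`,
#'   `division_frames`, `true_period_minutes`).
#' @examples
#' set.seed(1)
#' tr <- simulate_trajectory(synthetic_config(patch_size = 16, n_frames = 20,
#'                                            period_frames = 16))
#' @export
simulate_trajectory <- function(config = synthetic_config(), cell_id = "cell_001") {
  n <- config$n_frames
  p <- config$patch_size
  phase <- numeric(n)
  division <- integer(0)
  ph <- (config$initial_phase +
           stats::rnorm(1, 0, config$initial_phase_sd)) %% 1
  images <- array(0, dim = c(p, p, n))
  base_step <- 1 / config$period_frames
  for (t in seq_len(n)) {
    phase[t] <- ph
    scale <- (1 - config$photobleach_rate)^(t - 1)
    images[, , t] <- render_cell(ph, config, intensity_scale = scale)
    step <- base_step * (1 + config$period_jitter * stats::rnorm(1))
    step <- max(step, 1e-6)
    nxt <- ph + step
    if (nxt >= 1 && t < n) division <- c(division, t + 1L)
    ph <- nxt %% 1
  }
  truth <- list(phase = phase,
                stage = phase_to_stage(phase, config$stage_fractions),
                division_frames = division,
                true_period_minutes = config$period_frames * config$frame_interval)
  structure(list(images = images,
                 cell_id = cell_id,
                 time_min = (seq_len(n) - 1) * config$frame_interval,
                 stage = truth$stage,
                 truth = truth,
                 config = config),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("Cell trajectory ", x$cell_id, ": ", dim(x$images)[3], " frames of ",
      dim(x$images)[1], "x", dim(x$images)[2], " px (",
      round(max(x$time_min) / 60, 2), " h)\n", sep = "")
  invisible(x)
}

#' Simulate a dataset of independent single-cell trajectories
#'
#' Each cell gets its own RNG stream derived from the master seed in `config`,
#' so the dataset is reproducible as a whole and per cell.
#'
#' @param config A [synthetic_config()].
#' @param n_cells Number of trajectories.
#' @return List of `cell_trajectory` objects.
#' @export
simulate_dataset <- function(config = synthetic_config(), n_cells = 10) {
  stopifnot(n_cells >= 1)
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  purrr::map2(cell_seeds, seq_len(n_cells), function(s, i) {
    set.seed(s)
    simulate_trajectory(config, cell_id = sprintf("cell_%03d", i))
  })
}

#' Tabulate a trajectory dataset as a tidy manifest
#'
#' @param dataset List of `cell_trajectory` objects.
#' @return Tibble with one row per frame: `cell_id`, `frame`, `time_min`,
#'   `phase`, `stage`, `division_flag`.
#' @export
trajectory_manifest <- function(dataset) {
  if (inherits(dataset, "cell_trajectory")) dataset <- list(dataset)
  purrr::map_dfr(dataset, function(tr) {
    n <- dim(tr$images)[3]
    tibble::tibble(cell_id = tr$cell_id,
                   frame = seq_len(n),
                   time_min = tr$time_min,
                   phase = if (!is.null(tr$truth)) tr$truth$phase else NA_real_,
                   stage = if (!is.null(tr$stage)) tr$stage else NA_character_,
                   division_flag = if (!is.null(tr$truth))
                     seq_len(n) %in% tr$truth$division_frames else FALSE)
  })
}

#' Total imaging duration of a trajectory in hours
#'
#' Span of the frame timestamps (first to last frame).
#'
#' @param trajectory A `cell_trajectory` or anything with a `time_min` field.
#' @return Duration in hours.
#' @examples
#' cfg <- synthetic_config(patch_size = 16, n_frames = 20, period_frames = 16)
#' @export
imaging_duration_hours <- function(trajectory) {
  (max(trajectory$time_min) - min(trajectory$time_min)) / 60
}
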