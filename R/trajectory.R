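# Single-cell trajectory analytics on projected manifold coordinates:
# smoothing, prominence-based extremum detection, key-stage assignment on the
# first axis, and cycle-duration estimation on the second.

new_curve <- function(raw, smoothed, method, time_min) {
  structure(list(raw = raw, smoothed = smoothed, method = method,
                 time_min = time_min), class = "trajectory_curve")
}

#' @export
print.trajectory_curve <- function(x, ...) {
  cat("Trajectory curve: ", length(x$raw), " frames, smoothing: ", x$method,
      "\n", sep = "")
  invisible(x)
}

#' Smooth a projected trajectory with a cubic smoothing spline
#'
#' Fits a cubic B-spline to the per-frame series and evaluates it at the
#' original frames. `smoothing_factor` maps to the spline's smoothing
#' parameter: 0 gives the interpolating spline through every point, larger
#' values trade fidelity for smoothness.
#'
#' @param series Numeric per-frame values (length >= 8).
#' @param smoothing_factor Non-negative smoothness control (`spar` of
#'   [stats::smooth.spline()]; 0 = interpolation).
#' @param time_min Optional per-frame timestamps (minutes).
#' @return A `trajectory_curve`.
#' @export
smooth_bspline <- function(series, smoothing_factor = 0.6, time_min = NULL) {
  n <- length(series)
  if (n < 8) stop("series too short to smooth (need >= 8 frames)")
  stopifnot(smoothing_factor >= 0)
  x <- seq_len(n)
  if (smoothing_factor == 0 || stats::var(series) == 0) {
    sm <- series
  } else {
    fit <- stats::smooth.spline(x, series, spar = smoothing_factor,
                                cv = NA, all.knots = TRUE)
    sm <- stats::predict(fit, x)$y
  }
  new_curve(series, sm, "bspline", time_min %||% (x - 1))
}

#' Centered running average of a projected trajectory
#'
#' Moving mean with edge truncation: windows are shortened near the
#' boundaries so the output has the same length as the input. `window = 1`
#' is the identity.
#'
#' @param series Numeric per-frame values.
#' @param window Window width in frames (default 10).
#' @param time_min Optional per-frame timestamps (minutes).
#' @return A `trajectory_curve`.
#' @export
running_average <- function(series, window = 10, time_min = NULL) {
  n <- length(series)
  if (window < 1 || window > n) stop("window must be in [1, length(series)]")
  sm <- zoo::rollapply(series, width = window, FUN = mean, partial = TRUE,
                       align = "center")
  new_curve(series, as.numeric(sm), "running_average",
            time_min %||% (seq_len(n) - 1))
}

# Topographic prominence of an interior local maximum at index i: on each
# side, the lowest point reached before the curve exceeds the peak height (or
# before the signal edge); prominence is height minus the higher base.
peak_prominence <- function(y, i) {
  n <- length(y)
  h <- y[i]
  side_base <- function(idx) {
    if (length(idx) == 0) return(-Inf)
    m <- Inf
    for (j in idx) {
      if (y[j] > h) break
      m <- min(m, y[j])
    }
    m
  }
  left <- side_base(rev(seq_len(i - 1)))
  right <- side_base(if (i < n) seq.int(i + 1, n) else integer(0))
  h - max(left, right)
}

#' Detect peaks and troughs of a smoothed trajectory
#'
#' Interior local maxima (and minima, as maxima of the negated curve) whose
#' topographic prominence reaches `min_prominence`. The default prominence
#' threshold is a quarter of the curve's range.
#'
#' @param curve A `trajectory_curve` (its smoothed series is analysed).
#' @param min_prominence Minimum prominence; default `0.25 * range`.
#' @return List with tibbles `peaks` and `troughs`
#'   (`frame`, `value`, `prominence`), each sorted by frame (possibly empty).
#' @export
find_extrema <- function(curve, min_prominence = NULL) {
  y <- if (inherits(curve, "trajectory_curve")) curve$smoothed else curve
  n <- length(y)
  if (is.null(min_prominence)) min_prominence <- 0.25 * diff(range(y))
  locate <- function(v) {
    idx <- integer(0)
    d <- diff(v)
    s <- sign(d)
    # carry the previous slope sign through flat runs
    for (j in seq_along(s)) if (s[j] == 0 && j > 1) s[j] <- s[j - 1]
    turns <- which(s[-1] < 0 & s[-length(s)] > 0) + 1L
    if (length(turns) == 0) return(tibble::tibble(frame = integer(0),
                                                  value = numeric(0),
                                                  prominence = numeric(0)))
    prom <- vapply(turns, function(i) peak_prominence(v, i), numeric(1))
    keep <- prom >= min_prominence
    tibble::tibble(frame = turns[keep], value = v[turns[keep]],
                   prominence = prom[keep]) |> dplyr::arrange(.data$frame)
  }
  peaks <- locate(y)
  troughs <- locate(-y)
  troughs$value <- -troughs$value
  list(peaks = peaks, troughs = troughs)
}

#' Assign key cell-cycle stages to trajectory extrema
#'
#' On an orientation-normalised first projection axis (mitosis at the
#' minimum), the two lowest troughs mark consecutive mitoses bounding a full
#' cycle. Within the cycle, the first peak is G1, the following trough early
#' S, and the highest peak late S. Inflection frames (zero crossings of the
#' second difference of the smoothed curve) between consecutive key extrema
#' are annotated as transitions.
#'
#' @param curve A `trajectory_curve` of the first projection axis.
#' @param events Optional precomputed [find_extrema()] output.
#' @param min_prominence Passed to [find_extrema()] when `events` is `NULL`;
#'   defaults to 0 so that the two lowest troughs are chosen among all
#'   interior minima (mitoses near the recording edges keep their troughs).
#' @return A `key_events` object: list with `events` (tibble `frame`, `type`,
#'   `stage`), `inflections` (frames), and `complete` flag.
#' @export
assign_key_stages <- function(curve, events = NULL, min_prominence = 0) {
  if (is.null(events)) events <- find_extrema(curve, min_prominence)
  troughs <- events$troughs
  peaks <- events$peaks
  rows <- list()
  complete <- FALSE
  if (nrow(troughs) >= 2) {
    m2 <- troughs[order(troughs$value), ][1:2, ]
    m2 <- m2[order(m2$frame), ]
    rows$m <- tibble::tibble(frame = m2$frame, type = "trough", stage = "M")
    lo <- m2$frame[1]; hi <- m2$frame[2]
    pk_in <- peaks[peaks$frame > lo & peaks$frame < hi, ]
    tr_in <- troughs[troughs$frame > lo & troughs$frame < hi, ]
    if (nrow(pk_in) >= 1) {
      # the highest in-cycle peak is late S; the first peak, when distinct,
      # is G1, with the trough between them early S
      lateS <- pk_in$frame[which.max(pk_in$value)]
      g1 <- pk_in$frame[1]
      rows$ls <- tibble::tibble(frame = lateS, type = "peak", stage = "lateS")
      if (g1 != lateS) {
        rows$g1 <- tibble::tibble(frame = g1, type = "peak", stage = "G1")
        es <- tr_in$frame[tr_in$frame > g1 & tr_in$frame < lateS]
        if (length(es) >= 1) {
          rows$es <- tibble::tibble(frame = es[1], type = "trough",
                                    stage = "earlyS")
        }
      }
      complete <- TRUE
    }
  } else {
    warning("fewer than 2 troughs: no full cycle; returning partial assignment")
  }
  ev <- if (length(rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$frame)
  } else {
    tibble::tibble(frame = integer(0), type = character(0), stage = character(0))
  }
  y <- curve$smoothed
  d2 <- diff(diff(y))
  infl <- which(d2[-1] * d2[-length(d2)] < 0) + 1L
  if (nrow(ev) >= 2) {
    infl <- infl[infl > min(ev$frame) & infl < max(ev$frame)]
  } else {
    infl <- integer(0)
  }
  structure(list(events = ev, inflections = infl, complete = complete,
                 cycle_duration_hours = NA_real_),
            class = "key_events")
}

#' @export
print.key_events <- function(x, ...) {
  cat("Key cycle events (", if (x$complete) "complete" else "partial",
      " cycle):\n", sep = "")
  print(x$events)
  invisible(x)
}

#' Inferred late-S frame of a trajectory
#'
#' The frame of the highest peak between the two mitosis troughs; feeds the
#' G1-G2 constraint.
#'
#' @param events A `key_events` object.
#' @return Frame index.
#' @export
infer_lateS_time <- function(events) {
  ls <- events$events$frame[events$events$stage == "lateS"]
  if (length(ls) == 0) {
    stop("no late-S peak assigned; G1-G2 constraint cannot be applied")
  }
  ls[1]
}

#' Estimate cell-cycle duration from the second projection axis
#'
#' Division events appear as sudden drops of the running-average curve; the
#' time between the two most prominent troughs estimates one cycle. Invariant
#' to adding a constant to the series and to uniform amplitude scaling (the
#' default prominence threshold scales with the curve range).
#'
#' @param curve A `trajectory_curve` (typically [running_average()] of the
#'   second projection axis).
#' @param frame_interval Minutes between frames (default 5.9).
#' @param min_prominence Minimum trough prominence. Defaults to 0: every
#'   interior local minimum competes and the two most prominent win, which
#'   keeps cycle-boundary troughs near the start or end of a recording in
#'   play (their prominence is clipped by the series edge).
#' @return Duration in hours, or `NA` (with a warning) when fewer than two
#'   troughs are found.
#' @examples
#' s <- rep(c(seq(0, 1, length.out = 30), seq(1, 0, length.out = 3)), 3)
#' estimate_cycle_duration(running_average(s, 5), frame_interval = 5.9)
#' @export
estimate_cycle_duration <- function(curve, frame_interval = 5.9,
                                    min_prominence = 0) {
  ex <- find_extrema(curve, min_prominence)
  tr <- ex$troughs
  if (nrow(tr) < 2) {
    warning("fewer than 2 troughs; cannot estimate cycle duration")
    return(NA_real_)
  }
  two <- tr[order(-tr$prominence), ][1:2, ]
  abs(diff(sort(two$frame))) * frame_interval / 60
}
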