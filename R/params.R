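#' Peak velocity of a passive stretch
#'
#' Maximum absolute angular velocity over the movement window of a filtered
#' trial. When the movement target was not reached by the nominal movement
#' end (angle more than 1 deg from target), the search window is extended
#' to the end of the controller's persistence (capped at the hold end), so
#' that slowly driven arms are still credited with their true maximum.
#'
#' @param trial A filtered \code{kaps_trial}.
#' @param windows \code{kaps_windows} from \code{\link{segment}}.
#' @param timeout_ms Controller persistence cap for the extended search.
#' @return Peak velocity, deg/s (magnitude, >= 0).
#' @export
peak_velocity <- function(trial, windows, timeout_ms = 7000) {
  stopifnot(inherits(trial, "kaps_trial"), inherits(windows, "kaps_windows"))
  i0 <- .t2i(trial, windows$movement[1])
  i1 <- .t2i(trial, windows$movement[2])
  n <- nrow(trial$data)
  i1 <- min(i1, n)
  if (i1 < i0) stop("parameter error: empty movement window")
  end_angle <- trial$data$angle_deg[i1]
  if (abs(end_angle - trial$meta$target_angle_deg) > 1) {
    i1 <- min(.t2i(trial, min(windows$hold_end_ms,
                              windows$movement[1] + timeout_ms)), n)
  }
  max(abs(trial$data$velocity_deg_s[i0:i1]))
}

#' Final angle of a passive stretch
#'
#' Elbow angle at the final recorded position before the next movement,
#' estimated as the mean of the filtered angle over the last 50 ms of the
#' hold (noise-robust). Falls back to the last sample with a warning when
#' the hold is shorter than 50 ms.
#'
#' @inheritParams peak_velocity
#' @return Final angle, deg.
#' @export
final_angle <- function(trial, windows) {
  stopifnot(inherits(trial, "kaps_trial"), inherits(windows, "kaps_windows"))
  n <- nrow(trial$data)
  i1 <- min(.t2i(trial, windows$hold_end_ms), n)
  i0 <- .t2i(trial, windows$hold_end_ms - 49)
  if (i0 < 1 || windows$hold_end_ms - windows$movement[2] < 49) {
    warning("hold shorter than 50 ms; final angle from last sample only")
    return(trial$data$angle_deg[i1])
  }
  mean(trial$data$angle_deg[i0:i1])
}

#' Creep (post-stretch release)
#'
#' Direction-specific signed difference between the angle 1000 ms after the
#' nominal movement end and the final angle:
#' \itemize{
#'   \item flexion: (angle at 1000 ms post-stretch) - final angle
#'   \item extension: final angle - (angle at 1000 ms post-stretch)
#' }
#' so positive creep always reflects continued travel toward the final
#' angle in the direction of the imposed movement.
#'
#' @inheritParams peak_velocity
#' @param direction Movement direction; defaults to the trial metadata.
#' @return Creep, deg. The attribute \code{"clipped"} is \code{TRUE} when
#'   the post-stretch sample had to be clipped to the hold end.
#' @export
creep <- function(trial, windows, direction = trial$meta$direction) {
  stopifnot(inherits(trial, "kaps_trial"), inherits(windows, "kaps_windows"))
  n <- nrow(trial$data)
  ip <- min(.t2i(trial, windows$post_stretch_ms), n)
  a_post <- trial$data$angle_deg[ip]
  fa <- suppressWarnings(final_angle(trial, windows))
  val <- switch(direction,
                flexion = a_post - fa,
                extension = fa - a_post,
                stop("direction must be 'flexion' or 'extension'"))
  structure(val, clipped = isTRUE(windows$clipped))
}

#' Aggregate per-trial parameter values
#'
#' Collapses the (typically 3) same-duration trial values of a parameter to
#' one value per subject. The aggregator is the mean by default and is
#' configurable.
#'
#' @param values Numeric vector of per-trial values (length >= 1; NAs
#'   dropped).
#' @param method "mean" or "median".
#' @return A single aggregate value.
#' @export
aggregate_trials <- function(values, method = c("mean", "median")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  switch(method, mean = mean(values), median = median(values))
}

#' Between-arm difference parameters
#'
#' The three between-arm differences for one direction and duration:
#' absolute difference in peak velocity, and signed differences (more
#' affected / non-dominant minus less affected / dominant) in final angle
#' and creep.
#'
#' @param test Named list or one-row data.frame with \code{peak_velocity},
#'   \code{final_angle}, \code{creep}, \code{direction},
#'   \code{duration_ms} for the more-affected (test) arm.
#' @param reference Same for the less-affected (reference) arm.
#' @return List with \code{d_peak_velocity} (>= 0), \code{d_final_angle}
#'   and \code{d_creep} (signed).
#' @export
between_arm_differences <- function(test, reference) {
  if (!identical(test$direction, reference$direction))
    stop("parameter error: direction mismatch between arms")
  if (!is.null(test$duration_ms) &&
      !identical(test$duration_ms, reference$duration_ms))
    stop("parameter error: duration mismatch between arms")
  list(d_peak_velocity = abs(test$peak_velocity - reference$peak_velocity),
       d_final_angle = test$final_angle - reference$final_angle,
       d_creep = test$creep - reference$creep)
}

# time-aligned reference velocity: mean filtered velocity across the
# reference-arm trials, aligned at command onset
.reference_velocity <- function(ref_trials) {
  vs <- lapply(ref_trials, function(tr) {
    i0 <- .t2i(tr, tr$meta$onset_ms)
    tr$data$velocity_deg_s[i0:nrow(tr$data)]
  })
  len <- min(lengths(vs))
  rowMeans(do.call(cbind, lapply(vs, function(v) v[seq_len(len)])))
}

#' Between-arm catch angle
#'
#' Detects the catch as the first sample in the movement window at which
#' the affected-arm velocity deviates from the nominal reference-arm
#' velocity by more than the velocity-difference threshold. The nominal
#' reference is, by default, the time-aligned (at command onset) mean of
#' the reference-arm trials; alternatively each affected trial is compared
#' to the matching reference trial (\code{mode = "trial_to_trial"}). The
#' crossing is converted to angular excursion from the trial's start, the
#' median across trials with a crossing is reported (positive for
#' extension, negative for flexion), and \code{NA} is returned when no
#' trial crosses.
#'
#' @param test_trials List of filtered \code{kaps_trial}s for the affected
#'   arm (same direction and duration).
#' @param ref_trials List of filtered reference-arm trials.
#' @param threshold Velocity-difference threshold, deg/s; must be > 0.
#'   Default is the packaged normative threshold
#'   \code{\link{kaps_default_threshold}()}.
#' @param mode Reference construction, "trial_to_mean" (default) or
#'   "trial_to_trial".
#' @return Catch angle in degrees of excursion (signed by direction), or
#'   \code{NA_real_} when absent.
#' @export
catch_angle <- function(test_trials, ref_trials,
                        threshold = kaps_default_threshold(),
                        mode = c("trial_to_mean", "trial_to_trial")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("parameter error: threshold must be a positive number (deg/s)")
  stopifnot(length(test_trials) >= 1, length(ref_trials) >= 1)
  dirs <- unique(vapply(c(test_trials, ref_trials),
                        function(t) t$meta$direction, ""))
  if (length(dirs) != 1)
    stop("parameter error: direction mismatch across trials")
  sgn <- if (dirs == "extension") 1 else -1
  vref_mean <- if (mode == "trial_to_mean") .reference_velocity(ref_trials)

  crossings <- vapply(seq_along(test_trials), function(i) {
    tr <- test_trials[[i]]
    i0 <- .t2i(tr, tr$meta$onset_ms)
    i1 <- min(.t2i(tr, tr$meta$onset_ms + tr$meta$nominal_duration_ms),
              nrow(tr$data))
    v <- tr$data$velocity_deg_s[i0:i1]
    vr <- if (mode == "trial_to_mean") vref_mean else
      .reference_velocity(ref_trials[(i - 1) %% length(ref_trials) + 1])
    len <- min(length(v), length(vr))
    dv <- abs(v[seq_len(len)] - vr[seq_len(len)])
    k <- which(dv > threshold)
    if (!length(k)) return(NA_real_)
    abs(tr$data$angle_deg[i0 + k[1] - 1L] - tr$data$angle_deg[i0])
  }, numeric(1))

  if (all(is.na(crossings))) return(NA_real_)
  sgn * median(crossings, na.rm = TRUE)
}

# per-trial peak of the |velocity difference| trace against the nominal
# reference; the basis on which the normative velocity-difference threshold
# is fitted
.velocity_difference_peaks <- function(test_trials, ref_trials) {
  vref <- .reference_velocity(ref_trials)
  vapply(test_trials, function(tr) {
    i0 <- .t2i(tr, tr$meta$onset_ms)
    i1 <- min(.t2i(tr, tr$meta$onset_ms + tr$meta$nominal_duration_ms),
              nrow(tr$data))
    v <- tr$data$velocity_deg_s[i0:i1]
    len <- min(length(v), length(vref))
    max(abs(v[seq_len(len)] - vref[seq_len(len)]))
  }, numeric(1))
}

.is_test_arm <- function(arm) arm %in% c("affected", "non_dominant")

#' Extract the KAPS parameter set for one subject
#'
#' Filters all trials of a subject and computes, per movement direction and
#' duration: the single-arm parameters (peak velocity, final angle, creep)
#' for both arms, the three between-arm differences, the between-arm catch
#' angle, and the per-subject peak of the between-arm velocity-difference
#' trace (the quantity on which the normative threshold is fitted).
#'
#' @param trials List of \code{kaps_trial}s for one subject (both arms).
#' @param threshold Velocity-difference threshold for catch detection,
#'   deg/s.
#' @param durations_ms Durations to extract (default: all present).
#' @param cutoff_hz Filter cutoff, Hz.
#' @param aggregate Across-trial aggregator, "mean" or "median".
#' @param catch_mode Passed to \code{\link{catch_angle}}.
#' @return A data.frame of class \code{kaps_parameters}, one row per
#'   direction x duration, with columns \code{subject_id}, \code{direction},
#'   \code{duration_ms}, test-arm and reference-arm single-limb parameters
#'   (\code{peak_velocity}, \code{final_angle}, \code{creep},
#'   \code{ref_peak_velocity}, ...), \code{d_peak_velocity},
#'   \code{d_final_angle}, \code{d_creep}, \code{vdiff_peak},
#'   \code{catch_angle}, plus per-trial values in list columns.
#' @export
extract_subject_parameters <- function(trials,
                                       threshold = kaps_default_threshold(),
                                       durations_ms = NULL, cutoff_hz = 10,
                                       aggregate = "mean",
                                       catch_mode = "trial_to_mean") {
  stopifnot(length(trials) >= 2)
  filt <- lapply(trials, filter_trial, cutoff_hz = cutoff_hz)
  meta <- data.frame(
    i = seq_along(filt),
    arm = vapply(filt, function(t) t$meta$arm, ""),
    direction = vapply(filt, function(t) t$meta$direction, ""),
    duration = vapply(filt, function(t) t$meta$nominal_duration_ms, 0))
  subject_id <- filt[[1]]$meta$subject_id
  if (is.null(durations_ms)) durations_ms <- sort(unique(meta$duration))

  single <- function(tr_list) {
    vals <- lapply(tr_list, function(tr) {
      w <- suppressWarnings(segment(tr))
      list(pv = peak_velocity(tr, w), fa = final_angle(tr, w),
           cr = as.numeric(creep(tr, w)))
    })
    list(pv = vapply(vals, `[[`, 0, "pv"),
         fa = vapply(vals, `[[`, 0, "fa"),
         cr = vapply(vals, `[[`, 0, "cr"))
  }

  rows <- list()
  for (dur in durations_ms) {
    for (dir in c("extension", "flexion")) {
      sel <- meta$direction == dir & meta$duration == dur
      test_i <- meta$i[sel & .is_test_arm(meta$arm)]
      ref_i <- meta$i[sel & !.is_test_arm(meta$arm)]
      if (!length(test_i) || !length(ref_i)) next
      st <- single(filt[test_i])
      sr <- single(filt[ref_i])
      agg <- function(x) aggregate_trials(x, aggregate)
      test <- list(peak_velocity = agg(st$pv), final_angle = agg(st$fa),
                   creep = agg(st$cr), direction = dir, duration_ms = dur)
      ref <- list(peak_velocity = agg(sr$pv), final_angle = agg(sr$fa),
                  creep = agg(sr$cr), direction = dir, duration_ms = dur)
      d <- between_arm_differences(test, ref)
      ca <- catch_angle(filt[test_i], filt[ref_i], threshold = threshold,
                        mode = catch_mode)
      vdp <- agg(.velocity_difference_peaks(filt[test_i], filt[ref_i]))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, direction = dir, duration_ms = dur,
        peak_velocity = test$peak_velocity, final_angle = test$final_angle,
        creep = test$creep,
        ref_peak_velocity = ref$peak_velocity,
        ref_final_angle = ref$final_angle, ref_creep = ref$creep,
        d_peak_velocity = d$d_peak_velocity,
        d_final_angle = d$d_final_angle, d_creep = d$d_creep,
        vdiff_peak = vdp, catch_angle = ca,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kaps_parameters", "data.frame")
  out
}
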