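#' Commanded half-cosine stretch profile
#'
#' The commanded elbow trajectory for a passive stretch: a half-cosine
#' position profile \eqn{\theta(t) = \theta_s + (\theta_e - \theta_s)
#' (1 - \cos(\pi t / T)) / 2} for \eqn{t \le T}, clamped at the target for
#' \eqn{t > T}. Velocity is the analytic derivative (a single sine lobe)
#' and is zero at both endpoints.
#'
#' @param t_rel_ms Time since movement onset, ms (vectorised).
#' @param duration_ms Nominal movement duration T, ms. Must be > 0.
#' @param start_angle,end_angle Commanded endpoints, deg.
#' @return A data.frame with columns \code{angle} (deg) and
#'   \code{velocity} (deg/s).
#' @examples
#' commanded_profile(c(0, 300, 600), 600, 145, 65)
#' @export
commanded_profile <- function(t_rel_ms, duration_ms, start_angle, end_angle) {
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 ||
      !is.finite(duration_ms) || duration_ms <= 0)
    stop("invalid protocol: duration must be a positive number of ms")
  stopifnot(all(t_rel_ms >= 0))
  t <- t_rel_ms / 1000
  T <- duration_ms / 1000
  d <- end_angle - start_angle
  ph <- pi * pmin(t, T) / T
  angle <- start_angle + d * (1 - cos(ph)) / 2
  velocity <- ifelse(t >= T, 0, d * pi / (2 * T) * sin(ph))
  data.frame(angle = angle, velocity = velocity)
}

.direction_endpoints <- function(protocol, direction, start_angle) {
  target <- switch(direction,
                   flexion = protocol$flexed_angle,
                   extension = protocol$extended_angle,
                   stop("direction must be 'flexion' or 'extension'"))
  hold <- switch(direction,
                 flexion = protocol$intra_trial_wait_ms,
                 extension = protocol$inter_trial_wait_ms)
  list(target = target, hold_ms = hold)
}

#' Simulate one passive-stretch movement plus hold
#'
#' Integrates the limb equation of motion
#' \eqn{I \ddot\theta = \tau_{robot} + \tau_{passive} + \tau_{spastic} +
#' \tau_{contracture}} with fixed-step RK4 at the recording rate. During the
#' commanded movement the robot torque is the saturated PD + feedforward
#' law; afterwards a proportional hold torque pulls toward the target. The
#' recording covers the movement and the full hold. Gaussian measurement
#' noise is added to the recorded angle only; velocity is recorded from the
#' true state.
#'
#' If the target is not reached (within 1 deg) by the end of the hold (or by
#' the controller timeout if that comes first), the achieved angle is
#' reported as the next movement's start angle, mirroring the start-angle
#' carry-over of the robot protocol.
#'
#' @param limb A \code{\link{limb_config}}.
#' @param robot A \code{\link{robot_config}}.
#' @param protocol A \code{\link{protocol_config}}.
#' @param direction "flexion" or "extension".
#' @param duration_ms Nominal movement duration, ms.
#' @param start_angle Actual start angle, deg (defaults to the protocol
#'   endpoint opposite the target).
#' @param seed Optional integer seed for the measurement noise.
#' @param subject_id,arm,trial_index Metadata carried into the recording.
#' @return A \code{kaps_trial}: list with \code{meta} (schema metadata) and
#'   \code{data} (data.frame \code{time_ms}, \code{angle_deg},
#'   \code{velocity_deg_s}). The attribute \code{"truth"} carries the
#'   noise-free state, robot torque, spastic activation and the achieved
#'   next start angle for use as a test oracle.
#' @examples
#' tr <- simulate_trial(limb_config(), robot_config(), protocol_config(),
#'                      "extension", 600, seed = 1)
#' str(tr$data)
#' @export
simulate_trial <- function(limb, robot, protocol = protocol_config(),
                           direction = c("extension", "flexion"),
                           duration_ms = 600, start_angle = NULL,
                           seed = NULL, subject_id = "sim",
                           arm = "affected", trial_index = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(limb, "kaps_limb"), inherits(robot, "kaps_robot"),
            inherits(protocol, "kaps_protocol"))
  if (robot$timeout_ms < duration_ms)
    stop("invalid protocol: timeout_ms is shorter than the nominal duration")
  ep <- .direction_endpoints(protocol, direction, start_angle)
  if (is.null(start_angle))
    start_angle <- if (direction == "flexion") protocol$extended_angle
                   else protocol$flexed_angle
  if (start_angle < 55 || start_angle > 155)
    stop("start_angle outside the physical range of the elbow")
  if (!is.null(seed)) set.seed(seed)

  dt_ms <- 1000 / protocol$sample_rate_hz
  record_ms <- duration_ms + ep$hold_ms
  core <- .simulate_trial_core(start_angle, ep$target, duration_ms,
                               record_ms, dt_ms, unclass(robot),
                               unclass(limb))
  n <- length(core$angle)
  time_ms <- (seq_len(n) - 1) * dt_ms
  angle_rec <- core$angle +
    if (limb$noise_sd > 0) rnorm(n, 0, limb$noise_sd) else 0

  end_angle <- core$angle[n]
  reached <- abs(end_angle - ep$target) <= 1
  meta <- list(subject_id = subject_id, arm = arm, direction = direction,
               nominal_duration_ms = duration_ms,
               trial_index = as.integer(trial_index),
               onset_ms = 0, start_angle_deg = start_angle,
               target_angle_deg = ep$target,
               next_onset_ms = record_ms,
               sample_rate_hz = protocol$sample_rate_hz)
  trial <- structure(
    list(meta = meta,
         data = data.frame(time_ms = time_ms, angle_deg = angle_rec,
                           velocity_deg_s = core$velocity)),
    class = "kaps_trial")
  attr(trial, "truth") <- list(angle = core$angle,
                               torque = core$torque,
                               spastic_activation = core$spastic_activation,
                               target_reached = reached,
                               next_start_angle = if (reached) ep$target
                                                  else end_angle)
  trial
}

# where the positioning phase can actually place the arm before the first
# movement: with a contracture the hold pull toward full extension balances
# the contracture stiffness short of the protocol start angle
.resting_start <- function(limb, robot, protocol) {
  ext <- protocol$extended_angle
  if (is.na(limb$contracture_limit) || limb$contracture_stiffness <= 0 ||
      limb$contracture_limit >= ext)
    return(ext)
  (robot$hold_gain * ext +
     limb$contracture_stiffness * limb$contracture_limit) /
    (robot$hold_gain + limb$contracture_stiffness)
}

#' Simulate the full protocol for one subject
#'
#' Runs the complete trial sequence for both arms: for each nominal duration
#' in protocol order (slowest first), \code{trials_per_duration} trials of a
#' flexion movement, intra-trial wait, extension movement, inter-trial wait.
#' Start angles chain across movements: a movement that fails to reach its
#' target hands its achieved angle to the next movement. The test arm (more
#' affected / non-dominant) is simulated first. Deterministic given
#' \code{seed}.
#'
#' @param test_limb Limb config of the more-affected / non-dominant arm.
#' @param reference_limb Limb config of the less-affected / dominant arm.
#'   Pass configs with identical values for a control subject; measurement
#'   noise is drawn independently per arm.
#' @param robot,protocol Robot and protocol configs.
#' @param seed Integer seed (required for reproducibility).
#' @param subject_id Subject identifier.
#' @param arm_labels Length-2 character: labels for the test and reference
#'   arm, e.g. \code{c("affected", "less_affected")} or
#'   \code{c("non_dominant", "dominant")}.
#' @return List of \code{kaps_trial} objects.
#' @export
simulate_subject <- function(test_limb, reference_limb,
                             robot = robot_config(),
                             protocol = protocol_config(), seed = 1,
                             subject_id = "S1",
                             arm_labels = c("affected", "less_affected")) {
  stopifnot(length(arm_labels) == 2)
  if (!is.null(seed)) set.seed(seed)
  limbs <- list(test_limb, reference_limb)
  trials <- list()
  for (a in 1:2) {
    current_start <- .resting_start(limbs[[a]], robot, protocol)
    for (dur in protocol$durations_ms) {
      for (k in seq_len(protocol$trials_per_duration)) {
        for (dir in c("flexion", "extension")) {
          tr <- simulate_trial(limbs[[a]], robot, protocol, dir,
                               duration_ms = dur,
                               start_angle = current_start, seed = NULL,
                               subject_id = subject_id,
                               arm = arm_labels[a], trial_index = k)
          current_start <- attr(tr, "truth")$next_start_angle
          trials[[length(trials) + 1]] <- tr
        }
      }
    }
  }
  trials
}

#' @export
print.kaps_trial <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<kaps_trial> %s %s %s %d ms (trial %d), %d samples @ %g Hz\n",
              m$subject_id, m$arm, m$direction, m$nominal_duration_ms,
              m$trial_index, nrow(x$data), m$sample_rate_hz))
  invisible(x)
}
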