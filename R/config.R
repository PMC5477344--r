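#' Robot position-controller configuration
#'
#' Parameters of the exoskeleton's PD position controller used to drive
#' passive elbow stretches. During the commanded movement the controller
#' applies a proportional-derivative torque about the commanded trajectory
#' plus an inertial feedforward term; after the nominal movement end it
#' applies a weaker proportional pull toward the target angle (the hold
#' phase). All torques are saturated at \code{torque_limit}.
#'
#' @param kp Proportional gain, Nm/rad. Must be > 0.
#' @param kd Derivative gain, Nm/(rad/s). Must be >= 0.
#' @param hold_gain Post-stretch proportional gain, Nm/deg.
#' @param torque_limit Saturation torque, Nm. Must be > 0.
#' @param timeout_ms Controller persistence after movement onset, ms. The
#'   controller stops producing torque this long after onset if the target
#'   was never reached.
#' @param inertia_estimate Inertia (kg m^2) used by the feedforward term.
#'   The real robot uses an estimate of robot-plus-subject inertia; a single
#'   configurable value is used here.
#' @return An object of class \code{kaps_robot}.
#' @examples
#' robot_config()
#' @export
robot_config <- function(kp = 30, kd = 2.5, hold_gain = 0.26,
                         torque_limit = 13.2, timeout_ms = 7000,
                         inertia_estimate = 0.06) {
  stopifnot(is.numeric(kp), kp > 0, is.numeric(kd), kd >= 0,
            is.numeric(hold_gain), hold_gain >= 0,
            is.numeric(torque_limit), torque_limit > 0,
            is.numeric(timeout_ms), timeout_ms > 0,
            is.numeric(inertia_estimate), inertia_estimate >= 0)
  structure(list(kp = kp, kd = kd, hold_gain = hold_gain,
                 torque_limit = torque_limit, timeout_ms = timeout_ms,
                 inertia_estimate = inertia_estimate),
            class = "kaps_robot")
}

#' Simulated limb configuration
#'
#' Mechanical model of one arm for the stretch simulator: a second-order
#' rotational limb with passive viscous damping, an optional gated
#' velocity-proportional spastic resistance (the mechanistic stand-in for
#' velocity-dependent resistance to passive movement, producing the classic
#' catch), an exponential post-stretch release of that resistance (producing
#' creep), and an optional one-sided contracture stiffness that limits
#' extension range.
#'
#' @param inertia Limb inertia about the elbow, kg m^2. Must be > 0.
#' @param passive_damping Passive viscous damping, Nm/(rad/s).
#' @param spastic_gain Reflex resistance coefficient, Nm/(rad/s). Zero for a
#'   healthy limb.
#' @param catch_onset_excursion Degrees of travel from movement start after
#'   which the spastic torque engages.
#' @param release_time_constant Seconds over which the engaged spastic
#'   torque decays once the commanded movement ends; longer values give
#'   slower post-stretch relaxation and larger measured creep.
#' @param contracture_limit Internal elbow angle (deg) beyond which
#'   contracture stiffness engages, or \code{NA} to disable. When enabled it
#'   must lie in [65, 145].
#' @param contracture_stiffness Contracture stiffness, Nm/deg.
#' @param noise_sd Measurement noise SD on the recorded angle, deg. Velocity
#'   is recorded from the true state.
#' @return An object of class \code{kaps_limb}.
#' @examples
#' healthy <- limb_config()
#' spastic <- limb_config(spastic_gain = 8, catch_onset_excursion = 40)
#' @export
limb_config <- function(inertia = 0.06, passive_damping = 0.1,
                        spastic_gain = 0, catch_onset_excursion = 0,
                        release_time_constant = 0.8,
                        contracture_limit = NA_real_,
                        contracture_stiffness = 0, noise_sd = 0.1) {
  stopifnot(is.numeric(inertia), inertia > 0,
            passive_damping >= 0, spastic_gain >= 0,
            catch_onset_excursion >= 0, release_time_constant > 0,
            contracture_stiffness >= 0, noise_sd >= 0)
  if (!is.na(contracture_limit) && contracture_stiffness > 0 &&
      (contracture_limit < 65 || contracture_limit > 145))
    stop("contracture_limit must lie in [65, 145] deg when enabled")
  structure(list(inertia = inertia, passive_damping = passive_damping,
                 spastic_gain = spastic_gain,
                 catch_onset_excursion = catch_onset_excursion,
                 release_time_constant = release_time_constant,
                 contracture_limit = as.numeric(contracture_limit),
                 contracture_stiffness = contracture_stiffness,
                 noise_sd = noise_sd),
            class = "kaps_limb")
}

#' Passive-stretch protocol configuration
#'
#' Timing and geometry of the assessment protocol: movements span the 80
#' degree range between \code{flexed_angle} and \code{extended_angle}
#' (internal elbow angle; extension increases angle). One trial is a flexion
#' movement, an intra-trial wait, and an extension movement back, followed
#' by an inter-trial wait. Three trials are run at each nominal duration,
#' slowest duration first.
#'
#' @param extended_angle Extension target / initial start angle, deg
#'   (default 145).
#' @param flexed_angle Flexion target, deg (default 65).
#' @param durations_ms Nominal movement durations in protocol order, ms.
#' @param trials_per_duration Trials at each duration.
#' @param intra_trial_wait_ms Wait after the flexion movement, ms.
#' @param inter_trial_wait_ms Wait after the extension movement, ms.
#' @param sample_rate_hz Recording rate, Hz. The trial schema is defined at
#'   1000 Hz.
#' @return An object of class \code{kaps_protocol}.
#' @export
protocol_config <- function(extended_angle = 145, flexed_angle = 65,
                            durations_ms = c(1500, 1200, 1000, 800, 600),
                            trials_per_duration = 3,
                            intra_trial_wait_ms = 1500,
                            inter_trial_wait_ms = 3000,
                            sample_rate_hz = 1000) {
  stopifnot(extended_angle >= 65, extended_angle <= 145,
            flexed_angle >= 65, flexed_angle <= 145,
            flexed_angle < extended_angle,
            all(durations_ms > 0), trials_per_duration >= 1,
            intra_trial_wait_ms > 0, inter_trial_wait_ms > 0,
            sample_rate_hz >= 100) # well above twice the 10 Hz filter cutoff
  structure(list(extended_angle = extended_angle,
                 flexed_angle = flexed_angle,
                 durations_ms = durations_ms,
                 trials_per_duration = trials_per_duration,
                 intra_trial_wait_ms = intra_trial_wait_ms,
                 inter_trial_wait_ms = inter_trial_wait_ms,
                 sample_rate_hz = sample_rate_hz),
            class = "kaps_protocol")
}

#' @export
print.kaps_robot <- function(x, ...) {
  cat("<kaps_robot> kp", x$kp, "Nm/rad, kd", x$kd, "Nm/(rad/s), hold",
      x$hold_gain, "Nm/deg, limit", x$torque_limit, "Nm, timeout",
      x$timeout_ms, "ms\n")
  invisible(x)
}

#' @export
print.kaps_limb <- function(x, ...) {
  cat("<kaps_limb> inertia", x$inertia, "kg m^2, damping",
      x$passive_damping, "Nm/(rad/s)")
  if (x$spastic_gain > 0)
    cat(", spastic gain", x$spastic_gain, "engaging at",
        x$catch_onset_excursion, "deg, release tau",
        x$release_time_constant, "s")
  if (!is.na(x$contracture_limit) && x$contracture_stiffness > 0)
    cat(", contracture beyond", x$contracture_limit, "deg (",
        x$contracture_stiffness, "Nm/deg)")
  cat("\n")
  invisible(x)
}

#' @export
print.kaps_protocol <- function(x, ...) {
  cat("<kaps_protocol>", x$flexed_angle, "-", x$extended_angle,
      "deg; durations", paste(x$durations_ms, collapse = "/"), "ms x",
      x$trials_per_duration, "trials; waits", x$intra_trial_wait_ms, "/",
      x$inter_trial_wait_ms, "ms\n")
  invisible(x)
}
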