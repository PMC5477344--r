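# shared fixtures: all built in code, no files

protocol600 <- function() protocol_config(durations_ms = 600)

quiet_limb <- function(...) limb_config(noise_sd = 0, ...)

# hand-built trial at 1 kHz with consistent metadata
make_trial <- function(angle, velocity = NULL, direction = "extension",
                       duration = 600, onset = 0, next_onset = NULL,
                       start = NULL, target = NULL, subject = "T1",
                       arm = "affected", trial_index = 1L) {
  n <- length(angle)
  if (is.null(velocity)) velocity <- c(diff(angle), 0) * 1000
  if (is.null(next_onset)) next_onset <- n
  if (is.null(start)) start <- angle[1]
  if (is.null(target))
    target <- if (direction == "extension") max(145, start + 1)
              else min(65, start - 1)
  structure(list(
    meta = list(subject_id = subject, arm = arm, direction = direction,
                nominal_duration_ms = duration,
                trial_index = as.integer(trial_index), onset_ms = onset,
                start_angle_deg = start, target_angle_deg = target,
                next_onset_ms = next_onset, sample_rate_hz = 1000),
    data = data.frame(time_ms = 0:(n - 1), angle_deg = angle,
                      velocity_deg_s = velocity)),
    class = "kaps_trial")
}

# three identical reference trials following the commanded profile, plus
# affected trials that freeze at a given excursion (synthetic catch)
make_catch_pair <- function(excursion, direction = "extension",
                            duration = 600) {
  start <- if (direction == "extension") 65 else 145
  end <- if (direction == "extension") 145 else 65
  tt <- 0:(duration + 1500 - 1)
  cmd <- commanded_profile(tt, duration, start, end)
  ref <- lapply(1:3, function(k)
    make_trial(cmd$angle, cmd$velocity, direction, duration,
               arm = "less_affected", trial_index = k, start = start,
               target = end))
  stop_i <- which(abs(cmd$angle - start) >= excursion)[1]
  a <- cmd$angle; v <- cmd$velocity
  a[stop_i:length(a)] <- a[stop_i]
  v[stop_i:length(v)] <- 0
  aff <- lapply(1:3, function(k)
    make_trial(a, v, direction, duration, arm = "affected",
               trial_index = k, start = start, target = end))
  list(affected = aff, reference = ref)
}

# fabricated control parameter table (no simulation): Gaussian mechanics
# of a plausible cohort, for fast normative-model tests
make_params_cohort <- function(n = 96, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  one_dir <- function(dir) {
    pv_t <- rnorm(n, 300, 15); pv_r <- pv_t + rnorm(n, 0, 8)
    fa_mu <- if (dir == "extension") 143 else 67
    fa_t <- rnorm(n, fa_mu, 2); fa_r <- fa_t + rnorm(n, 0, 1)
    cr_t <- rnorm(n, 0, 0.3); cr_r <- cr_t + rnorm(n, 0, 0.2)
    data.frame(subject_id = ids, direction = dir, duration_ms = 600,
               peak_velocity = pv_t, final_angle = fa_t, creep = cr_t,
               ref_peak_velocity = pv_r, ref_final_angle = fa_r,
               ref_creep = cr_r,
               d_peak_velocity = abs(pv_t - pv_r),
               d_final_angle = fa_t - fa_r, d_creep = cr_t - cr_r,
               vdiff_peak = abs(rnorm(n, 0, 12)) + 2,
               catch_angle = NA_real_, stringsAsFactors = FALSE)
  }
  params <- rbind(one_dir("extension"), one_dir("flexion"))
  class(params) <- c("kaps_parameters", "data.frame")
  demo <- data.frame(subject_id = ids,
                     age = runif(n, 19, 81),
                     sex = ifelse(runif(n) < 0.45, "M", "F"),
                     handedness = ifelse(runif(n) < 0.9, "R", "L"),
                     stringsAsFactors = FALSE)
  list(params = params, demographics = demo)
}

# assessment reports for all subjects of a simulated cohort
assess_cohort <- function(cohort, model, group = NULL) {
  man <- cohort$manifest
  lapply(seq_len(nrow(man)), function(i) {
    sp <- cohort$params[cohort$params$subject_id == man$subject_id[i], ]
    assess_subject(sp, model, age = man$age[i], sex = man$sex[i],
                   group = if (is.null(group)) man$group[i] else group)
  })
}
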