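test_that("peak velocity is the windowed maximum speed", {
  # constant -100 deg/s inside the window
  angle <- c(seq(145, 85, by = -0.1), rep(85, 2999))
  tr <- make_trial(angle[1:3600], velocity = c(rep(-100, 601), rep(0, 2999)),
                   direction = "flexion", start = 145, target = 65,
                   next_onset = 3600)
  w <- suppressWarnings(segment(tr))
  expect_equal(peak_velocity(tr, w), 100)
  # a spike outside the movement window is ignored (target was reached)
  spike <- tr
  spike$data$angle_deg[601:3600] <- 64.5 # at target: no window extension
  spike$meta$start_angle_deg <- 145
  spike$data$velocity_deg_s[2000] <- 500
  expect_equal(peak_velocity(spike, suppressWarnings(segment(spike))), 100)
})

test_that("final angle is the 50 ms terminal mean", {
  angle <- rep(143, 3600)
  tr <- make_trial(angle, velocity = rep(0, 3600), direction = "extension",
                   start = 65, target = 145, next_onset = 3600)
  w <- segment(tr)
  expect_equal(final_angle(tr, w), 143)
  # linear drift from 144.9 to 145 across the last 50 ms
  angle2 <- c(rep(144.9, 3550), seq(144.9, 145, length.out = 50))
  tr2 <- make_trial(angle2, velocity = rep(0, 3600),
                    direction = "extension", start = 65, target = 145,
                    next_onset = 3600)
  expect_equal(final_angle(tr2, segment(tr2)), 144.95)
})

test_that("creep follows the direction-specific sign convention", {
  # extension: angle at post-stretch 140, final 143 -> +3
  angle <- c(commanded_profile(0:599, 600, 65, 140)$angle,
             rep(140, 1000), seq(140, 143, length.out = 1900),
             rep(143, 100))
  tr <- make_trial(angle, velocity = rep(0, length(angle)),
                   direction = "extension", start = 65, target = 145,
                   next_onset = length(angle))
  w <- segment(tr)
  expect_equal(as.numeric(creep(tr, w)), 3)
  # flexion: angle at post-stretch 70, final 68 -> +2
  angle_f <- c(commanded_profile(0:599, 600, 145, 70)$angle,
               rep(70, 1000), seq(70, 68, length.out = 1900),
               rep(68, 100))
  trf <- make_trial(angle_f, velocity = rep(0, length(angle_f)),
                    direction = "flexion", start = 145, target = 65,
                    next_onset = length(angle_f))
  expect_equal(as.numeric(creep(trf, segment(trf))), 2)
  # identical post-stretch and final angle -> 0 either way
  flat <- make_trial(c(commanded_profile(0:599, 600, 65, 145)$angle,
                       rep(145, 3000)),
                     velocity = rep(0, 3600), direction = "extension",
                     start = 65, target = 145, next_onset = 3600)
  expect_equal(as.numeric(creep(flat, segment(flat))), 0)
})

test_that("trial aggregation applies the configured statistic", {
  expect_equal(aggregate_trials(c(200, 210, 220)), 210)
  expect_equal(aggregate_trials(150), 150)
  expect_equal(aggregate_trials(c(200, 210, 400), method = "median"), 210)
})

test_that("between-arm differences have the stated signs and symmetry", {
  mk <- function(pv, fa, cr)
    list(peak_velocity = pv, final_angle = fa, creep = cr,
         direction = "extension", duration_ms = 600)
  expect_equal(between_arm_differences(mk(210, 143, 0.1), mk(210, 143, 0.1)),
               list(d_peak_velocity = 0, d_final_angle = 0, d_creep = 0))
  d <- between_arm_differences(mk(150, 130, 0.5), mk(210, 143, 0.1))
  expect_equal(d$d_peak_velocity, 60)
  expect_equal(d$d_final_angle, -13)
  expect_equal(d$d_creep, 0.4)
  # swapping arms negates the signed differences, |d_pv| unchanged
  swapped <- between_arm_differences(mk(210, 143, 0.1), mk(150, 130, 0.5))
  expect_equal(swapped$d_peak_velocity, d$d_peak_velocity)
  expect_equal(swapped$d_final_angle, -d$d_final_angle)
  expect_equal(swapped$d_creep, -d$d_creep)
  bad <- mk(150, 130, 0.5); bad$direction <- "flexion"
  expect_error(between_arm_differences(bad, mk(210, 143, 0.1)),
               "direction mismatch")
})

test_that("catch angle finds the constructed crossing with the right sign", {
  pair <- make_catch_pair(40, "extension")
  expect_equal(catch_angle(pair$affected, pair$reference, 50.1), 40,
               tolerance = 0.5)
  pairf <- make_catch_pair(40, "flexion")
  expect_equal(catch_angle(pairf$affected, pairf$reference, 50.1), -40,
               tolerance = 0.5)
  # both comparison modes agree on identical reference trials
  expect_equal(
    catch_angle(pair$affected, pair$reference, 50.1, mode = "trial_to_trial"),
    catch_angle(pair$affected, pair$reference, 50.1), tolerance = 1e-9)
  # identical arms never cross
  expect_true(is.na(catch_angle(pair$reference, pair$reference, 50.1)))
  expect_error(catch_angle(pair$affected, pair$reference, 0),
               "threshold")
})

test_that("simulated catch onset is recovered by the detector", {
  pro <- protocol_config()
  ref <- lapply(1:3, function(k)
    filter_trial(simulate_trial(quiet_limb(), robot_config(), pro,
                                "extension", 600, start_angle = 65,
                                trial_index = k, arm = "less_affected")))
  aff <- lapply(1:3, function(k)
    filter_trial(simulate_trial(
      quiet_limb(spastic_gain = 10, catch_onset_excursion = 40),
      robot_config(), pro, "extension", 600, start_angle = 65,
      trial_index = k, arm = "affected")))
  expect_equal(catch_angle(aff, ref, 50.1), 40, tolerance = 3)
})

test_that("extraction produces a complete per-direction parameter table", {
  trials <- simulate_subject(
    limb_config(spastic_gain = 8, catch_onset_excursion = 30),
    limb_config(), protocol = protocol600(), seed = 5)
  p <- extract_subject_parameters(trials)
  expect_s3_class(p, "kaps_parameters")
  expect_equal(sort(p$direction), c("extension", "flexion"))
  expect_true(all(c("peak_velocity", "d_creep", "vdiff_peak",
                    "catch_angle") %in% names(p)))
  # the affected arm is slower and falls short in both directions
  expect_true(all(p$peak_velocity < p$ref_peak_velocity))
  expect_true(all(!is.na(p$catch_angle)))
  expect_gt(p$catch_angle[p$direction == "extension"], 0)
  expect_lt(p$catch_angle[p$direction == "flexion"], 0)
})
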