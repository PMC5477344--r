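test_that("commanded profile matches the analytic half-cosine", {
  p0 <- commanded_profile(0, 600, 145, 65)
  expect_equal(p0$angle, 145)
  expect_equal(p0$velocity, 0)
  p1 <- commanded_profile(600, 600, 145, 65)
  expect_equal(p1$angle, 65)
  expect_equal(p1$velocity, 0)
  pm <- commanded_profile(300, 600, 145, 65)
  expect_equal(pm$angle, 105)
  expect_equal(pm$velocity, -pi * 80 / (2 * 0.6), tolerance = 1e-12)
  # clamped beyond the nominal duration
  pe <- commanded_profile(900, 600, 145, 65)
  expect_equal(pe$angle, 65)
  expect_equal(pe$velocity, 0)
  expect_error(commanded_profile(100, 0, 145, 65), "invalid protocol")
  expect_error(commanded_profile(100, -5, 145, 65), "invalid protocol")
})

test_that("a healthy noise-free limb tracks the command at all durations", {
  robot <- robot_config()
  pro <- protocol_config()
  for (d in pro$durations_ms) {
    tr <- simulate_trial(quiet_limb(), robot, pro, "extension",
                         duration_ms = d, start_angle = 65)
    truth <- attr(tr, "truth")
    cmd <- commanded_profile(tr$data$time_ms[1:(d + 1)], d, 65, 145)
    expect_lt(max(abs(truth$angle[1:(d + 1)] - cmd$angle)), 2)
    expect_true(truth$target_reached)
  }
  tr <- simulate_trial(quiet_limb(), robot, pro, "extension", 600,
                       start_angle = 65)
  pv <- max(abs(tr$data$velocity_deg_s))
  expect_lt(abs(pv - pi * 80 / (2 * 0.6)) / (pi * 80 / (2 * 0.6)), 0.10)
})

test_that("robot torque saturates at the configured limit", {
  robot <- robot_config()
  configs <- list(
    quiet_limb(),
    quiet_limb(spastic_gain = 30, catch_onset_excursion = 10),
    quiet_limb(contracture_limit = 100, contracture_stiffness = 5),
    quiet_limb(passive_damping = 3))
  for (lc in configs) {
    tr <- simulate_trial(lc, robot, protocol_config(), "extension", 600,
                         start_angle = 65)
    expect_lte(max(abs(attr(tr, "truth")$torque)), 13.2 + 1e-9)
  }
})

test_that("a strong contracture blocks extension and carries its angle over", {
  tr <- simulate_trial(quiet_limb(contracture_limit = 105,
                                  contracture_stiffness = 50),
                       robot_config(), protocol_config(), "extension", 600,
                       start_angle = 65)
  truth <- attr(tr, "truth")
  expect_lte(truth$angle[length(truth$angle)], 107)
  expect_false(truth$target_reached)
  expect_equal(truth$next_start_angle, truth$angle[length(truth$angle)])
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_subject(limb_config(), limb_config(),
                        protocol = protocol600(), seed = 7)
  b <- simulate_subject(limb_config(), limb_config(),
                        protocol = protocol600(), seed = 7)
  expect_identical(a, b)
})

test_that("peak velocity decreases with spastic gain, shortfall grows with contracture", {
  pro <- protocol_config()
  pv <- vapply(c(0, 1, 2, 4, 8, 16), function(g) {
    tr <- simulate_trial(quiet_limb(spastic_gain = g,
                                    catch_onset_excursion = 20),
                         robot_config(), pro, "extension", 600,
                         start_angle = 65)
    max(abs(tr$data$velocity_deg_s))
  }, 0)
  expect_true(all(diff(pv) <= 1e-6))
  shortfall <- vapply(c(0, 0.2, 0.5, 1, 2, 5), function(k) {
    tr <- simulate_trial(quiet_limb(contracture_limit = 110,
                                    contracture_stiffness = k),
                         robot_config(), pro, "extension", 600,
                         start_angle = 65)
    145 - attr(tr, "truth")$angle[length(attr(tr, "truth")$angle)]
  }, 0)
  expect_true(all(diff(shortfall) >= -1e-6))
})

test_that("overshoot past the commanded endpoint stays sub-degree", {
  # the PD loop coasts marginally past the target at movement end before
  # the hold pull settles it; the excursion stays well below measurement
  # precision concerns (< 0.5 deg on an 80 deg movement)
  for (dir in c("extension", "flexion")) {
    st <- if (dir == "extension") 65 else 145
    tr <- simulate_trial(quiet_limb(), robot_config(), protocol_config(),
                         dir, 600, start_angle = st)
    truth <- attr(tr, "truth")
    if (dir == "extension") expect_lte(max(truth$angle), 145 + 0.5)
    else expect_gte(min(truth$angle), 65 - 0.5)
  }
})

test_that("numerical blow-up raises an instability error naming parameters", {
  expect_error(
    simulate_trial(quiet_limb(inertia = 1e-5), robot_config(),
                   protocol_config(), "extension", 600, start_angle = 65),
    "instability")
})

test_that("identical healthy limbs give near-identical between-arm velocities", {
  trials <- simulate_subject(limb_config(), limb_config(),
                             protocol = protocol600(), seed = 3,
                             arm_labels = c("non_dominant", "dominant"))
  p <- extract_subject_parameters(trials)
  expect_true(all(p$d_peak_velocity < 15))
})

test_that("a spastic arm stalls near its onset excursion while the control completes", {
  sp <- quiet_limb(spastic_gain = 10, catch_onset_excursion = 40)
  tr <- simulate_trial(sp, robot_config(), protocol_config(), "extension",
                       600, start_angle = 65)
  truth <- attr(tr, "truth")
  # at nominal movement end the arm is well short of target
  expect_lt(truth$angle[601], 130)
  # velocity collapses shortly after 40 deg of travel
  i40 <- which(truth$angle - 65 >= 40)[1]
  expect_lt(tr$data$velocity_deg_s[i40 + 100], 80)
  hl <- simulate_trial(quiet_limb(), robot_config(), protocol_config(),
                       "extension", 600, start_angle = 65)
  expect_true(attr(hl, "truth")$target_reached)
})
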