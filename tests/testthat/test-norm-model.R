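test_that("age regression recovers exact and null relationships", {
  ages <- seq(20, 80, length.out = 30)
  exact <- 5 + 0.2 * ages
  fit <- suppressWarnings(fit_age_regression(exact, ages))
  expect_equal(fit$slope, 0.2, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  # slope-0 generator: fitted slope within 2 SE of zero
  set.seed(21)
  flat <- rnorm(96, 100, 5)
  f2 <- fit_age_regression(flat, runif(96, 19, 81))
  expect_lt(abs(f2$slope), 2 * f2$se)
  expect_warning(fit_age_regression(rnorm(12), rep(50, 12)),
                 "zero age variance")
})

test_that("Box-Cox transform has the textbook fixed points and inverse", {
  for (lam in c(-1, -0.5, 0, 0.5, 1, 2))
    expect_equal(boxcox_transform(rep(1, 5), lam), rep(0, 5))
  y <- c(0.2, 1, 3, 7)
  for (lam in c(-0.7, 0, 1.3))
    expect_equal(boxcox_inverse(boxcox_transform(y, lam), lam), y,
                 tolerance = 1e-10)
  expect_error(boxcox_normalize(rep(2, 50)), "degenerate")
})

test_that("Box-Cox lambda recovery on known families", {
  set.seed(42)
  ln <- boxcox_normalize(rlnorm(96, 0, 1))
  expect_gte(ln$lambda, -0.3)
  expect_lte(ln$lambda, 0.3)
  nm <- boxcox_normalize(pmax(rnorm(96, 10, 4), 0.1))
  expect_gte(nm$lambda, 0.6)
  expect_lte(nm$lambda, 1.4)
  expect_true(nm$normalizable)
})

test_that("the outlier screen excludes gross outliers and only those", {
  set.seed(8)
  vals <- as.data.frame(matrix(rnorm(96 * 6), 96, 6))
  ids <- sprintf("C%02d", 1:96)
  clean <- remove_outliers(vals, ids)
  expect_lte(length(clean$excluded), 2)
  # one subject at 10 SD on a single parameter is excluded everywhere
  vals2 <- vals
  vals2[17, 3] <- 10
  out <- remove_outliers(vals2, ids)
  expect_true("C17" %in% out$excluded)
  # constant column: MAD floored, no exclusions from it
  flat <- remove_outliers(data.frame(x = rep(1, 96)), ids)
  expect_length(flat$excluded, 0)
  # mass exclusion is refused
  vals3 <- vals
  vals3[1:30, 1] <- 50
  expect_error(remove_outliers(vals3, ids), "25%")
})

test_that("group-effect testing gates stratification correctly", {
  set.seed(31)
  x <- rnorm(96)
  g <- rep(c("M", "F"), 48)
  null_fit <- test_group_effects(x, g)
  expect_true(null_fit$tested)
  expect_false(null_fit$significant)
  shifted <- x + (g == "M") * 1.0 # 1 SD offset, n = 48/48
  alt <- test_group_effects(shifted, g)
  expect_true(alt$significant)
  tiny <- test_group_effects(rnorm(5), c("M", rep("F", 4)))
  expect_false(tiny$tested)
})

test_that("percentile cutoffs follow the linear-interpolation definition", {
  expect_equal(compute_cutoffs(1:100, "low", 5), 5.95)
  expect_equal(compute_cutoffs(rep(7, 40), "high"), 7)
  set.seed(4)
  q <- compute_cutoffs(rnorm(96), "high", 95)
  expect_gt(q, 1.35)
  expect_lt(q, 1.95)
})

test_that("the velocity-difference threshold falls back and fits", {
  d <- velocity_difference_threshold(NULL)
  expect_equal(as.numeric(d), 50.1)
  expect_equal(attr(d, "provenance"), "paper default")
  expect_equal(as.numeric(velocity_difference_threshold(rep(12, 30))), 12)
  # half-normal with known scale: 99th percentile = sigma * qnorm(0.995)
  set.seed(77)
  hn <- abs(rnorm(20000, 0, 20))
  fitted <- velocity_difference_threshold(hn)
  expect_equal(as.numeric(fitted), 20 * qnorm(0.995), tolerance = 0.02 * 51.5)
  expect_equal(attr(fitted, "provenance"), "fitted")
})

test_that("cutoffs back-transform consistently to the original scale", {
  set.seed(14)
  x <- rlnorm(96, 1, 0.6)
  bc <- boxcox_normalize(x)
  cut_t <- compute_cutoffs(bc$transformed, "low", 5)
  cut_orig <- boxcox_inverse(cut_t, bc$lambda) - bc$shift
  # round trip within 1e-8 and percentile preserved exactly
  expect_equal(boxcox_transform(cut_orig + bc$shift, bc$lambda), cut_t,
               tolerance = 1e-8)
  expect_equal(mean(x < cut_orig), mean(bc$transformed < cut_t))
})

test_that("a fitted model flags tails and scores z consistently", {
  ch <- make_params_cohort(96, seed = 3)
  model <- fit_normative_model(ch$params, ch$demographics)
  expect_s3_class(model, "kaps_model")
  expect_length(model$entries, 12)
  e <- model$entries[["extension:peak_velocity"]]
  expect_equal(e$tail, "low")
  # a value at the control centre scores z near 0 and classifies normal
  centre <- median(c(ch$params$peak_velocity,
                     ch$params$ref_peak_velocity)[
                       ch$params$direction == "extension"])
  r <- kaps_zscore(model, "peak_velocity", "extension", centre, age = 50,
                   sex = "M")
  if (r$normalizable) expect_lt(abs(r$z), 0.3)
  expect_false(r$impaired)
  # a value at the 5th-percentile cutoff of a normal model scores |z| ~ 1.645
  st <- e$stats$all
  if (e$normalizable) {
    at_cut <- kaps_zscore(model, "peak_velocity", "extension",
                          st$cutoff + e$age$slope * 0, age = e$age$mean_age)
    expect_equal(abs(at_cut$z), qnorm(0.95), tolerance = 0.45)
    expect_false(at_cut$impaired) # boundary is strict
  }
  # values just beyond the cutoff are impaired, just inside are normal
  expect_true(kaps_zscore(model, "peak_velocity", "extension",
                          st$cutoff - 1, age = e$age$mean_age)$impaired)
  expect_false(kaps_zscore(model, "peak_velocity", "extension",
                           st$cutoff + 1, age = e$age$mean_age)$impaired)
})

test_that("non-normalizable parameters carry flags but no z", {
  model <- structure(list(
    entries = list("extension:creep" = list(
      parameter = "creep", direction = "extension", tail = "high",
      age = list(slope = 0, mean_age = 50), lambda = NA_real_, shift = 0,
      normalizable = FALSE, strata = "none",
      stats = list(all = list(mean = NA_real_, sd = NA_real_,
                              cutoff_transformed = 0.3, cutoff = 0.3,
                              n = 96)))),
    velocity_difference_threshold = 50.1, duration_ms = 600),
    class = "kaps_model")
  r <- kaps_zscore(model, "creep", "extension", 0.5, age = 60)
  expect_true(is.na(r$z))
  expect_true(r$impaired)
  expect_false(kaps_zscore(model, "creep", "extension", 0.3, age = 60)$impaired)
})

test_that("model serialization round-trips through JSON", {
  ch <- make_params_cohort(48, seed = 6)
  model <- fit_normative_model(ch$params, ch$demographics)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_normative_model(model, path)
  back <- read_normative_model(path)
  expect_equal(back$velocity_difference_threshold,
               model$velocity_difference_threshold)
  expect_equal(back$n_controls_used, model$n_controls_used)
  e1 <- model$entries[["flexion:d_creep"]]
  e2 <- back$entries[["flexion:d_creep"]]
  expect_equal(e2$stats$all$cutoff, e1$stats$all$cutoff, tolerance = 1e-12)
  expect_equal(e2$lambda, e1$lambda)
  # a restored model classifies identically
  v <- kaps_zscore(model, "d_creep", "flexion", 0.9, age = 40, sex = "F")
  w <- kaps_zscore(back, "d_creep", "flexion", 0.9, age = 40, sex = "F")
  expect_equal(w$z, v$z, tolerance = 1e-12)
  expect_equal(w$impaired, v$impaired)
})
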