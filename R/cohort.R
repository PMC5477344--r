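#' Spasticity severity presets for the cohort generator
#'
#' Ranges from which the affected-arm pathology of an impaired simulated
#' subject is drawn. "moderate" draws a mid-range spastic resistance with
#' no contracture; "severe" draws a strong resistance (large enough to
#' stall the stretch against the torque-limited controller) plus a
#' contracture restricting extension range.
#'
#' @param level "moderate" or "severe".
#' @return List of ranges (each length 2) for \code{spastic_gain},
#'   \code{catch_onset_excursion}, \code{release_time_constant}, and (severe
#'   only) \code{contracture_limit}, \code{contracture_stiffness}.
#' @export
spasticity_severity <- function(level = c("severe", "moderate")) {
  level <- match.arg(level)
  switch(level,
    moderate = list(spastic_gain = c(1.5, 4),
                    catch_onset_excursion = c(20, 60),
                    release_time_constant = c(0.6, 1.2),
                    contracture_limit = NULL,
                    contracture_stiffness = NULL),
    severe = list(spastic_gain = c(6, 12),
                  catch_onset_excursion = c(20, 60),
                  release_time_constant = c(0.8, 1.6),
                  contracture_limit = c(100, 130),
                  contracture_stiffness = c(0.5, 1.5)))
}

.runif_range <- function(r) if (is.null(r)) NULL else runif(1, r[1], r[2])

#' Simulate a cohort of subjects
#'
#' Samples per-subject demographics (age, sex, handedness) and limb
#' mechanics, optionally maps demographic effects onto limb properties,
#' simulates every subject through the stretch protocol, and (by default)
#' extracts the KAPS parameter set per subject. A configurable fraction of
#' subjects receives an impaired (spastic) test arm drawn from a severity
#' preset; the rest are controls with two statistically identical healthy
#' arms.
#'
#' Healthy between-subject variability is lognormal on inertia (median
#' 0.06 kg m^2, sdlog 0.15) and passive damping (median 0.10 Nm/(rad/s),
#' sdlog 0.25), with small independent per-arm multipliers (sdlog 0.03 and
#' 0.05) so that between-arm differences are realistic but small.
#'
#' @param n Number of subjects (>= 2).
#' @param age_range Uniform age range, years.
#' @param male_fraction,right_handed_fraction Demographic mix.
#' @param effects Optional demographic effects on limb properties: a list
#'   with elements named after limb properties (\code{passive_damping},
#'   \code{inertia}), each a list with \code{age_slope} (units per year,
#'   centred at the mid age range) and/or \code{sex_offset} (added for
#'   males).
#' @param impaired_fraction Fraction of subjects given an impaired test
#'   arm (in [0, 1]).
#' @param severity Severity preset name or a list in the format of
#'   \code{\link{spasticity_severity}}.
#' @param protocol,robot Protocol and robot configurations.
#' @param seed Integer seed; the full cohort is deterministic given it.
#' @param extract Compute KAPS parameters per subject (default TRUE).
#' @param extract_durations_ms Durations at which parameters are extracted
#'   (default 600 ms, the most discriminative stretch).
#' @param threshold Catch-detection threshold used during extraction.
#' @param keep_trials Keep the raw trial recordings (memory-heavy for
#'   large cohorts; default FALSE).
#' @return An object of class \code{kaps_cohort}: list with
#'   \code{manifest} (subject_id, age, sex, handedness, group),
#'   \code{params} (stacked \code{kaps_parameters}, when extracted),
#'   \code{limb_configs} (ground-truth configs per subject),
#'   \code{trials} (when kept), and the protocol/robot used.
#' @export
simulate_cohort <- function(n, age_range = c(19, 81),
                            male_fraction = 41 / 96,
                            right_handed_fraction = 88 / 96,
                            effects = list(), impaired_fraction = 0,
                            severity = "severe",
                            protocol = protocol_config(),
                            robot = robot_config(), seed = 1,
                            extract = TRUE, extract_durations_ms = 600,
                            threshold = kaps_default_threshold(),
                            keep_trials = FALSE) {
  stopifnot(n >= 2, impaired_fraction >= 0, impaired_fraction <= 1,
            male_fraction >= 0, male_fraction <= 1)
  if (diff(range(age_range)) == 0) {
    slopes <- unlist(lapply(effects, function(e) e$age_slope))
    if (any(slopes != 0))
      warning("degenerate demographics: zero age range with a nonzero ",
              "age slope requested; slope has no effect")
  }
  if (is.character(severity)) severity <- spasticity_severity(severity)
  if (!is.null(seed)) set.seed(seed)

  ages <- runif(n, age_range[1], age_range[2])
  sexes <- ifelse(runif(n) < male_fraction, "M", "F")
  hands <- ifelse(runif(n) < right_handed_fraction, "R", "L")
  impaired <- seq_len(n) <= round(impaired_fraction * n)
  mid_age <- mean(age_range)

  eff <- function(prop, age, sex) {
    e <- effects[[prop]]
    if (is.null(e)) return(0)
    slope <- if (is.null(e$age_slope)) 0 else e$age_slope
    off <- if (is.null(e$sex_offset)) 0 else e$sex_offset
    slope * (age - mid_age) + off * (sex == "M")
  }

  manifest <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         age = ages, sex = sexes, handedness = hands,
                         group = ifelse(impaired, "impaired", "control"),
                         stringsAsFactors = FALSE)
  limb_configs <- vector("list", n)
  trials_all <- if (keep_trials) vector("list", n)
  params_all <- list()

  for (i in seq_len(n)) {
    base_inertia <- 0.06 * exp(rnorm(1, 0, 0.15)) +
      eff("inertia", ages[i], sexes[i])
    base_damping <- 0.10 * exp(rnorm(1, 0, 0.25)) +
      eff("passive_damping", ages[i], sexes[i])
    arm <- function(pathology = NULL) {
      inertia <- max(0.02, base_inertia * exp(rnorm(1, 0, 0.03)))
      damping <- max(0.02, base_damping * exp(rnorm(1, 0, 0.05)))
      if (is.null(pathology))
        limb_config(inertia = inertia, passive_damping = damping)
      else
        limb_config(inertia = inertia, passive_damping = damping,
                    spastic_gain = pathology$spastic_gain,
                    catch_onset_excursion = pathology$catch_onset_excursion,
                    release_time_constant = pathology$release_time_constant,
                    contracture_limit = if (is.null(pathology$contracture_limit))
                      NA_real_ else pathology$contracture_limit,
                    contracture_stiffness = if (is.null(pathology$contracture_stiffness))
                      0 else pathology$contracture_stiffness)
    }
    pathology <- if (impaired[i]) lapply(severity, .runif_range)
    test <- arm(pathology)
    reference <- arm()
    limb_configs[[i]] <- list(test = test, reference = reference,
                              pathology = pathology)
    labels <- if (impaired[i]) c("affected", "less_affected")
              else c("non_dominant", "dominant")
    trials <- simulate_subject(test, reference, robot, protocol,
                               seed = NULL,
                               subject_id = manifest$subject_id[i],
                               arm_labels = labels)
    if (keep_trials) trials_all[[i]] <- trials
    if (extract)
      params_all[[i]] <- extract_subject_parameters(
        trials, threshold = threshold,
        durations_ms = intersect(extract_durations_ms,
                                 protocol$durations_ms))
  }

  params <- if (extract) {
    p <- do.call(rbind, params_all)
    class(p) <- c("kaps_parameters", "data.frame")
    p
  }
  structure(list(manifest = manifest, params = params,
                 limb_configs = limb_configs,
                 trials = if (keep_trials) trials_all,
                 protocol = protocol, robot = robot,
                 threshold_used = threshold),
            class = "kaps_cohort")
}

#' @export
print.kaps_cohort <- function(x, ...) {
  cat("<kaps_cohort>", nrow(x$manifest), "subjects (",
      sum(x$manifest$group == "impaired"), "impaired );",
      if (!is.null(x$params)) paste(nrow(x$params), "parameter rows")
      else "parameters not extracted", "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes every trial as CSV + JSON sidecar under \code{dir}, a cohort
#' manifest CSV (subject, age, sex, handedness, group, and one row per
#' trial file), and the ground-truth limb configurations as JSON for use
#' as test oracles.
#'
#' @param cohort A \code{kaps_cohort} simulated with
#'   \code{keep_trials = TRUE}.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "kaps_cohort"))
  if (is.null(cohort$trials))
    stop("cohort was simulated with keep_trials = FALSE; nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort$trials)) {
    for (tr in cohort$trials[[i]]) {
      m <- tr$meta
      f <- sprintf("%s_%s_%s_%d_%d.csv", m$subject_id, m$arm, m$direction,
                   m$nominal_duration_ms, m$trial_index)
      write_trial(tr, file.path(dir, f))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = m$subject_id, arm = m$arm, direction = m$direction,
        duration_ms = m$nominal_duration_ms, trial_index = m$trial_index,
        file = f)
    }
  }
  files <- do.call(rbind, rows)
  manifest <- merge(cohort$manifest, files, by = "subject_id")
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  jsonlite::write_json(
    lapply(cohort$limb_configs, function(cfgs)
      lapply(cfgs, function(c) if (is.null(c)) NULL else unclass(c))),
    file.path(dir, "limb_configs.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}

#' Read trials listed in a cohort manifest
#'
#' @param manifest_path Path to a manifest CSV written by
#'   \code{\link{write_cohort}} (trial files are resolved relative to it).
#' @return Named list (by subject id) of lists of \code{kaps_trial}s.
#' @export
read_cohort_trials <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  out <- list()
  for (sid in unique(man$subject_id)) {
    fs <- man$file[man$subject_id == sid]
    out[[sid]] <- lapply(file.path(dir, fs), read_trial)
  }
  out
}
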