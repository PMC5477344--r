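#' Impairment tails of the KAPS parameters
#'
#' Which tail of the control distribution counts as impaired for each
#' parameter and direction. Peak velocity (a magnitude) is impaired in the
#' low tail in both directions; final angle is impaired where the movement
#' fell short of its target (low tail in extension, high tail in flexion);
#' creep, the absolute between-arm peak-velocity difference and the
#' between-arm creep difference are impaired in the high tail; the signed
#' between-arm final-angle difference is impaired toward the shortfall side
#' (low tail in extension, high in flexion).
#'
#' @return A data.frame with columns \code{direction}, \code{parameter},
#'   \code{tail} ("low" or "high").
#' @export
kaps_parameter_tails <- function() {
  rbind(
    data.frame(direction = "extension",
               parameter = c("peak_velocity", "final_angle", "creep",
                             "d_peak_velocity", "d_final_angle", "d_creep"),
               tail = c("low", "low", "high", "high", "low", "high")),
    data.frame(direction = "flexion",
               parameter = c("peak_velocity", "final_angle", "creep",
                             "d_peak_velocity", "d_final_angle", "d_creep"),
               tail = c("low", "high", "high", "high", "high", "high")))
}

#' Box-Cox power transform
#'
#' \eqn{(y^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0}, \eqn{\log y}
#' otherwise; monotone increasing in \eqn{y} for all \eqn{\lambda}.
#' \code{boxcox_inverse} is its inverse.
#'
#' @param y Positive values (after any shift).
#' @param lambda Power parameter.
#' @return Transformed (or back-transformed) values.
#' @export
boxcox_transform <- function(y, lambda) {
  stopifnot(all(y > 0))
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param z Transformed values.
#' @export
boxcox_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-8) exp(z) else (lambda * z + 1)^(1 / lambda)
}

#' Box-Cox normalization with normality verdict
#'
#' Shifts the values to be positive (shift = 1 - min when any value is
#' non-positive), finds the maximum-likelihood Box-Cox lambda on a fine
#' grid, and judges the transformed values "normalizable" when the
#' Shapiro-Wilk test does not reject at alpha = 0.01. Parameters failing
#' the verdict are handled non-parametrically (raw percentiles) downstream.
#'
#' @param values Numeric vector (length >= 10 recommended).
#' @param shapiro_alpha Normality-gate alpha (default 0.01).
#' @param lambda_grid Grid over which the profile likelihood is evaluated.
#' @return List with \code{lambda}, \code{shift}, \code{transformed},
#'   \code{normalizable} (logical) and \code{shapiro_p}.
#' @export
boxcox_normalize <- function(values, shapiro_alpha = 0.01,
                             lambda_grid = seq(-3, 3, by = 0.01)) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || sd(values) < 1e-12)
    stop("degenerate data: constant or near-constant input to Box-Cox")
  shift <- if (min(values) <= 0) 1 - min(values) else 0
  y <- values + shift
  prof <- MASS::boxcox(y ~ 1, data = data.frame(y = y),
                       lambda = lambda_grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  transformed <- boxcox_transform(y, lambda)
  p <- shapiro.test(transformed)$p.value
  list(lambda = lambda, shift = shift, transformed = transformed,
       normalizable = p >= shapiro_alpha, shapiro_p = p)
}

#' Age regression of a control parameter
#'
#' Ordinary least squares of parameter value on age. Subject values are
#' age-adjusted downstream by subtracting the model prediction relative to
#' the control mean age, so the adjusted values keep the original units and
#' level. With zero age variance the regression is skipped (slope 0) with a
#' warning.
#'
#' @param values Parameter values.
#' @param ages Ages, years (same length, >= 10 controls).
#' @return List with \code{slope}, \code{intercept}, \code{se} (slope SE),
#'   \code{mean_age}, \code{residuals} and \code{skipped}.
#' @export
fit_age_regression <- function(values, ages) {
  stopifnot(length(values) == length(ages), length(values) >= 10)
  if (sd(ages) < 1e-12) {
    warning("zero age variance; skipping age regression (slope 0)")
    return(list(slope = 0, intercept = mean(values), se = NA_real_,
                mean_age = mean(ages), residuals = values - mean(values),
                skipped = TRUE))
  }
  fit <- lm(values ~ ages)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       se = summary(fit)$coefficients[2, 2], mean_age = mean(ages),
       residuals = unname(fit$residuals), skipped = FALSE)
}

.age_adjust <- function(value, age, agefit) {
  value - agefit$slope * (age - agefit$mean_age)
}

#' Robust outlier screen across parameters
#'
#' A control subject is excluded when any parameter's robust z score
#' (median/MAD, MAD floored at a small epsilon) exceeds 3.29 in magnitude;
#' exclusion applies to all subsequent analyses. Refuses (with an error)
#' when more than 25\% of subjects would be excluded, which indicates a
#' model misfit rather than genuine outliers.
#'
#' @param value_matrix Data.frame or matrix of (transformed) parameter
#'   values, one row per observation.
#' @param subject_ids Subject id per row.
#' @param z_limit Robust z magnitude above which a value is an outlier.
#' @return List with \code{kept} and \code{excluded} subject ids.
#' @export
remove_outliers <- function(value_matrix, subject_ids, z_limit = 3.29) {
  value_matrix <- as.data.frame(value_matrix)
  stopifnot(nrow(value_matrix) == length(subject_ids))
  flagged <- rep(FALSE, nrow(value_matrix))
  for (j in seq_along(value_matrix)) {
    x <- value_matrix[[j]]
    m <- median(x, na.rm = TRUE)
    s <- max(mad(x, na.rm = TRUE), 1e-8)
    flagged <- flagged | (!is.na(x) & abs(x - m) / s > z_limit)
  }
  excluded <- unique(subject_ids[flagged])
  all_ids <- unique(subject_ids)
  if (length(excluded) > 0.25 * length(all_ids))
    stop("outlier screen would exclude > 25% of controls (",
         length(excluded), " of ", length(all_ids),
         "); refusing - check model fit")
  list(kept = setdiff(all_ids, excluded), excluded = excluded)
}

#' Two-group effect test (sex or handedness)
#'
#' Two-sample test of a parameter between groups: Welch t test on
#' normalizable (transformed) values, Wilcoxon rank-sum otherwise, at the
#' given alpha. A significant sex effect triggers sex-stratified cutoffs
#' downstream.
#'
#' @param values Parameter values (transformed scale when normalizable).
#' @param labels Two-level group labels.
#' @param normalizable Whether the values are (transformed-to-)normal.
#' @param alpha Test level (default 0.05).
#' @param min_per_group Minimum group size to run the test.
#' @return List with \code{tested}, \code{p}, \code{significant} and
#'   \code{method}.
#' @export
test_group_effects <- function(values, labels, normalizable = TRUE,
                               alpha = 0.05, min_per_group = 5) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < min_per_group))
    return(list(tested = FALSE, p = NA_real_, significant = FALSE,
                method = "none"))
  if (normalizable) {
    p <- t.test(values ~ labels)$p.value
    method <- "t"
  } else {
    p <- wilcox.test(values ~ labels, exact = FALSE)$p.value
    method <- "wilcoxon"
  }
  list(tested = TRUE, p = p, significant = p < alpha, method = method)
}

#' Empirical percentile cutoff
#'
#' Empirical percentile under the linear-interpolation definition
#' (\code{quantile} type 7): the 5th percentile for low-tail parameters,
#' the 95th for high-tail ones.
#'
#' @param values Control values (any scale; monotone transforms commute
#'   with percentiles).
#' @param tail "low" or "high".
#' @param percentile Cutoff percentile (5 for low tail, 95 for high tail by
#'   default).
#' @return The cutoff value.
#' @export
compute_cutoffs <- function(values, tail = c("low", "high"),
                            percentile = NULL) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  if (is.null(percentile)) percentile <- if (tail == "low") 5 else 95
  unname(quantile(values, percentile / 100, type = 7))
}

#' Velocity-difference threshold from control data
#'
#' The catch-detection threshold: the 99th empirical percentile of the
#' control between-arm velocity-difference values. The (n+1)p order
#' statistic convention (\code{quantile} type 6) is used for this extreme
#' percentile so that the expected exceedance among new healthy subjects
#' matches the nominal 1 percent: the interpolation convention used for
#' the 5th/95th cutoffs systematically underestimates an extreme quantile
#' at n near 100, which would let healthy catch rates exceed nominal.
#' When no control data are supplied the packaged default of 50.1 deg/s is
#' returned, flagged as the published normative value.
#'
#' @param diffs Control between-arm velocity-difference values, deg/s (per
#'   subject), or \code{NULL}.
#' @param percentile Percentile (default 99).
#' @return Threshold in deg/s with attribute \code{"provenance"} set to
#'   \code{"fitted"} or \code{"paper default"}.
#' @export
velocity_difference_threshold <- function(diffs = NULL, percentile = 99) {
  diffs <- diffs[!is.na(diffs)]
  if (is.null(diffs) || !length(diffs))
    return(structure(kaps_default_threshold(),
                     provenance = "paper default"))
  structure(unname(quantile(diffs, percentile / 100, type = 6)),
            provenance = "fitted")
}

.fit_entry <- function(df, tail, shapiro_alpha, alpha, percentiles,
                       min_stratum = 20) {
  agefit <- fit_age_regression(df$value, df$age)
  adjusted <- .age_adjust(df$value, df$age, agefit)
  bc <- tryCatch(boxcox_normalize(adjusted, shapiro_alpha),
                 error = function(e) NULL)
  normalizable <- !is.null(bc) && bc$normalizable
  tvals <- if (normalizable) bc$transformed else adjusted

  sexfit <- test_group_effects(tvals, df$sex, normalizable, alpha)
  handfit <- if (!is.null(df$handedness))
    test_group_effects(tvals, df$handedness, normalizable, alpha)
  else list(tested = FALSE, p = NA_real_, significant = FALSE,
            method = "none")
  strata <- if (isTRUE(sexfit$significant)) "sex" else "none"

  pct <- if (tail == "low") percentiles[1] else percentiles[2]
  make_stats <- function(tv) {
    cutoff_t <- compute_cutoffs(tv, tail, pct)
    cutoff <- if (normalizable)
      boxcox_inverse(cutoff_t, bc$lambda) - bc$shift else cutoff_t
    list(mean = if (normalizable) mean(tv) else NA_real_,
         sd = if (normalizable) sd(tv) else NA_real_,
         cutoff_transformed = cutoff_t, cutoff = cutoff, n = length(tv))
  }
  stats <- list(all = make_stats(tvals))
  if (strata == "sex") {
    for (s in unique(as.character(df$sex))) {
      tv <- tvals[df$sex == s]
      if (length(tv) < min_stratum) {
        warning("stratum ", s, " has fewer than ", min_stratum,
                " controls; falling back to pooled cutoff")
        stats[[s]] <- stats$all
      } else stats[[s]] <- make_stats(tv)
    }
  }
  list(tail = tail, n = nrow(df), age = agefit,
       lambda = if (normalizable) bc$lambda else NA_real_,
       shift = if (normalizable) bc$shift else 0,
       normalizable = normalizable,
       shapiro_p = if (!is.null(bc)) bc$shapiro_p else NA_real_,
       strata = strata, sex = sexfit, handedness = handfit,
       cutoff_percentile = pct, stats = stats)
}

.single_params <- c("peak_velocity", "final_angle", "creep")
.bilateral_params <- c("d_peak_velocity", "d_final_angle", "d_creep")

# long value table for one parameter x direction; single-limb parameters
# pool both arms as observations
.entry_values <- function(params, demo, dir, par) {
  p <- params[params$direction == dir, , drop = FALSE]
  if (par %in% .single_params) {
    df <- rbind(
      data.frame(subject_id = p$subject_id, value = p[[par]]),
      data.frame(subject_id = p$subject_id,
                 value = p[[paste0("ref_", par)]]))
  } else {
    df <- data.frame(subject_id = p$subject_id, value = p[[par]])
  }
  df <- merge(df, demo, by = "subject_id")
  df[!is.na(df$value), , drop = FALSE]
}

#' Fit the normative model from a control cohort
#'
#' Builds the full normative model for the six modelled parameters per
#' direction (the catch angle is normed through the velocity-difference
#' threshold instead): per parameter, age regression, Box-Cox
#' normalization with a Shapiro-Wilk gate, then a robust outlier screen
#' across all parameters (excluded controls are dropped from all
#' analyses and the model refitted), sex and handedness effect tests with
#' sex-stratified cutoffs where warranted, empirical percentile cutoffs
#' back-transformed to original units, and the 99th-percentile
#' velocity-difference threshold.
#'
#' Single-limb parameters pool both control arms as observations, so
#' cutoffs describe the distribution of a single arm's value.
#'
#' @param params A \code{kaps_parameters} data.frame of control subjects
#'   (one duration).
#' @param demographics Data.frame with \code{subject_id}, \code{age},
#'   \code{sex} ("M"/"F"), optional \code{handedness} ("R"/"L").
#' @param percentiles Low/high cutoff percentiles (default 5 and 95).
#' @param threshold_percentile Percentile for the velocity-difference
#'   threshold (default 99).
#' @param shapiro_alpha Normality-gate alpha.
#' @param alpha Group-effect test alpha.
#' @param outlier_z Robust z magnitude for the outlier screen.
#' @param threshold_basis Control quantity from which the threshold is
#'   fitted: \code{"difference_trace_peak"} (the per-subject peak of the
#'   between-arm |velocity difference| trace; default) or
#'   \code{"peak_difference"} (the absolute difference of the two arms'
#'   peak velocities).
#' @return An object of class \code{kaps_model}.
#' @export
fit_normative_model <- function(params, demographics,
                                percentiles = c(5, 95),
                                threshold_percentile = 99,
                                shapiro_alpha = 0.01, alpha = 0.05,
                                outlier_z = 3.29,
                                threshold_basis = c("difference_trace_peak",
                                                    "peak_difference")) {
  threshold_basis <- match.arg(threshold_basis)
  stopifnot(is.data.frame(params), is.data.frame(demographics),
            all(c("subject_id", "age", "sex") %in% names(demographics)))
  if (length(unique(params$duration_ms)) > 1)
    stop("fit the model on a single duration (filter params first)")
  tails <- kaps_parameter_tails()

  fit_all <- function(keep_ids) {
    entries <- list()
    for (r in seq_len(nrow(tails))) {
      dir <- tails$direction[r]; par <- tails$parameter[r]
      df <- .entry_values(params, demographics, dir, par)
      df <- df[df$subject_id %in% keep_ids, , drop = FALSE]
      e <- .fit_entry(df, tails$tail[r], shapiro_alpha, alpha, percentiles)
      e$parameter <- par; e$direction <- dir
      e$values <- df # kept for the outlier screen; dropped before return
      entries[[paste(dir, par, sep = ":")]] <- e
    }
    entries
  }

  all_ids <- unique(params$subject_id)
  entries <- fit_all(all_ids)

  # outlier screen in transformed space; a subject is screened on every
  # value it contributed (both arms for single-limb parameters). Entries
  # that could not be normalized are skipped: the 3.29 robust-z criterion
  # is a normal-theory threshold, and applying it to skewed raw values
  # would trim the very tails the percentile cutoffs estimate.
  flagged <- character(0)
  for (e in entries) {
    if (!e$normalizable) next
    adj <- .age_adjust(e$values$value, e$values$age, e$age)
    x <- boxcox_transform(pmax(adj + e$shift, 1e-8), e$lambda)
    m <- median(x); s <- max(mad(x), 1e-8)
    flagged <- c(flagged, e$values$subject_id[abs(x - m) / s > outlier_z])
  }
  excluded <- unique(flagged)
  if (length(excluded) > 0.25 * length(all_ids))
    stop("outlier screen would exclude > 25% of controls (",
         length(excluded), " of ", length(all_ids),
         "); refusing - check model fit")
  kept <- setdiff(all_ids, excluded)
  if (length(excluded)) entries <- fit_all(kept)
  entries <- lapply(entries, function(e) { e$values <- NULL; e })

  # the velocity-difference threshold is part of the outcome-measure
  # definitions and is fitted on the full control cohort, before the
  # normative outlier screen: excluding high-asymmetry controls first
  # would truncate exactly the tail the 99th percentile estimates and
  # bias healthy catch rates upward. One value per participant (max
  # across directions) keeps the percentile over independent subjects.
  vd <- switch(threshold_basis,
               difference_trace_peak = params$vdiff_peak,
               peak_difference = params$d_peak_velocity)
  vd <- tapply(vd, params$subject_id, max, na.rm = TRUE)
  threshold <- velocity_difference_threshold(as.numeric(vd),
                                             threshold_percentile)

  structure(list(entries = entries,
                 velocity_difference_threshold = as.numeric(threshold),
                 threshold_provenance = attr(threshold, "provenance"),
                 threshold_basis = threshold_basis,
                 duration_ms = unique(params$duration_ms),
                 n_controls_used = length(kept),
                 excluded_outlier_ids = excluded,
                 percentiles = percentiles),
            class = "kaps_model")
}

.model_entry <- function(model, parameter, direction) {
  e <- model$entries[[paste(direction, parameter, sep = ":")]]
  if (is.null(e))
    stop("no fitted model entry for ", parameter, " (", direction, ")")
  e
}

.entry_stats <- function(entry, sex) {
  if (entry$strata == "sex") {
    if (is.null(sex) || is.na(sex) || !sex %in% names(entry$stats))
      stop("classification error: sex required for the stratified ",
           entry$parameter, " (", entry$direction, ") entry")
    entry$stats[[sex]]
  } else entry$stats$all
}

#' Z score of a subject value under the normative model
#'
#' For normalizable parameters, the age-adjusted value is Box-Cox
#' transformed and standardised against the control mean and SD in
#' transformed space; the sign is oriented so that positive z points
#' toward the impaired tail (larger z = worse). Non-normalizable
#' parameters carry no z, only the percentile flag.
#'
#' @param model A \code{kaps_model}.
#' @param parameter,direction Parameter id and direction.
#' @param value Subject value (original units).
#' @param age Subject age, years.
#' @param sex "M" or "F" (needed for stratified entries).
#' @return List with \code{z} (NA when not defined), \code{impaired}
#'   (logical), and \code{normalizable}.
#' @export
kaps_zscore <- function(model, parameter, direction, value, age,
                        sex = NULL) {
  e <- .model_entry(model, parameter, direction)
  st <- .entry_stats(e, sex)
  adj <- .age_adjust(value, age, e$age)
  z <- NA_real_
  if (e$normalizable && !is.na(value)) {
    tv <- boxcox_transform(max(adj + e$shift, 1e-8), e$lambda)
    z <- (tv - st$mean) / st$sd
    if (e$tail == "low") z <- -z # positive z = toward impaired tail
  }
  impaired <- if (is.na(value)) NA else if (e$tail == "low")
    adj < st$cutoff else adj > st$cutoff
  list(z = z, impaired = impaired, normalizable = e$normalizable)
}

#' @export
print.kaps_model <- function(x, ...) {
  cat("<kaps_model>", length(x$entries), "entries,",
      x$n_controls_used, "controls used (",
      length(x$excluded_outlier_ids), "outliers removed )\n")
  cat("  velocity-difference threshold:",
      round(x$velocity_difference_threshold, 2), "deg/s (",
      x$threshold_provenance, ")\n")
  for (e in x$entries)
    cat(sprintf("  %-10s %-16s tail=%-4s %s strata=%-4s cutoff(all)=%.3g\n",
                e$direction, e$parameter, e$tail,
                if (e$normalizable)
                  sprintf("lambda=%+.2f", e$lambda) else "nonparam  ",
                e$strata, e$stats$all$cutoff))
  invisible(x)
}

#' Serialize / restore a normative model as JSON
#'
#' @param model A \code{kaps_model}.
#' @param path Output (or input) JSON path.
#' @return \code{write_normative_model}: the path, invisibly;
#'   \code{read_normative_model}: a \code{kaps_model}.
#' @export
write_normative_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  m$excluded_outlier_ids <- as.character(unlist(m$excluded_outlier_ids))
  m$percentiles <- as.numeric(unlist(m$percentiles))
  structure(m, class = "kaps_model")
}
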