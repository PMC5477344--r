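#' Classify one parameter value against the normative model
#'
#' One-tailed comparison of a subject's (age-adjusted) value against the
#' model entry's percentile cutoff, using the stratum matching the
#' subject's sex when the entry is sex-stratified. Values exactly at the
#' cutoff are "normal" (strict inequality).
#'
#' @param model A \code{kaps_model}.
#' @param parameter,direction Parameter id and direction.
#' @param value Subject value (original units).
#' @param age Subject age, years.
#' @param sex "M" or "F"; required for stratified entries.
#' @return "impaired" or "normal" (NA for a missing value).
#' @export
classify_parameter <- function(model, parameter, direction, value, age,
                               sex = NULL) {
  r <- kaps_zscore(model, parameter, direction, value, age, sex)
  if (is.na(r$impaired)) return(NA_character_)
  if (r$impaired) "impaired" else "normal"
}

#' Assess one subject against the normative model
#'
#' Applies the normative model to a subject's full KAPS parameter set:
#' per-parameter impairment flags and z scores for the six modelled
#' parameters per direction, a catch flag per direction (a detected catch
#' counts as a failure, since the detection threshold is already the
#' control 99th percentile), and failure counts over the 14 slots (7
#' parameters x 2 directions), reported both with and without the catch
#' parameter. Parameters that could not be computed are listed and
#' excluded from the failure-count denominator.
#'
#' @param params A \code{kaps_parameters} data.frame for one subject at the
#'   model's duration (one row per direction).
#' @param model A \code{kaps_model}.
#' @param age Subject age, years.
#' @param sex "M" or "F".
#' @param group Optional group label carried into the report.
#' @return An object of class \code{kaps_report}: list with
#'   \code{subject_id}, \code{group}, \code{table} (one row per parameter x
#'   direction: value, z, flag), \code{n_failed},
#'   \code{n_failed_excl_catch}, \code{n_evaluated}, \code{missing}.
#' @export
assess_subject <- function(params, model, age, sex = NULL, group = NULL) {
  stopifnot(is.data.frame(params), inherits(model, "kaps_model"))
  params <- params[params$duration_ms == model$duration_ms, , drop = FALSE]
  if (!nrow(params))
    stop("no parameter rows at the model duration (",
         model$duration_ms, " ms)")
  subject_id <- params$subject_id[1]
  modelled <- c(.single_params, .bilateral_params)
  rows <- list()
  for (dir in c("extension", "flexion")) {
    p <- params[params$direction == dir, , drop = FALSE]
    for (par in modelled) {
      value <- if (nrow(p)) p[[par]][1] else NA_real_
      if (is.na(value)) {
        rows[[length(rows) + 1]] <- data.frame(
          direction = dir, parameter = par, value = NA_real_,
          z = NA_real_, flag = NA_character_)
        next
      }
      r <- kaps_zscore(model, par, dir, value, age, sex)
      rows[[length(rows) + 1]] <- data.frame(
        direction = dir, parameter = par, value = value, z = r$z,
        flag = if (r$impaired) "impaired" else "normal")
    }
    ca <- if (nrow(p)) p$catch_angle[1] else NA_real_
    detected <- nrow(p) > 0 && !is.na(ca)
    rows[[length(rows) + 1]] <- data.frame(
      direction = dir, parameter = "catch_angle",
      value = if (detected) ca else NA_real_, z = NA_real_,
      flag = if (nrow(p)) (if (detected) "impaired" else "normal")
             else NA_character_)
  }
  tab <- do.call(rbind, rows)
  evaluated <- !is.na(tab$flag)
  failed <- evaluated & tab$flag == "impaired"
  excl <- tab$parameter != "catch_angle"
  structure(list(
    subject_id = subject_id, group = group, table = tab,
    n_failed = sum(failed),
    n_failed_excl_catch = sum(failed & excl),
    n_evaluated = sum(evaluated),
    missing = paste(tab$direction[!evaluated], tab$parameter[!evaluated],
                    sep = ":")),
    class = "kaps_report")
}

#' @export
print.kaps_report <- function(x, ...) {
  cat(sprintf("<kaps_report> %s%s: failed %d of %d parameters\n",
              x$subject_id,
              if (!is.null(x$group)) paste0(" (", x$group, ")") else "",
              x$n_failed, x$n_evaluated))
  fl <- x$table[!is.na(x$table$flag) & x$table$flag == "impaired", ]
  if (nrow(fl))
    cat("  impaired:", paste(fl$direction, fl$parameter, sep = ":",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Group failure rates and cumulative failure profiles
#'
#' Summarises a set of assessment reports by group: the percentage of each
#' group impaired on each parameter, the cumulative distribution of
#' per-subject failure counts per group, and the control 95th-percentile
#' failure-count boundary (computed from the reports whose group label
#' matches \code{control_group}).
#'
#' @param reports List of \code{kaps_report}s.
#' @param groups Group label per report (defaults to the labels stored in
#'   the reports).
#' @param control_group Label identifying the control group.
#' @return List with \code{rates} (data.frame group x direction x
#'   parameter, percent impaired), \code{failure_counts} (data.frame
#'   subject, group, n_failed), \code{cumulative} (per group, the
#'   proportion of subjects failing <= k parameters for k = 0..14), and
#'   \code{control_boundary} (95th percentile of control failure counts, NA
#'   when there are no controls).
#' @export
group_failure_rates <- function(reports, groups = NULL,
                                control_group = "control") {
  stopifnot(length(reports) >= 1)
  if (is.null(groups))
    groups <- vapply(reports, function(r)
      if (is.null(r$group)) "all" else r$group, "")
  tabs <- do.call(rbind, lapply(seq_along(reports), function(i) {
    t <- reports[[i]]$table
    t$group <- groups[i]
    t
  }))
  tabs <- tabs[!is.na(tabs$flag), , drop = FALSE]
  rates <- aggregate(flag ~ group + direction + parameter, data = tabs,
                     FUN = function(f) 100 * mean(f == "impaired"))
  names(rates)[names(rates) == "flag"] <- "percent_impaired"

  fc <- data.frame(
    subject_id = vapply(reports, function(r) r$subject_id, ""),
    group = groups,
    n_failed = vapply(reports, function(r) r$n_failed, 0L))
  ks <- 0:14
  cumulative <- do.call(rbind, lapply(split(fc, fc$group), function(g) {
    data.frame(group = g$group[1], n_failed = ks,
               cum_prop = vapply(ks, function(k) mean(g$n_failed <= k), 0))
  }))
  rownames(cumulative) <- NULL
  ctrl <- fc$n_failed[fc$group == control_group]
  boundary <- if (length(ctrl)) unname(quantile(ctrl, 0.95, type = 7))
              else NA_real_
  list(rates = rates, failure_counts = fc, cumulative = cumulative,
       control_boundary = boundary)
}
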