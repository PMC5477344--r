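#' Validate a trial recording against the schema
#'
#' Checks the on-disk trial schema invariants: required metadata fields and
#' data columns, uniform 1 kHz sampling (a gap is reported with its sample
#' index), trial index 1-3, canonical nominal durations, command timing
#' consistency (onset + duration <= next onset <= end of recording),
#' direction/target consistency and a plausible angle range.
#'
#' @param trial A \code{kaps_trial}.
#' @param angle_tolerance Allowance (deg) beyond the [60, 150] recording
#'   range, to accommodate measurement noise.
#' @return The trial, invisibly, if valid; otherwise an error with a
#'   field-level message.
#' @export
validate_trial <- function(trial, angle_tolerance = 5) {
  if (!inherits(trial, "kaps_trial") || !is.list(trial$meta) ||
      !is.data.frame(trial$data))
    stop("schema error: not a kaps_trial (need meta list + data frame)")
  m <- trial$meta
  need <- c("subject_id", "arm", "direction", "nominal_duration_ms",
            "trial_index", "onset_ms", "start_angle_deg",
            "target_angle_deg", "next_onset_ms", "sample_rate_hz")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("schema error: missing metadata field(s): ",
         paste(miss, collapse = ", "))
  cols <- c("time_ms", "angle_deg", "velocity_deg_s")
  missc <- setdiff(cols[1:2], names(trial$data))
  if (length(missc))
    stop("schema error: missing data column(s): ",
         paste(missc, collapse = ", "))
  if (!m$arm %in% c("affected", "less_affected", "dominant", "non_dominant"))
    stop("schema error: arm must be affected/less_affected/dominant/non_dominant")
  if (!m$direction %in% c("flexion", "extension"))
    stop("schema error: direction must be flexion or extension")
  if (!m$nominal_duration_ms %in% .canonical_durations)
    stop("schema error: nominal_duration_ms must be one of ",
         paste(.canonical_durations, collapse = ", "))
  if (!m$trial_index %in% 1:3)
    stop("schema error: trial_index must be 1, 2 or 3 (got ",
         m$trial_index, ")")
  dt <- 1000 / m$sample_rate_hz
  d <- diff(trial$data$time_ms)
  bad <- which(abs(d - dt) > 1e-6)
  if (length(bad))
    stop(sprintf(
      "schema error: non-uniform sampling, gap of %g ms after sample %d",
      d[bad[1]], bad[1]))
  if (m$onset_ms + m$nominal_duration_ms > m$next_onset_ms)
    stop("schema error: next_onset_ms precedes end of movement")
  last_t <- trial$data$time_ms[nrow(trial$data)]
  if (m$next_onset_ms > last_t + dt + 1e-9)
    stop("schema error: next_onset_ms beyond end of recording ",
         "(metadata/body length mismatch)")
  rng <- range(trial$data$angle_deg)
  if (rng[1] < 60 - angle_tolerance || rng[2] > 150 + angle_tolerance)
    stop(sprintf(
      "schema error: angle_deg outside [%g, %g] (observed [%g, %g])",
      60 - angle_tolerance, 150 + angle_tolerance, rng[1], rng[2]))
  if (m$direction == "extension" && m$target_angle_deg <= m$start_angle_deg)
    stop("schema error: extension trials must have target_angle > start_angle")
  if (m$direction == "flexion" && m$target_angle_deg >= m$start_angle_deg)
    stop("schema error: flexion trials must have target_angle < start_angle")
  invisible(trial)
}

#' Write / read a trial recording
#'
#' A trial is stored as a CSV body (columns \code{time_ms, angle_deg,
#' velocity_deg_s}) plus a JSON sidecar with the metadata fields, both
#' UTF-8. \code{write_trial} returns the CSV path; \code{read_trial}
#' validates the reconstructed record against the schema so that the
#' round-trip is the identity on schema-valid files.
#'
#' @param trial A \code{kaps_trial}.
#' @param path CSV path (the sidecar uses the same stem with extension
#'   \code{.json}).
#' @return \code{write_trial}: the CSV path, invisibly. \code{read_trial}:
#'   a validated \code{kaps_trial}.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  utils::write.csv(trial$data, path, row.names = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(trial$meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(path)) stop("schema error: no such trial file: ", path)
  if (!file.exists(side)) stop("schema error: missing JSON sidecar: ", side)
  data <- utils::read.csv(path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  meta$trial_index <- as.integer(meta$trial_index)
  trial <- structure(list(meta = meta, data = data), class = "kaps_trial")
  validate_trial(trial)
  trial
}

#' Movement-window segmentation
#'
#' Computes analysis windows from the command metadata (never from
#' data-driven onset detection): the movement window \code{[onset, onset +
#' nominal duration]}, the post-stretch sample at 1000 ms after nominal
#' movement end, and the end of the hold (last sample before the next
#' onset). If the hold is shorter than 1000 ms, the post-stretch sample is
#' clipped to the hold end with a warning.
#'
#' @param trial A valid \code{kaps_trial}.
#' @return An object of class \code{kaps_windows}: list with
#'   \code{movement} (length-2, ms), \code{post_stretch_ms},
#'   \code{hold_end_ms}, and a logical \code{clipped}.
#' @export
segment <- function(trial) {
  validate_trial(trial)
  m <- trial$meta
  dt <- 1000 / m$sample_rate_hz
  movement <- c(m$onset_ms, m$onset_ms + m$nominal_duration_ms)
  hold_end <- m$next_onset_ms - dt
  post <- movement[2] + 1000
  clipped <- FALSE
  if (post > hold_end) {
    warning("hold shorter than 1000 ms; post-stretch sample clipped to ",
            "hold end")
    post <- hold_end
    clipped <- TRUE
  }
  structure(list(movement = movement, post_stretch_ms = post,
                 hold_end_ms = hold_end, clipped = clipped),
            class = "kaps_windows")
}

#' @export
print.kaps_windows <- function(x, ...) {
  cat(sprintf(
    "<kaps_windows> movement [%g, %g] ms, post-stretch %g ms, hold end %g ms%s\n",
    x$movement[1], x$movement[2], x$post_stretch_ms, x$hold_end_ms,
    if (x$clipped) " (clipped)" else ""))
  invisible(x)
}

# index helpers: time (ms) -> row index
.t2i <- function(trial, t_ms) {
  round(t_ms * trial$meta$sample_rate_hz / 1000) + 1L
}
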