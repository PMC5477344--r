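#' Published normative cutoff values (reference)
#'
#' The percentile cutoff values reported for the original 96-subject
#' normative cohort at the 600 ms stretch, usable for orientation or when
#' no control cohort is available to refit. These are reference constants
#' from that cohort's data - they are not recomputable from this package
#' and are not used by the fitting code.
#'
#' Stratum "all" marks parameters without a sex effect; "M"/"F" carry the
#' sex-stratified cutoffs. Tails follow
#' \code{\link{kaps_parameter_tails}}.
#'
#' @return Data.frame with columns \code{direction}, \code{parameter},
#'   \code{stratum}, \code{tail}, \code{cutoff}; the companion
#'   velocity-difference threshold is \code{\link{kaps_default_threshold}()}.
#' @export
kaps_reference_cutoffs <- function() {
  df <- rbind(
    data.frame(direction = "extension", parameter = "peak_velocity",
               stratum = "all", cutoff = 286),
    data.frame(direction = "extension", parameter = "final_angle",
               stratum = c("M", "F"), cutoff = c(140, 141)),
    data.frame(direction = "extension", parameter = "creep",
               stratum = "all", cutoff = 0.16),
    data.frame(direction = "extension", parameter = "d_peak_velocity",
               stratum = c("M", "F"), cutoff = c(33.5, 27.5)),
    data.frame(direction = "extension", parameter = "d_final_angle",
               stratum = "all", cutoff = -1.9),
    data.frame(direction = "extension", parameter = "d_creep",
               stratum = c("M", "F"), cutoff = c(0.26, 0.37)),
    data.frame(direction = "flexion", parameter = "peak_velocity",
               stratum = c("M", "F"), cutoff = c(240, 255)),
    data.frame(direction = "flexion", parameter = "final_angle",
               stratum = c("M", "F"), cutoff = c(69, 70)),
    data.frame(direction = "flexion", parameter = "creep",
               stratum = "all", cutoff = 0.28),
    data.frame(direction = "flexion", parameter = "d_peak_velocity",
               stratum = c("M", "F"), cutoff = c(33.7, 30.7)),
    data.frame(direction = "flexion", parameter = "d_final_angle",
               stratum = "all", cutoff = 2.06),
    data.frame(direction = "flexion", parameter = "d_creep",
               stratum = "all", cutoff = 0.41))
  df <- merge(df, kaps_parameter_tails(), by = c("direction", "parameter"),
              sort = FALSE)
  df[, c("direction", "parameter", "stratum", "tail", "cutoff")]
}
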