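#' Two-way random-effects, single-measure, absolute-agreement ICC
#'
#' ICC(2,1): the intraclass correlation for absolute agreement between
#' raters under a two-way random-effects model, computed from the two-way
#' ANOVA mean squares
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares, \eqn{n} subjects, \eqn{k} raters. A systematic
#' rater offset therefore lowers the estimate (absolute agreement, not
#' consistency).
#'
#' @param ratings Numeric matrix or data.frame, one row per subject, one
#'   column per rater (n >= 3, k >= 2), no missing cells.
#' @return List with \code{icc}, the mean squares (\code{ms_subject},
#'   \code{ms_rater}, \code{ms_error}) and \code{n}, \code{k}.
#' @examples
#' set.seed(1)
#' s <- rnorm(50, sd = 3)
#' icc_absolute_agreement(cbind(s + rnorm(50), s + rnorm(50)))
#' @export
icc_absolute_agreement <- function(ratings) {
  x <- as.matrix(ratings)
  if (any(is.na(x))) stop("ratings must have no missing pairs")
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 3, k >= 2)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ms_r <- k * sum((rm_ - grand)^2) / (n - 1)
  ms_c <- n * sum((cm - grand)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (abs(denom) < 1e-12)
    stop("undefined ICC: zero total variance in ratings")
  list(icc = (ms_r - ms_e) / denom, ms_subject = ms_r, ms_rater = ms_c,
       ms_error = ms_e, n = n, k = k)
}

# midranks (ties averaged); tie-corrected Spearman rho is the Pearson
# correlation of midranks
.spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) return(NA_real_)
  cor(rx, ry)
}

.all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

.spearman_p <- function(x, y, rho) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n <= 7) { # exact permutation null, handles ties exactly
    perms <- .all_perms(seq_len(n))
    rhos <- vapply(perms, function(p) .spearman_rho(x, y[p]), 0)
    return(mean(abs(rhos) >= abs(rho) - 1e-12))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Spearman correlations with Bonferroni control
#'
#' Tie-corrected Spearman rank correlation (Pearson correlation of
#' midranks) between each kinematic parameter and each clinical score,
#' with the family-wise significance level divided by the number of tests.
#' P values are exact (full permutation enumeration) for n <= 7 and use
#' the t approximation otherwise.
#'
#' @param parameters Data.frame (or named list) of numeric parameter
#'   columns.
#' @param clinical Data.frame of clinical score columns (same row order,
#'   ordinal scores coded numerically; MAS 1+ conventionally coded 1.5).
#' @param n_tests Size of the Bonferroni family (>= 1); the corrected
#'   alpha is \code{family_alpha / n_tests}.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return A data.frame of class \code{kaps_correlations}: one row per
#'   parameter x scale with \code{rho}, \code{p}, \code{n},
#'   \code{significant}; the corrected alpha is in attribute
#'   \code{"corrected_alpha"}. Constant inputs yield an NA rho flagged
#'   \code{undefined}.
#' @export
spearman_with_bonferroni <- function(parameters, clinical, n_tests = 12,
                                     family_alpha = 0.05) {
  stopifnot(n_tests >= 1, family_alpha > 0)
  parameters <- as.data.frame(parameters)
  clinical <- as.data.frame(clinical)
  stopifnot(nrow(parameters) == nrow(clinical))
  corrected <- family_alpha / n_tests
  rows <- list()
  for (p in names(parameters)) for (s in names(clinical)) {
    ok <- complete.cases(parameters[[p]], clinical[[s]])
    x <- parameters[[p]][ok]; y <- clinical[[s]][ok]
    if (sum(ok) < 5)
      stop("need at least 5 paired observations for ", p, " vs ", s)
    rho <- .spearman_rho(x, y)
    pv <- .spearman_p(x, y, rho)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = p, scale = s, rho = rho, p = pv, n = sum(ok),
      significant = !is.na(pv) && pv < corrected,
      undefined = is.na(rho))
  }
  out <- do.call(rbind, rows)
  attr(out, "corrected_alpha") <- corrected
  class(out) <- c("kaps_correlations", "data.frame")
  out
}
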