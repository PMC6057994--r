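#' Adjust-then-transform: INT applied to covariate-adjusted residuals
#'
#' The processing order under scrutiny. The covariate is regressed out of the
#' phenotype by OLS (residuals are exactly linearly uncorrelated with the
#' covariate); the residuals are then rank-based inverse-normal transformed.
#' Although the residuals have zero Pearson correlation with the covariate, a
#' Spearman (rank) correlation generally survives adjustment — regressing the
#' covariate out of a tied or skewed phenotype imposes a covariate-based
#' ordering within tied blocks — and the INT converts that rank correlation
#' back into a linear one, typically stronger than and opposite in sign to
#' the original phenotype-covariate correlation.
#'
#' @param y Numeric phenotype vector.
#' @param covariate Numeric covariate vector of the same length.
#' @param spec A \code{\link{transform_spec}}; the default average tie
#'   handling matches applying a stock rank-based INT to the residuals
#'   (which are generically tie-free anyway).
#' @return A one-row \code{\link[tibble]{tibble}} (a "cell result") with
#'   columns \code{order} (\code{"adjust_then_int"}), \code{r_raw} (Pearson
#'   correlation of raw phenotype and covariate), \code{rho_resid} (Spearman
#'   correlation of residuals and covariate, before INT),
#'   \code{r_reintroduced} (Pearson correlation of INT-transformed residuals
#'   and covariate), \code{r_final} (identical to \code{r_reintroduced}; the
#'   transform is the last step in this arm), and \code{skew_final},
#'   \code{kurtosis_final} of the transformed residuals.
#' @seealso \code{\link{int_then_adjust}} for the recommended order.
#' @export
adjust_then_int <- function(y, covariate, spec = transform_spec()) {
  resid <- residualize(y, covariate)
  rho_resid <- stats::cor(resid, covariate, method = "spearman")
  z <- inverse_normal_transform(resid, spec)
  r_re <- stats::cor(z, covariate)
  tibble::tibble(
    order = "adjust_then_int",
    r_raw = stats::cor(y, covariate),
    rho_resid = rho_resid,
    r_reintroduced = r_re,
    r_final = r_re,
    skew_final = skewness(z),
    kurtosis_final = kurtosis(z)
  )
}

#' Transform-then-adjust: INT applied before covariate adjustment
#'
#' The recommended processing order. The raw phenotype undergoes rank-based
#' INT with random splitting of tied observations (so the transformed
#' variable is an exact permutation of normal scores), and the covariate is
#' regressed out of the transformed variable afterwards. The final residuals
#' are linearly uncorrelated with the covariate by construction — OLS
#' orthogonality is the last step — and are close to normal, at the cost of
#' the rank noise injected into tied blocks.
#'
#' When \code{y} contains ties the spec must use \code{tie_method =
#' "random"}: average-rank INT of a heavily tied variable leaves large blocks
#' of duplicated scores, which the recommended procedure exists to avoid.
#'
#' @param y Numeric phenotype vector.
#' @param covariate Numeric covariate vector of the same length.
#' @param spec A \code{\link{transform_spec}}; must use random tie-splitting
#'   if \code{y} has ties.
#' @return A one-row \code{\link[tibble]{tibble}} with columns \code{order}
#'   (\code{"int_then_adjust"}), \code{r_raw}, \code{r_raw_vs_int} (Pearson
#'   correlation of the phenotype with its own transform), \code{r_after_int}
#'   (Pearson correlation of the transformed phenotype and covariate),
#'   \code{skew_int} (skewness of the transformed phenotype, before
#'   adjustment), \code{r_final} (Pearson correlation of the final residuals
#'   and covariate, numerically zero), and \code{skew_final},
#'   \code{kurtosis_final} of the final residuals.
#' @export
int_then_adjust <- function(y, covariate, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (anyDuplicated(y) && spec$tie_method != "random") {
    stop("`y` contains tied observations: use a transform_spec with ",
         "tie_method = \"random\" so ties are split before adjustment.")
  }
  z <- inverse_normal_transform(y, spec)
  resid <- residualize(z, covariate)
  tibble::tibble(
    order = "int_then_adjust",
    r_raw = stats::cor(y, covariate),
    r_raw_vs_int = stats::cor(y, z),
    r_after_int = stats::cor(z, covariate),
    skew_int = skewness(z),
    r_final = stats::cor(resid, covariate),
    skew_final = skewness(resid),
    kurtosis_final = kurtosis(resid)
  )
}
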