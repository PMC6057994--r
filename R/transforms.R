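#' Specify a rank-based inverse normal transformation
#'
#' Bundles the two conventions that pin down a rank-based INT: the rank
#' offset \code{c} in the quantile argument \eqn{(r - c)/(n + 1 - 2c)}, and
#' how tied observations are ranked.
#'
#' With the default \code{rank_offset = 0.5} the quantile argument reduces to
#' \eqn{(r - 0.5)/n}, the convention used by GenABEL's \code{rntransform};
#' \code{rank_offset = 3/8} gives Blom scores. \code{tie_method = "average"}
#' assigns tied values their mean rank, so tied inputs map to equal outputs;
#' \code{tie_method = "random"} splits every tie uniformly at random (seeded),
#' so the output is a permutation of the \eqn{n} distinct van der Waerden
#' scores and is exactly normal in distribution.
#'
#' Random tie-splitting draws from a dedicated, seeded generator and restores
#' the caller's RNG state afterwards, so transform reproducibility never
#' depends on surrounding simulation code.
#'
#' @param rank_offset Real in (0, 1). Default 0.5.
#' @param tie_method \code{"average"} or \code{"random"}.
#' @param seed Non-negative integer; required when \code{tie_method = "random"},
#'   ignored otherwise.
#' @return An object of class \code{"transform_spec"}.
#' @examples
#' transform_spec()                                # rntransform convention
#' transform_spec(rank_offset = 3/8)               # Blom scores
#' transform_spec(tie_method = "random", seed = 1) # random tie-splitting
#' @export
transform_spec <- function(rank_offset = 0.5,
                           tie_method = c("average", "random"),
                           seed = NULL) {
  tie_method <- match.arg(tie_method)
  if (!is.numeric(rank_offset) || length(rank_offset) != 1 ||
      !is.finite(rank_offset) || rank_offset <= 0 || rank_offset >= 1) {
    stop("`rank_offset` must be a single number strictly between 0 and 1.")
  }
  if (tie_method == "random") {
    if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 ||
        is.na(seed) || seed < 0 || seed != floor(seed)) {
      stop("`tie_method = \"random\"` requires a non-negative integer `seed`.")
    }
    seed <- as.integer(seed)
  }
  structure(
    list(rank_offset = rank_offset, tie_method = tie_method, seed = seed),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("Rank-based INT spec: offset c =", x$rank_offset,
      "| ties =", x$tie_method,
      if (x$tie_method == "random") paste("| seed =", x$seed) else "", "\n")
  invisible(x)
}

#' Rank-based inverse normal transformation
#'
#' Maps each observation to the standard-normal quantile of its
#' offset-adjusted rank fraction,
#' \eqn{z_i = \Phi^{-1}((r_i - c) / (n + 1 - 2c))},
#' where \eqn{r_i} is the rank of \eqn{x_i} (1 = smallest) and \eqn{c} is the
#' rank offset. At the default \eqn{c = 0.5} this is
#' \eqn{\Phi^{-1}((r_i - 0.5)/n)}, the van der Waerden-type score set used by
#' GenABEL's \code{rntransform}.
#'
#' Under \code{tie_method = "average"} tied values share their mean rank and
#' therefore map to equal outputs, so the transformed marginal is only
#' approximately normal when ties are present. Under
#' \code{tie_method = "random"} ties are broken uniformly at random using the
#' spec's seed: all \eqn{n} ranks are distinct and the output is a permutation
#' of the fixed score set \eqn{\{\Phi^{-1}((i - c)/(n + 1 - 2c))\}}, hence
#' exactly normal-scored, at the cost of injected rank noise within tied
#' blocks. Either way the weak ordering of the input is preserved.
#'
#' @param x Numeric vector, length at least 3, no missing values, positive
#'   variance.
#' @param spec A \code{\link{transform_spec}}.
#' @return Numeric vector of the same length as \code{x}.
#' @examples
#' inverse_normal_transform(c(10, 20, 30))
#' inverse_normal_transform(c(5, 5, 5, 9),
#'                          transform_spec(tie_method = "random", seed = 7))
#' @export
inverse_normal_transform <- function(x, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!is.numeric(x)) stop("`x` must be numeric.")
  if (anyNA(x)) {
    stop("`x` contains missing values; filter them out before transforming.")
  }
  n <- length(x)
  if (n < 3) stop("`x` must contain at least 3 observations.")
  if (stats::var(x) == 0) {
    stop("`x` is constant (zero variance) and cannot be rank-transformed.")
  }
  r <- if (spec$tie_method == "average") {
    rank(x, ties.method = "average")
  } else {
    withr::with_seed(spec$seed, rank(x, ties.method = "random"))
  }
  cc <- spec$rank_offset
  stats::qnorm((r - cc) / (n + 1 - 2 * cc))
}

#' OLS residualization against covariates
#'
#' Regresses \code{y} on an intercept plus the covariate columns by ordinary
#' least squares and returns the residuals, which have mean zero and zero
#' Pearson correlation with every covariate column (to numerical tolerance).
#' With no covariates this is simple mean-centering.
#'
#' @param y Numeric response vector.
#' @param covariates Numeric vector, matrix or data frame with one row per
#'   observation, or \code{NULL} for intercept-only centering.
#' @return Numeric residual vector, same length as \code{y}.
#' @examples
#' residualize(c(1, 2, 3, 4), c(1, 2, 3, 4))  # perfect fit: all zeros
#' residualize(rnorm(20))                     # mean-centering
#' @export
residualize <- function(y, covariates = NULL) {
  if (!is.numeric(y)) stop("`y` must be numeric.")
  if (anyNA(y)) stop("`y` contains missing values; filter them out first.")
  n <- length(y)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.matrix(covariates)
    if (anyNA(cv)) stop("covariates contain missing values; filter them out first.")
    if (nrow(cv) != n) stop("`y` and `covariates` must have the same number of rows.")
    if (is.null(colnames(cv))) colnames(cv) <- paste0("x", seq_len(ncol(cv)))
    X <- cbind("(Intercept)" = 1, cv)
  }
  p <- ncol(X) - 1L
  if (n <= p + 1L) {
    stop("Need n > p + 1 observations to residualize against ", p, " covariate(s).")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("Design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(qx, y))
}

moment_check <- function(x, min_n, what) {
  if (!is.numeric(x)) stop("`x` must be numeric.")
  if (anyNA(x)) stop("`x` contains missing values; filter them out first.")
  if (length(x) < min_n) stop(what, " requires at least ", min_n, " observations.")
  if (stats::var(x) == 0) stop(what, " is undefined for constant input (zero variance).")
}

#' Sample skewness
#'
#' Third standardized sample moment, in the three estimator conventions of
#' e1071: with \eqn{m_k = n^{-1}\sum(x_i - \bar x)^k} and
#' \eqn{g_1 = m_3 / m_2^{3/2}}, type 1 is \eqn{g_1}, type 2 is
#' \eqn{g_1\sqrt{n(n-1)}/(n-2)}, and type 3 (default) is
#' \eqn{g_1((n-1)/n)^{3/2}}.
#'
#' @param x Numeric vector, length at least 3, positive variance.
#' @param type Estimator type 1, 2 or 3 (default 3, the e1071 default).
#' @return A single number.
#' @export
skewness <- function(x, type = 3) {
  moment_check(x, 3L, "Skewness")
  e1071::skewness(x, type = type)
}

#' Sample excess kurtosis
#'
#' Fourth standardized sample moment minus 3, in the three estimator
#' conventions of e1071: type 1 is \eqn{m_4/m_2^2 - 3}; types 2 and 3 apply
#' the standard small-sample adjustments; type 3 is the default. Zero for a
#' normal population.
#'
#' @param x Numeric vector, length at least 4, positive variance.
#' @param type Estimator type 1, 2 or 3 (default 3).
#' @return A single number.
#' @export
kurtosis <- function(x, type = 3) {
  moment_check(x, 4L, "Kurtosis")
  e1071::kurtosis(x, type = type)
}

#' Distributional and association diagnostics for a phenotype-covariate pair
#'
#' Bundles the four measurements the simulation study reports for any
#' processed variable: its skewness and excess kurtosis, and its Pearson and
#' Spearman correlations with a covariate.
#'
#' @param y Numeric vector (the phenotype, residual, or transformed variable).
#' @param covariate Numeric vector of the same length.
#' @param type Moment estimator type passed to \code{\link{skewness}} and
#'   \code{\link{kurtosis}}.
#' @return An object of class \code{"diagnostic_summary"}: a list with
#'   elements \code{skew}, \code{kurtosis}, \code{pearson_r},
#'   \code{spearman_rho} and \code{n}.
#' @examples
#' diagnostics(rnorm(100), rnorm(100))
#' @export
diagnostics <- function(y, covariate, type = 3) {
  if (length(y) != length(covariate)) {
    stop("`y` and `covariate` must have equal length.")
  }
  moment_check(y, 4L, "Diagnostics")
  moment_check(covariate, 4L, "Diagnostics")
  structure(
    list(
      skew = skewness(y, type = type),
      kurtosis = kurtosis(y, type = type),
      pearson_r = stats::cor(y, covariate),
      spearman_rho = stats::cor(y, covariate, method = "spearman"),
      n = length(y)
    ),
    class = "diagnostic_summary"
  )
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d | skew = %.4f | excess kurtosis = %.4f | Pearson r = %.4f | Spearman rho = %.4f\n",
    x$n, x$skew, x$kurtosis, x$pearson_r, x$spearman_rho
  ))
  invisible(x)
}
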