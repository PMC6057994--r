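#' Population skewness of a Beta(alpha, beta) distribution
#'
#' Closed form \eqn{2(\beta - \alpha)\sqrt{\alpha + \beta + 1} /
#' ((\alpha + \beta + 2)\sqrt{\alpha\beta})}.
#'
#' @param alpha,beta Positive shape parameters.
#' @return A single number.
#' @export
beta_population_skew <- function(alpha, beta) {
  2 * (beta - alpha) * sqrt(alpha + beta + 1) /
    ((alpha + beta + 2) * sqrt(alpha * beta))
}

#' Beta shape parameters achieving a target skewness
#'
#' Solves for \code{(alpha, beta)} on the one-parameter family
#' \code{alpha + beta = total} whose population skewness equals
#' \code{target_skew}, by bisection on \code{alpha}. Along this family the
#' population skew is strictly decreasing in \code{alpha}, so the root is
#' unique; a zero target gives the symmetric \code{alpha = beta = total/2},
#' and negating the target swaps the two shapes (the mirrored distribution).
#'
#' @param target_skew Target population skewness (the simulation grid uses
#'   \eqn{[-2, 2]}; values outside are accepted while the family supports
#'   them).
#' @param total Fixed shape-parameter sum of the family; default 10.
#' @param tol Tolerance on the achieved population skew; default 1e-8.
#' @return A list of class \code{"beta_shapes"} with elements \code{alpha}
#'   and \code{beta}.
#' @examples
#' beta_shapes_for_skew(0)   # alpha = beta = 5
#' beta_shapes_for_skew(1)
#' @export
beta_shapes_for_skew <- function(target_skew, total = 10, tol = 1e-8) {
  stopifnot(is.numeric(target_skew), length(target_skew) == 1,
            is.finite(target_skew), total > 0)
  if (target_skew == 0) {
    return(structure(list(alpha = total / 2, beta = total / 2),
                     class = "beta_shapes"))
  }
  if (target_skew < 0) {
    sh <- beta_shapes_for_skew(-target_skew, total = total, tol = tol)
    return(structure(list(alpha = sh$beta, beta = sh$alpha),
                     class = "beta_shapes"))
  }
  eps <- 1e-9 * total
  lo <- eps               # alpha -> 0+: skew -> +Inf
  hi <- total / 2         # alpha = beta: skew 0
  if (beta_population_skew(lo, total - lo) < target_skew) {
    stop("Target skew ", target_skew, " is not attainable with total = ",
         total, "; increase `total`.")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    s <- beta_population_skew(mid, total - mid)
    if (hi - lo < 1e-13 * total) break
    if (s > target_skew) lo <- mid else hi <- mid
  }
  if (abs(s - target_skew) > tol) {
    stop("Bisection failed to reach tolerance ", tol, " for target skew ",
         target_skew)
  }
  structure(list(alpha = mid, beta = total - mid), class = "beta_shapes")
}

#' Specify a simulated phenotype
#'
#' Describes one simulated dependent variable: its sample size, target
#' skewness, discretization (number of response bins, or none for a
#' continuous, tie-free variable), generating family and seed.
#'
#' The \code{"beta"} family draws from the Beta distribution whose shapes are
#' solved by \code{\link{beta_shapes_for_skew}}; the \code{"normal"} family
#' (valid only at zero target skew) draws standard normals, giving zero
#' population skew and zero excess kurtosis — useful for checking that
#' effects seen at zero skew are not driven by the Beta family's non-zero
#' kurtosis.
#'
#' @param n Sample size (study default 10,000).
#' @param target_skew Target skewness, typically in \eqn{[-2, 2]}.
#' @param n_bins \code{NULL} for a continuous variable, or an integer
#'   \eqn{\ge 2}: the continuous draw is collapsed into that many
#'   equal-width response bins, creating tied observations
#'   (questionnaire-type data).
#' @param family \code{"beta"} or \code{"normal"}.
#' @param seed Non-negative integer seed.
#' @return A list of class \code{"phenotype_spec"}.
#' @export
phenotype_spec <- function(n = 10000, target_skew = 0, n_bins = NULL,
                           family = c("beta", "normal"), seed = 1) {
  family <- match.arg(family)
  stopifnot(is.numeric(n), length(n) == 1, n >= 3, n == floor(n),
            is.numeric(target_skew), length(target_skew) == 1,
            is.finite(target_skew),
            is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  if (family == "normal" && target_skew != 0) {
    stop("`family = \"normal\"` is only valid with `target_skew = 0`.")
  }
  if (!is.null(n_bins)) {
    if (is.na(n_bins)) {
      n_bins <- NULL
    } else {
      stopifnot(is.numeric(n_bins), length(n_bins) == 1, n_bins == floor(n_bins))
      if (n_bins < 2) stop("`n_bins` must be at least 2 (or NULL for continuous).")
      n_bins <- as.integer(n_bins)
    }
  }
  structure(
    list(n = as.integer(n), target_skew = target_skew, n_bins = n_bins,
         family = family, seed = as.integer(seed)),
    class = "phenotype_spec"
  )
}

#' Simulate a continuous (tie-free) phenotype
#'
#' Draws \code{n} i.i.d. values: from the Beta distribution matching the
#' spec's target skew (\code{family = "beta"}), or from the standard normal
#' (\code{family = "normal"}, target skew 0). A pure function of the spec;
#' rerunning with the same seed reproduces the vector exactly.
#'
#' @param spec A \code{\link{phenotype_spec}} (its \code{n_bins} is ignored).
#' @return Numeric vector of length \code{spec$n}.
#' @export
simulate_continuous <- function(spec) {
  stopifnot(inherits(spec, "phenotype_spec"))
  withr::with_seed(spec$seed, {
    if (spec$family == "normal") {
      stats::rnorm(spec$n)
    } else {
      sh <- beta_shapes_for_skew(spec$target_skew)
      stats::rbeta(spec$n, sh$alpha, sh$beta)
    }
  })
}

#' Simulate a questionnaire-type (tied) phenotype
#'
#' Draws the continuous variable of \code{\link{simulate_continuous}} and
#' collapses it into \code{spec$n_bins} equal-width bins spanning the sample
#' range, returning the integer bin index (0 .. k-1) as the phenotype value.
#' Equal-width (not equal-frequency) binning preserves the skew of the
#' underlying draw while guaranteeing tied observations once \code{n} exceeds
#' the bin count; binning preserves the weak ordering of the underlying
#' values.
#'
#' @param spec A \code{\link{phenotype_spec}} with \code{n_bins} set.
#' @return Integer-valued numeric vector of length \code{spec$n} taking at
#'   most \code{spec$n_bins} distinct values.
#' @export
simulate_questionnaire <- function(spec) {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (is.null(spec$n_bins)) {
    stop("`spec$n_bins` must be set for a questionnaire-type phenotype.")
  }
  x <- simulate_continuous(spec)
  bin_equal_width(x, spec$n_bins)
}

#' Collapse a continuous vector into equal-width bins
#'
#' @param x Numeric vector.
#' @param k Number of bins (at least 2).
#' @return Numeric vector of bin indices in 0 .. k-1.
#' @keywords internal
bin_equal_width <- function(x, k) {
  if (k < 2) stop("`k` must be at least 2.")
  breaks <- seq(min(x), max(x), length.out = k + 1)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE) - 1
}

#' Simulate a phenotype (continuous or questionnaire-type)
#'
#' Dispatches on \code{spec$n_bins}: \code{NULL} gives the continuous
#' variable, an integer gives the binned questionnaire-type variable.
#'
#' @param spec A \code{\link{phenotype_spec}}.
#' @return Numeric vector of length \code{spec$n}.
#' @export
simulate_phenotype <- function(spec) {
  if (is.null(spec$n_bins)) simulate_continuous(spec) else simulate_questionnaire(spec)
}

#' Specify a correlated covariate
#'
#' @param target_r Target Pearson correlation with the phenotype, non-zero,
#'   in \eqn{(-1, 1)} (the study grid uses \eqn{[-0.5, 0.5]}).
#' @param tolerance Acceptable |achieved r - target r|; default 0.005.
#' @param seed Non-negative integer seed.
#' @return A list of class \code{"covariate_spec"}.
#' @export
covariate_spec <- function(target_r, tolerance = 0.005, seed = 1) {
  stopifnot(is.numeric(target_r), length(target_r) == 1, is.finite(target_r),
            is.numeric(tolerance), length(tolerance) == 1, tolerance > 0,
            is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  if (abs(target_r) <= 0 || abs(target_r) >= 1) {
    stop("`target_r` must satisfy 0 < |target_r| < 1.")
  }
  structure(
    list(target_r = target_r, tolerance = tolerance, seed = as.integer(seed)),
    class = "covariate_spec"
  )
}

#' Construct a covariate with a target correlation to a phenotype
#'
#' Builds the covariate by the noise-addition scheme: Gaussian noise is added
#' to (a copy of) the phenotype and its scale tuned until the sample Pearson
#' correlation with the phenotype hits the target. The noise standard
#' deviation starts at the closed-form value
#' \eqn{\sigma_0 = \mathrm{sd}(y)\sqrt{1/r^2 - 1}} — which yields population
#' correlation \eqn{|r|} exactly for the additive construction — and is then
#' refined by bisection (the sample correlation is monotone decreasing in the
#' noise scale for a fixed noise draw) until
#' \eqn{|\hat r - |r|| \le} \code{tolerance}. A negative target flips the sign
#' of the returned covariate.
#'
#' Tied phenotypes (questionnaire-type) first receive a small uniform jitter
#' — amplitude one tenth of the smallest gap between distinct values, far too
#' small to reorder distinct bins — mirroring the use of R's \code{jitter}
#' before noise addition; the returned covariate is continuous in all cases.
#' The target correlation is always measured against the original,
#' un-jittered phenotype.
#'
#' Occasionally a noise draw is itself too correlated with the phenotype for
#' the target to be reachable at any noise scale (the sample correlation
#' tends to the raw noise-phenotype correlation as the scale grows); when
#' that happens a fresh seeded noise vector is drawn, up to
#' \code{max_redraws} times, before giving up.
#'
#' @param y Numeric phenotype vector, non-constant, length at least 10.
#' @param spec A \code{\link{covariate_spec}}.
#' @param max_iter Bisection iteration cap per noise draw; default 200.
#' @param max_redraws Fresh noise draws to attempt on non-convergence;
#'   default 5.
#' @return Numeric covariate vector of the same length as \code{y}, with the
#'   achieved correlation in attribute \code{"achieved_r"}.
#' @export
create_covariate <- function(y, spec, max_iter = 200, max_redraws = 5) {
  stopifnot(inherits(spec, "covariate_spec"))
  if (anyNA(y)) stop("`y` contains missing values; filter them out first.")
  n <- length(y)
  if (n < 10) stop("Need at least 10 observations to tune the correlation.")
  if (stats::var(y) == 0) stop("`y` is constant; correlation is undefined.")

  rt <- abs(spec$target_r)
  best_r <- NA_real_
  for (attempt in 0:max_redraws) {
    seed_a <- (spec$seed + 7919 * attempt) %% 2147483629
    draws <- withr::with_seed(seed_a, {
      z <- stats::rnorm(n)
      yj <- y
      if (anyDuplicated(y)) {
        gaps <- diff(sort(unique(y)))
        amp <- 0.1 * min(gaps)
        yj <- y + stats::runif(n, -amp, amp)
      }
      list(z = z, yj = yj)
    })
    z <- draws$z
    yj <- draws$yj
    f <- function(sigma) stats::cor(y, yj + sigma * z) - rt

    sigma0 <- stats::sd(y) * sqrt(1 / rt^2 - 1)
    lo <- 0
    hi <- sigma0
    it <- 0
    while (f(hi) > 0 && it < 60) {
      lo <- hi
      hi <- 2 * hi
      it <- it + 1
    }
    sigma <- NA_real_
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      r_mid <- fm + rt
      if (is.na(best_r) || abs(r_mid - rt) < abs(best_r - rt)) best_r <- r_mid
      if (abs(fm) <= spec$tolerance) {
        sigma <- mid
        break
      }
      if (fm > 0) lo <- mid else hi <- mid
    }
    if (!is.na(sigma)) {
      cv <- sign(spec$target_r) * (yj + sigma * z)
      attr(cv, "achieved_r") <- stats::cor(y, cv)
      return(cv)
    }
  }
  stop(sprintf(
    "Covariate construction did not converge: best achieved |r| = %.5f for target |r| = %.5f.",
    best_r, rt
  ))
}
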