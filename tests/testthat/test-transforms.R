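test_that("INT reproduces closed-form van der Waerden scores", {
  # strictly increasing input: ranks are the identity
  z <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(z, qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)

  for (n in c(7, 25, 100)) {
    x <- withr::with_seed(n, rnorm(n))
    z <- inverse_normal_transform(x)
    expect_equal(sort(z), vdw_scores(n), tolerance = 1e-12)
    expect_equal(mean(z), 0, tolerance = 1e-12)  # c = 0.5 scores are symmetric
    expect_equal(order(z), order(x))
  }

  # Blom convention: offset 3/8, denominator n + 1/4
  zb <- inverse_normal_transform(c(4, 1, 9), transform_spec(rank_offset = 3 / 8))
  expect_equal(sort(zb), qnorm((1:3 - 3 / 8) / 3.25), tolerance = 1e-12)
})

test_that("average tie handling assigns mean-rank scores to tied blocks", {
  z <- inverse_normal_transform(c(5, 5, 5, 9))
  expect_equal(z[1:3], rep(qnorm(0.375), 3))
  expect_equal(z[4], qnorm(0.875))
})

test_that("random tie-splitting permutes the tied block's scores uniformly", {
  x <- c(5, 5, 5, 9)
  tied_scores <- qnorm(c(0.125, 0.375, 0.625))
  counts <- matrix(0, 3, 3)  # position x score
  n_seeds <- 600
  for (s in seq_len(n_seeds)) {
    z <- inverse_normal_transform(x, transform_spec(tie_method = "random", seed = s))
    expect_equal(sort(z[1:3]), tied_scores, tolerance = 1e-12)
    expect_equal(z[4], qnorm(0.875))
    for (i in 1:3) counts[i, which.min(abs(tied_scores - z[i]))] <-
        counts[i, which.min(abs(tied_scores - z[i]))] + 1
  }
  # enumeration of the 3! tie orderings gives each score probability 1/3 per
  # position; 600 seeds put the frequency within ~5 binomial SDs of 1/3
  expect_true(all(abs(counts / n_seeds - 1 / 3) < 5 * sqrt((1 / 3) * (2 / 3) / n_seeds)))

  # same (input, seed) reproduces; the caller's RNG stream is untouched
  s1 <- inverse_normal_transform(x, transform_spec(tie_method = "random", seed = 42))
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  s2 <- inverse_normal_transform(x, transform_spec(tie_method = "random", seed = 42))
  expect_identical(s1, s2)
  expect_identical(rnorm(1), before)
})

test_that("INT is idempotent on tie-free input and rejects bad input", {
  x <- withr::with_seed(5, rexp(40))
  z1 <- inverse_normal_transform(x)
  expect_equal(inverse_normal_transform(z1), z1, tolerance = 1e-12)

  expect_error(inverse_normal_transform(rep(3, 10)), "constant")
  expect_error(inverse_normal_transform(c(1, NA, 2, 4)), "missing")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
  expect_error(transform_spec(rank_offset = 1.2), "between 0 and 1")
  expect_error(transform_spec(tie_method = "random"), "seed")
})

test_that("residualize matches the explicit normal-equations solution", {
  expect_equal(residualize(c(1, 2, 3, 4), c(1, 2, 3, 4)), rep(0, 4))
  y <- withr::with_seed(2, rnorm(30))
  expect_equal(residualize(y), y - mean(y))

  # single covariate: compare with solve(t(X) X) t(X) y, check the
  # variance-ratio identity var(res)/var(y) = 1 - r^2 and orthogonality
  withr::with_seed(3, {
    x <- rnorm(200)
    y <- 0.4 * x + rnorm(200)
  })
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res_oracle <- as.numeric(y - X %*% beta)
  res <- residualize(y, x)
  expect_equal(res, res_oracle, tolerance = 1e-10)
  r <- cor(y, x)
  expect_equal(sum(res^2) / sum((y - mean(y))^2), 1 - r^2, tolerance = 1e-10)
  expect_lt(abs(cor(res, x)), 1e-10)
  expect_equal(mean(res), 0, tolerance = 1e-12)

  # multiple covariates: orthogonal to every column at n = 10^4
  withr::with_seed(4, {
    X2 <- matrix(rnorm(3e4), ncol = 3)
    y2 <- X2 %*% c(1, -2, 0.5) + rnorm(1e4)
  })
  r2 <- residualize(as.numeric(y2), X2)
  expect_true(all(abs(cor(r2, X2)) < 1e-10))
})

test_that("residualize reports rank deficiency and short input", {
  x <- rnorm(20)
  expect_error(residualize(rnorm(20), cbind(a = x, b = 2 * x)), "collinear.*b")
  expect_error(residualize(rnorm(3), cbind(rnorm(3), rnorm(3))), "n > p")
})

test_that("skewness and kurtosis match direct moment-formula evaluation", {
  expect_equal(skewness(c(-2, -1, 0, 1, 2), type = 1), 0)
  expect_equal(skewness(c(0, 0, 1), type = 1), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(kurtosis(c(-1, 1, -1, 1), type = 1), -2)

  for (i in 1:10) {
    n <- sample(5:50, 1)
    x <- withr::with_seed(100 + i, rgamma(n, shape = 2))
    for (tp in 1:3) {
      expect_equal(skewness(x, type = tp), oracle_skewness(x, tp),
                   tolerance = 1e-12)
      expect_equal(kurtosis(x, type = tp), oracle_kurtosis(x, tp),
                   tolerance = 1e-12)
    }
  }
  expect_error(skewness(rep(1, 5)), "zero variance")
  expect_error(kurtosis(rep(1, 5)), "zero variance")
})

test_that("large-sample moments approach their population values", {
  withr::with_seed(7, {
    xb <- rbeta(2e4, 2, 6)
    xu <- runif(2e4)
  })
  pop_skew <- beta_population_skew(2, 6)
  expect_lt(abs(skewness(xb) - pop_skew), 3 * sqrt(6 / 2e4) * 2)
  expect_lt(abs(kurtosis(xu) - (-1.2)), 0.1)
})

test_that("diagnostics bundles the four measures and matches a rank oracle", {
  y <- c(1, 2, 3, 4, 5)
  d <- diagnostics(y, y)
  expect_s3_class(d, "diagnostic_summary")
  expect_equal(d$pearson_r, 1)
  expect_equal(d$spearman_rho, 1)
  expect_equal(diagnostics(1:6, 6:1)$spearman_rho, -1)

  withr::with_seed(8, {
    a <- rexp(300)
    b <- 0.5 * a + rnorm(300)
  })
  d2 <- diagnostics(a, b)
  expect_equal(d2$spearman_rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(d2$skew, skewness(a))
  expect_equal(d2$n, 300)
  expect_error(diagnostics(1:5, 1:4), "equal length")
})
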