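test_that("beta shape solver hits the target population skew", {
  sh0 <- beta_shapes_for_skew(0)
  expect_equal(sh0$alpha, 5)
  expect_equal(sh0$beta, 5)

  for (s in c(0.3, 1, 2)) {
    sh <- beta_shapes_for_skew(s)
    # plug the returned shapes back into the closed-form skew
    expect_equal(beta_population_skew(sh$alpha, sh$beta), s, tolerance = 1e-8)
    expect_equal(sh$alpha + sh$beta, 10, tolerance = 1e-9)
    # mirror symmetry: negated target swaps the shapes
    shm <- beta_shapes_for_skew(-s)
    expect_equal(shm$alpha, sh$beta)
    expect_equal(shm$beta, sh$alpha)
  }
  expect_error(beta_shapes_for_skew(1e6, total = 10), "not attainable")
})

test_that("continuous simulation is deterministic and recovers target skew", {
  sp <- phenotype_spec(n = 1e4, target_skew = 0, family = "normal", seed = 31)
  x1 <- simulate_continuous(sp)
  x2 <- simulate_continuous(sp)
  expect_identical(x1, x2)
  # asymptotic se of sample skewness is sqrt(6/n); allow ~3 se
  expect_lt(abs(skewness(x1)), 0.07)

  xb <- simulate_continuous(phenotype_spec(n = 1e4, target_skew = 2, seed = 32))
  expect_lt(abs(skewness(xb) - 2), 0.25)
  expect_equal(anyDuplicated(xb), 0L)

  xn <- simulate_continuous(phenotype_spec(n = 1e4, target_skew = -1, seed = 33))
  expect_lt(abs(skewness(xn) + 1), 0.25)

  expect_error(phenotype_spec(target_skew = 1, family = "normal"), "normal")
})

test_that("questionnaire binning is equal-width, order-preserving and tied", {
  expect_equal(
    intorder:::bin_equal_width(c(0, 0.2, 0.4, 0.6, 0.8, 1), 2),
    c(0, 0, 0, 1, 1, 1)
  )
  sp <- phenotype_spec(n = 1e4, target_skew = 1, n_bins = 5, seed = 41)
  y <- simulate_questionnaire(sp)
  expect_lte(length(unique(y)), 5)
  expect_true(all(y %in% 0:4))
  # binning preserves the weak ordering of the underlying continuous draw
  x <- simulate_continuous(sp)
  expect_true(all(diff(y[order(x)]) >= 0))
  # skew survives binning at moderate bin counts
  y40 <- simulate_questionnaire(phenotype_spec(n = 1e4, target_skew = 1,
                                               n_bins = 40, seed = 42))
  expect_lt(abs(skewness(y40) - 1), 0.3)
  expect_error(phenotype_spec(n_bins = 1), "at least 2")
})

test_that("simulate_phenotype dispatches on the bin field", {
  spc <- phenotype_spec(n = 500, target_skew = 0.5, seed = 5)
  expect_identical(simulate_phenotype(spc), simulate_continuous(spc))
  spq <- phenotype_spec(n = 500, target_skew = 0.5, n_bins = 8, seed = 5)
  expect_identical(simulate_phenotype(spq), simulate_questionnaire(spq))
})

test_that("covariate construction achieves the target correlation", {
  # closed-form initializer: corr(y, y + sigma Z) = 1/sqrt(1 + sigma^2/var(y))
  withr::with_seed(51, {
    y <- rnorm(1e5)
    z <- rnorm(1e5)
  })
  r <- 0.3
  sigma <- sd(y) * sqrt(1 / r^2 - 1)
  se <- (1 - r^2) / sqrt(1e5)
  expect_lt(abs(cor(y, y + sigma * z) - r), 3 * se)

  yq <- simulate_phenotype(phenotype_spec(n = 5000, target_skew = 1,
                                          n_bins = 5, seed = 52))
  for (tr in c(-0.5, 0.06, 0.25)) {
    cv <- create_covariate(yq, covariate_spec(tr, seed = 53))
    expect_lt(abs(cor(yq, cv) - tr), 0.005)
  }
  # determinism
  c1 <- create_covariate(yq, covariate_spec(0.25, seed = 54))
  c2 <- create_covariate(yq, covariate_spec(0.25, seed = 54))
  expect_identical(c1, c2)
  # negated target negates the achieved correlation
  cn <- create_covariate(yq, covariate_spec(-0.25, seed = 54))
  expect_equal(cor(yq, cn), -cor(yq, c1), tolerance = 1e-12)

  expect_error(covariate_spec(0), "target_r")
  expect_error(create_covariate(rep(1, 100), covariate_spec(0.2)), "constant")
})

test_that("covariate jitter never reorders distinct response bins", {
  yq <- simulate_phenotype(phenotype_spec(n = 2000, target_skew = 0.5,
                                          n_bins = 5, seed = 61))
  cv <- create_covariate(yq, covariate_spec(0.9, tolerance = 0.02, seed = 62))
  # at very high target r the covariate is nearly the jittered phenotype;
  # averaging it within bins must preserve the bin order
  expect_true(all(diff(tapply(as.numeric(cv), yq, mean)) > 0))
})
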