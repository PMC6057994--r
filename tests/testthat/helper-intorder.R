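# Independent moment-formula oracles (e1071's printed conventions,
# evaluated directly) used to cross-check the packaged estimators.
oracle_skewness <- function(x, type) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  switch(type,
         g1,
         g1 * sqrt(n * (n - 1)) / (n - 2),
         g1 * ((n - 1) / n)^1.5)
}

oracle_kurtosis <- function(x, type) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  switch(type,
         g2,
         ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
         (g2 + 3) * (1 - 1 / n)^2 - 3)
}

# Van der Waerden score set under offset c (denominator n + 1 - 2c).
vdw_scores <- function(n, c = 0.5) qnorm((seq_len(n) - c) / (n + 1 - 2 * c))

# A quick questionnaire-type phenotype + covariate pair for pipeline tests.
sim_pair <- function(n = 2000, skew = 1, bins = 5, r = 0.06, seed = 1) {
  y <- simulate_phenotype(phenotype_spec(n = n, target_skew = skew,
                                         n_bins = bins, seed = seed))
  cv <- create_covariate(y, covariate_spec(r, seed = seed + 1000))
  list(y = y, cv = cv)
}
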