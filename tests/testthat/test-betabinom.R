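test_that("beta-binomial pmf matches closed forms and numeric integration", {
  expect_equal(betabinom_log_pmf(1, 0, 1, 1), log(0.5))
  # uniform prior, two alt draws: integral of p^2 over [0,1] = 1/3
  expect_equal(betabinom_log_pmf(2, 0, 1, 1), log(1 / 3))
  oracle <- integrate(function(p) p^2, 0, 1)$value
  expect_equal(exp(betabinom_log_pmf(2, 0, 1, 1)), oracle, tolerance = 1e-8)

  # general case against direct numeric integration of C(n,a) p^a (1-p)^r dBeta
  a <- 3; r <- 4; al <- 2.5; be <- 7
  oracle2 <- integrate(function(p) {
    choose(a + r, a) * p^a * (1 - p)^r * dbeta(p, al, be)
  }, 0, 1, rel.tol = 1e-12)$value
  expect_equal(exp(betabinom_log_pmf(a, r, al, be)), oracle2, tolerance = 1e-9)

  expect_error(betabinom_log_pmf(-1, 0, 1, 1), "non-negative")
  expect_error(betabinom_log_pmf(1, 0, 0, 1), "positive")
})

test_that("pmf normalizes to one over its support", {
  for (n in c(1, 5, 20)) {
    for (ab in list(c(1, 1), c(2.5, 7), c(0.3, 0.9), c(40, 2))) {
      tot <- sum(exp(betabinom_log_pmf(0:n, n:0, ab[1], ab[2])))
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("pmf converges to the binomial in the large-concentration limit", {
  p <- 0.3
  conc <- 1e6
  for (n in c(1, 5, 8)) {
    bb <- betabinom_log_pmf(0:n, n:0, conc * p, conc * (1 - p))
    bi <- dbinom(0:n, n, p, log = TRUE)
    expect_lt(max(abs(bb - bi)), 1e-4)
  }
})

test_that("majority model is the +1-prior conjugate update of column sums", {
  ref <- rbind(c(4, 2, 0), c(1, 0, 0))
  alt <- rbind(c(1, 3, 0), c(0, 0, 2))
  cnt <- toy_counts(ref, alt)

  m <- fit_majority_model(cnt)
  expect_equal(m$alpha, c(1 + 4, 1 + 2))   # alt totals 4, 2
  expect_equal(m$beta, c(1 + 6, 1 + 1))    # ref totals 6, 1

  # contributing cells with zero counts everywhere -> pure prior
  m0 <- fit_majority_model(cnt, contributing_cells = 3L)
  expect_equal(m0$alpha, c(1, 3))
  expect_equal(m0$beta, c(1, 1))

  # removing cell 2 (alt=3, ref=2 at locus 1) shifts only locus 1
  m2 <- fit_majority_model(cnt, contributing_cells = c(1L, 3L))
  expect_equal(m$alpha - m2$alpha, c(3, 0))
  expect_equal(m$beta - m2$beta, c(2, 0))

  expect_error(fit_majority_model(cnt, integer(0)), "non-empty")
})

test_that("cell scores compose pmfs over covered loci and normalize per UMI", {
  # single cell, leave-one-out reduces the model to the uniform prior
  cnt1 <- toy_counts(matrix(0L, 1, 1), matrix(1L, 1, 1))
  s1 <- score_cells(cnt1, fit_majority_model(cnt1), leave_one_out = TRUE)
  expect_equal(s1$normalized_log_likelihood, log(0.5))
  expect_equal(s1$n_observations, 1)

  # zero-coverage cell is flagged undefined
  cnt0 <- toy_counts(cbind(c(1L, 0L), c(0L, 0L)), matrix(0L, 2, 2))
  s0 <- score_cells(cnt0, fit_majority_model(cnt0))
  expect_true(is.na(s0$normalized_log_likelihood[2]))
  expect_equal(s0$n_observations[2], 0)

  # a cell carrying alt alleles where the others carry only ref scores lower
  ref <- rbind(c(5, 6, 0), c(3, 4, 4))
  alt <- rbind(c(0, 0, 5), c(0, 0, 0))
  s3 <- score_cells(toy_counts(ref, alt),
                    fit_majority_model(toy_counts(ref, alt)))
  expect_lt(s3$normalized_log_likelihood[3],
            min(s3$normalized_log_likelihood[1:2]))
})

test_that("scores are invariant to locus and cell ordering", {
  sim <- simulate_mixture(sim_config(n_loci = 50, n_majority_cells = 18,
                                     n_minority_cells = 2, seed = 9))
  cnt <- sim$counts
  s <- score_cells(cnt, fit_majority_model(cnt))

  set.seed(1)
  pl <- sample(n_loci(cnt))
  pc <- sample(n_cells(cnt))
  perm <- allele_counts(cnt$ref[pl, pc], cnt$alt[pl, pc],
                        cnt$barcodes[pc], cnt$loci[pl, ])
  sp <- score_cells(perm, fit_majority_model(perm))
  expect_equal(sp$total_log_likelihood,
               s$total_log_likelihood[pc], tolerance = 1e-12)
  expect_equal(sp$deviance_z, s$deviance_z[pc], tolerance = 1e-10)
})

test_that("leave-one-out equals scoring under a model refit without the cell", {
  sim <- simulate_mixture(sim_config(n_loci = 40, n_majority_cells = 12,
                                     n_minority_cells = 0, seed = 5))
  cnt <- sim$counts
  full <- fit_majority_model(cnt)
  s_loo <- score_cells(cnt, full, leave_one_out = TRUE)
  for (cell in c(1L, 7L)) {
    refit <- fit_majority_model(cnt, setdiff(seq_len(n_cells(cnt)), cell))
    s_ref <- score_cells(cnt, refit, leave_one_out = FALSE)
    expect_equal(s_loo$total_log_likelihood[cell],
                 s_ref$total_log_likelihood[cell])
    expect_equal(s_loo$expected_log_likelihood[cell],
                 s_ref$expected_log_likelihood[cell])
  }
})

test_that("adding a covered locus strictly lowers the total log-likelihood", {
  model <- structure(list(alpha = c(2, 3), beta = c(5, 4)),
                     class = "LocusModelSet")
  before <- toy_counts(rbind(3L, 0L), rbind(1L, 0L))   # locus 1 only
  after <- toy_counts(rbind(3L, 2L), rbind(1L, 0L))    # plus 2 ref UMIs at locus 2
  sb <- score_cells(before, model, leave_one_out = FALSE)
  sa <- score_cells(after, model, leave_one_out = FALSE)
  expect_lt(sa$total_log_likelihood, sb$total_log_likelihood)
  expect_lte(sb$total_log_likelihood, 0)
})

test_that("deviance calibration matches direct enumeration of the null", {
  cnt <- toy_counts(rbind(c(2, 7), c(0, 3)), rbind(c(1, 1), c(0, 2)))
  model <- fit_majority_model(cnt)
  s <- score_cells(cnt, model, leave_one_out = FALSE)

  # recompute cell 1's expected log-likelihood and variance by brute force
  ev <- 0; vv <- 0
  for (loc in 1:2) {
    n <- cnt$ref[loc, 1] + cnt$alt[loc, 1]
    if (n == 0) next
    lp <- betabinom_log_pmf(0:n, n:0, model$alpha[loc], model$beta[loc])
    p <- exp(lp)
    ev <- ev + sum(p * lp)
    vv <- vv + sum(p * lp^2) - sum(p * lp)^2
  }
  expect_equal(s$expected_log_likelihood[1], ev, tolerance = 1e-12)
  expect_equal(s$sd_log_likelihood[1], sqrt(vv), tolerance = 1e-12)
  expect_equal(s$deviance_z[1],
               (s$total_log_likelihood[1] - ev) / sqrt(vv), tolerance = 1e-12)
})
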