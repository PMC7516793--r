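test_that("Laplace-smoothed estimators match hand evaluation", {
  d <- binary_dataset(matrix(c(1, 0), 2, 1), c(1, 0))
  est <- laplace_estimates(d)
  expect_equal(est$pi_hat, 3 / 6)
  expect_equal(est$mu1_hat, 2 / 6)
  expect_equal(est$mu0_hat, 1 / 6)
  expect_equal(est$theta1_hat, 2 / 3)
  expect_equal(est$theta0_hat, 1 / 3)
  expect_equal(est$theta_hat, 0.5)

  # all labels 1: pi_hat = 6/8 and mu0 pinned at 1/8 whatever x is
  d2 <- binary_dataset(matrix(c(1, 0, 1, 1, 0, 0, 0, 1), 4, 2), rep(1, 4))
  est2 <- laplace_estimates(d2)
  expect_equal(est2$pi_hat, 0.75)
  expect_equal(est2$mu0_hat, rep(1 / 8, 2))
})

test_that("estimate invariants hold on random data", {
  set.seed(11)
  for (rep in 1:20) {
    d <- rand_dataset(n = sample(5:80, 1), p = sample(1:10, 1))
    est <- laplace_estimates(d)
    n <- d$n
    expect_gte(est$pi_hat, 2 / (n + 4))
    expect_lte(est$pi_hat, (n + 2) / (n + 4))
    expect_true(all(est$mu1_hat >= 1 / (n + 4) & est$mu1_hat <= (n + 1) / (n + 4)))
    expect_equal(est$theta_hat, est$mu1_hat + est$mu0_hat)
    expect_equal(est$theta1_hat, est$mu1_hat / est$pi_hat)
    expect_equal(est$theta0_hat, est$mu0_hat / (1 - est$pi_hat))
    probs <- c(est$pi_hat, est$mu1_hat, est$mu0_hat, est$theta1_hat,
               est$theta0_hat, est$theta_hat)
    expect_true(all(probs > 0 & probs < 1))
  }
})

test_that("dataset validation rejects malformed inputs", {
  expect_error(binary_dataset(matrix(c(0, 2), 2, 1), c(0, 1)), "exactly 0 or 1")
  expect_error(binary_dataset(matrix(0:1, 2, 1), c(0, 0.5)), "0 or 1")
  expect_error(binary_dataset(matrix(numeric(0), 0, 0), numeric(0)), "empty")
  expect_error(binary_dataset(matrix(0:1, 2, 1), c(0, 1, 1)), "length")
})

test_that("contingency counts match direct summation", {
  d <- binary_dataset(matrix(c(1, 0, 1, 0), 4, 1), c(1, 1, 0, 0))
  cc <- contingency_counts(d)
  expect_equal(cc$n, 4)
  expect_equal(cc$n1dot, 2)
  expect_equal(cc$ndotj, 2)
  expect_equal(cc$n1j, 1)

  # all-zero column and a column equal to the label
  y <- c(1, 0, 1, 1, 0)
  d2 <- binary_dataset(cbind(0, y), y)
  cc2 <- contingency_counts(d2)
  expect_equal(cc2$ndotj, c(0, 3))
  expect_equal(cc2$n1j, c(0, 3))
  expect_equal(cc2$n1j[2], cc2$n1dot)
})

test_that("WMSD scores follow the defining formula", {
  # zero when the conditional probabilities agree
  est0 <- screening_estimates(pi_hat = 0.5, mu1_hat = 0.2, mu0_hat = 0.2, n = 50)
  expect_equal(wmsd_scores(est0)$values, 0)

  # pi = 0.5, theta1 = 0.7, theta0 = 0.3 -> 0.25 * 0.16
  est <- screening_estimates(pi_hat = 0.5, mu1_hat = 0.35, mu0_hat = 0.15, n = 50)
  expect_equal(wmsd_scores(est)$values, 0.04)
})

test_that("wmsd, chi2 and mi are invariant under a label swap", {
  set.seed(23)
  for (rep in 1:10) {
    d <- rand_dataset(n = sample(20:100, 1), p = 5)
    d_sw <- binary_dataset(d$features, 1 - d$labels)
    expect_equal(wmsd_scores(laplace_estimates(d))$values,
                 wmsd_scores(laplace_estimates(d_sw))$values)
    expect_equal(chi2_exact(contingency_counts(d))$values,
                 chi2_exact(contingency_counts(d_sw))$values)
    expect_equal(mi_exact(contingency_counts(d))$values,
                 mi_exact(contingency_counts(d_sw))$values)
  }
})

test_that("exact chi-square matches the plug-in Pearson oracle", {
  # exact independence: cross-product term is zero
  cc <- new_contingency_counts(n = 40, n1dot = 20, ndotj = 20, n1j = 10)
  expect_equal(chi2_exact(cc)$values, 0)

  # perfectly aligned feature on n = 8
  cc2 <- new_contingency_counts(n = 8, n1dot = 4, ndotj = 4, n1j = 4)
  expect_equal(chi2_exact(cc2)$values, 8)

  set.seed(37)
  for (rep in 1:50) {
    tb <- rand_table()
    got <- chi2_exact(new_contingency_counts(tb$n, tb$n1dot, tb$ndotj, tb$n1j))
    expect_equal(got$values,
                 chisq_table_oracle(tb$n, tb$n1dot, tb$ndotj, tb$n1j),
                 tolerance = 1e-12)
    # and against the stats oracle on the raw table
    O <- matrix(c(tb$n1j, tb$n1dot - tb$n1j, tb$ndotj - tb$n1j,
                  tb$n - tb$n1dot - tb$ndotj + tb$n1j), 2, 2)
    expect_equal(got$values,
                 unname(suppressWarnings(chisq.test(O, correct = FALSE))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("exact mutual information matches the entropy oracle", {
  cc <- new_contingency_counts(n = 40, n1dot = 20, ndotj = 20, n1j = 10)
  expect_equal(mi_exact(cc)$values, 0)

  cc2 <- new_contingency_counts(n = 8, n1dot = 4, ndotj = 4, n1j = 4)
  expect_equal(mi_exact(cc2)$values, log(2))

  set.seed(41)
  for (rep in 1:50) {
    tb <- rand_table()
    expect_equal(
      mi_exact(new_contingency_counts(tb$n, tb$n1dot, tb$ndotj, tb$n1j))$values,
      mi_entropy_oracle(tb$n, tb$n1dot, tb$ndotj, tb$n1j),
      tolerance = 1e-8)
  }
})

test_that("degenerate tables score zero with a warning", {
  d <- binary_dataset(cbind(c(0, 0, 0, 0), c(1, 1, 0, 0)), c(1, 1, 0, 0))
  cc <- contingency_counts(d)
  expect_warning(chi <- chi2_exact(cc), "degenerate")
  expect_equal(chi$values[1], 0)
  expect_gt(chi$values[2], 0) # non-degenerate neighbour unaffected
  expect_warning(mi <- mi_exact(cc), "degenerate")
  expect_equal(mi$values[1], 0)
})

test_that("chi2_approx from plug-in proportions equals the exact statistic", {
  set.seed(53)
  for (rep in 1:50) {
    tb <- rand_table()
    cc <- new_contingency_counts(tb$n, tb$n1dot, tb$ndotj, tb$n1j)
    est <- plugin_estimates(cc)
    approx <- chi2_approx(wmsd_scores(est), est)
    expect_equal(approx$values, chi2_exact(cc)$values, tolerance = 1e-10)
  }
})

test_that("mi_approx is chi2/n and tightens as association weakens", {
  s <- screening_scores(c(20, 30), "chi2_exact")
  expect_equal(mi_approx(s, 100)$values, c(0.2, 0.3))
  expect_equal(mi_approx(screening_scores(0, "chi2_approx"), 10)$values, 0)
  expect_error(mi_approx(s, 0), "positive")
  expect_error(mi_approx(screening_scores(1, "wmsd"), 10), "chi-square")

  # second-order accuracy: halving the departure from independence shrinks
  # the |MI - chi2/n| gap
  gap <- function(delta) {
    cc <- new_contingency_counts(n = 1000, n1dot = 500, ndotj = 400,
                                 n1j = 200 + delta)
    abs(mi_exact(cc)$values - chi2_exact(cc)$values / 1000)
  }
  expect_lt(gap(20), gap(40))
  expect_lt(gap(10), gap(20))
})

test_that("ordering by WMSD and approximate chi-square agree at equal theta", {
  # two features with identical marginal theta: the theta(1-theta) factor
  # cancels, so the two statistics induce the same order
  est <- screening_estimates(pi_hat = 0.4,
                             mu1_hat = c(0.20, 0.16),
                             mu0_hat = c(0.10, 0.14), n = 200)
  expect_equal(est$theta_hat[1], est$theta_hat[2])
  w <- wmsd_scores(est)
  ca <- chi2_approx(w, est)
  expect_equal(order(-w$values), order(-ca$values))
})

test_that("feature ranking is decreasing with deterministic tie-breaks", {
  expect_equal(rank_features(screening_scores(c(0.1, 0.3, 0.2), "wmsd")),
               c(2L, 3L, 1L))
  expect_equal(rank_features(screening_scores(rep(1, 5), "wmsd")), 1:5)
  set.seed(61)
  for (rep in 1:10) {
    v <- round(runif(50), 2) # duplicates likely
    r <- rank_features(screening_scores(v, "wmsd"))
    # brute-force oracle: stable sort on (-value, index)
    ord <- order(-v, seq_along(v))
    expect_identical(r, ord)
  }
})

test_that("wmsd_screen ties the pieces together", {
  set.seed(71)
  cfg <- sim_config(pi = 0.5, n = 2000, p = 300, d0 = 10, seed = 5)
  sim <- generate_dataset(cfg)
  fit <- wmsd_screen(sim$train, m = 50, d_min = 2, d_max = 50)
  expect_s3_class(fit, "wmsd_screen")
  expect_equal(nrow(fit$scores), 300)
  expect_equal(sort(fit$scores$rank), 1:300)
  expect_equal(fit$selected, fit$ranking[seq_len(fit$d_hat)])
  expect_equal(unname(coef(fit)), fit$values)
  # most of the relevant set should surface at the top at this n
  expect_gt(length(intersect(fit$ranking[1:10], 1:10)), 7)
  s <- summary(fit)
  expect_equal(s$d_hat, fit$d_hat)
  expect_output(print(fit), "d_hat")
})
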