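test_that("selection metrics apply the study definitions verbatim", {
  m <- selection_metrics(1:20, 1:20, p = 500)
  expect_equal(c(m$fpr, m$fnr), c(0, 0))

  m2 <- selection_metrics(c(1:10, 21:25), 1:20, p = 500)
  expect_equal(m2$fpr, 0.5)
  expect_equal(m2$fnr, 5 / 480)

  m3 <- selection_metrics(1:500, 1:20, p = 500)
  expect_equal(c(m3$fpr, m3$fnr), c(0, 1))

  # empty selection is legal; empty or full truth is not
  expect_equal(selection_metrics(integer(0), 1:20, p = 500)$fpr, 1)
  expect_error(selection_metrics(1:5, integer(0), p = 10), "nonempty")
  expect_error(selection_metrics(1:5, 1:10, p = 10), "proper subset")
  expect_error(selection_metrics(11, 1:5, p = 10), "subset of 1..p")
})

test_that("naive Bayes posterior equals a brute-force Bayes computation", {
  set.seed(31)
  d <- rand_dataset(n = 120, p = 4)
  nb <- fit_bernoulli_nb(d)
  newx <- rand_dataset(n = 30, p = 4)$features
  post <- predict(nb, newx, type = "posterior")
  for (i in 1:30) {
    x <- newx[i, ]
    l1 <- nb$prior1 * prod(nb$prob1^x * (1 - nb$prob1)^(1 - x))
    l0 <- (1 - nb$prior1) * prod(nb$prob0^x * (1 - nb$prob0)^(1 - x))
    expect_equal(post[i], l1 / (l1 + l0), tolerance = 1e-12)
  }
})

test_that("naive Bayes is monotone in a label-aligned feature", {
  y <- rep(c(1, 0), each = 25)
  d <- binary_dataset(cbind(y), y)
  nb <- fit_bernoulli_nb(d, subset = 1)
  p1 <- predict(nb, matrix(1, 1, 1), type = "posterior")
  p0 <- predict(nb, matrix(0, 1, 1), type = "posterior")
  expect_gt(p1, p0)
})

test_that("naive Bayes on an uninformative feature returns the prior", {
  set.seed(43)
  n <- 5000
  y <- rbinom(n, 1, 0.5)
  d <- binary_dataset(cbind(rbinom(n, 1, 0.4)), y)
  nb <- fit_bernoulli_nb(d)
  post <- predict(nb, matrix(c(0, 1), 2, 1), type = "posterior")
  expect_true(all(abs(post - nb$prior1) < 0.05))
})

test_that("logistic fit zeroes the penalized score and handles separation", {
  set.seed(47)
  d <- rand_dataset(n = 150, p = 3)
  fit <- fit_logistic(d)
  # analytic gradient oracle at the returned solution
  X <- cbind(1, d$features)
  mu <- 1 / (1 + exp(-as.numeric(X %*% fit$coefficients)))
  g <- as.numeric(crossprod(X, d$labels - mu)) -
    c(0, rep(fit$lambda, 3)) * fit$coefficients
  expect_lt(max(abs(g)), 1e-8)
  expect_true(fit$converged)

  # complete separation: ridge keeps the fit finite and ordering perfect
  y <- rep(c(1, 0), each = 10)
  dsep <- binary_dataset(cbind(y), y)
  fsep <- fit_logistic(dsep, subset = 1)
  expect_true(all(is.finite(fsep$coefficients)))
  expect_equal(auc(predict(fsep, dsep), y), 1)
})

test_that("logistic fit with pure noise predicts the class frequency", {
  set.seed(59)
  n <- 2000
  y <- rbinom(n, 1, 0.7)
  d <- binary_dataset(cbind(rbinom(n, 1, 0.5)), y)
  fit <- fit_logistic(d)
  # unpenalized intercept forces the fitted mean onto the class frequency
  expect_equal(mean(predict(fit, d, type = "response")), mean(y),
               tolerance = 1e-8)
  expect_lt(abs(plogis(fit$coefficients[1]) - mean(y)), 0.1)
})

test_that("AUC matches the pair-counting oracle and its invariances", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(1, 6), rep(c(1, 0), 3)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
  expect_error(auc(1:3, c(1, 0)), "equal length")

  set.seed(67)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties guaranteed
    expect_equal(auc(s, y), auc_pair_oracle(s, y), tolerance = 1e-12)
    # invariant under a strictly increasing transform
    expect_equal(auc(exp(3 * s), y), auc(s, y), tolerance = 1e-12)
  }
})
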