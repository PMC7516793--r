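#' Configuration for the multivariate Bernoulli simulator
#'
#' Validates and bundles the generative parameters: the class-1 probability
#' `pi`, training size `n`, test size `n_test`, feature count `p`, true
#' model size `d0` (even, since the design splits the relevant set in two
#' halves at `d0/2`) and the master seed.
#'
#' @param pi class-1 probability, in (0, 1). The reference simulation study
#'   uses 0.5 (balanced) and 0.8 (unbalanced).
#' @param n training sample size.
#' @param p feature count.
#' @param d0 true model size; even and strictly less than p (the design
#'   needs irrelevant features).
#' @param n_test test sample size, default 1000.
#' @param seed integer master seed.
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(pi = 0.5, n = 1000, p = 500, d0 = 20, seed = 1)
#' @export
sim_config <- function(pi = 0.5, n = 1000, p = 500, d0 = 20, n_test = 1000,
                       seed = 1L) {
  if (length(pi) != 1L || is.na(pi) || pi <= 0 || pi >= 1)
    stop("`pi` must lie strictly inside (0, 1)")
  for (nm in c("n", "p", "d0", "n_test")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop("`", nm, "` must be a positive integer")
  }
  if (d0 %% 2 != 0) stop("`d0` must be even (the design splits T at d0/2)")
  if (d0 >= p)
    stop("`d0` must be strictly less than `p`: the design requires ",
         "irrelevant features")
  structure(list(pi = pi, n = as.integer(n), p = as.integer(p),
                 d0 = as.integer(d0), n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generative truth of the multivariate Bernoulli design
#'
#' Deterministic parameters of the simulation design with known relevant
#' set \eqn{T = \{1, \ldots, d_0\}}:
#' \deqn{\theta_{1j} = 0.05\{j^{-0.2}p^{0.2}
#'   + I(1 \le j \le d_0/2)\, j^{-0.5} d_0^{0.5}\},}
#' \deqn{\theta_{0j} = 0.05\{j^{-0.2}p^{0.2}
#'   + I(d_0/2 < j \le d_0)\, j^{-0.5} d_0^{0.5}\},}
#' so the first half of T is informative through class 1 and the second
#' half through class 0, while features beyond \eqn{d_0} share the same
#' slowly decaying marginal probability in both classes and carry
#' population WMSD \eqn{\omega_j = \pi(1-\pi)(\theta_{1j}-\theta_{0j})^2 = 0}.
#'
#' @param config a [sim_config()].
#' @return An object of class `"sim_truth"`: `theta1`, `theta0`, `omega`,
#'   `true_model`, plus the scalars `pi`, `p`, `d0`.
#' @examples
#' tr <- make_truth(sim_config(p = 500, d0 = 20))
#' tr$theta1[1] # 0.05 * (500^0.2 + sqrt(20))
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  j <- seq_len(config$p)
  base <- j^(-0.2) * config$p^0.2
  bump <- j^(-0.5) * config$d0^0.5
  theta1 <- 0.05 * (base + ifelse(j <= config$d0 / 2, bump, 0))
  theta0 <- 0.05 * (base + ifelse(j > config$d0 / 2 & j <= config$d0, bump, 0))
  if (any(theta1 <= 0 | theta1 >= 1 | theta0 <= 0 | theta0 >= 1))
    stop("design probabilities fall outside (0, 1) for this (p, d0)")
  structure(list(theta1 = theta1, theta0 = theta0,
                 omega = config$pi * (1 - config$pi) * (theta1 - theta0)^2,
                 true_model = seq_len(config$d0),
                 pi = config$pi, p = config$p, d0 = config$d0),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Multivariate Bernoulli truth: p = ", x$p, ", d0 = ", x$d0,
      ", pi = ", x$pi, "\n", sep = "")
  cat("  omega range over T: [", format(min(x$omega[x$true_model]), digits = 4),
      ", ", format(max(x$omega[x$true_model]), digits = 4), "]\n", sep = "")
  invisible(x)
}

# one draw of n observations given the truth: labels Bernoulli(pi),
# features conditionally independent Bernoulli given the label
draw_bernoulli <- function(n, truth) {
  y <- stats::rbinom(n, 1L, truth$pi)
  p <- truth$p
  x <- matrix(0L, n, p)
  for (k in c(1L, 0L)) {
    idx <- which(y == k)
    if (length(idx) == 0L) next
    th <- if (k == 1L) truth$theta1 else truth$theta0
    x[idx, ] <- matrix(
      stats::rbinom(length(idx) * p, 1L, rep(th, each = length(idx))),
      length(idx), p)
  }
  binary_dataset(x, y)
}

#' Generate a train/test pair from the multivariate Bernoulli model
#'
#' Draws labels i.i.d. Bernoulli(`pi`) and features conditionally
#' independent Bernoulli given the label, with the class-conditional
#' probabilities of [make_truth()]. The random stream is seeded from
#' `config$seed`; the training set is drawn first and the test set from the
#' continuation of the stream, so the two are disjoint substreams and the
#' whole pair is byte-identical across repeated calls.
#'
#' @param config a [sim_config()].
#' @param truth optionally a precomputed `"sim_truth"` (it is deterministic
#'   given the config, so sharing one across replications is safe).
#' @return A list with elements `train` and `test` (two
#'   [binary_dataset()]s), `truth` and `config`.
#' @examples
#' sim <- generate_dataset(sim_config(n = 100, p = 50, d0 = 4, seed = 3))
#' dim(sim$train$features)
#' @export
generate_dataset <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- make_truth(config)
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed)
  train <- draw_bernoulli(config$n, truth)
  test <- draw_bernoulli(config$n_test, truth)
  list(train = train, test = test, truth = truth, config = config)
}
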