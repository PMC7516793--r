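#' Contingency counts for every feature against the label
#'
#' Computes, in one pass, the sufficient counts of the p per-feature 2x2
#' tables: the sample size n, the number of label-1 observations
#' \eqn{n_{1\cdot}}, the per-feature count of feature-1 observations
#' \eqn{n_{\cdot j}}, and the joint count \eqn{n_{1j}} of (feature = 1,
#' label = 1).
#'
#' @param data a [binary_dataset()].
#' @return An object of class `"contingency_counts"` with elements `n`,
#'   `n1dot`, `ndotj`, `n1j` and `feature_ids`.
#' @examples
#' d <- binary_dataset(matrix(c(1, 0, 1, 0), 4, 1), c(1, 1, 0, 0))
#' contingency_counts(d)$n1j
#' @export
contingency_counts <- function(data) {
  data <- as_binary_dataset(data)
  n1j <- as.numeric(Matrix::crossprod(data$features, data$labels))
  new_contingency_counts(n = data$n,
                         n1dot = sum(data$labels),
                         ndotj = as.numeric(Matrix::colSums(data$features)),
                         n1j = n1j,
                         feature_ids = data$feature_ids)
}

#' Low-level constructor for contingency counts
#'
#' Builds a `"contingency_counts"` object directly from the four count
#' summaries, validating the 2x2-table constraints
#' \eqn{0 \le n_{1j} \le \min(n_{1\cdot}, n_{\cdot j})} and
#' \eqn{n_{1\cdot} \le n}, \eqn{n_{\cdot j} \le n}. Useful for working with
#' tables directly rather than raw data.
#'
#' @param n sample count.
#' @param n1dot count of label-1 observations.
#' @param ndotj per-feature counts of feature-1 observations.
#' @param n1j per-feature joint counts of (feature = 1, label = 1).
#' @param feature_ids optional identifiers.
#' @return An object of class `"contingency_counts"`.
#' @export
new_contingency_counts <- function(n, n1dot, ndotj, n1j, feature_ids = NULL) {
  p <- length(ndotj)
  if (length(n1j) != p) stop("`ndotj` and `n1j` must have equal length")
  if (n < 1) stop("need n >= 1")
  if (n1dot < 0 || n1dot > n) stop("n1dot must lie in [0, n]")
  if (any(ndotj < 0) || any(ndotj > n)) stop("ndotj must lie in [0, n]")
  if (any(n1j < 0) || any(n1j > pmin(n1dot, ndotj)))
    stop("n1j must lie in [0, min(n1dot, ndotj)] for every feature")
  if (is.null(feature_ids)) feature_ids <- as.character(seq_len(p))
  structure(list(n = n, n1dot = n1dot, ndotj = as.numeric(ndotj),
                 n1j = as.numeric(n1j), feature_ids = as.character(feature_ids)),
            class = "contingency_counts")
}

#' Laplace-smoothed probability estimates
#'
#' Estimates the class probability and the per-feature marginal and
#' conditional probabilities with Laplace (additive) smoothing, so every
#' estimate is bounded strictly away from 0 and 1:
#' \deqn{\hat\pi = (2 + \sum_i y_i)/(n + 4), \quad
#'       \hat\mu_{1j} = (1 + \sum_i y_i x_{ij})/(n + 4), \quad
#'       \hat\mu_{0j} = (1 + \sum_i (1 - y_i) x_{ij})/(n + 4),}
#' with the derived quantities \eqn{\hat\theta_{1j} = \hat\mu_{1j}/\hat\pi},
#' \eqn{\hat\theta_{0j} = \hat\mu_{0j}/(1-\hat\pi)} and
#' \eqn{\hat\theta_j = \hat\mu_{1j} + \hat\mu_{0j}}.
#'
#' @param data a [binary_dataset()].
#' @return An object of class `"laplace_estimates"`; see
#'   [screening_estimates()] for the fields.
#' @examples
#' d <- binary_dataset(matrix(c(1, 0), 2, 1), c(1, 0))
#' laplace_estimates(d)$pi_hat # (2 + 1) / (2 + 4)
#' @export
laplace_estimates <- function(data) {
  data <- as_binary_dataset(data)
  cc <- contingency_counts(data)
  screening_estimates(pi_hat = (2 + cc$n1dot) / (cc$n + 4),
                      mu1_hat = (1 + cc$n1j) / (cc$n + 4),
                      mu0_hat = (1 + cc$ndotj - cc$n1j) / (cc$n + 4),
                      n = cc$n, feature_ids = cc$feature_ids,
                      smoothing = "laplace")
}

#' Low-level constructor for probability estimates
#'
#' Assembles an estimates object from a class probability and the two joint
#' probability vectors, deriving the conditional probabilities
#' `theta1_hat = mu1_hat / pi_hat`, `theta0_hat = mu0_hat / (1 - pi_hat)` and
#' the marginal `theta_hat = mu1_hat + mu0_hat`. All stored probabilities
#' must be strictly inside (0, 1). [laplace_estimates()] is the usual entry
#' point; this constructor also serves plug-in (unsmoothed) estimates, e.g.
#' via [plugin_estimates()].
#'
#' @param pi_hat class-1 probability.
#' @param mu1_hat,mu0_hat per-feature joint probabilities
#'   P(X = 1, Y = 1) and P(X = 1, Y = 0).
#' @param n sample count the estimates are based on.
#' @param feature_ids optional identifiers.
#' @param smoothing label recording how the estimates were obtained.
#' @return An object of class `"laplace_estimates"` with fields `pi_hat`,
#'   `mu1_hat`, `mu0_hat`, `theta1_hat`, `theta0_hat`, `theta_hat`, `n`,
#'   `feature_ids`, `smoothing`.
#' @export
screening_estimates <- function(pi_hat, mu1_hat, mu0_hat, n,
                                feature_ids = NULL, smoothing = "plugin") {
  p <- length(mu1_hat)
  if (length(mu0_hat) != p) stop("`mu1_hat` and `mu0_hat` must have equal length")
  theta1 <- mu1_hat / pi_hat
  theta0 <- mu0_hat / (1 - pi_hat)
  theta <- mu1_hat + mu0_hat
  # pi_hat and theta_hat must be strictly interior (they appear in
  # denominators); plug-in cell probabilities may sit on the boundary
  if (anyNA(pi_hat) || pi_hat <= 0 || pi_hat >= 1)
    stop("`pi_hat` must lie strictly inside (0, 1)")
  if (anyNA(theta) || any(theta <= 0) || any(theta >= 1))
    stop("all marginal probabilities theta_hat must lie strictly inside (0, 1)")
  vals <- c(mu1_hat, mu0_hat, theta1, theta0)
  eps <- 1e-9 # tolerate rounding from the mu/pi divisions at the boundary
  if (anyNA(vals) || any(vals < -eps) || any(vals > 1 + eps))
    stop("all probability estimates must lie inside [0, 1]")
  theta1 <- pmin(pmax(theta1, 0), 1)
  theta0 <- pmin(pmax(theta0, 0), 1)
  if (is.null(feature_ids)) feature_ids <- as.character(seq_len(p))
  structure(list(pi_hat = pi_hat, mu1_hat = as.numeric(mu1_hat),
                 mu0_hat = as.numeric(mu0_hat), theta1_hat = as.numeric(theta1),
                 theta0_hat = as.numeric(theta0), theta_hat = as.numeric(theta),
                 n = n, feature_ids = as.character(feature_ids),
                 smoothing = smoothing),
            class = "laplace_estimates")
}

#' Unsmoothed plug-in probability estimates from contingency counts
#'
#' Maximum-likelihood (relative frequency) counterparts of
#' [laplace_estimates()]. They exist mainly because the Chi-square statistic
#' equals its WMSD-based approximation exactly when plug-in proportions are
#' substituted for the smoothed ones; see [chi2_approx()]. Degenerate tables
#' (a zero margin) put a probability on the boundary and are rejected.
#'
#' @param counts a `"contingency_counts"` object.
#' @return An object of class `"laplace_estimates"` with
#'   `smoothing = "plugin"`.
#' @export
plugin_estimates <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  screening_estimates(pi_hat = counts$n1dot / counts$n,
                      mu1_hat = counts$n1j / counts$n,
                      mu0_hat = (counts$ndotj - counts$n1j) / counts$n,
                      n = counts$n, feature_ids = counts$feature_ids,
                      smoothing = "plugin")
}

#' @export
print.laplace_estimates <- function(x, ...) {
  cat(if (identical(x$smoothing, "laplace")) "Laplace-smoothed" else "Plug-in",
      " probability estimates (n = ", x$n, ", p = ", length(x$theta_hat), ")\n",
      "  pi_hat = ", format(x$pi_hat, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Construct a screening-score object
#'
#' Wraps a vector of nonnegative per-feature statistic values together with
#' the method label and the induced decreasing ranking (ties broken by
#' ascending feature index, so rankings are deterministic).
#'
#' @param values nonnegative finite per-feature statistic values.
#' @param method one of `"wmsd"`, `"chi2_exact"`, `"chi2_approx"`,
#'   `"mi_exact"`, `"mi_approx"`.
#' @param feature_ids optional identifiers.
#' @return An object of class `"screening_scores"` with elements `values`,
#'   `method`, `ranking` and `feature_ids`.
#' @export
screening_scores <- function(values,
                             method = c("wmsd", "chi2_exact", "chi2_approx",
                                        "mi_exact", "mi_approx"),
                             feature_ids = NULL) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("score values must be finite and nonnegative")
  if (is.null(feature_ids)) feature_ids <- as.character(seq_along(values))
  structure(list(values = values, method = method,
                 ranking = order_decreasing(values),
                 feature_ids = as.character(feature_ids)),
            class = "screening_scores")
}

# decreasing stable order; radix sort breaks ties by ascending index
order_decreasing <- function(values) {
  order(values, decreasing = TRUE, method = "radix")
}

#' @export
print.screening_scores <- function(x, ...) {
  cat("Screening scores (", x$method, "), p = ", length(x$values), "\n", sep = "")
  top <- utils::head(x$ranking, 5L)
  cat("  top features: ",
      paste0(x$feature_ids[top], " (", format(x$values[top], digits = 4), ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Weighted mean squared deviation (WMSD) scores
#'
#' The WMSD statistic for feature j is
#' \deqn{\hat\omega_j = \hat\pi(1-\hat\pi)(\hat\theta_{1j}-\hat\theta_{0j})^2,}
#' the squared gap between the two class-conditional success probabilities,
#' weighted by the class balance. It is zero iff the smoothed estimates are
#' class-independent, and — unlike the Chi-square statistic — does not divide
#' by \eqn{\hat\theta_j(1-\hat\theta_j)}, so features with marginal
#' probability near 0.5 are not down-weighted.
#'
#' @param est estimates from [laplace_estimates()].
#' @return A `"screening_scores"` object with `method = "wmsd"`.
#' @examples
#' d <- binary_dataset(matrix(rbinom(40, 1, 0.4), 20, 2), rbinom(20, 1, 0.5))
#' wmsd_scores(laplace_estimates(d))
#' @export
wmsd_scores <- function(est) {
  stopifnot(inherits(est, "laplace_estimates"))
  screening_scores(est$pi_hat * (1 - est$pi_hat) *
                     (est$theta1_hat - est$theta0_hat)^2,
                   method = "wmsd", feature_ids = est$feature_ids)
}

#' Exact Chi-square scores from 2x2 contingency tables
#'
#' Pearson's Chi-square statistic of each feature-by-label 2x2 table,
#' computed from the count summaries:
#' \deqn{\chi^2_j = \frac{n\{n_{1j}(n-n_{1\cdot}-n_{\cdot j}+n_{1j})
#'   - (n_{\cdot j}-n_{1j})(n_{1\cdot}-n_{1j})\}^2}
#'   {n_{\cdot j}\, n_{1\cdot}\,(n-n_{\cdot j})(n-n_{1\cdot})}.}
#' A degenerate table (any zero margin) leaves the statistic undefined; such
#' features score 0 — a constant feature or an all-one-class sample carries
#' no discrimination — and a warning reports how many were affected.
#'
#' @param counts a `"contingency_counts"` object.
#' @return A `"screening_scores"` object with `method = "chi2_exact"`.
#' @export
chi2_exact <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  n <- counts$n; n1dot <- counts$n1dot
  ndotj <- counts$ndotj; n1j <- counts$n1j
  cross <- n1j * (n - n1dot - ndotj + n1j) - (ndotj - n1j) * (n1dot - n1j)
  den <- ndotj * n1dot * (n - ndotj) * (n - n1dot)
  degenerate <- den == 0
  vals <- numeric(length(ndotj))
  vals[!degenerate] <- n * cross[!degenerate]^2 / den[!degenerate]
  warn_degenerate(degenerate, "chi2_exact")
  screening_scores(vals, method = "chi2_exact", feature_ids = counts$feature_ids)
}

#' Exact mutual information scores from 2x2 contingency tables
#'
#' Plug-in mutual information (natural logarithm) of each feature-by-label
#' 2x2 table, as the sum of the four cell terms
#' \eqn{(n_{kl}/n)\log\{n\,n_{kl}/(n_{k\cdot}n_{\cdot l})\}}, with the
#' convention that a zero cell contributes exactly 0. Degenerate tables
#' (a zero margin) score 0 with a warning, as in [chi2_exact()].
#'
#' @param counts a `"contingency_counts"` object.
#' @return A `"screening_scores"` object with `method = "mi_exact"`.
#' @export
mi_exact <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  n <- counts$n; n1dot <- counts$n1dot
  ndotj <- counts$ndotj; n1j <- counts$n1j
  a <- n1j                       # x = 1, y = 1
  b <- n1dot - n1j               # x = 0, y = 1
  cc <- ndotj - n1j              # x = 1, y = 0
  d <- n - n1dot - ndotj + n1j   # x = 0, y = 0
  term <- function(cell, rowm, colm) {
    out <- numeric(length(cell))
    pos <- cell > 0 & rowm > 0 & colm > 0
    out[pos] <- (cell[pos] / n) * log(n * cell[pos] / (rowm[pos] * colm[pos]))
    out
  }
  p1 <- rep(n1dot, length(ndotj)); p0 <- rep(n - n1dot, length(ndotj))
  vals <- term(a, p1, ndotj) + term(b, p1, n - ndotj) +
    term(cc, p0, ndotj) + term(d, p0, n - ndotj)
  degenerate <- ndotj * n1dot * (n - ndotj) * (n - n1dot) == 0
  vals[degenerate] <- 0
  vals <- pmax(vals, 0) # guard tiny negative rounding at independence
  warn_degenerate(degenerate, "mi_exact")
  screening_scores(vals, method = "mi_exact", feature_ids = counts$feature_ids)
}

warn_degenerate <- function(degenerate, where) {
  k <- sum(degenerate)
  if (k > 0)
    warning(k, " feature(s) with a degenerate 2x2 table (zero margin); ",
            "score set to 0 in ", where, call. = FALSE)
  invisible(NULL)
}

#' Chi-square scores approximated from WMSD
#'
#' The large-sample relation linking the Chi-square statistic to WMSD:
#' \deqn{\chi^2_j \approx n\,\hat\omega_j /
#'   \{\hat\theta_j(1-\hat\theta_j)\}.}
#' With unsmoothed plug-in proportions substituted for the Laplace
#' estimates, the relation is an exact algebraic identity on every
#' non-degenerate table (see [plugin_estimates()]).
#'
#' @param wmsd a `"screening_scores"` object with `method = "wmsd"`.
#' @param est the estimates the WMSD scores were computed from.
#' @return A `"screening_scores"` object with `method = "chi2_approx"`.
#' @export
chi2_approx <- function(wmsd, est) {
  stopifnot(inherits(wmsd, "screening_scores"), inherits(est, "laplace_estimates"))
  if (!identical(wmsd$method, "wmsd"))
    stop("`wmsd` must carry method \"wmsd\", got \"", wmsd$method, "\"")
  screening_scores(est$n * wmsd$values / (est$theta_hat * (1 - est$theta_hat)),
                   method = "chi2_approx", feature_ids = wmsd$feature_ids)
}

#' Mutual information approximated from Chi-square
#'
#' The second-order relation \eqn{MI_j \approx \chi^2_j / n}, accurate near
#' independence.
#'
#' @param chi2 a `"screening_scores"` object with method `"chi2_exact"` or
#'   `"chi2_approx"`.
#' @param n sample count.
#' @return A `"screening_scores"` object with `method = "mi_approx"`.
#' @export
mi_approx <- function(chi2, n) {
  stopifnot(inherits(chi2, "screening_scores"))
  if (!chi2$method %in% c("chi2_exact", "chi2_approx"))
    stop("`chi2` must carry a chi-square method, got \"", chi2$method, "\"")
  if (length(n) != 1L || is.na(n) || n < 1) stop("`n` must be a positive count")
  screening_scores(chi2$values / n, method = "mi_approx",
                   feature_ids = chi2$feature_ids)
}

#' Rank features by decreasing score
#'
#' @param scores a `"screening_scores"` object.
#' @return An integer permutation of `1:p` ordering the values
#'   non-increasingly, ties broken by ascending feature index.
#' @examples
#' s <- screening_scores(c(0.1, 0.3, 0.2), "wmsd")
#' rank_features(s) # 2 3 1
#' @export
rank_features <- function(scores) {
  stopifnot(inherits(scores, "screening_scores"))
  scores$ranking
}
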