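#' Bernoulli naive Bayes on a feature subset
#'
#' Fits a Bernoulli naive Bayes classifier on the given columns, with
#' add-one (Laplace) smoothing of the class-conditional probabilities
#' \eqn{\hat P(X_j = 1 | Y = k) = (1 + \#\{x_j = 1, y = k\})/(n_k + 2)} and
#' of the class prior \eqn{(n_1 + 1)/(n + 2)}, so every stored probability
#' is strictly inside (0, 1).
#'
#' @param train a [binary_dataset()].
#' @param subset integer indices of the feature columns to use; default all.
#' @return An object of class `"bernoulli_nb"` with elements `prior1`,
#'   `prob1`, `prob0`, `subset` and `feature_ids`.
#' @seealso [predict.bernoulli_nb()]
#' @export
fit_bernoulli_nb <- function(train, subset = NULL) {
  train <- as_binary_dataset(train)
  subset <- check_subset(subset, train$p)
  x <- train$features[, subset, drop = FALSE]
  y <- train$labels
  n1 <- sum(y)
  n0 <- train$n - n1
  ones1 <- as.numeric(Matrix::crossprod(x, y))
  ones0 <- as.numeric(Matrix::colSums(x)) - ones1
  structure(list(prior1 = (n1 + 1) / (train$n + 2),
                 prob1 = (1 + ones1) / (n1 + 2),
                 prob0 = (1 + ones0) / (n0 + 2),
                 subset = subset,
                 feature_ids = train$feature_ids[subset]),
            class = "bernoulli_nb")
}

check_subset <- function(subset, p) {
  if (is.null(subset)) subset <- seq_len(p)
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("feature `subset` must be nonempty")
  if (anyNA(subset) || any(subset < 1L) || any(subset > p))
    stop("feature `subset` must index columns 1..", p)
  subset
}

#' Predict with a Bernoulli naive Bayes model
#'
#' @param object a `"bernoulli_nb"` fit.
#' @param newdata a [binary_dataset()] or 0/1 matrix; either the full
#'   feature matrix the model was trained from (the stored subset is
#'   applied) or a matrix already restricted to the subset columns.
#' @param type `"posterior"` for P(Y = 1 | x), `"score"` for the
#'   log-posterior odds.
#' @param ... unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.bernoulli_nb <- function(object, newdata,
                                 type = c("posterior", "score"), ...) {
  type <- match.arg(type)
  x <- classifier_newdata(newdata, object$subset)
  score <- as.numeric(
    x %*% (log(object$prob1) - log(object$prob0)) +
      (1 - x) %*% (log(1 - object$prob1) - log(1 - object$prob0))
  ) + log(object$prior1 / (1 - object$prior1))
  if (type == "score") score else stats::plogis(score)
}

classifier_newdata <- function(newdata, subset) {
  x <- if (inherits(newdata, "binary_dataset")) newdata$features else newdata
  if (is.data.frame(x)) x <- as.matrix(x)
  if (ncol(x) == length(subset)) return(x)
  if (max(subset) <= ncol(x)) return(x[, subset, drop = FALSE])
  stop("`newdata` has ", ncol(x), " columns; expected the full training ",
       "matrix or exactly the ", length(subset), " subset columns")
}

#' @export
print.bernoulli_nb <- function(x, ...) {
  cat("Bernoulli naive Bayes on ", length(x$subset), " feature(s), prior1 = ",
      format(x$prior1, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Ridge-stabilised logistic regression on a feature subset
#'
#' Maximum-likelihood logistic regression fitted by Newton iterations, with
#' a small ridge penalty `lambda` (default 1e-6) on the non-intercept
#' coefficients so the fit stays finite under complete separation. The
#' objective is the log-likelihood minus \eqn{\lambda\|\beta\|^2/2};
#' convergence requires the gradient's max-norm below `tol`.
#'
#' @param train a [binary_dataset()].
#' @param subset integer indices of the feature columns to use; default all.
#' @param lambda ridge penalty on the slopes, default 1e-6.
#' @param tol convergence tolerance on the penalized score, default 1e-8.
#' @param max_iter Newton iteration cap.
#' @return An object of class `"ridge_logistic"` with elements
#'   `coefficients` (intercept first), `lambda`, `converged`, `iterations`,
#'   `grad_norm`, `subset`, `feature_ids`.
#' @seealso [predict.ridge_logistic()]
#' @export
fit_logistic <- function(train, subset = NULL, lambda = 1e-6, tol = 1e-8,
                         max_iter = 100L) {
  train <- as_binary_dataset(train)
  subset <- check_subset(subset, train$p)
  X <- cbind(1, as.matrix(train$features[, subset, drop = FALSE]))
  y <- train$labels
  pen <- c(0, rep(lambda, length(subset))) # intercept unpenalized
  beta <- numeric(ncol(X))
  converged <- FALSE
  g <- NULL
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    g <- as.numeric(crossprod(X, y - mu)) - pen * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X) + diag(pen, ncol(X))
    beta <- beta + solve(H, g)
  }
  if (!converged) {
    # final score check: the last Newton step may have landed on the optimum
    mu <- stats::plogis(as.numeric(X %*% beta))
    g <- as.numeric(crossprod(X, y - mu)) - pen * beta
    converged <- max(abs(g)) < tol
    it <- max_iter
  }
  if (!converged)
    stop("logistic fit did not converge within ", max_iter,
         " iterations for a subset of size ", length(subset))
  structure(list(coefficients = stats::setNames(
                   beta, c("(Intercept)", train$feature_ids[subset])),
                 lambda = lambda, converged = converged, iterations = it,
                 grad_norm = max(abs(g)), subset = subset,
                 feature_ids = train$feature_ids[subset]),
            class = "ridge_logistic")
}

#' Predict with a ridge-stabilised logistic model
#'
#' @param object a `"ridge_logistic"` fit.
#' @param newdata as in [predict.bernoulli_nb()].
#' @param type `"link"` for the linear predictor, `"response"` for
#'   probabilities.
#' @param ... unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.ridge_logistic <- function(object, newdata,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  x <- classifier_newdata(newdata, object$subset)
  eta <- as.numeric(cbind(1, as.matrix(x)) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.ridge_logistic <- function(x, ...) {
  cat("Ridge-stabilised logistic regression on ", length(x$subset),
      " feature(s)\n  converged in ", x$iterations,
      " iteration(s), max |score| = ", format(x$grad_norm, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney with midranks)
#'
#' The probability that a randomly chosen class-1 observation outscores a
#' randomly chosen class-0 observation, ties counting one half; computed
#' from midranks in O(n log n).
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)) # 1
#' auc(rep(1, 4), c(1, 1, 0, 0)) # 0.5
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length")
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0/1 and scores free of NA")
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
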