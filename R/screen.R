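#' Screen binary features against a binary label
#'
#' The central fitting function of the package. Computes Laplace-smoothed
#' estimates and all three marginal screening statistics — WMSD
#' \eqn{\hat\omega_j = \hat\pi(1-\hat\pi)(\hat\theta_{1j}-\hat\theta_{0j})^2},
#' the exact Chi-square statistic and the exact mutual information — ranks
#' the features by the chosen method, and (optionally) selects the number of
#' retained features with the power-law window rule of
#' [select_model_size()].
#'
#' @param x an n x p 0/1 feature matrix (dense or \pkg{Matrix} sparse), or a
#'   ready-made [binary_dataset()].
#' @param y length-n 0/1 label vector; ignored when `x` is already a
#'   `binary_dataset`.
#' @param method statistic used for the ranking and the size selection:
#'   `"wmsd"` (default), `"chi2"` or `"mi"`.
#' @param m,d_min,d_max size-selection parameters, see
#'   [select_model_size()]. The defaults (100, 10, 100) are the simulation
#'   settings of the reference study; document-term studies there used
#'   `d_min = 20`.
#' @param select logical; set `FALSE` to skip size selection (required when
#'   `p < d_max + m - 1`).
#' @param feature_ids optional identifiers, one per feature column.
#' @return An object of class `"wmsd_screen"`: a list with elements
#'   \describe{
#'     \item{scores}{data frame with columns `feature_id`, `wmsd`, `chi2`,
#'       `mi` and `rank` (position under the chosen method).}
#'     \item{values, ranking}{the chosen method's statistic values and the
#'       induced permutation.}
#'     \item{estimates, counts}{the smoothed estimates and contingency
#'       counts.}
#'     \item{fit}{the `"power_law_fit"` (or `NULL` when `select = FALSE`).}
#'     \item{d_hat, selected, selected_ids}{the selected size and the
#'       retained features.}
#'   }
#' @examples
#' cfg <- sim_config(pi = 0.5, n = 1000, p = 300, d0 = 10, seed = 7)
#' sim <- generate_dataset(cfg)
#' fit <- wmsd_screen(sim$train, m = 50, d_min = 2, d_max = 50)
#' print(fit)
#' head(summary(fit)$top)
#' @seealso [screen_file()] for the file-based workflow, [run_cell()] for
#'   simulation studies.
#' @export
wmsd_screen <- function(x, y = NULL, method = c("wmsd", "chi2", "mi"),
                        m = 100, d_min = 10, d_max = 100, select = TRUE,
                        feature_ids = NULL) {
  method <- match.arg(method)
  data <- as_binary_dataset(x, y, feature_ids)
  counts <- contingency_counts(data)
  est <- laplace_estimates(data)
  sc <- list(wmsd = wmsd_scores(est),
             chi2 = chi2_exact(counts),
             mi = mi_exact(counts))
  chosen <- sc[[method]]
  ranking <- chosen$ranking
  fit <- NULL
  d_hat <- NA_integer_
  selected <- integer(0)
  if (select) {
    fit <- select_model_size(chosen$values[ranking], m = m,
                             d_min = d_min, d_max = d_max)
    d_hat <- fit$d_hat
    selected <- ranking[seq_len(d_hat)]
  }
  rank_of <- integer(data$p)
  rank_of[ranking] <- seq_len(data$p)
  structure(
    list(call = match.call(), n = data$n, p = data$p, method = method,
         feature_ids = data$feature_ids,
         scores = data.frame(feature_id = data$feature_ids,
                             wmsd = sc$wmsd$values,
                             chi2 = sc$chi2$values,
                             mi = sc$mi$values,
                             rank = rank_of,
                             stringsAsFactors = FALSE),
         values = chosen$values, ranking = ranking,
         estimates = est, counts = counts,
         fit = fit, d_hat = d_hat, selected = selected,
         selected_ids = data$feature_ids[selected]),
    class = "wmsd_screen"
  )
}

#' @export
print.wmsd_screen <- function(x, ...) {
  cat("Feature screening (", x$method, "): n = ", x$n, ", p = ", x$p, "\n",
      sep = "")
  if (!is.null(x$fit)) {
    cat("  selected model size d_hat = ", x$d_hat, " (power-law rule, m = ",
        x$fit$m, ", d in [", x$fit$d_min, ", ", x$fit$d_max, "])\n", sep = "")
  } else {
    cat("  size selection skipped\n")
  }
  top <- utils::head(x$ranking, 5L)
  cat("  top features: ",
      paste0(x$feature_ids[top], " (",
             format(x$values[top], digits = 3), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.wmsd_screen <- function(object, n_top = 10L, ...) {
  ord <- object$ranking
  structure(
    list(n = object$n, p = object$p, method = object$method,
         d_hat = object$d_hat, fit = object$fit,
         pi_hat = object$estimates$pi_hat,
         top = object$scores[utils::head(ord, n_top), , drop = FALSE],
         selected_ids = object$selected_ids),
    class = "summary.wmsd_screen"
  )
}

#' @export
print.summary.wmsd_screen <- function(x, ...) {
  cat("Feature screening summary (", x$method, ")\n", sep = "")
  cat("  n = ", x$n, ", p = ", x$p, ", pi_hat = ",
      format(x$pi_hat, digits = 4), "\n", sep = "")
  if (!is.null(x$fit))
    cat("  selected size d_hat = ", x$d_hat, "\n", sep = "")
  cat("  top-ranked features:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.wmsd_screen <- function(object, ...) {
  stats::setNames(object$values, object$feature_ids)
}

#' Rank plot of screening scores with the selected model size
#'
#' Sorted scores of the chosen method on doubly logarithmic axes; when a
#' size selection was performed, the best-fitting power-law window is shaded
#' and the selected size marked.
#'
#' @param x a `"wmsd_screen"` object.
#' @param ... passed to the underlying plot.
#' @export
plot.wmsd_screen <- function(x, ...) {
  s <- x$values[x$ranking]
  if (!is.null(x$fit)) {
    plot(x$fit, scores = s, ...)
  } else {
    keep <- s > 0
    plot(seq_along(s)[keep], s[keep], log = "xy", pch = 20, cex = 0.5,
         xlab = "rank", ylab = paste(x$method, "score"),
         main = "rank plot", ...)
  }
  invisible(x)
}
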