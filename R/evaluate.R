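#' Selection error rates against a known true model
#'
#' The two rates of the reference simulation design, applied verbatim:
#' \deqn{FPR = |T \setminus \hat M| / |T|, \qquad
#'       FNR = |(F \setminus T) \cap \hat M| / |F \setminus T|,}
#' where T is the true relevant set, F = \{1..p\} the full set and
#' \eqn{\hat M} the selected set. Note the naming is swapped relative to
#' common usage: this FPR is the fraction of relevant features *missed* and
#' this FNR the fraction of irrelevant features *selected*. The convention
#' is kept for fidelity with the study these rates reproduce.
#'
#' @param selected integer indices of the selected features.
#' @param true_model integer indices of the truly relevant features;
#'   nonempty and a proper subset of 1..p (both denominators must be
#'   positive).
#' @param p total feature count.
#' @return An object of class `"selection_metrics"` with elements `fpr`,
#'   `fnr`, `selected`, `true_model` and `p`.
#' @examples
#' m <- selection_metrics(c(1:10, 21:25), 1:20, p = 500)
#' c(m$fpr, m$fnr) # 0.5, 5/480
#' @export
selection_metrics <- function(selected, true_model, p) {
  selected <- as.integer(selected)
  true_model <- as.integer(true_model)
  if (anyNA(selected) || any(selected < 1L) || any(selected > p))
    stop("`selected` must be a subset of 1..p")
  if (anyNA(true_model) || any(true_model < 1L) || any(true_model > p))
    stop("`true_model` must be a subset of 1..p")
  if (length(true_model) == 0L)
    stop("`true_model` must be nonempty (FPR denominator)")
  if (length(unique(true_model)) >= p)
    stop("`true_model` must be a proper subset of 1..p (FNR denominator)")
  selected <- unique(selected)
  true_model <- unique(true_model)
  structure(list(
    fpr = length(setdiff(true_model, selected)) / length(true_model),
    fnr = length(setdiff(selected, true_model)) / (p - length(true_model)),
    selected = selected, true_model = true_model, p = p),
    class = "selection_metrics")
}

#' @export
print.selection_metrics <- function(x, ...) {
  cat("Selection metrics (study convention: FPR = missed relevant, ",
      "FNR = selected irrelevant)\n", sep = "")
  cat("  |T| = ", length(x$true_model), ", |M_hat| = ", length(x$selected),
      ", p = ", x$p, "\n", sep = "")
  cat("  FPR = ", format(x$fpr, digits = 4),
      ", FNR = ", format(x$fnr, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Run one simulation cell of the screening study
#'
#' The full pipeline of the simulation study, replicated R times: simulate a
#' train/test pair from the multivariate Bernoulli design, compute the
#' WMSD, Chi-square and mutual-information rankings, select the model size
#' \eqn{\hat d} from the WMSD ranking with the power-law rule, evaluate the
#' selection error rates of the WMSD model against the known relevant set,
#' and fit naive Bayes and logistic regression on each method's top-\eqn{\hat d}
#' features (the same \eqn{\hat d} for all three rankings), scoring them by
#' test-set AUC. Replication r uses seed `seed + r`, so any single
#' replication can be replayed in isolation.
#'
#' @param pi,n,p,d0,n_test generative parameters, see [sim_config()].
#' @param R number of replications.
#' @param m,d_min,d_max size-selection parameters, see
#'   [select_model_size()].
#' @param seed master seed; replication r is seeded with `seed + r`.
#' @param classifiers any subset of `c("nb", "lr")`.
#' @return An object of class `"sim_cell"`: a list with the cell settings,
#'   the per-replication data frame `replications` (seed, `d_hat`, `fpr`,
#'   `fnr` and one AUC column per classifier x method) and the column
#'   `means`.
#' @examples
#' \donttest{
#' cell <- run_cell(pi = 0.5, n = 500, p = 250, d0 = 10, R = 5,
#'                  m = 50, d_min = 2, d_max = 50, seed = 1)
#' cell$means[c("fpr", "auc_nb_wmsd")]
#' }
#' @export
run_cell <- function(pi = 0.5, n = 1000, p = 500, d0 = 20, R = 100,
                     n_test = 1000, m = 100, d_min = 10, d_max = 100,
                     seed = 1L, classifiers = c("nb", "lr")) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (R < 1) stop("`R` must be at least 1")
  cfg0 <- sim_config(pi = pi, n = n, p = p, d0 = d0, n_test = n_test,
                     seed = seed)
  truth <- make_truth(cfg0)
  methods <- c("wmsd", "chi2", "mi")
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    cfg <- cfg0
    cfg$seed <- as.integer(seed + r)
    sim <- generate_dataset(cfg, truth)
    counts <- contingency_counts(sim$train)
    est <- laplace_estimates(sim$train)
    sc <- list(wmsd = wmsd_scores(est),
               chi2 = chi2_exact(counts),
               mi = mi_exact(counts))
    fit <- select_model_size(sc$wmsd$values[sc$wmsd$ranking],
                             m = m, d_min = d_min, d_max = d_max)
    d_hat <- fit$d_hat
    met <- selection_metrics(sc$wmsd$ranking[seq_len(d_hat)],
                             truth$true_model, p)
    row <- list(replication = r, seed = cfg$seed, d_hat = d_hat,
                fpr = met$fpr, fnr = met$fnr)
    for (meth in methods) {
      sel <- sc[[meth]]$ranking[seq_len(d_hat)]
      if ("nb" %in% classifiers) {
        nb <- fit_bernoulli_nb(sim$train, sel)
        row[[paste0("auc_nb_", meth)]] <-
          auc(predict(nb, sim$test, type = "score"), sim$test$labels)
      }
      if ("lr" %in% classifiers) {
        lr <- fit_logistic(sim$train, sel)
        row[[paste0("auc_lr_", meth)]] <-
          auc(predict(lr, sim$test, type = "link"), sim$test$labels)
      }
    }
    rows[[r]] <- as.data.frame(row)
  }
  reps <- do.call(rbind, rows)
  means <- colMeans(reps[, setdiff(names(reps), c("replication", "seed")),
                         drop = FALSE])
  structure(list(pi = pi, n = n, p = p, d0 = d0, R = R, n_test = n_test,
                 m = m, d_min = d_min, d_max = d_max, seed = seed,
                 replications = reps, means = means),
            class = "sim_cell")
}

#' @export
print.sim_cell <- function(x, ...) {
  cat("Simulation cell: pi = ", x$pi, ", d0 = ", x$d0, ", p = ", x$p,
      ", n = ", x$n, " (R = ", x$R, ")\n", sep = "")
  print(round(x$means, 4))
  invisible(x)
}

#' Parameter grid of the reference simulation study
#'
#' All 24 cells of the simulation study: pi in \{0.5, 0.8\}, d0 in
#' \{20, 50\}, p in \{500, 1000\} and n in \{1000, 2000, 5000\}.
#'
#' @return A data frame with columns `pi`, `d0`, `p`, `n`.
#' @export
table1_settings <- function() {
  expand.grid(n = c(1000, 2000, 5000), p = c(500, 1000), d0 = c(20, 50),
              pi = c(0.5, 0.8))[, c("pi", "d0", "p", "n")]
}

#' Reproduce the simulation study table
#'
#' Runs [run_cell()] over a grid of settings and binds one summary row per
#' cell. The defaults reproduce the full study grid at a reduced
#' replication count; pass a subset of [table1_settings()] for single
#' cells.
#'
#' @param settings data frame with columns `pi`, `d0`, `p`, `n`.
#' @param R replications per cell (the reference study used 1000).
#' @param seed master seed; cell i uses `seed + (i - 1) * R` so replication
#'   seed streams do not overlap across cells.
#' @param ... further arguments passed to [run_cell()].
#' @return A data frame with one row per cell: the settings, mean AUC per
#'   classifier x method, mean FPR/FNR and mean selected size.
#' @export
reproduce_table1 <- function(settings = table1_settings(), R = 100,
                             seed = 1L, ...) {
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    s <- settings[i, ]
    cell <- run_cell(pi = s$pi, n = s$n, p = s$p, d0 = s$d0, R = R,
                     seed = as.integer(seed + (i - 1) * R), ...)
    cbind(s, as.data.frame(as.list(round(cell$means, 4))),
          row.names = NULL)
  })
  do.call(rbind, rows)
}
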