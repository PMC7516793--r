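# Independent oracles used across tests. These deliberately take the
# slow, direct route (cell-by-cell tables, entropies, O(n^2) pair counts)
# so they share no code with the implementation they check.

# Pearson chi-square of one 2x2 table from expected cell counts
chisq_table_oracle <- function(n, n1dot, ndotj, n1j) {
  O <- matrix(c(n1j, n1dot - n1j,
                ndotj - n1j, n - n1dot - ndotj + n1j), 2, 2)
  rowm <- rowSums(O); colm <- colSums(O)
  E <- outer(rowm, colm) / n
  sum((O - E)^2 / E)
}

# plug-in mutual information as H(X) + H(Y) - H(X, Y), natural log
mi_entropy_oracle <- function(n, n1dot, ndotj, n1j) {
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  joint <- c(n1j, n1dot - n1j, ndotj - n1j, n - n1dot - ndotj + n1j) / n
  ent(c(ndotj, n - ndotj) / n) + ent(c(n1dot, n - n1dot) / n) - ent(joint)
}

# AUC by explicit pair counting, ties worth one half
auc_pair_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}

# Pearson correlation from raw sums, mirroring the window formula directly
pearson_raw_oracle <- function(x, y) {
  m <- length(x)
  (m * sum(x * y) - sum(x) * sum(y)) /
    (sqrt(m * sum(x^2) - sum(x)^2) * sqrt(m * sum(y^2) - sum(y)^2))
}

# random non-degenerate 2x2 table counts
rand_table <- function(n_min = 20, n_max = 200) {
  repeat {
    n <- sample(n_min:n_max, 1)
    n1dot <- sample(1:(n - 1), 1)
    ndotj <- sample(1:(n - 1), 1)
    lo <- max(0, n1dot + ndotj - n)
    hi <- min(n1dot, ndotj)
    n1j <- sample(lo:hi, 1)
    if (n1dot > 0 && n1dot < n && ndotj > 0 && ndotj < n)
      return(list(n = n, n1dot = n1dot, ndotj = ndotj, n1j = n1j))
  }
}

# random binary dataset with a mix of informative and noise columns
rand_dataset <- function(n = 60, p = 8) {
  y <- rbinom(n, 1, 0.5)
  x <- sapply(seq_len(p), function(j) {
    if (j %% 2 == 0) rbinom(n, 1, 0.3) else rbinom(n, 1, 0.2 + 0.5 * y)
  })
  binary_dataset(x, y)
}
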