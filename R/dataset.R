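#' Construct a validated binary dataset
#'
#' Bundles an n x p feature matrix with 0/1 entries and a length-n 0/1 label
#' vector. All screening functions in the package operate on this container.
#' Sparse matrices from the \pkg{Matrix} package are accepted and kept sparse;
#' only column sums and label cross-products are ever taken, so large sparse
#' document-term matrices stay cheap.
#'
#' @param features numeric matrix (base or \pkg{Matrix} sparse) with entries
#'   in \{0, 1\}; rows are observations, columns are features.
#' @param labels numeric vector of class labels in \{0, 1\}, one per row.
#' @param feature_ids optional character or integer identifiers, one per
#'   column; defaults to `1:p`.
#'
#' @return An object of class `"binary_dataset"`: a list with elements
#'   `features`, `labels`, `feature_ids`, `n` and `p`.
#' @examples
#' d <- binary_dataset(matrix(c(1, 0, 1, 0, 1, 1), 3, 2), c(1, 0, 1))
#' d$n
#' @export
binary_dataset <- function(features, labels, feature_ids = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!(is.matrix(features) || inherits(features, "Matrix")))
    stop("`features` must be a matrix (base or Matrix sparse)")
  if (methods::is(features, "nMatrix"))
    features <- methods::as(features, "dMatrix")
  n <- nrow(features)
  p <- ncol(features)
  if (n < 1L || p < 1L) stop("empty dataset: need n >= 1 and p >= 1")
  labels <- as.numeric(labels)
  if (length(labels) != n)
    stop("length of `labels` (", length(labels),
         ") must equal nrow(features) (", n, ")")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be exactly 0 or 1")
  check_binary_entries(features)
  if (is.null(feature_ids)) {
    feature_ids <- colnames(features)
    if (is.null(feature_ids)) feature_ids <- as.character(seq_len(p))
  }
  if (length(feature_ids) != p)
    stop("`feature_ids` must have one entry per feature column")
  structure(
    list(features = features, labels = labels,
         feature_ids = as.character(feature_ids), n = n, p = p),
    class = "binary_dataset"
  )
}

# entries must be exactly 0 or 1; sparse matrices are checked on their
# stored values only (structural zeros are 0 by construction)
check_binary_entries <- function(x) {
  if (inherits(x, "Matrix")) {
    vals <- methods::as(x, "CsparseMatrix")@x
  } else {
    vals <- x
  }
  if (anyNA(vals) || !all(vals == 0 | vals == 1))
    stop("feature entries must be exactly 0 or 1 (no NA)")
  invisible(TRUE)
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat("Binary dataset: ", x$n, " observations x ", x$p, " features\n", sep = "")
  cat("  label-1 fraction: ", format(mean(x$labels), digits = 4), "\n", sep = "")
  invisible(x)
}

as_binary_dataset <- function(x, y = NULL, feature_ids = NULL) {
  if (inherits(x, "binary_dataset")) return(x)
  binary_dataset(x, y, feature_ids)
}
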