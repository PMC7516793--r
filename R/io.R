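#' Read a dense TSV binary dataset
#'
#' Rows are observations; the first column is the 0/1 label and the
#' remaining columns the 0/1 features. Fields are whitespace-separated.
#'
#' @param path file path.
#' @param header logical; does the first line name the columns?
#' @return A [binary_dataset()].
#' @export
read_binary_tsv <- function(path, header = FALSE) {
  tab <- tryCatch(
    utils::read.table(path, header = header, colClasses = "numeric"),
    error = function(e) stop("failed to parse '", path, "' as dense TSV: ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2L)
    stop("dense TSV needs a label column plus at least one feature column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  ids <- if (header) colnames(m) else NULL
  if (!header) dimnames(m) <- NULL # read.table's V2.. placeholders
  binary_dataset(m, tab[[1L]], feature_ids = ids)
}

#' Read a MatrixMarket binary dataset
#'
#' The sparse n x p feature matrix in MatrixMarket coordinate format plus a
#' one-column text file of 0/1 labels (one per row of the matrix).
#'
#' @param path path of the MatrixMarket file.
#' @param labels_path path of the label file.
#' @return A [binary_dataset()] whose features stay sparse.
#' @export
read_binary_mtx <- function(path, labels_path) {
  mat <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("failed to parse '", path,
                                           "' as MatrixMarket: ",
                                           conditionMessage(e), call. = FALSE))
  # pattern matrices (ngCMatrix, written for all-one data) carry no values
  if (methods::is(mat, "nMatrix")) mat <- methods::as(mat, "dMatrix")
  mat <- methods::as(mat, "CsparseMatrix")
  mat@x <- as.numeric(mat@x)
  labels <- scan(labels_path, what = numeric(), quiet = TRUE)
  binary_dataset(mat, labels)
}

#' Read a libsvm-style sparse binary dataset
#'
#' One observation per line: the 0/1 label followed by `index:value` pairs
#' of the nonzero features (values must be 1 for binary data). Indices are
#' 1-based.
#'
#' @param path file path.
#' @param p feature count; defaults to the largest index seen.
#' @return A [binary_dataset()] with a sparse feature matrix.
#' @export
read_binary_libsvm <- function(path, p = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("'", path, "' contains no observations")
  labels <- numeric(length(lines))
  ii <- jj <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[k]]), "[[:space:]]+")[[1L]]
    lab <- suppressWarnings(as.numeric(fields[1L]))
    if (is.na(lab))
      stop("line ", k, " of '", path, "': label '", fields[1L],
           "' is not numeric")
    labels[k] <- lab
    if (length(fields) > 1L) {
      parts <- strsplit(fields[-1L], ":", fixed = TRUE)
      bad <- vapply(parts, length, integer(1)) != 2L
      if (any(bad))
        stop("line ", k, " of '", path, "': malformed index:value pair '",
             fields[-1L][which(bad)[1L]], "'")
      idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
      val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
      if (anyNA(idx) || any(idx < 1L))
        stop("line ", k, " of '", path, "': feature indices must be ",
             "positive integers")
      if (anyNA(val) || !all(val %in% c(0, 1)))
        stop("line ", k, " of '", path, "': feature values must be 0 or 1")
      keep <- val == 1
      ii[[k]] <- rep.int(k, sum(keep))
      jj[[k]] <- idx[keep]
    } else {
      ii[[k]] <- integer(0)
      jj[[k]] <- integer(0)
    }
  }
  jj_all <- unlist(jj)
  if (is.null(p)) p <- if (length(jj_all)) max(jj_all) else 1L
  if (length(jj_all) && max(jj_all) > p)
    stop("feature index ", max(jj_all), " exceeds p = ", p)
  mat <- Matrix::sparseMatrix(i = unlist(ii), j = jj_all, x = 1,
                              dims = c(length(lines), p))
  binary_dataset(mat, labels)
}

#' Read a binary dataset in any supported format
#'
#' @param path main input path.
#' @param format `"tsv"` (dense, label first column), `"mtx"`
#'   (MatrixMarket + label file) or `"libsvm"` (sparse lines).
#' @param labels_path label file, required for `"mtx"`.
#' @param header for `"tsv"`: does the file carry a header line?
#' @return A [binary_dataset()].
#' @export
read_binary_dataset <- function(path, format = c("tsv", "mtx", "libsvm"),
                                labels_path = NULL, header = FALSE) {
  format <- match.arg(format)
  switch(format,
         tsv = read_binary_tsv(path, header = header),
         mtx = {
           if (is.null(labels_path))
             stop("`labels_path` is required for MatrixMarket input")
           read_binary_mtx(path, labels_path)
         },
         libsvm = read_binary_libsvm(path))
}

#' Write the per-feature score table
#'
#' Writes a TSV with columns `feature_id`, `wmsd`, `chi2`, `mi` and `rank`
#' (the feature's position in the chosen method's ranking).
#'
#' @param x a [wmsd_screen()] fit.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_score_table <- function(x, path) {
  stopifnot(inherits(x, "wmsd_screen"))
  utils::write.table(x$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Screen a binary dataset stored in a file
#'
#' End-to-end file workflow: read the dataset, compute all three score
#' vectors, rank by the chosen method, optionally select the model size,
#' and optionally write the score table.
#'
#' @inheritParams read_binary_dataset
#' @inheritParams wmsd_screen
#' @param out optional path; when given, the score table is written there
#'   via [write_score_table()].
#' @return The [wmsd_screen()] fit, invisibly when `out` is given.
#' @export
screen_file <- function(path, format = c("tsv", "mtx", "libsvm"),
                        method = c("wmsd", "chi2", "mi"),
                        m = 100, d_min = 10, d_max = 100, select = TRUE,
                        labels_path = NULL, header = FALSE, out = NULL) {
  data <- read_binary_dataset(path, format = format,
                              labels_path = labels_path, header = header)
  fit <- wmsd_screen(data, method = method, m = m, d_min = d_min,
                     d_max = d_max, select = select)
  if (!is.null(out)) {
    write_score_table(fit, out)
    return(invisible(fit))
  }
  fit
}
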