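#' Construct a feature table
#'
#' A feature table holds the steady-state sensor features for a set of
#' samples: an `n x d` numeric matrix `X` (one row per sample, one column per
#' sensor feature) plus a class label for every sample. It is the common
#' currency of the package: the preprocessing step produces one, the
#' extractors and cross-validation consume one.
#'
#' @param X numeric matrix (`n x d`) of sensor features; a data frame of
#'   numeric columns is accepted and converted.
#' @param labels vector of class labels, length `n`. Stored as a factor;
#'   its levels define the class order used by memberships and scatters.
#' @param feature_names optional character vector of `d` feature (sensor)
#'   names; defaults to the column names of `X` or `S1..Sd`.
#' @param sample_ids optional character vector of `n` sample identifiers.
#'
#' @return An object of class `feature_table`: a list with elements `X`
#'   (numeric matrix), `labels` (factor), `feature_names`, `sample_ids`.
#' @export
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' nrow(ft$X)
feature_table <- function(X, labels, feature_names = NULL, sample_ids = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix")
  n <- nrow(X); d <- ncol(X)
  if (length(labels) != n)
    stop(sprintf("length(labels) == %d but X has %d rows", length(labels), n))
  if (anyNA(X) || any(!is.finite(X)))
    stop("`X` contains missing or non-finite values")
  # factor levels are preserved as given: cross-validation relies on empty
  # classes staying visible so a fold that loses a class can be rejected
  labels <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(labels) < 1L) stop("at least one class is required")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("S", seq_len(d))
  }
  if (length(feature_names) != d)
    stop("`feature_names` must have one entry per column of `X`")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  }
  if (anyDuplicated(sample_ids)) stop("`sample_ids` must be unique")
  dimnames(X) <- list(sample_ids, feature_names)
  structure(
    list(X = X, labels = labels, feature_names = feature_names,
         sample_ids = sample_ids),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %d classes (%s)\n",
              nrow(x$X), ncol(x$X), nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Subset a feature table by sample index
#'
#' @param table a [feature_table()].
#' @param idx integer or logical index over samples.
#' @param drop_levels drop empty classes from the label factor (default TRUE).
#' @return A `feature_table` with the selected samples.
#' @export
ft_subset <- function(table, idx, drop_levels = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  labs <- table$labels[idx]
  if (drop_levels) labs <- droplevels(labs)
  feature_table(table$X[idx, , drop = FALSE], labs,
                feature_names = table$feature_names,
                sample_ids = table$sample_ids[idx])
}

#' Number of samples per class
#' @param table a [feature_table()].
#' @return Named integer vector of per-class counts.
#' @export
class_counts <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table(table$labels)
}

#' Write a feature table to CSV
#'
#' Layout: header `sample_id,label,<feature_1>,...,<feature_d>`, one row per
#' sample, UTF-8, '.' decimal separator. Numeric values are written with full
#' (17 significant digit) precision so a write/read round-trip is exact.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_ids,
                   label = as.character(table$labels),
                   stringsAsFactors = FALSE)
  num <- as.data.frame(
    apply(table$X, 2, function(col) sprintf("%.17g", col)),
    stringsAsFactors = FALSE
  )
  if (nrow(table$X) == 1L) num <- as.data.frame(as.list(num))  # apply drops dim
  names(num) <- table$feature_names
  utils::write.csv(cbind(df, num), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]. Expects the columns `sample_id` and
#' `label` followed by one numeric column per feature.
#'
#' @param path CSV file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("sample_id", "label")
  if (!all(need %in% names(df)))
    stop("feature-table CSV must contain 'sample_id' and 'label' columns")
  feats <- setdiff(names(df), need)
  if (length(feats) == 0L) stop("no feature columns found in ", path)
  X <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  feature_table(X, df$label, feature_names = feats, sample_ids = df$sample_id)
}
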