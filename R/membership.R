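#' Construct a fuzzy membership matrix
#'
#' A `c x n` matrix of membership degrees `u_ik` of sample `k` in class `i`.
#' Columns sum to 1 (each sample's memberships form a partition of unity) and
#' all entries lie in \[0, 1\]. The weight exponent `m_f` travels with the
#' matrix because fuzzy centers and scatters raise memberships to `u^m_f`.
#'
#' @param U numeric `c x n` matrix.
#' @param class_order character vector of the `c` class identifiers (row order).
#' @param m_f membership weight exponent, strictly greater than 1 (default 2,
#'   the value that works best for e-nose liquor data).
#' @return An object of class `membership_matrix`.
#' @export
membership_matrix <- function(U, class_order, m_f = 2) {
  if (!is.matrix(U) || !is.numeric(U)) stop("`U` must be a numeric matrix")
  if (nrow(U) != length(class_order))
    stop("`class_order` must name every row of `U`")
  if (m_f <= 1) stop("`m_f` must be greater than 1")
  if (any(U < -1e-12) || any(U > 1 + 1e-12))
    stop("memberships must lie in [0, 1]")
  cs <- colSums(U)
  if (any(abs(cs - 1) > 1e-9))
    stop("membership columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  rownames(U) <- class_order
  structure(list(U = U, class_order = as.character(class_order), m_f = m_f),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("membership_matrix: %d classes x %d samples, m_f = %g\n",
              nrow(x$U), ncol(x$U), x$m_f))
  invisible(x)
}

#' Fuzzy K-nearest-neighbour class memberships
#'
#' Computes soft class memberships from labelled training data with the
#' Keller initialization rule of the fuzzy KNN algorithm. For sample `k` with
#' label `j`, let `n_i` be how many of its `K` nearest neighbours (Euclidean
#' distance, the sample itself excluded) carry label `i`. Then
#' \deqn{u_{jk} = 0.51 + 0.49 \, n_j / K, \qquad
#'       u_{ik} = 0.49 \, n_i / K \; (i \neq j).}
#' A sample keeps majority membership in its own class but cedes weight to
#' classes crowding its neighbourhood — exactly the soft information the
#' fuzzy scatter matrices exploit in overlapping clusters. Columns are then
#' renormalized to sum exactly to 1 (the raw rule already sums to 1, so this
#' only removes rounding slack; it can be disabled).
#'
#' Distance ties are broken by ascending sample index, so results are
#' deterministic even with duplicated points.
#'
#' @param table a [feature_table()].
#' @param K neighbour count, `1 <= K <= n - 1` (default 7).
#' @param m_f weight exponent stored with the result (default 2).
#' @param renormalize force exact column sums of 1 (default `TRUE`).
#' @return A [membership_matrix()] with rows in `levels(table$labels)` order.
#' @export
#' @examples
#' ft <- feature_table(matrix(c(0, .1, .2, 5, 5.1, 5.2)), c(1, 1, 1, 2, 2, 2))
#' fuzzy_knn_memberships(ft, K = 3)$U
fuzzy_knn_memberships <- function(table, K = 7, m_f = 2, renormalize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$X)
  if (K < 1 || K > n - 1)
    stop(sprintf("K must satisfy 1 <= K <= n - 1 (n = %d, K = %d)", n, K))
  cls <- levels(table$labels)
  c_ <- length(cls)
  lab_idx <- as.integer(table$labels)
  if (c_ == 1L) {
    U <- matrix(1, 1L, n)
    return(membership_matrix(U, cls, m_f))
  }
  D <- as.matrix(stats::dist(table$X))
  U <- matrix(0, c_, n)
  for (k in seq_len(n)) {
    others <- setdiff(seq_len(n), k)
    # order() is stable: equal distances resolve to the lower sample index
    nb <- others[order(D[k, others])][seq_len(K)]
    counts <- tabulate(lab_idx[nb], nbins = c_)
    u <- 0.49 * counts / K
    u[lab_idx[k]] <- u[lab_idx[k]] + 0.51
    U[, k] <- u
  }
  if (renormalize) U <- sweep(U, 2, colSums(U), "/")
  membership_matrix(U, cls, m_f)
}

#' Crisp (hard) memberships from labels
#'
#' The indicator encoding `u_ik = 1` iff sample `k` belongs to class `i`.
#' With crisp memberships the fuzzy scatters collapse to the classical
#' Fisher scatters, which makes this the reference point for checking the
#' fuzzy machinery.
#'
#' @param labels vector or factor of class labels.
#' @param m_f weight exponent stored with the result (default 2; irrelevant
#'   for 0/1 memberships but kept for interface symmetry).
#' @return A [membership_matrix()].
#' @export
crisp_memberships <- function(labels, m_f = 2) {
  if (length(labels) == 0L) stop("`labels` must be nonempty")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  cls <- levels(labels)
  U <- matrix(0, length(cls), length(labels))
  U[cbind(as.integer(labels), seq_along(labels))] <- 1
  membership_matrix(U, cls, m_f)
}

#' Fuzzy cluster centers
#'
#' The membership-weighted mean of every class:
#' \deqn{v_i = \frac{\sum_k u_{ik}^{m_f} x_k}{\sum_k u_{ik}^{m_f}}.}
#' Every sample contributes to every center in proportion to its (powered)
#' membership; with crisp memberships this reduces exactly to the per-class
#' arithmetic means.
#'
#' @param table a [feature_table()].
#' @param U a [membership_matrix()] over the same samples.
#' @return An object of class `center_set`: list with `V` (`c x d` matrix of
#'   centers, rows in class order) and `class_order`.
#' @export
cluster_centers <- function(table, U) {
  stopifnot(inherits(table, "feature_table"),
            inherits(U, "membership_matrix"))
  if (ncol(U$U) != nrow(table$X))
    stop("membership matrix and feature table disagree on sample count")
  W <- U$U ^ U$m_f                     # c x n powered memberships
  wsum <- rowSums(W)
  if (any(wsum <= 0))
    stop("zero total membership weight for class(es): ",
         paste(U$class_order[wsum <= 0], collapse = ", "))
  V <- (W %*% table$X) / wsum
  rownames(V) <- U$class_order
  colnames(V) <- table$feature_names
  structure(list(V = V, class_order = U$class_order), class = "center_set")
}

#' Write a membership matrix to CSV
#'
#' Rows are classes, columns are sample ids; `m_f` is recorded on a leading
#' comment line (`# m_f=...`).
#'
#' @param U a [membership_matrix()].
#' @param path output file path.
#' @param sample_ids optional column names (default `sample_1..n`).
#' @return `path`, invisibly.
#' @export
write_membership_matrix <- function(U, path, sample_ids = NULL) {
  stopifnot(inherits(U, "membership_matrix"))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(U$U)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# m_f=%.17g", U$m_f), con)
  df <- data.frame(class = U$class_order,
                   apply(U$U, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE)
  names(df) <- c("class", sample_ids)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a membership matrix written by [write_membership_matrix()]
#'
#' @param path CSV file path.
#' @return A [membership_matrix()].
#' @export
read_membership_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# m_f=", first)) stop("missing '# m_f=' header line in ", path)
  m_f <- as.numeric(sub("^# m_f=", "", first))
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  U <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(U) <- "double"
  membership_matrix(U, df[[1]], m_f)
}
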