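#' Construct a scatter-matrix pair
#'
#' Bundles the numerator and denominator matrices of a discriminant
#' generalized eigenproblem: the between-class scatter `B` with either the
#' within-class scatter (classical Fisher pair, `kind = "classical"`) or the
#' fuzzy total scatter (`kind = "fuzzy"`). Both matrices must be symmetric
#' positive semidefinite; `B` has rank at most `c - 1`.
#'
#' @param B between-class scatter, `d x d`.
#' @param T_or_W within-class (classical) or total (fuzzy) scatter, `d x d`.
#' @param kind `"classical"` or `"fuzzy"`.
#' @return An object of class `scatter_pair`.
#' @export
scatter_pair <- function(B, T_or_W, kind = c("classical", "fuzzy")) {
  kind <- match.arg(kind)
  for (nm in c("B", "T_or_W")) {
    Mx <- if (nm == "B") B else T_or_W
    if (!is.matrix(Mx) || nrow(Mx) != ncol(Mx))
      stop("`", nm, "` must be a square matrix")
    sc <- max(1, max(abs(Mx)))
    if (max(abs(Mx - t(Mx))) > 1e-10 * sc)
      stop("`", nm, "` is not symmetric within tolerance")
    ev <- eigen((Mx + t(Mx)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * sc)
      stop("`", nm, "` is not positive semidefinite within tolerance")
  }
  if (!all(dim(B) == dim(T_or_W)))
    stop("`B` and `T_or_W` must have the same dimension")
  structure(list(B = unname((B + t(B)) / 2),
                 T_or_W = unname((T_or_W + t(T_or_W)) / 2),
                 kind = kind),
            class = "scatter_pair")
}

#' @export
print.scatter_pair <- function(x, ...) {
  cat(sprintf("scatter_pair (%s): %d x %d\n", x$kind, nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Classical Fisher scatter matrices
#'
#' The standard between- and within-class scatters of labelled data:
#' \deqn{S_B = \sum_i n_i (\bar x_i - \bar x)(\bar x_i - \bar x)^T, \qquad
#'       S_W = \sum_i \sum_{k \in i} (x_k - \bar x_i)(x_k - \bar x_i)^T,}
#' where \eqn{\bar x_i} is the mean of class `i` (with `n_i` samples) and
#' \eqn{\bar x} the global mean. They satisfy `S_B + S_W = S_T`, the total
#' scatter about the global mean.
#'
#' @param table a [feature_table()]; every class needs at least 2 samples.
#' @return A [scatter_pair()] with `B = S_B`, `T_or_W = S_W`,
#'   `kind = "classical"`.
#' @export
classical_scatter <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cnt <- table(table$labels)
  if (any(cnt < 2L))
    stop("every class needs >= 2 samples for the within-class scatter; ",
         "offending: ", paste(names(cnt)[cnt < 2], collapse = ", "))
  X <- table$X
  d <- ncol(X)
  gmean <- colMeans(X)
  SB <- matrix(0, d, d)
  SW <- matrix(0, d, d)
  for (cl in levels(table$labels)) {
    Xi <- X[table$labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    dv <- mi - gmean
    SB <- SB + nrow(Xi) * tcrossprod(dv)
    Ci <- sweep(Xi, 2, mi)
    SW <- SW + crossprod(Ci)
  }
  scatter_pair(SB, SW, "classical")
}

#' Fuzzy between-class and fuzzy total scatter matrices
#'
#' The membership-weighted scatters driving FDPCA:
#' \deqn{S_{fB} = \sum_i \sum_k u_{ik}^{m_f} (v_i - \bar x)(v_i - \bar x)^T,
#'       \qquad
#'       S_{fT} = \sum_i \sum_k u_{ik}^{m_f} (x_k - \bar x)(x_k - \bar x)^T,}
#' with \eqn{\bar x} the plain mean of all samples and `v_i` the fuzzy
#' cluster centers. The inner sum over `k` in \eqn{S_{fB}} collapses to the
#' class weight \eqn{w_i = \sum_k u_{ik}^{m_f}} times one rank-1 term. With
#' crisp memberships \eqn{S_{fB}} equals the classical \eqn{S_B} and
#' \eqn{S_{fT}} equals the classical total scatter \eqn{S_B + S_W}.
#'
#' @param table a [feature_table()].
#' @param U a [membership_matrix()] over the same samples.
#' @param centers a `center_set` from [cluster_centers()] consistent with `U`.
#' @return A [scatter_pair()] with `B = S_fB`, `T_or_W = S_fT`,
#'   `kind = "fuzzy"`.
#' @export
fuzzy_scatter <- function(table, U, centers) {
  stopifnot(inherits(table, "feature_table"),
            inherits(U, "membership_matrix"),
            inherits(centers, "center_set"))
  X <- table$X
  n <- nrow(X); d <- ncol(X)
  if (ncol(U$U) != n)
    stop("membership matrix and feature table disagree on sample count")
  if (!identical(dim(centers$V), c(nrow(U$U), d)))
    stop("center set dimensions do not match memberships and features")
  if (!identical(centers$class_order, U$class_order))
    stop("center set and membership matrix disagree on class order")
  W <- U$U ^ U$m_f
  xbar <- colMeans(X)
  wi <- rowSums(W)                       # class weights sum_k u_ik^mf
  Vc <- sweep(centers$V, 2, xbar)        # c x d centered centers
  SfB <- crossprod(Vc * sqrt(wi), Vc * sqrt(wi))
  wk <- colSums(W)                       # per-sample weights sum_i u_ik^mf
  Xc <- sweep(X, 2, xbar)
  SfT <- crossprod(Xc * sqrt(wk), Xc * sqrt(wk))
  scatter_pair(SfB, SfT, "fuzzy")
}
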