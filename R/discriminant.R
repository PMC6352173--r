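#' Construct a discriminant basis
#'
#' An ordered set of `p` unit-norm, mutually orthogonal direction vectors in
#' feature space, with the eigenvalue attained by each and the training mean
#' used for centering at projection time. Produced by [pca_fit()],
#' [dpca_fit()] or [fdpca_fit()].
#'
#' @param vectors `d x p` matrix, columns unit norm.
#' @param eigenvalues numeric vector of length `p`.
#' @param method one of `"PCA"`, `"DPCA"`, `"FDPCA"`.
#' @param center length-`d` training mean.
#' @param contribution_rates percentage of total variance per component
#'   (PCA only; `NULL` otherwise).
#' @param feature_names optional names of the `d` input features.
#' @param m_f weight exponent used (FDPCA only; `NA` otherwise).
#' @return An object of class `discriminant_basis`.
#' @export
discriminant_basis <- function(vectors, eigenvalues,
                               method = c("PCA", "DPCA", "FDPCA"),
                               center, contribution_rates = NULL,
                               feature_names = NULL, m_f = NA_real_) {
  method <- match.arg(method)
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  p <- ncol(vectors)
  if (length(eigenvalues) != p)
    stop("need one eigenvalue per basis vector")
  if (length(center) != nrow(vectors))
    stop("`center` must have one entry per feature")
  nrm <- sqrt(colSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("basis vectors must have unit Euclidean norm")
  G <- crossprod(vectors)
  if (max(abs(G - diag(p))) > 1e-8)
    stop("basis vectors must be mutually orthogonal")
  if (any(!is.finite(eigenvalues)) || any(eigenvalues < -1e-8))
    stop("eigenvalues must be finite and nonnegative (within tolerance)")
  structure(
    list(vectors = vectors, eigenvalues = as.numeric(eigenvalues),
         method = method, center = as.numeric(center),
         contribution_rates = contribution_rates,
         feature_names = feature_names, m_f = m_f),
    class = "discriminant_basis"
  )
}

#' @export
print.discriminant_basis <- function(x, ...) {
  cat(sprintf("discriminant_basis: %s, %d x %d\n", x$method,
              nrow(x$vectors), ncol(x$vectors)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 5), "\n")
  if (!is.null(x$contribution_rates))
    cat("contribution rates (%):",
        format(x$contribution_rates, digits = 4), "\n")
  invisible(x)
}

# Unit norm with the largest-magnitude component positive: deterministic
# representative of the +/- eigenvector ambiguity.
fix_sign <- function(v) {
  v <- v / sqrt(sum(v^2))
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}

# Ridge-regularized copy of the denominator scatter: T + eps * tr(T)/d * I
# (plain eps * I if T has zero trace). Guards inversion on rank-deficient
# synthetic edge cases; negligible at eps = 1e-8 on well-conditioned data.
ridge_T <- function(T_or_W, ridge) {
  d <- nrow(T_or_W)
  sc <- sum(diag(T_or_W)) / d
  if (sc <= 0) sc <- 1
  T_or_W + ridge * sc * diag(d)
}

#' Principal component basis
#'
#' Eigendecomposition of the sample covariance of a feature table: the top
#' `p` eigenvectors ordered by decreasing variance, with each component's
#' contribution rate (its eigenvalue as a percentage of the eigenvalue
#' total). Used both as the pipeline's compression step and as the baseline
#' feature extractor.
#'
#' @param table a [feature_table()].
#' @param p number of components, at most the rank of the centered data.
#' @return A [discriminant_basis()] with `method = "PCA"`.
#' @export
#' @examples
#' ft <- feature_table(cbind(x = rnorm(50), y = rnorm(50)), rep("a", 50))
#' pca_fit(ft, 2)$contribution_rates
pca_fit <- function(table, p) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$X
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  CV <- crossprod(Xc) / (nrow(X) - 1)
  es <- eigen(CV, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  rank <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-12)
  if (p < 1 || p > rank)
    stop(sprintf("p = %d exceeds the covariance rank; at most %d components available",
                 p, rank))
  vecs <- apply(es$vectors[, seq_len(p), drop = FALSE], 2, fix_sign)
  vecs <- matrix(vecs, nrow = nrow(es$vectors))
  rates <- 100 * ev / sum(ev)
  discriminant_basis(vecs, ev[seq_len(p)], "PCA", ctr,
                     contribution_rates = rates[seq_len(p)],
                     feature_names = table$feature_names)
}

#' Leading generalized discriminant vector
#'
#' Solves the generalized eigenproblem `T^{-1} B psi = lambda psi` for its
#' dominant eigenpair, where `(B, T)` is a [scatter_pair()] (classical
#' `S_W^{-1} S_B` or fuzzy `S_fT^{-1} S_fB`). Both matrices are symmetric
#' PSD, so the pencil is solved stably by Cholesky whitening of the
#' (ridge-regularized) denominator: with `T = R'R`, the symmetric matrix
#' `R^{-T} B R^{-1}` shares eigenvalues with `T^{-1} B` and its eigenvectors
#' map back via `R^{-1}`. The returned vector has unit Euclidean norm with
#' the deterministic sign convention (largest-magnitude component positive).
#' If `B` vanishes the eigenvalue is 0 and the first standard basis vector is
#' returned.
#'
#' @param pair a [scatter_pair()].
#' @param ridge relative ridge added to the denominator before inversion
#'   (default `1e-8`).
#' @return List with `vector` (unit norm, length `d`) and `value`
#'   (the maximal eigenvalue, `>= 0`).
#' @export
leading_vector <- function(pair, ridge = 1e-8) {
  stopifnot(inherits(pair, "scatter_pair"))
  B <- pair$B
  d <- nrow(B)
  if (max(abs(B)) < .Machine$double.eps * 100) {
    e1 <- c(1, rep(0, d - 1L))
    return(list(vector = e1, value = 0))
  }
  Tr <- ridge_T(pair$T_or_W, ridge)
  R <- chol(Tr)
  Ri <- backsolve(R, diag(d))
  C <- crossprod(Ri, B %*% Ri)
  C <- (C + t(C)) / 2
  es <- eigen(C, symmetric = TRUE)
  lambda <- max(es$values[1], 0)
  psi <- fix_sign(as.numeric(Ri %*% es$vectors[, 1]))
  list(vector = psi, value = lambda)
}

#' Next discriminant vector by deflation
#'
#' Given `r` already-extracted discriminant vectors `Psi`, computes the
#' `r+1`-th as the dominant eigenvector of the deflated operator
#' \deqn{M\, T^{-1} B, \qquad M = I - T^{-1}\Psi N^{-1}\Psi^T, \qquad
#'       N = \Psi^T T^{-1} \Psi.}
#' Because \eqn{\Psi^T M = 0}, every vector in the range of the deflated
#' operator — in particular its eigenvectors with nonzero eigenvalue — is
#' Euclidean-orthogonal to all previous vectors, so the construction yields
#' an orthogonal set that maximizes the scatter-ratio Rayleigh quotient on
#' the orthogonal complement at each step. The same operator with the fuzzy
#' pair `(S_fB, S_fT)` (there usually written `P` and `Q`) yields the fuzzy
#' discriminant vectors.
#'
#' The dense eigendecomposition of the (non-symmetric) deflated operator is
#' taken and the eigenvalue of largest real part selected; theory promises a
#' real spectrum, so a material imaginary part is an error. When the
#' deflated spectrum has collapsed to (numerically) zero — the discriminant
#' directions are exhausted — a deterministic unit vector in the orthogonal
#' complement of `Psi` is returned with eigenvalue 0.
#'
#' @param pair a [scatter_pair()].
#' @param previous a [discriminant_basis()] holding the `r >= 1` vectors
#'   found so far (`r + 1 <= d`).
#' @param ridge relative ridge for the denominator inversion (default `1e-8`).
#' @return List with `vector` (unit norm, orthogonal to all previous) and
#'   `value` (its eigenvalue under the deflated operator).
#' @export
deflate_and_next <- function(pair, previous, ridge = 1e-8) {
  stopifnot(inherits(pair, "scatter_pair"),
            inherits(previous, "discriminant_basis"))
  Psi <- previous$vectors
  d <- nrow(Psi); r <- ncol(Psi)
  if (r < 1L) stop("`previous` must contain at least one vector")
  if (r + 1L > d) stop("no further directions available (r + 1 > d)")
  Tr <- ridge_T(pair$T_or_W, ridge)
  Tinv <- chol2inv(chol(Tr))
  TiPsi <- Tinv %*% Psi
  N <- crossprod(Psi, TiPsi)
  Ninv <- tryCatch(solve(N), error = function(e)
    stop("deflation metric N = Psi' T^{-1} Psi is numerically singular: ",
         "previous vectors are nearly dependent under the scatter metric"))
  M <- diag(d) - TiPsi %*% Ninv %*% t(Psi)
  A <- M %*% (Tinv %*% pair$B)
  ee <- eigen(A)
  i <- which.max(Re(ee$values))
  lam <- ee$values[i]
  if (abs(Im(lam)) > 1e-6 * (1 + abs(Re(lam))))
    stop("deflated operator returned a materially complex dominant eigenvalue")
  value <- max(Re(lam), 0)
  psi <- Re(ee$vectors[, i])
  # enforce the exact-orthogonality identity Psi' M = 0 against roundoff
  psi <- psi - Psi %*% crossprod(Psi, psi)
  nr <- sqrt(sum(psi^2))
  if (value <= 1e-10 || nr < 1e-8) {
    # spectrum exhausted: deterministic complement direction
    resid <- diag(d) - tcrossprod(Psi)
    norms <- sqrt(colSums(resid^2))
    j <- which.max(norms > 0.5)  # first well-conditioned standard direction
    if (norms[j] <= 0.5) j <- which.max(norms)
    psi <- resid[, j]
    value <- 0
  }
  list(vector = fix_sign(as.numeric(psi)), value = value)
}

# Shared driver: leading vector + p-1 deflation steps on a scatter pair.
extract_discriminant_set <- function(pair, p, ridge, method, center,
                                     feature_names, m_f = NA_real_) {
  d <- nrow(pair$B)
  if (p < 1 || p > d)
    stop(sprintf("p must lie in 1..%d (got %d)", d, p))
  first <- leading_vector(pair, ridge)
  vectors <- matrix(first$vector, d, 1)
  values <- first$value
  while (ncol(vectors) < p) {
    basis_so_far <- discriminant_basis(vectors, values, method, center,
                                       feature_names = feature_names,
                                       m_f = m_f)
    nxt <- deflate_and_next(pair, basis_so_far, ridge)
    vectors <- cbind(vectors, nxt$vector)
    values <- c(values, nxt$value)
  }
  if (p > 1 && any(values[-1] <= 1e-10) || values[1] <= 1e-10)
    warning("requested more discriminant vectors than the between-class ",
            "scatter supports; trailing eigenvalues are ~0")
  discriminant_basis(vectors, values, method, center,
                     feature_names = feature_names, m_f = m_f)
}

#' Discriminant principal component analysis (DPCA)
#'
#' Extracts `p` optimal discriminant vectors from labelled data: the first
#' maximizes the Fisher ratio `psi' S_B psi / psi' S_W psi`; each subsequent
#' vector maximizes the same ratio subject to Euclidean orthogonality to all
#' previous ones, computed through the deflation operator of
#' [deflate_and_next()].
#'
#' @param table a [feature_table()] (every class needs >= 2 samples).
#' @param p number of discriminant vectors (default 5).
#' @param ridge denominator ridge (default `1e-8`).
#' @return A [discriminant_basis()] with `method = "DPCA"`.
#' @export
dpca_fit <- function(table, p = 5, ridge = 1e-8) {
  stopifnot(inherits(table, "feature_table"))
  pair <- classical_scatter(table)
  extract_discriminant_set(pair, p, ridge, "DPCA", colMeans(table$X),
                           table$feature_names)
}

#' Fuzzy discriminant principal component analysis (FDPCA)
#'
#' The fuzzy extension of [dpca_fit()]: class structure enters through fuzzy
#' KNN memberships rather than hard labels. Fuzzy cluster centers and the
#' fuzzy between-class / total scatter pair are formed with membership
#' weights `u_ik^m_f`, and `p` mutually orthogonal fuzzy optimal discriminant
#' vectors are extracted by the same leading-eigenvector-plus-deflation
#' scheme, now on `S_fT^{-1} S_fB`. In overlap regions a sample's weight is
#' shared across the classes crowding it, which softens the scatter
#' estimates and improves class separation downstream.
#'
#' @param table a [feature_table()].
#' @param U optional [membership_matrix()]; computed by
#'   [fuzzy_knn_memberships()] with `K` and `m_f` when omitted.
#' @param p number of discriminant vectors (default 5).
#' @param m_f membership weight exponent (default 2).
#' @param K neighbour count for membership estimation (default 7).
#' @param ridge denominator ridge (default `1e-8`).
#' @return A [discriminant_basis()] with `method = "FDPCA"`.
#' @export
fdpca_fit <- function(table, U = NULL, p = 5, m_f = 2, K = 7, ridge = 1e-8) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(U)) U <- fuzzy_knn_memberships(table, K = K, m_f = m_f)
  centers <- cluster_centers(table, U)
  pair <- fuzzy_scatter(table, U, centers)
  extract_discriminant_set(pair, p, ridge, "FDPCA", colMeans(table$X),
                           table$feature_names, m_f = U$m_f)
}

#' Project a feature table onto a discriminant basis
#'
#' Centers the data with the training mean stored in the basis and projects:
#' `Y = (X - x_bar_train) V`. Using the stored mean (not the mean of the
#' table being projected) keeps train/test geometry consistent.
#'
#' @param table a [feature_table()] with the same features as the basis.
#' @param basis a [discriminant_basis()].
#' @return An object of class `projected_table`: list with `Y` (`n x p`),
#'   `labels`, `sample_ids`, `method`.
#' @export
project <- function(table, basis) {
  stopifnot(inherits(table, "feature_table"),
            inherits(basis, "discriminant_basis"))
  if (ncol(table$X) != nrow(basis$vectors))
    stop("feature dimension of `table` does not match the basis")
  Y <- sweep(table$X, 2, basis$center) %*% basis$vectors
  colnames(Y) <- paste0("F", seq_len(ncol(Y)))
  structure(list(Y = Y, labels = table$labels,
                 sample_ids = table$sample_ids, method = basis$method),
            class = "projected_table")
}

#' @export
print.projected_table <- function(x, ...) {
  cat(sprintf("projected_table (%s): %d samples x %d features\n",
              x$method, nrow(x$Y), ncol(x$Y)))
  invisible(x)
}

#' Write a discriminant basis to CSV
#'
#' Header comment lines carry the method, eigenvalues, `m_f` and training
#' mean at 17 significant digits; the body is the `d x p` vector matrix.
#' [read_basis()] restores the object exactly to that printed precision.
#'
#' @param basis a [discriminant_basis()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "discriminant_basis"))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# method=", basis$method),
    paste0("# eigenvalues=", fmt(basis$eigenvalues)),
    paste0("# m_f=", sprintf("%.17g", basis$m_f)),
    paste0("# center=", fmt(basis$center)),
    if (!is.null(basis$contribution_rates))
      paste0("# contribution_rates=", fmt(basis$contribution_rates))
  ), con)
  df <- data.frame(feature = basis$feature_names %||%
                     paste0("S", seq_len(nrow(basis$vectors))),
                   apply(basis$vectors, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE)
  names(df) <- c("feature", paste0("psi_", seq_len(ncol(basis$vectors))))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a discriminant basis written by [write_basis()]
#'
#' @param path CSV file path.
#' @return A [discriminant_basis()].
#' @export
read_basis <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(ln) == 0L) return(NULL)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  nums <- function(s) if (is.null(s)) NULL else
    suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "# ")]),
                        check.names = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(V) <- "double"
  discriminant_basis(V, nums(get("eigenvalues")), get("method"),
                     nums(get("center")),
                     contribution_rates = nums(get("contribution_rates")),
                     feature_names = df[[1]], m_f = nums(get("m_f")))
}
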