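# Shared fixtures and independent oracles for the test suite.

# Two 2-D classes of four points each: within-class scatter 4*I, between-class
# scatter diag(0, 32); leading Fisher eigenpair (lambda, psi) = (8, (0,1)).
toy2d_table <- function() {
  X <- rbind(c(0, 0), c(2, 0), c(1, 1), c(1, -1),
             c(0, 4), c(2, 4), c(1, 5), c(1, 3))
  feature_table(X, rep(c("a", "b"), each = 4))
}

# One sample per class at x = 0 and x = 2: crisp fuzzy scatters S_fB = S_fT = 2.
fuzzy1d_table <- function() feature_table(matrix(c(0, 2)), c(1, 2))

# Random Gaussian class clusters for property tests.
random_gauss_table <- function(n_classes, d, per_class = 12, mean_sd = 3,
                               seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(n_classes * d, sd = mean_sd), n_classes, d)
  X <- mu[rep(seq_len(n_classes), each = per_class), , drop = FALSE] +
    matrix(rnorm(n_classes * per_class * d), n_classes * per_class, d)
  feature_table(X, rep(seq_len(n_classes), each = per_class))
}

# Principal angles (radians) between the column spans of two orthonormal bases.
principal_angles <- function(A, B) {
  acos(pmin(pmax(svd(crossprod(A, B))$d, -1), 1))
}

# Independent random-search oracle for the constrained generalized Rayleigh
# quotient max psi' B psi / psi' T psi over unit vectors orthogonal to Psi.
rayleigh_oracle <- function(B, T_or_W, Psi = NULL, nsamp = 1e5) {
  d <- nrow(B)
  Z <- matrix(rnorm(nsamp * d), nsamp, d)
  if (!is.null(Psi)) Z <- Z - (Z %*% Psi) %*% t(Psi)
  keep <- rowSums(Z^2) > 1e-12
  Z <- Z[keep, , drop = FALSE]
  max(rowSums((Z %*% B) * Z) / rowSums((Z %*% T_or_W) * Z))
}

rayleigh_quotient <- function(psi, B, T_or_W) {
  c(crossprod(psi, B %*% psi)) / c(crossprod(psi, T_or_W %*% psi))
}
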