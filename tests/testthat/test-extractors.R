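test_that("classical scatters match the hand-computed 2-D fixture", {
  sp <- classical_scatter(toy2d_table())
  expect_equal(unname(sp$T_or_W), diag(c(4, 4)))
  expect_equal(unname(sp$B), rbind(c(0, 0), c(0, 32)))
})

test_that("classical scatters decompose the total scatter", {
  ft <- random_gauss_table(4, 6, per_class = 9, seed = 13)
  sp <- classical_scatter(ft)
  Xc <- sweep(ft$X, 2, colMeans(ft$X))
  expect_equal(sp$B + sp$T_or_W, crossprod(Xc), tolerance = 1e-10,
               ignore_attr = TRUE)
  # identical samples give zero scatters
  same <- feature_table(matrix(2, 4, 3), rep(c("a", "b"), each = 2))
  sp0 <- classical_scatter(same)
  expect_equal(max(abs(sp0$B)), 0)
  expect_equal(max(abs(sp0$T_or_W)), 0)
  # singleton classes are rejected
  expect_error(classical_scatter(feature_table(matrix(1:3), c(1, 1, 2))),
               ">= 2 samples")
})

test_that("fuzzy scatters reproduce the 1-D fixture and the crisp reduction", {
  ft <- fuzzy1d_table()
  U <- crisp_memberships(ft$labels)
  fs <- fuzzy_scatter(ft, U, cluster_centers(ft, U))
  expect_equal(fs$B[1, 1], 2)
  expect_equal(fs$T_or_W[1, 1], 2)

  # crisp memberships: S_fB == S_B and S_fT == S_B + S_W exactly
  toy <- toy2d_table()
  Ut <- crisp_memberships(toy$labels, m_f = 3.7)
  ff <- fuzzy_scatter(toy, Ut, cluster_centers(toy, Ut))
  cs <- classical_scatter(toy)
  expect_equal(ff$B, cs$B, tolerance = 1e-12)
  expect_equal(ff$T_or_W, cs$B + cs$T_or_W, tolerance = 1e-12)

  # identical samples -> zero fuzzy scatters
  same <- feature_table(matrix(5, 6, 2), rep(c("a", "b", "c"), 2))
  Us <- fuzzy_knn_memberships(same, K = 2)
  f0 <- fuzzy_scatter(same, Us, cluster_centers(same, Us))
  expect_equal(max(abs(f0$B)), 0)
  expect_equal(max(abs(f0$T_or_W)), 0)

  # dimension mismatch is rejected
  expect_error(fuzzy_scatter(toy, U, cluster_centers(ft, U)),
               "sample count")
})

test_that("PCA basis, contribution rates and rank guard behave", {
  # four points whose sample covariance is exactly isotropic
  iso <- feature_table(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                       rep("a", 4))
  expect_equal(pca_fit(iso, 2)$contribution_rates, c(50, 50))

  # noiseless line y = 2x: one component carries everything
  line <- feature_table(cbind(x = -3:3, y = 2 * (-3:3)), rep("a", 7))
  b <- pca_fit(line, 1)
  expect_equal(b$contribution_rates[1], 100)
  expect_equal(abs(b$vectors[, 1]), c(1, 2) / sqrt(5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(pca_fit(line, 2), "at most 1")

  ft <- random_gauss_table(3, 5, per_class = 10, seed = 2)
  rates <- pca_fit(ft, 5)$contribution_rates
  expect_equal(sum(rates), 100, tolerance = 1e-10)
  expect_true(all(diff(pca_fit(ft, 5)$eigenvalues) <= 1e-12))
})

test_that("leading generalized eigenvector matches the hand fixtures", {
  lv <- leading_vector(classical_scatter(toy2d_table()), ridge = 0)
  expect_equal(lv$value, 8, tolerance = 1e-12)
  expect_equal(lv$vector, c(0, 1), tolerance = 1e-12)

  ft <- fuzzy1d_table()
  U <- crisp_memberships(ft$labels)
  expect_equal(leading_vector(fuzzy_scatter(ft, U, cluster_centers(ft, U)),
                              ridge = 0)$value, 1, tolerance = 1e-12)

  # vanishing between-class scatter: eigenvalue 0, first basis vector
  zero <- scatter_pair(matrix(0, 3, 3), diag(3), "classical")
  expect_equal(leading_vector(zero), list(vector = c(1, 0, 0), value = 0))
})

test_that("deflation produces the forced orthogonal complement on the toy", {
  sp <- classical_scatter(toy2d_table())
  first <- leading_vector(sp, ridge = 0)
  basis1 <- discriminant_basis(matrix(first$vector), first$value, "DPCA",
                               center = c(1, 2))
  nxt <- deflate_and_next(sp, basis1, ridge = 0)
  expect_equal(nxt$vector, c(1, 0), tolerance = 1e-12)
  expect_equal(nxt$value, 0)
})

test_that("deflated operator annihilates the previous vectors", {
  ft <- random_gauss_table(4, 6, per_class = 10, seed = 31)
  sp <- classical_scatter(ft)
  b <- dpca_fit(ft, 3, ridge = 0)
  Psi <- b$vectors[, 1:2]
  Tinv <- solve(sp$T_or_W)
  N <- crossprod(Psi, Tinv %*% Psi)
  M <- diag(6) - Tinv %*% Psi %*% solve(N) %*% t(Psi)
  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(6)
    expect_lt(max(abs(crossprod(Psi, M %*% v))), 1e-10 * sqrt(sum(v^2)))
  }
})

test_that("deflation attains the constrained Rayleigh maximum (small oracle)", {
  set.seed(44)
  for (i in 1:4) {
    c_ <- sample(3:5, 1); d <- sample(4:6, 1)
    ft <- random_gauss_table(c_, d, per_class = 9, mean_sd = 2,
                             seed = 300 + i)
    sp <- classical_scatter(ft)
    p <- min(c_ - 1, 3)
    b <- dpca_fit(ft, p, ridge = 0)
    for (r in seq_len(p)) {
      attained <- rayleigh_quotient(b$vectors[, r], sp$B, sp$T_or_W)
      Psi <- if (r > 1) b$vectors[, seq_len(r - 1), drop = FALSE] else NULL
      expect_gte(attained, rayleigh_oracle(sp$B, sp$T_or_W, Psi,
                                           nsamp = 2e4) * (1 - 1e-6))
    }
  }
})

test_that("DPCA and FDPCA bases are orthonormal with ordered structure", {
  ft <- random_gauss_table(5, 7, per_class = 10, seed = 17)
  for (b in list(dpca_fit(ft, 4), fdpca_fit(ft, p = 4, K = 5))) {
    G <- crossprod(b$vectors)
    expect_lt(max(abs(G - diag(4))), 1e-8)
    expect_true(all(b$eigenvalues >= 0))
  }
  # p = d on full-rank data: complete orthogonal set
  bfull <- suppressWarnings(dpca_fit(ft, 7))
  expect_lt(max(abs(crossprod(bfull$vectors) - diag(7))), 1e-8)
})

test_that("FDPCA with crisp memberships aligns with DPCA", {
  ft <- random_gauss_table(4, 6, per_class = 12, seed = 23)
  p <- 3
  bd <- dpca_fit(ft, p)
  bf <- fdpca_fit(ft, U = crisp_memberships(ft$labels), p = p)
  # first directions collinear
  expect_gt(abs(sum(bd$vectors[, 1] * bf$vectors[, 1])), 1 - 1e-8)
  # same spanned subspace
  expect_lt(max(principal_angles(bd$vectors, bf$vectors)), 1e-6)
  # eigenvalues related by lambda / (1 + lambda)
  expect_equal(bf$eigenvalues, bd$eigenvalues / (1 + bd$eigenvalues),
               tolerance = 1e-6)
})

test_that("two identical classes yield a vanishing leading eigenvalue", {
  X <- matrix(rnorm(40), 20, 2)
  ft <- feature_table(rbind(X, X), rep(c("a", "b"), each = 20))
  b <- suppressWarnings(dpca_fit(ft, 1))
  expect_lt(b$eigenvalues[1], 1e-8)
})

test_that("bases are invariant to a constant shift of all samples", {
  ft <- random_gauss_table(3, 5, per_class = 10, seed = 51)
  shift <- feature_table(sweep(ft$X, 2, rnorm(5) * 10, "+"), ft$labels)
  expect_equal(dpca_fit(ft, 2)$vectors, dpca_fit(shift, 2)$vectors,
               tolerance = 1e-7)
  Uc <- fuzzy_knn_memberships(ft, K = 5)
  Us <- fuzzy_knn_memberships(shift, K = 5)
  expect_equal(fdpca_fit(ft, U = Uc, p = 2)$vectors,
               fdpca_fit(shift, U = Us, p = 2)$vectors, tolerance = 1e-7)
})

test_that("projection centers on the training mean", {
  toy <- toy2d_table()
  b <- suppressWarnings(dpca_fit(toy, 2))
  # the training mean projects to the origin
  mean_tab <- feature_table(matrix(colMeans(toy$X), 1), "a",
                            feature_names = toy$feature_names)
  expect_equal(max(abs(project(mean_tab, b)$Y)), 0, tolerance = 1e-12)
  # psi_1 = (0, 1): class means project to -2 and +2
  pr <- project(toy, b)
  expect_equal(mean(pr$Y[toy$labels == "a", 1]), -2, tolerance = 1e-12)
  expect_equal(mean(pr$Y[toy$labels == "b", 1]), 2, tolerance = 1e-12)
  # identity basis returns the centered data
  idb <- discriminant_basis(diag(2), c(0, 0), "PCA", colMeans(toy$X))
  expect_equal(project(toy, idb)$Y, sweep(toy$X, 2, colMeans(toy$X)),
               ignore_attr = TRUE)
  expect_error(project(fuzzy1d_table(), b), "dimension")
})

test_that("basis CSV round-trip is exact", {
  ft <- random_gauss_table(4, 5, per_class = 8, seed = 77)
  for (b in list(pca_fit(ft, 3), fdpca_fit(ft, p = 3, K = 5))) {
    path <- tempfile(fileext = ".csv")
    write_basis(b, path)
    back <- read_basis(path)
    expect_equal(back$vectors, b$vectors, tolerance = 0, ignore_attr = TRUE)
    expect_identical(back$eigenvalues, b$eigenvalues)
    expect_identical(back$center, b$center)
    expect_identical(back$method, b$method)
    if (!is.null(b$contribution_rates))
      expect_identical(back$contribution_rates, b$contribution_rates)
  }
})
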