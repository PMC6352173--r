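proj_of <- function(X, labels) {
  structure(list(Y = as.matrix(X), labels = factor(labels)),
            class = "projected_table")
}

test_that("KNN votes follow the hand-checked examples", {
  # k = 1 on a training point returns that point's label
  tr <- proj_of(matrix(c(0, 1, 10, 11)), c("A", "A", "B", "B"))
  expect_equal(as.character(knn_classify(tr, matrix(10), 1)), "B")
  # 1-D vote: neighbours of 0.5 at k = 3 are {0, 1, 10} -> two A, one B
  expect_equal(as.character(knn_classify(tr, matrix(0.5), 3)), "A")
  expect_error(knn_classify(tr, matrix(0.5), 5), "exceeds training size")
  expect_error(knn_classify(structure(list(Y = matrix(0, 0, 1),
                                           labels = factor(character())),
                                      class = "projected_table"),
                            matrix(1), 1), "empty")
})

test_that("KNN tie-breaks are deterministic", {
  # k = n with balanced classes: vote ties; B's neighbours are closer
  tr <- proj_of(matrix(c(0, 1, 2.1, 3.1)), c("A", "A", "B", "B"))
  expect_equal(as.character(knn_classify(tr, matrix(2.05), 4)), "B")
  # exact mirror symmetry: inverse distances tie too -> lowest class index
  tr2 <- proj_of(matrix(c(-1, 1)), c("A", "B"))
  expect_equal(as.character(knn_classify(tr2, matrix(0), 2)), "A")
  # rerun identical
  expect_identical(knn_classify(tr, matrix(c(2.05, 0.2)), 4),
                   knn_classify(tr, matrix(c(2.05, 0.2)), 4))
})

test_that("LOO reaches 100% on well-separated classes for every extractor", {
  tab <- generate_features(synthetic_config(n_classes = 3, per_class = 10,
                                            d = 5, delta = 0, seed = 12))
  for (m in c("PCA", "DPCA", "FDPCA")) {
    cfg <- pipeline_config(m, p = 2, seed = 1)
    expect_equal(loo_validate(tab, cfg)$accuracy, 100)
  }
})

test_that("identical copies per class classify perfectly with k = 1", {
  X <- matrix(rep(c(0, 5, 9), each = 4), ncol = 1)
  tab <- feature_table(X, rep(c("a", "b", "c"), each = 4))
  cfg <- pipeline_config("DPCA", p = 1, knn_k = 1, seed = 1)
  expect_equal(loo_validate(tab, cfg)$accuracy, 100)
})

test_that("LOO guards its preconditions", {
  tiny <- feature_table(matrix(1:3), c("a", "b", "c"))
  expect_error(loo_validate(tiny, pipeline_config("DPCA")), "c \\+ 1")
  # holding out the only sample of class b empties that class in the fold
  solo <- feature_table(matrix(c(1, 2, 3, 7)), c("a", "a", "a", "b"))
  expect_error(loo_validate(solo, pipeline_config("PCA", p = 1, knn_k = 1)),
               "fold 4")
})

test_that("k-fold validation is reproducible and degenerates to LOO at folds = n", {
  tab <- generate_features(synthetic_config(n_classes = 3, per_class = 8,
                                            d = 4, delta = 0.9, sigma = 2,
                                            seed = 5))
  cfg <- pipeline_config("FDPCA", p = 2, seed = 42)
  a1 <- kfold_validate(tab, cfg, folds = 4, repeats = 3)
  a2 <- kfold_validate(tab, cfg, folds = 4, repeats = 3)
  expect_identical(a1, a2)
  expect_true(a1 >= 0 && a1 <= 100)
  # folds = n is the LOO partition; the pipeline is deterministic
  expect_equal(kfold_validate(tab, cfg, folds = nrow(tab$X), repeats = 2),
               loo_validate(tab, cfg)$accuracy)
  expect_error(kfold_validate(tab, cfg, folds = 10), "fewer than")
})

test_that("fold models never see held-out samples", {
  tab <- generate_features(synthetic_config(n_classes = 3, per_class = 10,
                                            d = 5, seed = 31))
  cfg <- pipeline_config("FDPCA", p = 2, seed = 1)
  heldout <- c(3, 14, 27)
  model <- fdpca:::fit_pipeline(ft_subset(tab, -heldout,
                                          drop_levels = FALSE), cfg)
  # corrupt the held-out rows wildly; the fold model must be bit-identical
  X2 <- tab$X
  X2[heldout, ] <- 1e6
  tab2 <- feature_table(X2, tab$labels, sample_ids = tab$sample_ids)
  model2 <- fdpca:::fit_pipeline(ft_subset(tab2, -heldout,
                                           drop_levels = FALSE), cfg)
  expect_identical(model$basis$vectors, model2$basis$vectors)
  expect_identical(model$normalizer, model2$normalizer)
  expect_identical(model$compression$vectors, model2$compression$vectors)
  expect_identical(model$train_proj$Y, model2$train_proj$Y)
})

test_that("cv_report averages its schemes and compare_extractors is paired", {
  tab <- generate_features(synthetic_config(n_classes = 3, per_class = 10,
                                            d = 5, delta = 0.8, sigma = 2,
                                            seed = 77))
  cfg <- pipeline_config("DPCA", p = 2, seed = 9)
  rep1 <- cv_report(tab, cfg, folds = c(2, 5), repeats = 2)
  expect_equal(rep1$average, mean(rep1$scheme))
  expect_equal(names(rep1$scheme), c("LOO", "2-fold", "5-fold"))
  expect_true(all(rep1$scheme >= 0 & rep1$scheme <= 100))

  cmp <- compare_extractors(tab, cfg, folds = 5, repeats = 2)
  expect_named(cmp, c("PCA", "DPCA", "FDPCA"))
  # paired design: the DPCA row of the comparison equals a standalone run
  solo <- cv_report(tab, cfg, folds = 5, repeats = 2)
  expect_identical(cmp$DPCA$scheme, solo$scheme)
  # identical config + seed -> identical reports on rerun
  cmp2 <- compare_extractors(tab, cfg, folds = 5, repeats = 2)
  expect_identical(lapply(cmp, `[[`, "scheme"), lapply(cmp2, `[[`, "scheme"))
})

test_that("reports serialize to stable JSON", {
  tab <- generate_features(synthetic_config(n_classes = 3, per_class = 8,
                                            d = 4, seed = 2))
  cfg <- pipeline_config("PCA", p = 2, seed = 3)
  r <- cv_report(tab, cfg, folds = 4, repeats = 2)
  j1 <- report_to_json(r)
  j2 <- report_to_json(cv_report(tab, cfg, folds = 4, repeats = 2))
  expect_identical(as.character(j1), as.character(j2))
  path <- tempfile(fileext = ".json")
  report_to_json(r, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$average_validation_accuracy_percent, r$average)
})
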