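# Run code with a private RNG stream: the global .Random.seed is saved and
# restored, so package functions never disturb user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the classification pipeline: which feature
#' extractor to use, how many features it keeps, the KNN classifier's
#' neighbour count, the fuzzy-membership parameters, the PCA compression
#' level, and numerical/reproducibility knobs.
#'
#' @param extractor `"PCA"`, `"DPCA"` or `"FDPCA"`.
#' @param p number of extracted features (default 5).
#' @param knn_k classifier neighbour count (default 7).
#' @param membership_K neighbour count for fuzzy-KNN memberships (default 7).
#' @param m_f membership weight exponent, > 1 (default 2).
#' @param pca_compress compression before extraction: a fraction in (0, 1\]
#'   keeps the fewest leading components whose cumulative contribution rate
#'   reaches that fraction (default 0.9999); an integer >= 1 keeps exactly
#'   that many components.
#' @param normalize min-max normalize features, fitted on the training
#'   partition (default `TRUE`).
#' @param ridge denominator ridge for the scatter inversions (default `1e-8`).
#' @param seed base seed for fold shuffling (default 1).
#' @param global_memberships compute fuzzy memberships once on the full table
#'   instead of per training fold (default `FALSE`; per-fold is leakage-free).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(extractor = c("FDPCA", "DPCA", "PCA"), p = 5,
                            knn_k = 7, membership_K = 7, m_f = 2,
                            pca_compress = 0.9999, normalize = TRUE,
                            ridge = 1e-8, seed = 1,
                            global_memberships = FALSE) {
  extractor <- match.arg(toupper(extractor), c("FDPCA", "DPCA", "PCA"))
  stopifnot(p >= 1, knn_k >= 1, membership_K >= 1, m_f > 1,
            pca_compress > 0, ridge >= 0)
  structure(list(extractor = extractor, p = as.integer(p),
                 knn_k = as.integer(knn_k),
                 membership_K = as.integer(membership_K), m_f = m_f,
                 pca_compress = pca_compress, normalize = isTRUE(normalize),
                 ridge = ridge, seed = as.integer(seed),
                 global_memberships = isTRUE(global_memberships)),
            class = "pipeline_config")
}

#' K-nearest-neighbour classification
#'
#' Majority vote among the `k` Euclidean-nearest training points. Vote ties
#' are broken by the larger summed inverse distance of the tied classes'
#' neighbours, then by the lowest class index; distance ties in the
#' neighbour search resolve to the lower training-sample index. All
#' tie-breaks are deterministic.
#'
#' @param train a `projected_table` (or any list with `Y` and `labels`).
#' @param test_points numeric matrix of query points (`m x p`).
#' @param k neighbour count, `k <= nrow(train$Y)`.
#' @return Factor of `m` predicted labels with the training label levels.
#' @export
knn_classify <- function(train, test_points, k) {
  if (is.null(train$Y) || nrow(train$Y) == 0L)
    stop("empty training set")
  if (!is.matrix(test_points)) test_points <- matrix(test_points, ncol = ncol(train$Y))
  n <- nrow(train$Y)
  if (k > n) stop(sprintf("k = %d exceeds training size %d", k, n))
  lab <- train$labels
  cls <- levels(lab)
  lab_idx <- as.integer(lab)
  # squared distances, m x n
  D2 <- outer(rowSums(test_points^2), rep(1, n)) +
    outer(rep(1, nrow(test_points)), rowSums(train$Y^2)) -
    2 * tcrossprod(test_points, train$Y)
  D2[D2 < 0] <- 0
  out <- integer(nrow(test_points))
  for (i in seq_len(nrow(test_points))) {
    nb <- order(D2[i, ])[seq_len(k)]           # stable: index breaks ties
    votes <- tabulate(lab_idx[nb], nbins = length(cls))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      invd <- vapply(top, function(cl) {
        sel <- nb[lab_idx[nb] == cl]
        sum(1 / pmax(sqrt(D2[i, sel]), .Machine$double.eps))
      }, 0)
      top <- top[invd == max(invd)]
    }
    out[i] <- min(top)
  }
  factor(cls[out], levels = cls)
}

# Fit the whole per-fold pipeline on a training table:
# normalize -> PCA compress -> (memberships) -> extractor -> project train.
fit_pipeline <- function(train, cfg, U = NULL) {
  stopifnot(inherits(train, "feature_table"),
            inherits(cfg, "pipeline_config"))
  cnt <- table(train$labels)
  if (any(cnt == 0L))
    stop("training partition lost class(es): ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  norm <- NULL
  tr <- train
  if (cfg$normalize) {
    norm <- fit_normalizer(train)
    tr <- apply_normalizer(train, norm)
  }
  # compression step
  ctr <- colMeans(tr$X)
  Xc <- sweep(tr$X, 2, ctr)
  ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  rank <- sum(pmax(ev, 0) > max(ev[1], .Machine$double.eps) * 1e-12)
  q <- if (cfg$pca_compress >= 1) min(as.integer(cfg$pca_compress), rank)
       else max(min(which(cumsum(ev) / sum(pmax(ev, 0)) >= cfg$pca_compress)),
                1L)
  q <- min(max(q, 1L), rank)
  comp <- pca_fit(tr, q)
  trc_proj <- project(tr, comp)
  trc <- feature_table(trc_proj$Y, tr$labels, sample_ids = tr$sample_ids)
  p_eff <- min(cfg$p, q)
  basis <- switch(cfg$extractor,
    PCA = pca_fit(trc, p_eff),
    DPCA = suppressWarnings(dpca_fit(trc, p_eff, ridge = cfg$ridge)),
    FDPCA = {
      Uf <- if (is.null(U))
        fuzzy_knn_memberships(trc, K = min(cfg$membership_K, nrow(trc$X) - 1L),
                              m_f = cfg$m_f)
      else U
      suppressWarnings(fdpca_fit(trc, U = Uf, p = p_eff, ridge = cfg$ridge))
    })
  structure(list(cfg = cfg, normalizer = norm, compression = comp,
                 basis = basis, train_proj = project(trc, basis)),
            class = "enose_pipeline")
}

# Transform new samples through a fitted pipeline and classify them.
predict_pipeline <- function(model, test) {
  stopifnot(inherits(model, "enose_pipeline"),
            inherits(test, "feature_table"))
  te <- test
  if (!is.null(model$normalizer)) te <- apply_normalizer(test, model$normalizer)
  tec <- feature_table(project(te, model$compression)$Y, te$labels,
                       sample_ids = te$sample_ids)
  Yte <- project(tec, model$basis)$Y
  knn_classify(model$train_proj, Yte,
               min(model$cfg$knn_k, nrow(model$train_proj$Y)))
}

# Global (full-table) memberships for the paper-faithful replication flag:
# estimated once on the normalized full table, then subset per fold.
global_membership_matrix <- function(table, cfg) {
  tn <- if (cfg$normalize) apply_normalizer(table, fit_normalizer(table))
        else table
  fuzzy_knn_memberships(tn, K = min(cfg$membership_K, nrow(tn$X) - 1L),
                        m_f = cfg$m_f)
}

subset_memberships <- function(U, idx) {
  membership_matrix(U$U[, idx, drop = FALSE], U$class_order, U$m_f)
}

#' Leave-one-out cross-validation of the pipeline
#'
#' Each sample in turn is held out; the entire pipeline (normalizer, PCA
#' compression, memberships, extractor, classifier) is refit on the other
#' `n - 1` samples only, and the held-out sample is classified. Accuracy is
#' the percentage of correctly classified samples. LOO is deterministic, so
#' no repeats are involved.
#'
#' @param table a [feature_table()].
#' @param cfg a [pipeline_config()].
#' @return List with `accuracy` (percent), `predicted` (factor of length
#'   `n`) and `confusion` (table of true x predicted).
#' @export
loo_validate <- function(table, cfg) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$X)
  if (n < nlevels(table$labels) + 1L)
    stop("need at least c + 1 samples for LOO")
  Ug <- if (cfg$global_memberships && cfg$extractor == "FDPCA")
    global_membership_matrix(table, cfg) else NULL
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- ft_subset(table, -i, drop_levels = FALSE)
    if (any(table(tr$labels) == 0L))
      stop(sprintf("LOO fold %d removes the only sample of its class", i))
    Ui <- if (!is.null(Ug)) subset_memberships(Ug, -i) else NULL
    model <- fit_pipeline(tr, cfg, U = Ui)
    pred[i] <- as.character(
      predict_pipeline(model, ft_subset(table, i, drop_levels = FALSE)))
  }
  pred <- factor(pred, levels = levels(table$labels))
  list(accuracy = 100 * mean(pred == table$labels, na.rm = FALSE),
       predicted = pred,
       confusion = table(true = table$labels, predicted = pred))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into `folds` folds, so every fold sees every class.
# folds == n degenerates to the LOO partition (one sample per fold).
make_fold_assignment <- function(labels, folds) {
  n <- length(labels)
  if (folds == n) return(seq_len(n))
  assign <- integer(n)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                   cl, length(idx), folds))
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# One pass over a fixed fold assignment; returns fraction correct.
run_folds <- function(table, cfg, assign, Ug = NULL) {
  correct <- 0L
  for (f in sort(unique(assign))) {
    te_idx <- which(assign == f)
    tr <- ft_subset(table, -te_idx, drop_levels = FALSE)
    Ui <- if (!is.null(Ug)) subset_memberships(Ug, -te_idx) else NULL
    model <- fit_pipeline(tr, cfg, U = Ui)
    pred <- predict_pipeline(model, ft_subset(table, te_idx,
                                              drop_levels = FALSE))
    correct <- correct + sum(pred == table$labels[te_idx])
  }
  correct / nrow(table$X)
}

#' Repeated stratified k-fold cross-validation
#'
#' Splits the data into `folds` stratified folds (every class present in
#' every fold), refits the full pipeline on each training portion, and
#' classifies the held-out fold. The split is reshuffled `repeats` times
#' from `cfg$seed` and the mean accuracy over all repeats is returned.
#'
#' @param table a [feature_table()].
#' @param cfg a [pipeline_config()].
#' @param folds number of folds (>= 2; every class needs at least `folds`
#'   samples).
#' @param repeats number of reshuffled repetitions (default 30).
#' @return Mean accuracy in percent.
#' @export
kfold_validate <- function(table, cfg, folds, repeats = 30) {
  stopifnot(inherits(table, "feature_table"), folds >= 2)
  assigns <- with_seed(cfg$seed,
    lapply(seq_len(repeats),
           function(r) make_fold_assignment(table$labels, folds)))
  Ug <- if (cfg$global_memberships && cfg$extractor == "FDPCA")
    global_membership_matrix(table, cfg) else NULL
  accs <- vapply(assigns, function(a) run_folds(table, cfg, a, Ug), 0)
  100 * mean(accs)
}

#' Full validation report for one extractor
#'
#' Runs LOO plus repeated stratified k-fold cross-validation for each entry
#' of `folds`, and averages the scheme accuracies — the per-method row of
#' the standard comparison table.
#'
#' @param table a [feature_table()].
#' @param cfg a [pipeline_config()].
#' @param folds fold counts for the k-fold schemes (default `c(5, 10, 20, 25)`).
#' @param repeats repeats per k-fold scheme (default 30).
#' @param fold_assignments optional precomputed assignments (list per scheme
#'   of list per repeat), used by [compare_extractors()] for paired designs.
#' @param include_loo include LOO as a scheme in the average (default `TRUE`).
#' @return An object of class `cv_report`: scheme accuracies (percent), their
#'   mean `average`, the LOO confusion table and the config.
#' @export
cv_report <- function(table, cfg, folds = c(5, 10, 20, 25), repeats = 30,
                      fold_assignments = NULL, include_loo = TRUE) {
  scheme <- numeric(0)
  confusion <- NULL
  Ug <- if (cfg$global_memberships && cfg$extractor == "FDPCA")
    global_membership_matrix(table, cfg) else NULL
  if (include_loo) {
    loo <- loo_validate(table, cfg)
    scheme <- c(LOO = loo$accuracy)
    confusion <- loo$confusion
  }
  if (is.null(fold_assignments))
    fold_assignments <- with_seed(cfg$seed, lapply(folds, function(fk)
      lapply(seq_len(repeats),
             function(r) make_fold_assignment(table$labels, fk))))
  for (j in seq_along(folds)) {
    accs <- vapply(fold_assignments[[j]],
                   function(a) run_folds(table, cfg, a, Ug), 0)
    scheme[paste0(folds[j], "-fold")] <- 100 * mean(accs)
  }
  structure(list(extractor = cfg$extractor, scheme = scheme,
                 average = mean(scheme), confusion = confusion,
                 folds = folds, repeats = repeats, config = cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s]\n", x$extractor))
  for (nm in names(x$scheme))
    cat(sprintf("  %-8s %7.2f%%\n", nm, x$scheme[nm]))
  cat(sprintf("  %-8s %7.2f%%\n", "average", x$average))
  invisible(x)
}

#' Paired comparison of the PCA, DPCA and FDPCA extractors
#'
#' Produces one [cv_report()] per extractor using identical fold assignments
#' and seeds across the three, so accuracy differences reflect the
#' extractors, not the splits.
#'
#' @param table a [feature_table()].
#' @param base_cfg a [pipeline_config()]; its `extractor` field is overridden.
#' @param folds fold counts (default `c(5, 10, 20, 25)`).
#' @param repeats repeats per scheme (default 30).
#' @param include_loo include LOO in each report (default `TRUE`).
#' @return Object of class `cv_comparison`: named list of `cv_report`s
#'   (`PCA`, `DPCA`, `FDPCA`).
#' @export
compare_extractors <- function(table, base_cfg, folds = c(5, 10, 20, 25),
                               repeats = 30, include_loo = TRUE) {
  assignments <- with_seed(base_cfg$seed, lapply(folds, function(fk)
    lapply(seq_len(repeats),
           function(r) make_fold_assignment(table$labels, fk))))
  reports <- lapply(c("PCA", "DPCA", "FDPCA"), function(m) {
    cfg <- base_cfg
    cfg$extractor <- m
    cv_report(table, cfg, folds = folds, repeats = repeats,
              fold_assignments = assignments, include_loo = include_loo)
  })
  names(reports) <- c("PCA", "DPCA", "FDPCA")
  structure(reports, class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  schemes <- names(x[[1]]$scheme)
  cat(sprintf("%-8s", "method"))
  for (s in schemes) cat(sprintf("%10s", s))
  cat(sprintf("%10s\n", "average"))
  for (m in names(x)) {
    cat(sprintf("%-8s", m))
    for (s in schemes) cat(sprintf("%9.2f%%", x[[m]]$scheme[s]))
    cat(sprintf("%9.2f%%\n", x[[m]]$average))
  }
  invisible(x)
}

#' Serialize a cv_report (or comparison) to JSON
#'
#' @param x a `cv_report` or `cv_comparison`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_to_json <- function(x, path = NULL) {
  to_list <- function(r) list(
    extractor = r$extractor,
    scheme_accuracy_percent = as.list(r$scheme),
    average_validation_accuracy_percent = r$average,
    folds = r$folds, repeats = r$repeats,
    confusion = if (!is.null(r$confusion)) as.data.frame(r$confusion))
  obj <- if (inherits(x, "cv_comparison")) lapply(x, to_list) else to_list(x)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
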