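#' Construct a set of sensor response curves
#'
#' Raw electronic-nose output: for each sample, a matrix of sensor voltages
#' over time (`T` time points x `d` sensors). All samples must share the same
#' sensors in the same order.
#'
#' @param samples a list; each element is a list with fields `sample_id`,
#'   `label`, and `curve` (a `T x d` numeric matrix, `T >= 5`).
#' @param sensor_names character vector of `d` sensor names.
#' @return An object of class `response_curve_set`.
#' @export
response_curve_set <- function(samples, sensor_names) {
  if (length(samples) == 0L) stop("at least one sample is required")
  d <- length(sensor_names)
  for (s in samples) {
    if (!all(c("sample_id", "label", "curve") %in% names(s)))
      stop("each sample needs fields sample_id, label, curve")
    cur <- s$curve
    if (!is.matrix(cur) || ncol(cur) != d)
      stop(sprintf("sample '%s': curve must be a matrix with %d sensor columns",
                   s$sample_id, d))
    if (nrow(cur) < 5L)
      stop(sprintf("sample '%s' has %d time points; at least 5 are required",
                   s$sample_id, nrow(cur)))
    if (any(!is.finite(cur)))
      stop(sprintf("sample '%s' contains non-finite values", s$sample_id))
  }
  structure(list(samples = samples, sensor_names = sensor_names),
            class = "response_curve_set")
}

#' @export
print.response_curve_set <- function(x, ...) {
  cat(sprintf("response_curve_set: %d samples, %d sensors\n",
              length(x$samples), length(x$sensor_names)))
  invisible(x)
}

#' Steady-state features from response curves
#'
#' Reduces each sensor trace to a single steady-state feature: the arithmetic
#' mean of the response at five moments in the saturation region of the curve.
#' Averaging several plateau readings suppresses current noise that a single
#' reading would carry. By default the last five time points of each curve are
#' used (the plateau at the end of the gas-intake phase); any five valid
#' indices may be supplied instead.
#'
#' @param curves a [response_curve_set()].
#' @param window_indices integer vector of 5 time indices to average, or
#'   `NULL` (default) for the final five points of each curve.
#' @param baseline_subtract subtract each sensor's first reading before
#'   averaging (default `FALSE`; the plain plateau level is the feature).
#' @return A [feature_table()] with one feature per sensor.
#' @export
#' @examples
#' tm <- seq(0, 600, by = 10)
#' curve <- outer(1 - exp(-tm / 60), c(2, 3))
#' rcs <- response_curve_set(
#'   list(list(sample_id = "s1", label = "A", curve = curve)),
#'   sensor_names = c("TGS1", "TGS2"))
#' steady_state_features(rcs)$X
steady_state_features <- function(curves, window_indices = NULL,
                                  baseline_subtract = FALSE) {
  stopifnot(inherits(curves, "response_curve_set"))
  n <- length(curves$samples)
  d <- length(curves$sensor_names)
  X <- matrix(NA_real_, n, d)
  ids <- character(n); labs <- character(n)
  for (j in seq_len(n)) {
    s <- curves$samples[[j]]
    cur <- s$curve
    idx <- if (is.null(window_indices)) {
      seq.int(nrow(cur) - 4L, nrow(cur))
    } else {
      window_indices
    }
    if (length(idx) != 5L)
      stop("`window_indices` must contain exactly 5 time indices")
    if (any(idx < 1L) || any(idx > nrow(cur)))
      stop(sprintf("window indices out of range for sample '%s' (T = %d)",
                   s$sample_id, nrow(cur)))
    win <- cur[idx, , drop = FALSE]
    if (any(!is.finite(win)))
      stop(sprintf("non-finite values in averaging window of sample '%s'",
                   s$sample_id))
    if (baseline_subtract) win <- sweep(win, 2, cur[1L, ], "-")
    X[j, ] <- colMeans(win)
    ids[j] <- s$sample_id
    labs[j] <- as.character(s$label)
  }
  feature_table(X, labs, feature_names = curves$sensor_names,
                sample_ids = ids)
}

#' Fit a min-max normalizer on a training table
#'
#' Learns the per-feature minimum and maximum of a (training) feature table.
#' MOS sensors have heterogeneous response ranges, so features are rescaled
#' to a common \[0, 1\] range before distance-based steps. Fitting on the
#' training partition only and applying the frozen parameters to test data
#' keeps cross-validation leakage-free.
#'
#' @param table a [feature_table()] with at least 2 samples.
#' @return An object of class `normalizer_params`: per-feature `min`, `max`,
#'   and a logical `constant` flag for features with `max == min` (those map
#'   to 0 at transform time rather than dividing by zero).
#' @export
fit_normalizer <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$X) < 2L) stop("need at least 2 samples to fit a normalizer")
  mins <- apply(table$X, 2, min)
  maxs <- apply(table$X, 2, max)
  structure(
    list(min = mins, max = maxs, constant = maxs == mins,
         feature_names = table$feature_names),
    class = "normalizer_params"
  )
}

#' Apply a fitted min-max normalizer
#'
#' Maps every feature to `(x - min) / (max - min)` with the training
#' parameters. Training values land in \[0, 1\]; test values outside the
#' training range extrapolate beyond \[0, 1\] and are deliberately not
#' clipped. Features that were constant in training map to 0.
#'
#' @param table a [feature_table()] whose feature names match `params`.
#' @param params a `normalizer_params` from [fit_normalizer()].
#' @return A normalized [feature_table()].
#' @export
apply_normalizer <- function(table, params) {
  stopifnot(inherits(table, "feature_table"),
            inherits(params, "normalizer_params"))
  if (!identical(table$feature_names, params$feature_names))
    stop("feature names of `table` do not match the fitted normalizer")
  rng <- params$max - params$min
  rng[params$constant] <- 1  # avoid 0/0; numerator forced to 0 below
  Xs <- sweep(table$X, 2, params$min, "-")
  Xs[, params$constant] <- 0
  Xs <- sweep(Xs, 2, rng, "/")
  feature_table(Xs, table$labels, feature_names = table$feature_names,
                sample_ids = table$sample_ids)
}

#' Read response curves from per-sample CSV files
#'
#' Each curve file has the header `time,<sensor_1>,...,<sensor_d>` and one row
#' per time point. A manifest CSV with columns `file,sample_id,label` maps
#' curve files to samples; relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A [response_curve_set()].
#' @export
read_response_curves <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "sample_id", "label") %in% names(man)))
    stop("manifest must contain columns file, sample_id, label")
  base <- dirname(manifest_path)
  sensor_names <- NULL
  samples <- vector("list", nrow(man))
  for (j in seq_len(nrow(man))) {
    f <- man$file[j]
    if (!file.exists(f)) f <- file.path(base, man$file[j])
    df <- utils::read.csv(f, check.names = FALSE)
    if (names(df)[1] != "time")
      stop("curve file ", man$file[j], ": first column must be 'time'")
    sens <- names(df)[-1]
    if (is.null(sensor_names)) sensor_names <- sens
    else if (!identical(sensor_names, sens))
      stop("curve file ", man$file[j], ": sensor columns differ from previous files")
    cur <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(cur) <- "double"
    samples[[j]] <- list(sample_id = man$sample_id[j], label = man$label[j],
                         curve = cur)
  }
  response_curve_set(samples, sensor_names)
}

#' Write response curves to per-sample CSV files plus a manifest
#'
#' @param curves a [response_curve_set()].
#' @param dir output directory (created if needed).
#' @param times optional numeric vector of time stamps (default row index).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_response_curves <- function(curves, dir, times = NULL) {
  stopifnot(inherits(curves, "response_curve_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(curves$samples))
  for (j in seq_along(curves$samples)) {
    s <- curves$samples[[j]]
    tt <- if (is.null(times)) seq_len(nrow(s$curve)) else times
    df <- data.frame(time = tt)
    df[curves$sensor_names] <- as.data.frame(s$curve)
    files[j] <- paste0("curve_", s$sample_id, ".csv")
    utils::write.csv(df, file.path(dir, files[j]), row.names = FALSE,
                     quote = FALSE)
  }
  man <- data.frame(
    file = files,
    sample_id = vapply(curves$samples, `[[`, "", "sample_id"),
    label = vapply(curves$samples, function(s) as.character(s$label), ""))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
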