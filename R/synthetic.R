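#' Configuration for the synthetic sensor-array generator
#'
#' Describes a Gaussian class-conditional model of an e-nose experiment:
#' `n_classes` volatile-compound classes, `per_class` replicate samples each,
#' and `d` cross-sensitive sensors whose noise is equicorrelated (a single
#' correlation `rho` across channels, standard deviation `sigma`). Class
#' means are placed on mutually orthogonal axes at a pairwise distance of
#' `separation` noise standard deviations; an overlap parameter `delta` then
#' pulls a designated subset of class means toward their common centroid
#' (`delta = 0` leaves them apart, `delta = 1` makes them coincide),
#' mimicking the geometry of real liquor data where some brands' headspace
#' fingerprints nearly coincide.
#'
#' The defaults (6 classes x 50 samples x 10 sensors, three far classes and
#' three overlapped ones) emulate the sample design of a typical liquor
#' discrimination experiment.
#'
#' @param n_classes number of classes (default 6).
#' @param per_class samples per class (default 50).
#' @param d number of sensors (default 10).
#' @param class_means optional `n_classes x d` matrix of mean responses;
#'   when `NULL`, means are auto-placed (requires `d >= n_classes`).
#' @param separation pairwise distance between auto-placed class means, in
#'   units of `sigma` (default 10; with `sigma = 0` absolute units).
#' @param sigma per-sensor noise standard deviation (default 1).
#' @param rho common inter-sensor noise correlation (default 0.5); must keep
#'   the equicorrelation matrix positive definite.
#' @param delta overlap in \[0, 1\] applied to `overlap_classes` (default 0.8).
#' @param overlap_classes indices of the classes pulled together (default:
#'   the last 3 when `n_classes >= 4`, otherwise all).
#' @param seed RNG seed (default 1).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 6, per_class = 50, d = 10,
                             class_means = NULL, separation = 10,
                             sigma = 1, rho = 0.5, delta = 0.8,
                             overlap_classes = NULL, seed = 1) {
  stopifnot(n_classes >= 1, per_class >= 1, d >= 1,
            separation >= 0, sigma >= 0,
            delta >= 0, delta <= 1)
  if (sigma > 0) {
    # equicorrelation eigenvalues: 1 - rho and 1 + (d-1) rho
    if (rho >= 1 || (d > 1 && rho <= -1 / (d - 1)))
      stop("covariance is not positive definite: need -1/(d-1) < rho < 1")
  }
  if (is.null(class_means)) {
    if (d < n_classes)
      stop("auto-placed means need d >= n_classes; pass `class_means`")
    unit <- if (sigma > 0) sigma else 1
    class_means <- matrix(0, n_classes, d)
    class_means[cbind(seq_len(n_classes), seq_len(n_classes))] <-
      separation * unit / sqrt(2)
  } else {
    class_means <- as.matrix(class_means)
    if (!identical(dim(class_means), c(as.integer(n_classes), as.integer(d))))
      stop("`class_means` must be an n_classes x d matrix")
  }
  if (is.null(overlap_classes))
    overlap_classes <- if (n_classes >= 4) {
      seq.int(n_classes - 2L, n_classes)
    } else {
      seq_len(n_classes)
    }
  if (delta > 0 && length(overlap_classes) >= 2) {
    ctr <- colMeans(class_means[overlap_classes, , drop = FALSE])
    class_means[overlap_classes, ] <-
      (1 - delta) * class_means[overlap_classes, , drop = FALSE] +
      delta * matrix(ctr, length(overlap_classes), d, byrow = TRUE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class), d = as.integer(d),
                 class_means = class_means, separation = separation,
                 sigma = sigma, rho = rho, delta = delta,
                 overlap_classes = overlap_classes,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Cholesky factor of the equicorrelated noise covariance sigma^2 *
# ((1 - rho) I + rho J); NULL when sigma == 0 (noise-free).
noise_chol <- function(cfg) {
  if (cfg$sigma == 0) return(NULL)
  Sig <- cfg$sigma^2 * ((1 - cfg$rho) * diag(cfg$d) +
                          cfg$rho * matrix(1, cfg$d, cfg$d))
  chol(Sig)
}

#' Generate a synthetic feature table
#'
#' Draws `per_class` samples per class from the multivariate Gaussian model
#' of a [synthetic_config()]. Reproducible from the config seed; the global
#' RNG state is left untouched.
#'
#' @param cfg a [synthetic_config()].
#' @return A [feature_table()] with classes `class_1 .. class_c`.
#' @export
#' @examples
#' ft <- generate_features(synthetic_config(n_classes = 3, per_class = 10,
#'                                          d = 4, seed = 42))
#' class_counts(ft)
generate_features <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  R <- noise_chol(cfg)
  n <- cfg$n_classes * cfg$per_class
  X <- with_seed(cfg$seed, {
    Z <- if (is.null(R)) matrix(0, n, cfg$d)
         else matrix(stats::rnorm(n * cfg$d), n, cfg$d) %*% R
    Z + cfg$class_means[rep(seq_len(cfg$n_classes), each = cfg$per_class), ,
                        drop = FALSE]
  })
  labels <- factor(rep(paste0("class_", seq_len(cfg$n_classes)),
                       each = cfg$per_class),
                   levels = paste0("class_", seq_len(cfg$n_classes)))
  feature_table(X, labels,
                feature_names = paste0("S", seq_len(cfg$d)),
                sample_ids = sprintf("c%02d_s%03d",
                                     rep(seq_len(cfg$n_classes),
                                         each = cfg$per_class),
                                     rep(seq_len(cfg$per_class),
                                         cfg$n_classes)))
}

#' Generate synthetic sensor response curves
#'
#' Builds first-order saturation kinetics around the feature table of the
#' same config: each sensor trace is `plateau * (1 - exp(-t / tau)) + noise`,
#' where the plateau is that sample's steady-state feature value from
#' [generate_features()]. The mean of the final five time points therefore
#' recovers the feature table up to the exponential tail (bounded by
#' `exp(-(t_end - 4 dt)/tau)` relative) plus curve noise.
#'
#' @param cfg a [synthetic_config()].
#' @param tau sensor rise time constant, seconds (default 60).
#' @param t_end end of the gas-intake phase, seconds (default 600, i.e. a
#'   10-minute intake; `t_end >= 10 * tau` keeps the tail bias below 1e-3).
#' @param dt sampling interval, seconds (default 5).
#' @param curve_noise additive iid Gaussian noise on each curve reading
#'   (default 0).
#' @return A [response_curve_set()]; time runs from 0 to `t_end` in steps of
#'   `dt`.
#' @export
generate_curves <- function(cfg, tau = 60, t_end = 600, dt = 5,
                            curve_noise = 0) {
  stopifnot(inherits(cfg, "synthetic_config"), tau >= 0, t_end > 0, dt > 0)
  ft <- generate_features(cfg)
  tm <- seq(0, t_end, by = dt)
  rise <- if (tau == 0) rep(1, length(tm)) else 1 - exp(-tm / tau)
  samples <- with_seed(cfg$seed + 10007L, {
    lapply(seq_len(nrow(ft$X)), function(j) {
      curve <- outer(rise, ft$X[j, ])
      if (curve_noise > 0)
        curve <- curve + matrix(stats::rnorm(length(curve), sd = curve_noise),
                                nrow(curve), ncol(curve))
      list(sample_id = ft$sample_ids[j],
           label = as.character(ft$labels[j]),
           curve = curve)
    })
  })
  response_curve_set(samples, ft$feature_names)
}
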