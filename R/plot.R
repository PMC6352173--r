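#' Scatter plot of the first projected features
#'
#' Pairwise scatter panels of the first (up to) three projected features,
#' coloured by class — the quick look at how well an extractor separates the
#' clusters. Uses base graphics.
#'
#' @param proj a `projected_table` from [project()].
#' @param dims which feature columns to show (default first 3, capped at
#'   what is available).
#' @param ... passed to [graphics::pairs()] / [graphics::plot()].
#' @return `proj`, invisibly.
#' @export
plot_projected <- function(proj, dims = 1:3, ...) {
  stopifnot(inherits(proj, "projected_table"))
  dims <- dims[dims <= ncol(proj$Y)]
  cols <- as.integer(proj$labels) + 1L
  if (length(dims) >= 2) {
    graphics::pairs(proj$Y[, dims, drop = FALSE], col = cols,
                    pch = 19, main = proj$method, ...)
  } else {
    graphics::plot(proj$Y[, dims[1]], col = cols, pch = 19,
                   ylab = colnames(proj$Y)[dims[1]], main = proj$method, ...)
  }
  invisible(proj)
}
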