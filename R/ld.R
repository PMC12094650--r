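#' Estimate a block linkage-disequilibrium matrix from a genotype panel
#'
#' Computes Pearson correlations of dosages within each LD block (by default
#' the generator's blocks; for external data a fixed-size window can be
#' imposed instead), optionally shrinking each block matrix toward the
#' identity by a factor `lambda` to guarantee positive definiteness.
#'
#' @param panel a `genotype_panel` (or any list with a `dosage` matrix and a
#'   `variants` data.frame carrying `id` and `block`).
#' @param window optional variant count; when given, contiguous windows of
#'   this size replace the panel's block annotation.
#' @param lambda shrinkage toward the identity in `[0, 1]`; each block matrix
#'   becomes `(1 - lambda) * R + lambda * I`. Default 0.01.
#' @return an object of class `ld_matrix`: list with `blocks` (list of
#'   correlation matrices), `block_index` (block id per variant), `ids`,
#'   `n` (panel size) and `lambda`.
#' @examples
#' panel <- simulate_panel(sim_config(M = 20, n_ref = 100, block_size = 5))
#' ld <- estimate_ld(panel)
#' length(ld$blocks)
#' @export
estimate_ld <- function(panel, window = NULL, lambda = 0.01) {
  X <- panel$dosage
  if (nrow(X) < 2L) stop("panel must contain at least 2 individuals")
  if (!is.null(window)) {
    if (window < 1) stop("`window` must be >= 1")
    block_index <- variant_blocks(ncol(X), as.integer(window))
  } else {
    block_index <- panel$variants$block
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- panel$variants$id[which(sds == 0)[1]]
    stop(sprintf("zero-variance variant '%s': cannot compute LD", bad))
  }
  blocks <- lapply(split(seq_along(block_index), block_index), function(idx) {
    R <- stats::cor(X[, idx, drop = FALSE])
    R <- (1 - lambda) * R + lambda * diag(length(idx))
    dimnames(R) <- list(panel$variants$id[idx], panel$variants$id[idx])
    R
  })
  structure(
    list(blocks = blocks, block_index = block_index,
         ids = panel$variants$id, n = nrow(X), lambda = lambda),
    class = "ld_matrix"
  )
}

#' Per-variant LD scores
#'
#' The LD score of variant j is the sum of squared correlations with all
#' variants in its block (including itself). With `adjust = TRUE` the usual
#' finite-sample bias correction `r2 - (1 - r2)/(n - 2)` is applied, which is
#' appropriate when the block matrices estimate an external truth; leave it
#' off when the same matrices define the sampling model of the summary
#' statistics.
#'
#' @param ld an `ld_matrix`.
#' @param adjust logical; apply the finite-panel r-squared bias correction.
#' @return numeric vector of LD scores aligned to `ld$ids`.
#' @export
ld_scores <- function(ld, adjust = FALSE) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- unlist(lapply(ld$blocks, function(R) {
    r2 <- R^2
    if (adjust) r2 <- r2 - (1 - r2) / (ld$n - 2)
    rowSums(r2)
  }), use.names = FALSE)
  # blocks were split() in block-index order, which follows variant order
  out
}
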