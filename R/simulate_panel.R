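#' Simulate an LD-blocked genotype reference panel
#'
#' Genotypes are generated from a haplotype threshold model: within each block
#' two independent latent haplotype vectors per individual follow a
#' first-order autoregressive Gaussian process with adjacent correlation
#' `rho`; an allele is carried when the latent value falls below the normal
#' quantile of the variant's minor allele frequency, and the dosage is the sum
#' over the two haplotypes. This yields Hardy-Weinberg genotype frequencies at
#' the drawn MAFs, banded positive-definite LD within blocks, and exact
#' independence across blocks.
#'
#' @param config a [sim_config()].
#' @return an object of class `genotype_panel`: a list with `dosage`
#'   (individuals x variants matrix, values 0/1/2), `variants` (data.frame
#'   with id, block, a1, a2, freq) and the generating `rho`.
#' @examples
#' panel <- simulate_panel(sim_config(M = 20, n_ref = 50, block_size = 5))
#' dim(panel$dosage)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- substream_seed(config$master_seed, "panel")
  with_seed(seed, {
    maf <- stats::runif(config$M, config$maf_range[1], config$maf_range[2])
    blocks <- variant_blocks(config$M, config$block_size)
    variants <- data.frame(
      id = sprintf("snp_%05d", seq_len(config$M)),
      block = blocks,
      a1 = "A", a2 = "G",
      freq = maf,
      stringsAsFactors = FALSE
    )
    dosage <- draw_dosages(variants, config$rho, config$n_ref)
    colnames(dosage) <- variants$id
  })
  structure(
    list(dosage = dosage, variants = variants, rho = config$rho),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d variants in %d LD blocks\n",
              nrow(x$dosage), nrow(x$variants), length(unique(x$variants$block))))
  invisible(x)
}

# Draw n individuals' dosages for a given variant table (MAFs + blocks)
# under the AR(1) haplotype threshold model. Uses the current RNG state.
draw_dosages <- function(variants, rho, n) {
  draw_dosages_cpp(as.integer(n), stats::qnorm(variants$freq),
                   as.integer(variants$block), rho)
}
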