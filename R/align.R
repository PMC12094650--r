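#' Align external summary statistics to a genotype panel's allele coding
#'
#' Matches variants by id, flips the sign of the effect (and complements the
#' frequency) when the effect/other alleles are swapped relative to the
#' panel, drops variants whose allele pairs do not match at all, and
#' optionally drops strand-ambiguous pairs (A/T, C/G) whose orientation
#' cannot be resolved.
#'
#' @param sumstats data.frame with columns snp, a1 (effect allele), a2,
#'   beta, se, n, freq.
#' @param panel a `genotype_panel`.
#' @param drop_ambiguous drop A/T and C/G variants (default FALSE; the
#'   synthetic generator never produces them).
#' @return list with `sumstats` (aligned, in panel variant order) and
#'   `report` (counts: n_matched, n_flipped, n_dropped_mismatch,
#'   n_dropped_ambiguous).
#' @export
align_alleles <- function(sumstats, panel, drop_ambiguous = FALSE) {
  pv <- panel$variants
  idx <- match(pv$id, sumstats$snp)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no overlapping variant ids between sumstats and panel")
  ss <- sumstats[idx[keep], , drop = FALSE]
  pv <- pv[keep, , drop = FALSE]

  ambiguous <- function(a, b) {
    pair <- paste(pmin(a, b), pmax(a, b))
    pair %in% c("A T", "C G")
  }
  amb <- drop_ambiguous &
    (ambiguous(ss$a1, ss$a2) | ambiguous(pv$a1, pv$a2))
  same <- ss$a1 == pv$a1 & ss$a2 == pv$a2
  flipped <- ss$a1 == pv$a2 & ss$a2 == pv$a1
  mismatch <- !same & !flipped

  n_amb <- sum(amb & !mismatch)
  n_mis <- sum(mismatch & !amb)
  ok <- !amb & !mismatch
  ss$beta[flipped & ok] <- -ss$beta[flipped & ok]
  ss$freq[flipped & ok] <- 1 - ss$freq[flipped & ok]
  tmp <- ss$a1[flipped & ok]
  ss$a1[flipped & ok] <- ss$a2[flipped & ok]
  ss$a2[flipped & ok] <- tmp
  out <- ss[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("all overlapping variants were dropped during alignment")
  list(
    sumstats = out,
    report = list(
      n_matched = nrow(out),
      n_flipped = sum(flipped & ok),
      n_dropped_mismatch = n_mis,
      n_dropped_ambiguous = sum(amb)
    )
  )
}
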