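# Readers/writers for the pipeline's plain-text interchange formats.

#' Write/read GWAS summary statistics TSV
#'
#' Tab-delimited with columns snp, a1, a2, beta, se, n, freq; missing values
#' written as ".".
#'
#' @param sumstats data.frame in the standard column layout.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_sumstats <- function(sumstats, path) {
  out <- sumstats[, c("snp", "a1", "a2", "beta", "se", "n", "freq")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  required <- c("snp", "a1", "a2", "beta", "se", "n", "freq")
  missing_cols <- setdiff(required, names(ss))
  if (length(missing_cols)) {
    stop("sumstats file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ss$snp)) stop("duplicate variant ids in sumstats")
  if (any(!is.na(ss$se) & ss$se <= 0)) stop("non-positive standard error")
  ss
}

#' Write/read a genotype dosage matrix TSV
#'
#' Rows are individuals (first column `id`), remaining columns one per
#' variant (header = variant ids), dosages 0-2 with up to 3 decimals.
#'
#' @param panel a `genotype_panel` (or matrix with rownames).
#' @param path file path.
#' @export
write_genotypes <- function(panel, path) {
  X <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  df <- data.frame(id = rownames(X) %||% sprintf("ind_%05d", seq_len(nrow(X))),
                   round(X, 3), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  if (any(X < 0 | X > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  X
}

#' Write PRS weights TSV
#'
#' Columns: snp, a1, weight, p, method.
#'
#' @param weights a `prs_weights`.
#' @param sumstats the aligned sumstats (for allele columns).
#' @param path file path.
#' @export
write_weights <- function(weights, sumstats, path) {
  df <- data.frame(snp = weights$ids,
                   a1 = sumstats$a1[match(weights$ids, sumstats$snp)],
                   weight = weights$weights, p = weights$p,
                   method = weights$method)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-individual scores CSV
#'
#' Columns: id, raw, standardized, adjusted.
#'
#' @param scores data.frame from [score_individuals()], optionally with an
#'   `adjusted` column.
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  if (is.null(scores$adjusted)) scores$adjusted <- NA_real_
  utils::write.csv(scores[, c("id", "raw", "standardized", "adjusted")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write/read a cohort table CSV
#'
#' @param cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
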