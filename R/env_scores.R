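#' Construct and validate an environmental weight table
#'
#' The aggregate environmental risk score is a weighted sum over exposure
#' domains, each domain contributing the log relative-risk weight of the
#' individual's observed level. The weight table is treated as data: the
#' package ships a clearly-labelled placeholder fixture, and substantive use
#' requires the user to supply weights from their own instrument.
#'
#' @param table data.frame with columns `domain`, `level`, `weight`,
#'   `is_reference` (logical).
#' @return validated data.frame of class `env_weight_table`.
#' @export
env_weight_table <- function(table) {
  required <- c("domain", "level", "weight", "is_reference")
  if (!all(required %in% names(table))) {
    stop("weight table needs columns: ", paste(required, collapse = ", "))
  }
  table$level <- as.character(table$level)
  table$is_reference <- as.logical(table$is_reference)
  if (any(!is.finite(table$weight))) stop("non-finite weight in table")
  for (d in unique(table$domain)) {
    rows <- table[table$domain == d, ]
    if (anyDuplicated(rows$level)) {
      stop(sprintf("duplicate level within domain '%s'", d))
    }
    nref <- sum(rows$is_reference)
    if (nref != 1L) {
      stop(sprintf("domain '%s' must have exactly one reference level", d))
    }
    if (rows$weight[rows$is_reference] != 0) {
      stop(sprintf("reference level of domain '%s' must carry weight 0", d))
    }
  }
  structure(as.data.frame(table), class = c("env_weight_table", "data.frame"))
}

#' Load an environmental weight table from YAML or TSV
#'
#' YAML layout: optional top-level `scale: or` (weights given as odds/risk
#' ratios, log-transformed on load), then `domains:` — a list of entries with
#' `name`, `reference`, and a `levels` mapping of level to weight. TSV layout:
#' columns domain, level, weight, is_reference.
#'
#' @param path file path (`.yaml`/`.yml` or `.tsv`).
#' @return an `env_weight_table`.
#' @export
load_weight_table <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw$domains)) stop("YAML weight table must have a 'domains' key")
    as_log <- identical(raw$scale, "or")
    rows <- lapply(raw$domains, function(d) {
      if (is.null(d$name) || is.null(d$reference) || is.null(d$levels)) {
        stop("each domain needs 'name', 'reference' and 'levels'")
      }
      lv <- names(d$levels)
      wt <- as.numeric(unlist(d$levels))
      if (as_log) wt <- log(wt)
      if (!d$reference %in% lv) {
        stop(sprintf("missing reference level '%s' in domain '%s'",
                     d$reference, d$name))
      }
      data.frame(domain = d$name, level = lv, weight = wt,
                 is_reference = lv == d$reference, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  env_weight_table(tab)
}

#' Write an environmental weight table to TSV
#'
#' @param table an `env_weight_table`.
#' @param path output path.
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "env_weight_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate weighted environmental risk total
#'
#' For each individual, sums the weight of the observed level across the
#' domains of the weight table (a reference level contributes zero).
#' Individuals missing any domain get an `NA` total (complete-case default);
#' the missingness report identifies them.
#'
#' @param exposures data.frame with one column per domain holding level
#'   labels (or 0/1 for binary domains coded as levels "0"/"1").
#' @param table an `env_weight_table`.
#' @return list with `total` (numeric), `contributions` (individuals x
#'   domains matrix) and `missing` (per-individual count of missing domains).
#' @export
pers_total <- function(exposures, table) {
  stopifnot(inherits(table, "env_weight_table"))
  domains <- unique(table$domain)
  missing_cols <- setdiff(domains, names(exposures))
  if (length(missing_cols)) {
    stop("exposure columns missing for domain(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(exposures)
  contrib <- matrix(NA_real_, n, length(domains),
                    dimnames = list(NULL, domains))
  for (d in domains) {
    rows <- table[table$domain == d, ]
    lev <- as.character(exposures[[d]])
    known <- is.na(lev) | lev %in% rows$level
    if (!all(known)) {
      stop(sprintf("unknown level '%s' in domain '%s'",
                   lev[!known][1], d))
    }
    contrib[, d] <- rows$weight[match(lev, rows$level)]
  }
  miss <- rowSums(is.na(contrib))
  list(total = rowSums(contrib), contributions = contrib, missing = miss)
}

#' Trauma-inventory total with reverse-scored positive subdomains
#'
#' Totals the negative subdomain raw scores together with the reversed
#' (`max - raw`) positively-framed subdomains, so that a higher total always
#' means more reported early trauma.
#'
#' @param subdomain_scores data.frame/list with numeric elements named in
#'   `names(max_by_subdomain)`.
#' @param max_by_subdomain named numeric vector of per-subdomain maxima.
#' @param positive character vector naming the subdomains to reverse.
#' @return list with `total` and `subdomain_scores` (the oriented per-
#'   subdomain contributions).
#' @export
eti_total <- function(subdomain_scores,
                      max_by_subdomain = c(eti_neg_self = 24,
                                           eti_neg_others = 24,
                                           eti_pos_self = 24,
                                           eti_pos_others = 24),
                      positive = c("eti_pos_self", "eti_pos_others")) {
  nm <- names(max_by_subdomain)
  if (!all(nm %in% names(subdomain_scores))) {
    stop("missing subdomain column(s): ",
         paste(setdiff(nm, names(subdomain_scores)), collapse = ", "))
  }
  oriented <- sapply(nm, function(s) {
    x <- subdomain_scores[[s]]
    if (any(x < 0 | x > max_by_subdomain[s], na.rm = TRUE)) {
      stop(sprintf("raw score outside [0, %g] in subdomain '%s'",
                   max_by_subdomain[s], s))
    }
    if (s %in% positive) max_by_subdomain[s] - x else x
  })
  oriented <- matrix(oriented, ncol = length(nm), dimnames = list(NULL, nm))
  list(total = rowSums(oriented), subdomain_scores = oriented)
}

#' Shipped placeholder weight table
#'
#' Loads the package's synthetic placeholder weight table for the six
#' exposure domains (binary levels "0"/"1"). These weights are illustrative
#' defaults matching the synthetic generator, not published instrument
#' weights.
#'
#' @return an `env_weight_table`.
#' @export
default_weight_table <- function() {
  load_weight_table(system.file("extdata", "env_weights_synthetic.yaml",
                                package = "geiprs", mustWork = TRUE))
}
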