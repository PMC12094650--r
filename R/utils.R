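# Internal helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic expansion of a master seed into named substreams. Names are
# hashed position-dependently so "panel"/"cohort" etc. get distinct, stable
# streams; result always fits in a 32-bit integer.
substream_seed <- function(master_seed, name) {
  stopifnot(is_scalar_number(master_seed))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 7919)
  as.integer((abs(master_seed) %% 94906265 * 48271 + h) %% 2147483647)
}

#' Standardize a numeric vector
#'
#' Centres and scales values to mean 0, SD 1 over the non-missing entries,
#' optionally using only a reference subset (e.g. controls) to define the
#' centring constants, so that per-SD effect sizes can be anchored to a
#' reference population.
#'
#' @param values numeric vector, possibly with `NA`s.
#' @param reference_mask optional logical vector (same length): entries used
#'   to compute the mean and SD. All values are transformed either way.
#' @return numeric vector of standardized values; `NA`s are preserved.
#' @examples
#' standardize_scores(c(1, 2, 3, 4))
#' @export
standardize_scores <- function(values, reference_mask = NULL) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  ref <- if (is.null(reference_mask)) values else {
    if (length(reference_mask) != length(values)) {
      stop("`reference_mask` must match the length of `values`")
    }
    values[reference_mask]
  }
  ref <- ref[!is.na(ref)]
  if (length(ref) < 2L) stop("need at least 2 non-missing reference values")
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stop("zero standard deviation: cannot standardize")
  (values - mean(ref)) / s
}

# Quietly evaluate `expr` under `seed` without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
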