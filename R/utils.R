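#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted: mapping vendor probe identifiers or aliases to official symbols
#' is the responsibility of the probe annotation supplied by the user.
#' Idempotent: `normalize_gene_symbols(normalize_gene_symbols(x))` equals
#' `normalize_gene_symbols(x)`.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_gene_symbols(c(" snca", "Thy1  "))
normalize_gene_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# ceil(fraction * n), the rank-cutoff rounding used everywhere a "top
# fraction" is selected; fixed so results do not depend on the platform.
top_n_count <- function(fraction, n) {
  as.integer(ceiling(fraction * n))
}

# Deterministic top-k selection: decreasing key, ties broken by increasing id.
top_k_ids <- function(ids, key, k) {
  ord <- order(-key, ids, method = "radix")
  ids[ord][seq_len(min(k, length(ids)))]
}

abort_parse <- function(msg, ...) abort(msg, class = "compactdm_parse_error", ...)
abort_validation <- function(msg, ...) abort(msg, class = "compactdm_validation_error", ...)

# All exported stochastic operations take an explicit seed and restore the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  withr::with_seed(as.integer(seed), code)
}
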