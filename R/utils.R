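# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; with seed = NULL the ambient RNG stream is
# used unchanged.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive a per-stage substream seed from a global seed, so adding a stage
# never perturbs the draws of earlier stages. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  offsets <- c(
    simulate = 101L, de = 211L, ranking = 307L, gsea = 401L,
    connect = 503L, null = 601L, cs = 701L
  )
  off <- offsets[[stage]]
  (as.integer(seed) * 1009L + off) %% .Machine$integer.max
}

# Round half away from zero, the convention used for two-decimal report
# columns. A tiny epsilon shields values such as 0.745 whose binary
# representation falls a hair below the half-way point.
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format an empirical p-value for display
#'
#' Empirical p-values from `n_perm` simulations cannot resolve below
#' `1 / (n_perm + 1)`; values at that floor are displayed as an inequality
#' (for example `"<1e-04"` at 10,000 simulations), matching the usual
#' reporting convention for simulation p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param n_perm Number of simulations behind each p-value.
#' @param digits Significant digits for values above the floor.
#' @return Character vector.
#' @examples
#' format_pvalue(c(1e-4, 0.23), n_perm = 10000)
#' @export
format_pvalue <- function(p, n_perm, digits = 4) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  floor_p <- 1 / (n_perm + 1)
  out <- ifelse(
    p <= floor_p + 1e-12,
    sprintf("<%.0e", 1 / n_perm),
    formatC(p, digits = digits, format = "g")
  )
  out[is.na(p)] <- NA_character_
  out
}

# Stop unless `x` is a character vector of gene identifiers, returned
# deduplicated in input order.
as_gene_vector <- function(x, what = "genes") {
  if (is.list(x) && !is.null(x$members)) x <- x$members
  if (!is.character(x)) {
    abort(sprintf("`%s` must be a character vector of gene identifiers.", what))
  }
  unique(x[!is.na(x) & nzchar(x)])
}
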