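# Weighted Kolmogorov-Smirnov-like enrichment engine: running sum, ES,
# simulation nulls, NES, empirical p-values and batch scoring with FDR.

#' Configuration for enrichment scoring
#'
#' @param weight_exponent Non-negative exponent applied to `|score|` when
#'   weighting hit increments. `1` (default) gives the weighted statistic;
#'   `0` gives the classical equal-weight Kolmogorov-Smirnov-style
#'   statistic.
#' @param n_perm Number of random-set simulations for null distributions
#'   (default 10,000).
#' @param seed Optional integer seed making all simulations reproducible;
#'   `NULL` uses the ambient RNG stream.
#' @param two_sided Logical; if `TRUE` (default) connectivity-score
#'   p-values compare `|CS|` against the null, otherwise only
#'   greater-or-equal agreement counts.
#' @return A list of class `es_config`.
#' @examples
#' es_config(n_perm = 1000, seed = 1)
#' @export
es_config <- function(weight_exponent = 1, n_perm = 10000, seed = NULL,
                      two_sided = TRUE) {
  stopifnot(
    is.numeric(weight_exponent), length(weight_exponent) == 1,
    weight_exponent >= 0,
    is.numeric(n_perm), length(n_perm) == 1, n_perm >= 1
  )
  structure(
    list(
      weight_exponent = weight_exponent,
      n_perm = as.integer(n_perm),
      seed = if (!is.null(seed)) as.integer(seed),
      two_sided = isTRUE(two_sided)
    ),
    class = "es_config"
  )
}

# Normalized hit weights for hit positions `pos` given |score|^p; when the
# weighted mass vanishes (all hit scores exactly zero) equal weights are
# used so the statistic stays defined.
hit_weights <- function(abs_scores, p) {
  w <- abs_scores^p
  s <- sum(w)
  if (s <= 0) {
    w <- rep(1, length(w))
    s <- length(w)
  }
  w / s
}

# Running-sum enrichment statistic over the full list. Returns the profile.
es_running <- function(scores, hit, p) {
  n <- length(scores)
  n_hit <- sum(hit)
  step <- numeric(n)
  step[hit] <- hit_weights(abs(scores[hit]), p)
  step[!hit] <- -1 / (n - n_hit)
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

# O(n_hit) enrichment score from sorted hit positions only; used for
# simulation nulls where the full profile is not needed. The running sum is
# piecewise linear between hits, so its extrema occur immediately after a
# hit or immediately before one; both candidate sets are examined and ties
# resolved towards the earliest list position, matching es_running().
es_fast <- function(pos, abs_scores, n, p) {
  k <- length(pos)
  w <- hit_weights(abs_scores, p)
  cw <- cumsum(w)
  miss <- 1 / (n - k)
  ahead <- (pos - seq_len(k)) * miss
  dev_at <- cw - ahead            # value at position pos_i
  dev_before <- c(0, cw[-k]) - ahead # value at position pos_i - 1
  vals <- c(dev_at, dev_before)
  at <- c(pos, pos - 1L)
  keep <- at >= 1L
  vals <- vals[keep]
  at <- at[keep]
  o <- order(at)
  vals <- vals[o]
  es <- vals[which.max(abs(vals))]
  es
}

#' Enrichment score of a gene set in a ranked list
#'
#' Walks down the ranked list accumulating a running sum: meeting a member
#' of the set ("hit") increases the sum proportionally to
#' `|score|^weight_exponent` (normalized over the set), meeting a non-member
#' decreases it by `1/(N - N_H)`. The enrichment score (ES) is the running-
#' sum value of maximal absolute deviation from zero: close to +1 when the
#' set concentrates at the top of the list, close to -1 at the bottom, and
#' near 0 when members are scattered at random. Set members absent from the
#' ranking are dropped before scoring (their count is recorded), so the
#' reported set size is the post-intersection size.
#'
#' @param ranked A `ranked_list` (see [build_ranked_list()]).
#' @param genes Character vector of gene identifiers (the gene set).
#' @param config An [es_config()].
#' @param set_name Optional label carried into the result.
#' @return An `enrichment_result`: list with elements `set_name`, `size`
#'   (post-intersection), `n_dropped`, `es`, `peak_index`, `running_sum`
#'   (length-N profile), `hit_index`, `leading_edge`, `nes`, `p_value`,
#'   `fdr` (the last three `NA` until filled by [normalize_es()],
#'   [nominal_p()] or [gsea_batch()]).
#' @examples
#' rl <- build_ranked_list(setNames(10:1, letters[1:10]))
#' enrichment_score(rl, c("a", "b", "c"))$es
#' @export
enrichment_score <- function(ranked, genes, config = es_config(),
                             set_name = "gene_set") {
  validate_ranked_list(ranked)
  genes <- as_gene_vector(genes)
  n <- nrow(ranked)
  hit <- ranked$gene %in% genes
  n_hit <- sum(hit)
  n_dropped <- length(genes) - n_hit
  if (n_hit == 0) {
    abort(sprintf("Gene set `%s` has no overlap with the ranked list.", set_name))
  }
  if (n_hit == n) {
    abort("Gene set covers the whole ranking universe; miss decrement is undefined.")
  }
  rs <- es_running(ranked$score, hit, config$weight_exponent)
  hit_index <- which(hit)
  leading <- if (rs$es >= 0) {
    ranked$gene[hit_index[hit_index <= rs$peak]]
  } else {
    ranked$gene[hit_index[hit_index >= rs$peak]]
  }
  structure(
    list(
      set_name = set_name,
      size = n_hit,
      n_dropped = n_dropped,
      es = rs$es,
      peak_index = rs$peak,
      running_sum = rs$running,
      hit_index = hit_index,
      leading_edge = leading,
      weight_exponent = config$weight_exponent,
      nes = NA_real_,
      p_value = NA_real_,
      fdr = NA_real_
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s: size %d, ES %.4f%s%s\n",
    x$set_name, x$size, x$es,
    if (!is.na(x$nes)) sprintf(", NES %.3f", x$nes) else "",
    if (!is.na(x$p_value)) sprintf(", p %.4g", x$p_value) else ""
  ))
  invisible(x)
}

#' Simulation null distribution of the enrichment score
#'
#' Draws `config$n_perm` gene sets of size `set_size` uniformly at random
#' (without replacement) from the ranking universe and records the
#' enrichment score of each: the random-set null against which observed
#' scores are normalized and tested.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets (matched to the observed set's
#'   post-intersection size).
#' @return A `null_distribution`: list with `es` (length `n_perm`),
#'   `n_perm`, `set_size`, `mode` and `seed`.
#' @examples
#' rl <- build_ranked_list(setNames(rnorm(50), paste0("g", 1:50)))
#' nd <- null_distribution(rl, 5, es_config(n_perm = 100, seed = 1))
#' range(nd$es)
#' @export
null_distribution <- function(ranked, set_size, config = es_config()) {
  validate_ranked_list(ranked)
  n <- nrow(ranked)
  set_size <- as.integer(set_size)
  if (set_size < 1 || set_size > n - 1) {
    abort(sprintf("`set_size` must be between 1 and N - 1 = %d.", n - 1))
  }
  abs_scores <- abs(ranked$score)
  p <- config$weight_exponent
  es <- with_seed_if(config$seed, {
    vapply(seq_len(config$n_perm), function(b) {
      pos <- sort.int(sample.int(n, set_size))
      es_fast(pos, abs_scores[pos], n, p)
    }, numeric(1))
  })
  structure(
    list(
      es = es, n_perm = config$n_perm, set_size = set_size,
      mode = "random-set", seed = config$seed
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d random sets of size %d (mode %s)\n",
    x$n_perm, x$set_size, x$mode
  ))
  invisible(x)
}

#' Tidy a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return Tibble with column `es`.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) tibble(es = x$es)

#' Normalized enrichment score
#'
#' Divides the observed ES by the mean magnitude of same-sign null scores,
#' adjusting for gene-set size: random sets of different sizes have
#' different typical |ES|, and the NES puts sets of different sizes on a
#' common scale. `sign(NES) = sign(ES)`.
#'
#' @param es Observed enrichment score (scalar) or an `enrichment_result`.
#' @param null A [null_distribution()] matched to the set's size.
#' @return For scalar input, the NES (or `NA` with a warning when the null
#'   contains no same-sign sample); for an `enrichment_result`, the result
#'   with `nes` filled in.
#' @examples
#' normalize_es(0.8, structure(list(es = c(0.4, -0.2)), class = "null_distribution"))
#' @export
normalize_es <- function(es, null) {
  if (inherits(es, "enrichment_result")) {
    es$nes <- normalize_es(es$es, null)
    return(es)
  }
  stopifnot(is.numeric(es), length(es) == 1, inherits(null, "null_distribution"))
  if (es == 0) {
    return(0)
  }
  same <- null$es[sign(null$es) == sign(es)]
  if (length(same) == 0) {
    warn("Null distribution has no samples with the sign of `es`; NES is NA.")
    return(NA_real_)
  }
  es / mean(abs(same))
}

#' Empirical p-value of an enrichment score
#'
#' Add-one-smoothed fraction of same-sign null scores at least as extreme
#' in magnitude as the observed ES:
#' `p = (1 + #same-sign with |ES_null| >= |ES|) / (1 + #same-sign)`.
#' The smoothing keeps p strictly positive; scores beyond every null
#' sample are best reported as below the simulation resolution (see
#' [format_pvalue()]).
#'
#' @inheritParams normalize_es
#' @return For scalar input, the p-value; for an `enrichment_result`, the
#'   result with `p_value` filled in.
#' @examples
#' nominal_p(0.9, structure(list(es = c(0.1, -0.2, 0.3)), class = "null_distribution"))
#' @export
nominal_p <- function(es, null) {
  if (inherits(es, "enrichment_result")) {
    es$p_value <- nominal_p(es$es, null)
    return(es)
  }
  stopifnot(is.numeric(es), length(es) == 1, inherits(null, "null_distribution"))
  if (length(null$es) == 0) abort("Null distribution is empty.")
  same <- null$es[sign(null$es) == sign(es)]
  (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
}

#' Score a collection of gene sets against one ranking
#'
#' Computes ES, NES and empirical p-value for every gene set in a
#' collection, then Benjamini-Hochberg-adjusts the p-values separately
#' within the positive-ES and negative-ES classes (top-enriched and
#' bottom-enriched sets are distinct families of hypotheses). Null
#' distributions are shared between sets of equal post-intersection size.
#' Sets with no overlap with the ranking are skipped with a warning.
#'
#' @inheritParams enrichment_score
#' @param collection Named list of character vectors (for example from
#'   [read_gmt()]).
#' @return A tibble with columns `name`, `size`, `es`, `nes`, `p_value`,
#'   `fdr`, sorted by decreasing NES.
#' @examples
#' rl <- build_ranked_list(setNames(20:1, paste0("g", 1:20)))
#' gsea_batch(rl,
#'   list(top = paste0("g", 1:4), bottom = paste0("g", 17:20)),
#'   es_config(n_perm = 200, seed = 1)
#' )
#' @export
gsea_batch <- function(ranked, collection, config = es_config()) {
  validate_ranked_list(ranked)
  if (!is.list(collection) || length(collection) == 0) {
    abort("`collection` must be a non-empty named list of gene sets.")
  }
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    abort("Every gene set in `collection` must be named.")
  }
  results <- list()
  for (nm in names(collection)) {
    res <- tryCatch(
      enrichment_score(ranked, collection[[nm]], config, set_name = nm),
      error = function(e) {
        warn(sprintf("Skipping gene set `%s`: %s", nm, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) results[[nm]] <- res
  }
  if (length(results) == 0) {
    abort("No gene set in `collection` overlaps the ranking.")
  }
  sizes <- vapply(results, function(r) r$size, integer(1))
  nulls <- list()
  for (s in unique(sizes)) {
    nulls[[as.character(s)]] <- null_distribution(ranked, s, config)
  }
  rows <- purrr::map(results, function(r) {
    nd <- nulls[[as.character(r$size)]]
    tibble(
      name = r$set_name,
      size = r$size,
      es = r$es,
      nes = normalize_es(r$es, nd),
      p_value = nominal_p(r$es, nd)
    )
  })
  out <- bind_rows(rows) |>
    group_by(.data$es >= 0) |>
    mutate(fdr = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    select("name", "size", "es", "nes", "p_value", "fdr") |>
    arrange(desc(.data$nes))
  out
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble with the headline statistics.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    set_name = x$set_name,
    size = x$size,
    es = x$es,
    nes = x$nes,
    p_value = x$p_value,
    fdr = x$fdr,
    peak_index = x$peak_index,
    leading_edge_size = length(x$leading_edge),
    n_dropped = x$n_dropped
  )
}

#' @rdname tidy.enrichment_result
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    es = x$es, nes = x$nes, p_value = x$p_value,
    size = x$size, weight_exponent = x$weight_exponent
  )
}
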