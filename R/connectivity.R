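# Connectivity scoring of up/down DEG signatures against a ranked list.

#' Enrichment score pair for an up/down signature
#'
#' Scores a signature's up-regulated and down-regulated gene sets
#' separately against the same ranked list, producing two full enrichment
#' results with NES and p-values from independent null distributions
#' matched to each direction's post-intersection size.
#'
#' @inheritParams enrichment_score
#' @param signature A `deg_signature` (see [load_signature()]).
#' @return Named list with elements `up` and `down`, each an
#'   `enrichment_result` (or `NULL` when that direction has no overlap
#'   with the ranking, in which case a warning is raised).
#' @examples
#' rl <- build_ranked_list(setNames(20:1, paste0("g", 1:20)))
#' sig <- load_signature(paste0("g", 1:3), paste0("g", 18:20), "toy")
#' pair <- signature_es_pair(rl, sig, es_config(n_perm = 100, seed = 1))
#' c(pair$up$es, pair$down$es)
#' @export
signature_es_pair <- function(ranked, signature, config = es_config()) {
  stopifnot(is_deg_signature(signature))
  score_dir <- function(genes, label) {
    if (length(genes) == 0 || !any(ranked$gene %in% genes)) {
      warn(sprintf(
        "Signature `%s` direction `%s` has no overlap with the ranking; its ES is unset.",
        signature$study, label
      ))
      return(NULL)
    }
    res <- enrichment_score(
      ranked, genes, config,
      set_name = paste(signature$study, label, sep = " - ")
    )
    nd <- null_distribution(ranked, res$size, config)
    res <- normalize_es(res, nd)
    nominal_p(res, nd)
  }
  list(
    up = score_dir(signature$up, "up"),
    down = score_dir(signature$down, "down")
  )
}

#' Combine an up/down enrichment-score pair into a connectivity score
#'
#' The connectivity score (CS) condenses the agreement between a published
#' signature and a new ranking into one number: `CS = (es_up - es_down)/2`
#' when the two scores have opposite signs (or either is zero), and 0 when
#' they share a sign, the convention used for signature-versus-ranking
#' matching in connectivity scoring. `CS = 1` exactly when
#' `(es_up, es_down) = (1, -1)` (perfect agreement), `-1` for perfect
#' opposition, and 0 means no agreement.
#'
#' @param es_up,es_down Enrichment scores in `[-1, 1]` for the signature's
#'   up- and down-regulated sets; vectorized.
#' @return Connectivity score(s) in `[-1, 1]`.
#' @examples
#' connectivity_score(0.93, -0.91)
#' connectivity_score(0.5, 0.3) # same sign: no agreement
#' @export
connectivity_score <- function(es_up, es_down) {
  stopifnot(is.numeric(es_up), is.numeric(es_down))
  if (any(abs(es_up) > 1, na.rm = TRUE) || any(abs(es_down) > 1, na.rm = TRUE)) {
    abort("Enrichment scores must lie in [-1, 1].")
  }
  same_sign <- sign(es_up) == sign(es_down) & es_up != 0 & es_down != 0
  ifelse(same_sign, 0, (es_up - es_down) / 2)
}

#' Simulation p-value for a connectivity score
#'
#' Draws disjoint random up/down gene-set pairs of the observed sizes from
#' the ranking universe, computes each pair's connectivity score, and
#' returns the add-one-smoothed fraction of null scores at least as
#' extreme as the observed one. Two-sided (`|CS_null| >= |CS|`) by
#' default; with `config$two_sided = FALSE` only `CS_null >= CS` counts
#' (positive agreement).
#'
#' @inheritParams enrichment_score
#' @param n_up,n_down Sizes of the up and down sets (post-intersection).
#' @param observed_cs The observed connectivity score.
#' @return The p-value, with attributes `n_perm` and `null` (the simulated
#'   null scores).
#' @examples
#' rl <- build_ranked_list(setNames(30:1, paste0("g", 1:30)))
#' cs_pvalue(rl, 3, 3, 0.9, es_config(n_perm = 200, seed = 1))
#' @export
cs_pvalue <- function(ranked, n_up, n_down, observed_cs,
                      config = es_config()) {
  validate_ranked_list(ranked)
  n <- nrow(ranked)
  n_up <- as.integer(n_up)
  n_down <- as.integer(n_down)
  stopifnot(n_up >= 1, n_down >= 1)
  if (n_up + n_down > n - 1) {
    abort("`n_up + n_down` must leave at least one gene outside the signature.")
  }
  stopifnot(is.numeric(observed_cs), length(observed_cs) == 1, abs(observed_cs) <= 1)
  abs_scores <- abs(ranked$score)
  p <- config$weight_exponent
  null_cs <- with_seed_if(config$seed, {
    vapply(seq_len(config$n_perm), function(b) {
      idx <- sample.int(n, n_up + n_down)
      up_pos <- sort.int(idx[seq_len(n_up)])
      down_pos <- sort.int(idx[n_up + seq_len(n_down)])
      connectivity_score(
        es_fast(up_pos, abs_scores[up_pos], n, p),
        es_fast(down_pos, abs_scores[down_pos], n, p)
      )
    }, numeric(1))
  })
  pv <- if (config$two_sided) {
    (1 + sum(abs(null_cs) >= abs(observed_cs))) / (1 + config$n_perm)
  } else {
    (1 + sum(null_cs >= observed_cs)) / (1 + config$n_perm)
  }
  structure(pv, n_perm = config$n_perm, null = null_cs)
}

#' Compare a panel of DEG signatures against one ranking
#'
#' The cross-study comparison: for each signature, both directions are
#' enrichment-scored (with NES and p), combined into a connectivity score,
#' and the CS is tested against a disjoint-random-signature null. Failures
#' for individual signatures (for example no overlap) are reported in the
#' `error` column and do not stop the batch.
#'
#' @inheritParams enrichment_score
#' @param signatures A list of `deg_signature` objects (a single signature
#'   is accepted).
#' @return A `study_comparison` tibble with one row per signature
#'   (`study`, `n_up`, `n_down`, `es_up`, `nes_up`, `p_up`, `es_down`,
#'   `nes_down`, `p_down`, `cs`, `p_cs`, `error`), ordered by decreasing
#'   CS.
#' @examples
#' rl <- build_ranked_list(setNames(30:1, paste0("g", 1:30)))
#' sig <- load_signature(paste0("g", 1:4), paste0("g", 27:30), "toy")
#' compare_studies(rl, list(sig), es_config(n_perm = 100, seed = 1))
#' @export
compare_studies <- function(ranked, signatures, config = es_config()) {
  if (is_deg_signature(signatures)) signatures <- list(signatures)
  if (length(signatures) == 0) abort("Supply at least one DEG signature.")
  stopifnot(all(vapply(signatures, is_deg_signature, logical(1))))
  rows <- purrr::map(signatures, function(sig) {
    row <- tibble(
      study = sig$study,
      n_up = NA_integer_, n_down = NA_integer_,
      es_up = NA_real_, nes_up = NA_real_, p_up = NA_real_,
      es_down = NA_real_, nes_down = NA_real_, p_down = NA_real_,
      cs = NA_real_, p_cs = NA_real_, error = NA_character_
    )
    tryCatch(
      {
        pair <- signature_es_pair(ranked, sig, config)
        if (!is.null(pair$up)) {
          row$n_up <- pair$up$size
          row$es_up <- pair$up$es
          row$nes_up <- pair$up$nes
          row$p_up <- pair$up$p_value
        }
        if (!is.null(pair$down)) {
          row$n_down <- pair$down$size
          row$es_down <- pair$down$es
          row$nes_down <- pair$down$nes
          row$p_down <- pair$down$p_value
        }
        if (is.null(pair$up) || is.null(pair$down)) {
          row$error <- "one direction empty after intersection; CS not computed"
        } else {
          row$cs <- connectivity_score(row$es_up, row$es_down)
          row$p_cs <- as.numeric(
            cs_pvalue(ranked, row$n_up, row$n_down, row$cs, config)
          )
        }
        row
      },
      error = function(e) {
        row$error <- conditionMessage(e)
        row
      }
    )
  })
  out <- bind_rows(rows) |> arrange(desc(.data$cs))
  class(out) <- c("study_comparison", class(tibble()))
  out
}
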