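# Domain types for rankings, gene sets and up/down DEG signatures.

#' Collapse probeset-level scores to gene-level scores
#'
#' Microarray platforms measure several probesets per gene; gene-level
#' analyses need one score per gene. Following the usual reporting rule for
#' fold changes, the probeset with the largest fold change is retained for
#' each gene. Because fold changes are signed, "largest" is interpreted as
#' largest absolute log2 fold change with the sign preserved
#' (`method = "absolute"`, the default), so strongly down-regulated genes
#' are not masked by a weak positive probeset; `method = "signed"` retains
#' the numerically largest score instead.
#'
#' @param table Data frame with columns `probeset_id`, `gene_id`, `score`
#'   (signed, log2 fold-change units). `gene_id` may be `NA` for unmapped
#'   probesets; such rows are dropped and counted.
#' @param method `"absolute"` (largest `|score|`, sign kept) or `"signed"`
#'   (largest score).
#' @return A tibble with columns `gene_id`, `score`, one row per mapped
#'   gene, with attribute `n_unmapped` giving the number of dropped rows.
#' @examples
#' collapse_probesets(tibble::tibble(
#'   probeset_id = c("ps1", "ps2"), gene_id = c("GACT", "GACT"),
#'   score = c(3, 1.2)
#' ))
#' @export
collapse_probesets <- function(table, method = c("absolute", "signed")) {
  method <- match.arg(method)
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("`table` must be a non-empty data frame of probeset scores.")
  }
  stopifnot(all(c("probeset_id", "gene_id", "score") %in% names(table)))
  if (anyDuplicated(table$probeset_id)) {
    abort("`probeset_id` values must be unique.")
  }
  mapped <- dplyr::filter(table, !is.na(.data$gene_id) & nzchar(.data$gene_id))
  n_unmapped <- nrow(table) - nrow(mapped)
  if (nrow(mapped) == 0) {
    abort("No probeset in `table` maps to a gene identifier; check the probeset-to-gene mapping.")
  }
  key <- if (method == "absolute") quote(abs(.data$score)) else quote(.data$score)
  out <- mapped |>
    group_by(.data$gene_id) |>
    slice_max(order_by = !!key, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$gene_id) |>
    select("gene_id", "score")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build a ranked gene list from gene-level scores
#'
#' Orders genes by decreasing signed score (log2 fold change); ties are
#' broken lexicographically by gene identifier so the ranking is fully
#' deterministic. The ranked list is the substrate of every enrichment
#' computation: position 1 is the most up-regulated gene and position N
#' the most down-regulated.
#'
#' @param scores A data frame with columns `gene` and `score`, or a named
#'   numeric vector of scores.
#' @return A `ranked_list`: a tibble with columns `gene`, `score`, sorted
#'   by non-increasing score.
#' @examples
#' build_ranked_list(c(A = 2, B = -1, C = 5))
#' @export
build_ranked_list <- function(scores) {
  if (is.numeric(scores)) {
    if (is.null(names(scores))) {
      abort("A numeric `scores` vector must be named by gene.")
    }
    scores <- tibble(gene = names(scores), score = unname(scores))
  }
  if (!is.data.frame(scores)) {
    abort("`scores` must be a data frame or a named numeric vector.")
  }
  df <- as_tibble(scores)
  if (!all(c("gene", "score") %in% names(df))) {
    if (all(c("gene_id", "score") %in% names(df))) {
      df <- rename(df, gene = "gene_id")
    } else {
      abort("`scores` must have columns `gene` (or `gene_id`) and `score`.")
    }
  }
  df <- select(df, "gene", "score")
  if (nrow(df) < 2) abort("A ranked list needs at least 2 genes.")
  if (anyDuplicated(df$gene)) {
    dup <- unique(df$gene[duplicated(df$gene)])
    abort(sprintf(
      "Duplicate gene identifiers in `scores`: %s",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  if (!is.numeric(df$score) || anyNA(df$score) || any(!is.finite(df$score))) {
    abort("`score` must be finite and numeric for every gene.")
  }
  out <- df[order(-df$score, df$gene, method = "radix"), ]
  new_ranked_list(out)
}

new_ranked_list <- function(df) {
  structure(df, class = c("ranked_list", class(tibble())))
}

#' Test or validate a ranked list
#'
#' @param x Object to test.
#' @return `is_ranked_list()` returns a logical; `validate_ranked_list()`
#'   returns `x` invisibly or fails.
#' @export
is_ranked_list <- function(x) inherits(x, "ranked_list")

#' @rdname is_ranked_list
#' @export
validate_ranked_list <- function(x) {
  stopifnot(is.data.frame(x), all(c("gene", "score") %in% names(x)))
  if (nrow(x) < 2) abort("Ranked list must contain at least 2 genes.")
  if (anyDuplicated(x$gene)) abort("Ranked list genes must be unique.")
  if (is.unsorted(rev(x$score))) abort("Ranked list scores must be non-increasing.")
  invisible(x)
}

#' Construct an up/down DEG signature
#'
#' A differentially-expressed-gene (DEG) signature is a pair of gene sets
#' (up-regulated, down-regulated) published by a study; here the pair is
#' treated as a pathway-like gene set for enrichment scoring. Genes listed
#' in both directions are contradictory, so they are removed from both
#' sets and reported via the `conflicting` attribute and a warning.
#'
#' @param up,down Character vectors of gene identifiers (either may be
#'   empty, but not both).
#' @param study_name Label for the originating study.
#' @return A `deg_signature`: list with elements `study`, `up`, `down`.
#' @examples
#' load_signature(c("A", "B"), c("C"), "toy")
#' @export
load_signature <- function(up, down, study_name = "signature") {
  up <- as_gene_vector(up, "up")
  down <- as_gene_vector(down, "down")
  conflicting <- intersect(up, down)
  if (length(conflicting) > 0) {
    warn(sprintf(
      "%d gene(s) listed as both up- and down-regulated removed from `%s`: %s",
      length(conflicting), study_name,
      paste(head(conflicting, 5), collapse = ", ")
    ))
    up <- setdiff(up, conflicting)
    down <- setdiff(down, conflicting)
  }
  if (length(up) == 0 && length(down) == 0) {
    abort("A DEG signature needs at least one up- or down-regulated gene.")
  }
  structure(
    list(study = study_name, up = up, down = down),
    conflicting = conflicting,
    class = "deg_signature"
  )
}

#' @rdname load_signature
#' @param x Object to test.
#' @export
is_deg_signature <- function(x) inherits(x, "deg_signature")

#' @export
print.deg_signature <- function(x, ...) {
  cat(sprintf(
    "<deg_signature> %s: %d up / %d down gene(s)\n",
    x$study, length(x$up), length(x$down)
  ))
  invisible(x)
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %d genes, scores in [%.3g, %.3g]\n",
              nrow(x), min(x$score), max(x$score)))
  NextMethod()
}

#' Tidy a DEG signature into a gene/direction table
#'
#' @param x A `deg_signature`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `direction` (`"up"`/`"down"`) and
#'   `study`.
#' @method tidy deg_signature
#' @export
tidy.deg_signature <- function(x, ...) {
  tibble(
    gene = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down))),
    study = x$study
  )
}
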