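# Identifier harmonization and k-way DEG-list intersection ("Venn
# diagram approach") across platforms.

#' Gene universe common to several platforms
#'
#' Cross-platform list comparisons are only meaningful on genes measurable
#' by every platform; this returns the intersection of the platforms'
#' mapped gene sets.
#'
#' @param maps List (length >= 2) of platform maps: each either a data
#'   frame with columns `probeset_id`, `gene_id`, or a character vector of
#'   gene identifiers.
#' @return Sorted character vector of common gene identifiers.
#' @examples
#' common_universe(list(c("A", "B", "C"), c("B", "C", "D")))
#' @export
common_universe <- function(maps) {
  if (!is.list(maps) || length(maps) < 2) {
    abort("Supply at least 2 platform maps.")
  }
  gene_sets <- purrr::map(maps, function(m) {
    if (is.data.frame(m)) {
      stopifnot("gene_id" %in% names(m))
      if ("probeset_id" %in% names(m) && anyDuplicated(m$probeset_id)) {
        abort("`probeset_id` values must be unique within a platform map.")
      }
      as_gene_vector(m$gene_id, "gene_id")
    } else {
      as_gene_vector(m, "platform map")
    }
  })
  out <- sort(Reduce(intersect, gene_sets))
  if (length(out) == 0) abort("The platforms share no gene identifiers.")
  out
}

#' Region counts for a k-way gene-list comparison
#'
#' Classifies every gene in the union of the lists by its membership
#' vector and counts each of the `2^k - 1` non-empty Venn regions. Genes
#' outside `universe` (when given) are dropped and counted.
#'
#' @param lists Named list of 2 to 6 character vectors (for example the
#'   up-regulated DEG lists of k studies).
#' @param universe Optional character vector restricting the comparison to
#'   genes measurable in all studies.
#' @return A `venn_report`: tibble with one row per region (`mask`, a
#'   string of 0/1 membership flags in list order; `studies`, the
#'   "+"-joined member names; `count`; `genes`, a list-column), with
#'   attributes `k`, `universe_size`, `totals` and `dropped`.
#' @examples
#' venn_counts(list(s1 = c("A", "B"), s2 = c("B", "C"), s3 = c("B", "D")))
#' @export
venn_counts <- function(lists, universe = NULL) {
  k <- length(lists)
  if (k < 2 || k > 6) abort("`lists` must contain between 2 and 6 gene lists.")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("list", seq_len(k))
  }
  lists <- purrr::map(lists, as_gene_vector)
  dropped <- rep(0L, k)
  names(dropped) <- names(lists)
  if (!is.null(universe)) {
    universe <- as_gene_vector(universe, "universe")
    kept <- purrr::map(lists, intersect, y = universe)
    dropped <- lengths(lists) - lengths(kept)
    lists <- kept
  }
  union_genes <- sort(unique(unlist(lists, use.names = FALSE)))
  membership <- vapply(
    lists, function(l) union_genes %in% l,
    logical(length(union_genes))
  )
  membership <- matrix(membership, nrow = length(union_genes), ncol = k)
  mask_of <- function(bits) paste(as.integer(bits), collapse = "")
  gene_mask <- apply(membership, 1, mask_of)
  all_masks <- vapply(
    seq_len(2^k - 1),
    function(i) mask_of(as.logical(bitwAnd(i, 2^(seq_len(k) - 1)))),
    character(1)
  )
  regions <- tibble(
    mask = all_masks,
    studies = vapply(all_masks, function(m) {
      paste(names(lists)[strsplit(m, "")[[1]] == "1"], collapse = "+")
    }, character(1), USE.NAMES = FALSE),
    count = vapply(all_masks, function(m) {
      sum(gene_mask == m)
    }, integer(1), USE.NAMES = FALSE),
    genes = unname(purrr::map(all_masks, function(m) union_genes[gene_mask == m]))
  )
  structure(
    regions,
    k = k,
    universe_size = if (is.null(universe)) NA_integer_ else length(universe),
    totals = setNames(lengths(lists), names(lists)),
    dropped = dropped,
    class = c("venn_report", class(tibble()))
  )
}

#' @export
print.venn_report <- function(x, ...) {
  cat(sprintf(
    "<venn_report> %d lists, %d genes in union\n",
    attr(x, "k"), sum(x$count)
  ))
  NextMethod()
}

#' Tidy a Venn report
#'
#' @param x A `venn_report`.
#' @param ... Unused.
#' @return The region table without the list-column.
#' @method tidy venn_report
#' @export
tidy.venn_report <- function(x, ...) {
  as_tibble(x)[c("mask", "studies", "count")]
}

#' Genes present in every list
#'
#' The consensus (all-studies) intersection, i.e. the central Venn region.
#'
#' @param lists List (length >= 2) of character vectors.
#' @return Sorted character vector of genes common to all lists.
#' @examples
#' consensus_list(list(c("A", "B"), c("B", "C"), c("B")))
#' @export
consensus_list <- function(lists) {
  if (!is.list(lists) || length(lists) < 2) abort("Supply at least 2 gene lists.")
  sort(Reduce(intersect, purrr::map(lists, as_gene_vector)))
}
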