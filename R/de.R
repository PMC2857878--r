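# Paired differential-expression stage: fold changes, (moderated) paired
# t statistics, multiple-testing adjustment, DEG selection and the
# low-intensity / filtering utilities.

#' Construct a paired expression object
#'
#' Holds a log2 expression matrix together with the lesional/non-lesional
#' pairing of its columns (one pair per patient). All downstream paired
#' statistics contrast the two members of each pair.
#'
#' @param exprs Numeric matrix of log2 expression values, features in rows
#'   (rownames required), samples in columns (colnames required).
#' @param pairing Data frame with columns `patient`, `lesional`,
#'   `nonlesional`; the latter two name columns of `exprs`.
#' @return A `paired_expression` object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))
#' )
#' paired_expression(m, data.frame(
#'   patient = c("p1", "p2"), lesional = c("s1", "s3"),
#'   nonlesional = c("s2", "s4")
#' ))
#' @export
paired_expression <- function(exprs, pairing) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    abort("`exprs` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    abort("`exprs` needs both rownames (features) and colnames (samples).")
  }
  if (any(!is.finite(exprs))) abort("`exprs` must contain only finite values.")
  pairing <- as_tibble(pairing)
  req <- c("patient", "lesional", "nonlesional")
  if (!all(req %in% names(pairing))) {
    abort("`pairing` needs columns `patient`, `lesional`, `nonlesional`.")
  }
  if (nrow(pairing) < 2) abort("At least 2 patient pairs are required.")
  used <- c(pairing$lesional, pairing$nonlesional)
  missing <- setdiff(used, colnames(exprs))
  if (length(missing) > 0) {
    bad <- pairing$patient[pairing$lesional %in% missing |
      pairing$nonlesional %in% missing]
    abort(sprintf(
      "Pair member(s) missing from the expression matrix for patient(s): %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  if (anyDuplicated(used)) {
    abort("Each sample may appear in exactly one pair slot.")
  }
  structure(
    list(exprs = exprs, pairing = pairing[req], n_pairs = nrow(pairing)),
    class = "paired_expression"
  )
}

#' @export
print.paired_expression <- function(x, ...) {
  cat(sprintf(
    "<paired_expression> %d features x %d samples (%d lesional/non-lesional pairs)\n",
    nrow(x$exprs), ncol(x$exprs), x$n_pairs
  ))
  invisible(x)
}

# Matrix of within-pair differences (lesional - non-lesional), one column
# per patient.
pair_differences <- function(pe) {
  stopifnot(inherits(pe, "paired_expression"))
  d <- pe$exprs[, pe$pairing$lesional, drop = FALSE] -
    pe$exprs[, pe$pairing$nonlesional, drop = FALSE]
  colnames(d) <- pe$pairing$patient
  d
}

#' Per-feature paired log2 fold change
#'
#' On log2 data the fold change of lesional over non-lesional tissue is
#' the mean within-pair difference of log2 expression.
#'
#' @param pe A [paired_expression()].
#' @return Tibble with columns `feature`, `log2_fch`.
#' @export
paired_log2_fch <- function(pe) {
  d <- pair_differences(pe)
  tibble(feature = rownames(d), log2_fch = unname(rowMeans(d)))
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; needed for the method-of-moments fit of the
# variance prior.
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1, is.finite(y), y > 0)
  if (y > 1e7) {
    return(1 / sqrt(y))
  }
  if (y < 1e-6) {
    return(1 / y)
  }
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

# Method-of-moments fit of a scaled inverse-chi-square prior for
# per-feature variances: log s2_g is matched to the moments of the implied
# log-F distribution. Returns prior df d0 (possibly Inf) and prior
# variance s0sq.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) abort("All features have zero variance; cannot fit a variance prior.")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Paired t statistics, optionally variance-moderated
#'
#' With `moderation = FALSE`, the classical paired t-test per feature
#' (`df = n_pairs - 1`). With `moderation = TRUE` (default), per-feature
#' variances of the paired differences are shrunk toward a prior variance
#' by empirical Bayes:
#' `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)` with `d = n_pairs - 1`,
#' and the moderated t uses `df = d0 + d`. The prior `(d0, s0^2)` is
#' estimated from all features by closed-form moment matching on
#' `log s2`. Variance moderation stabilizes the many near-zero sample
#' variances seen with few pairs and is standard practice for microarray
#' differential expression.
#'
#' @param pe A [paired_expression()].
#' @param moderation Logical; shrink variances (default `TRUE`).
#' @param prior Optional list with fixed `d0` and `s0sq`, bypassing
#'   estimation.
#' @return Tibble with columns `feature`, `log2_fch`, `t`, `df`, `p`, and
#'   attributes `d0`, `s0sq` when moderated.
#' @examples
#' m <- matrix(rnorm(300, 8), 50, 6,
#'   dimnames = list(paste0("g", 1:50), paste0("s", 1:6))
#' )
#' pe <- paired_expression(m, data.frame(
#'   patient = paste0("p", 1:3),
#'   lesional = paste0("s", c(1, 3, 5)),
#'   nonlesional = paste0("s", c(2, 4, 6))
#' ))
#' head(moderated_paired_t(pe))
#' @export
moderated_paired_t <- function(pe, moderation = TRUE, prior = NULL) {
  d <- pair_differences(pe)
  n <- ncol(d)
  fch <- unname(rowMeans(d))
  s2 <- unname(rowSums((d - fch)^2)) / (n - 1)
  df_resid <- n - 1
  if (!moderation) {
    tt <- fch / sqrt(s2 / n)
    df_total <- rep(df_resid, length(fch))
  } else {
    pr <- prior %||% tryCatch(
      fit_variance_prior(s2, df_resid),
      error = function(e) {
        if (grepl("zero variance", conditionMessage(e))) stop(e)
        NULL
      }
    )
    if (is.null(pr) || !is.finite(pr$s0sq) || is.nan(pr$d0)) {
      warn("Variance-prior estimation failed; falling back to the unmoderated paired t-test.")
      return(moderated_paired_t(pe, moderation = FALSE))
    }
    if (is.infinite(pr$d0)) {
      s2_post <- rep(pr$s0sq, length(s2))
      df_total <- rep(Inf, length(fch))
    } else {
      s2_post <- (pr$d0 * pr$s0sq + df_resid * s2) / (pr$d0 + df_resid)
      df_total <- rep(pr$d0 + df_resid, length(fch))
    }
    tt <- fch / sqrt(s2_post / n)
  }
  p <- 2 * pt(-abs(tt), df_total)
  # Exactly constant differences give infinite t; flag and floor p instead
  # of propagating 0/NaN.
  degenerate <- !is.finite(tt) | p == 0
  p[p == 0] <- .Machine$double.xmin
  p[is.nan(p)] <- 1
  out <- tibble(
    feature = rownames(d), log2_fch = fch, t = tt,
    df = df_total, p = p, degenerate_variance = degenerate
  )
  if (moderation) {
    attr(out, "d0") <- pr$d0
    attr(out, "s0sq") <- pr$s0sq
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (a validating wrapper around [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
    any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must be numeric values in [0, 1] without NAs.")
  }
  p.adjust(pvals, method = "BH")
}

#' Full per-feature differential-expression table
#'
#' Convenience wrapper combining [moderated_paired_t()], [bh_adjust()] and
#' [low_intensity_fraction()] into the per-feature statistics table used
#' by DEG selection and ranking.
#'
#' @inheritParams moderated_paired_t
#' @param low_threshold Log2 expression below which a sample counts as
#'   low-intensity (default 4).
#' @return Tibble with columns `feature`, `log2_fch`, `t`, `df`, `p`,
#'   `fdr`, `low_intensity_fraction`.
#' @export
de_stats <- function(pe, moderation = TRUE, low_threshold = 4) {
  stats <- moderated_paired_t(pe, moderation = moderation)
  stats$fdr <- bh_adjust(stats$p)
  low <- low_intensity_fraction(pe, threshold = low_threshold)
  out <- dplyr::left_join(stats, low, by = "feature")
  out <- out[c(
    "feature", "log2_fch", "t", "df", "p", "fdr", "degenerate_variance",
    "low_intensity_fraction"
  )]
  attr(out, "d0") <- attr(stats, "d0")
  attr(out, "s0sq") <- attr(stats, "s0sq")
  out
}

#' Select differentially expressed genes
#'
#' Applies the conventional cutoffs: FDR below `fdr_threshold` and linear
#' fold change strictly greater than `fch_threshold` ("more than 2-fold"),
#' i.e. `|log2 FCH| > log2(fch_threshold)`. Boundary features sitting
#' exactly at the threshold are excluded.
#'
#' @param stats Per-feature table with columns `feature` (or `gene`),
#'   `log2_fch` and `fdr` (see [de_stats()]).
#' @param fch_threshold Linear fold-change cutoff (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param study_name Label for the resulting signature.
#' @return A `deg_signature` with the up- and down-regulated genes.
#' @export
select_deg <- function(stats, fch_threshold = 2, fdr_threshold = 0.05,
                       study_name = "study") {
  stopifnot(is.data.frame(stats), nrow(stats) > 0)
  if (!"feature" %in% names(stats) && "gene" %in% names(stats)) {
    stats <- rename(stats, feature = "gene")
  }
  stopifnot(all(c("feature", "log2_fch", "fdr") %in% names(stats)))
  log2_thr <- log2(fch_threshold)
  sig <- stats$fdr < fdr_threshold
  up <- stats$feature[sig & stats$log2_fch > log2_thr]
  down <- stats$feature[sig & stats$log2_fch < -log2_thr]
  if (length(up) == 0 && length(down) == 0) {
    warn("No feature passes the DEG thresholds; returning an empty signature.")
    sig <- structure(
      list(study = study_name, up = character(), down = character()),
      conflicting = character(), class = "deg_signature"
    )
    return(sig)
  }
  load_signature(up, down, study_name)
}

#' Fraction of samples with low expression, per feature
#'
#' Microarray fold changes are unreliable for transcripts expressed near
#' background; a feature's percentage of samples with log2 expression
#' strictly below `threshold` (default 4) flags such cases.
#'
#' @param x A [paired_expression()] or a numeric matrix with feature
#'   rownames.
#' @param threshold Log2 expression cutoff (default 4).
#' @return Tibble with columns `feature`, `low_intensity_fraction`
#'   (percent, 0-100).
#' @export
low_intensity_fraction <- function(x, threshold = 4) {
  m <- if (inherits(x, "paired_expression")) x$exprs else x
  stopifnot(is.matrix(m), is.numeric(m), !is.null(rownames(m)))
  tibble(
    feature = rownames(m),
    low_intensity_fraction = unname(100 * rowMeans(m < threshold))
  )
}

#' Filter unreliable features from an expression matrix
#'
#' Removes features that are low-expressed in more than
#' `max_low_fraction` of samples (log2 expression below `min_expr`) or
#' whose variance falls below `min_variance`. Both comparisons are strict,
#' so `expression_filter(pe, 0, 0, 0)` is the identity. A per-rule report
#' is attached as the `filter_report` attribute.
#'
#' @param pe A [paired_expression()].
#' @param min_expr Log2 expression defining "low" (default 4).
#' @param max_low_fraction Largest tolerated fraction of low samples
#'   (default 0.9).
#' @param min_variance Smallest tolerated per-feature variance
#'   (default 1e-3).
#' @return A filtered `paired_expression`.
#' @export
expression_filter <- function(pe, min_expr = 4, max_low_fraction = 0.9,
                              min_variance = 1e-3) {
  stopifnot(inherits(pe, "paired_expression"))
  m <- pe$exprs
  low_frac <- rowMeans(m < min_expr)
  v <- apply(m, 1, var)
  drop_low <- low_frac > max_low_fraction
  drop_var <- v < min_variance
  keep <- !(drop_low | drop_var)
  if (!any(keep)) abort("Expression filter removed every feature; relax the thresholds.")
  out <- paired_expression(m[keep, , drop = FALSE], pe$pairing)
  attr(out, "filter_report") <- tibble(
    rule = c("low_expression", "low_variance"),
    removed = c(sum(drop_low), sum(drop_var & !drop_low)),
    threshold = c(max_low_fraction, min_variance)
  )
  out
}

#' Convert between log2 and linear fold change
#'
#' @param x Log2 fold change(s).
#' @return `2^x`, the linear fold change.
#' @examples
#' log2fch_to_linear(6.17) # ~71.9-fold
#' @export
log2fch_to_linear <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  2^x
}
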