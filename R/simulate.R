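# Synthetic two-study generator: paired lesional/non-lesional log2
# expression for two studies sharing a planted disease signature, with
# per-study effect jitter and partially overlapping platforms.

#' Configuration for the two-study simulation
#'
#' Defaults emulate a pair of moderately sized paired-design microarray
#' studies of the same disease: a shared signature of 300 up- and 300
#' down-regulated genes with 4-fold (2 log2 units) average effects, a
#' between-study jitter on each gene's realized effect (laboratory,
#' platform and protocol differences), unit-variance log2 noise, 15 and 16
#' patient pairs, platforms sharing 80% of the gene universe, and a tenth
#' of genes expressed near the low-intensity threshold of 4 log2 units.
#'
#' @param n_genes Number of genes in the full universe.
#' @param n_signature_up,n_signature_down Planted signature sizes.
#' @param effect_log2 Mean |log2 effect| of signature genes.
#' @param effect_sd_between_studies SD of the per-study jitter added to
#'   each signature gene's effect.
#' @param noise_sd SD of the log2 noise added to each measurement.
#' @param n_pairs_study_a,n_pairs_study_b Patient pairs per study.
#' @param platform_shared_fraction Fraction of the gene universe present
#'   on both platforms; the remainder is split evenly into
#'   platform-private genes.
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline log2
#'   expression for ordinarily expressed genes.
#' @param low_expression_fraction Fraction of genes whose baseline is
#'   drawn near the low-intensity threshold.
#' @param low_expression_mean,low_expression_sd Baseline distribution for
#'   those low-expression genes.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_signature_up = 300,
                       n_signature_down = 300,
                       effect_log2 = 2,
                       effect_sd_between_studies = 0.5,
                       noise_sd = 1,
                       n_pairs_study_a = 15,
                       n_pairs_study_b = 16,
                       platform_shared_fraction = 0.8,
                       baseline_mean = 7,
                       baseline_sd = 1,
                       low_expression_fraction = 0.1,
                       low_expression_mean = 3.5,
                       low_expression_sd = 0.5,
                       seed = NULL) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_signature_up = as.integer(n_signature_up),
    n_signature_down = as.integer(n_signature_down),
    effect_log2 = effect_log2,
    effect_sd_between_studies = effect_sd_between_studies,
    noise_sd = noise_sd,
    n_pairs_study_a = as.integer(n_pairs_study_a),
    n_pairs_study_b = as.integer(n_pairs_study_b),
    platform_shared_fraction = platform_shared_fraction,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    low_expression_fraction = low_expression_fraction,
    low_expression_mean = low_expression_mean,
    low_expression_sd = low_expression_sd,
    seed = if (!is.null(seed)) as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 10,
    cfg$n_signature_up >= 0, cfg$n_signature_down >= 0,
    cfg$n_signature_up < cfg$n_genes / 2,
    cfg$n_signature_down < cfg$n_genes / 2,
    cfg$effect_log2 >= 0,
    cfg$effect_sd_between_studies >= 0,
    cfg$noise_sd > 0,
    cfg$n_pairs_study_a >= 2, cfg$n_pairs_study_b >= 2,
    cfg$platform_shared_fraction > 0, cfg$platform_shared_fraction <= 1,
    cfg$low_expression_fraction >= 0, cfg$low_expression_fraction <= 1
  )
  structure(cfg, class = "sim_config")
}

simulate_one_study <- function(genes, baseline, delta, n_pairs, noise_sd,
                               study_label) {
  n_g <- length(genes)
  nonles <- baseline +
    matrix(rnorm(n_g * n_pairs, sd = noise_sd), n_g, n_pairs)
  les <- nonles + delta +
    matrix(rnorm(n_g * n_pairs, sd = noise_sd), n_g, n_pairs)
  patients <- sprintf("%s_p%02d", study_label, seq_len(n_pairs))
  les_names <- paste0(patients, "_LS")
  nonles_names <- paste0(patients, "_NL")
  exprs <- cbind(les, nonles)
  dimnames(exprs) <- list(genes, c(les_names, nonles_names))
  paired_expression(
    exprs,
    tibble(patient = patients, lesional = les_names, nonlesional = nonles_names)
  )
}

#' Simulate two paired-design studies sharing a planted signature
#'
#' Generates, per study, a paired lesional/non-lesional log2 expression
#' matrix. For every gene and patient the non-lesional value is
#' `baseline_g + noise`; the lesional value adds the study's realized
#' effect `delta` for that gene plus independent pair noise. Signature
#' genes have `delta = +/-effect_log2 + jitter` with the jitter drawn
#' independently per study (`effect_sd_between_studies`); all other genes
#' have `delta = 0`. Each study observes only its platform's genes: a
#' shared fraction of the universe plus platform-private genes.
#'
#' @param config A [sim_config()].
#' @return A `two_study_simulation`: list with `study_a`, `study_b`
#'   ([paired_expression()] objects), `truth` (elements `true_up`,
#'   `true_down`, and `effects`, a tibble of per-study realized effects
#'   with `NA` for genes off a platform), `platforms` (character vectors
#'   `study_a`, `study_b`), and `config`.
#' @examples
#' sim <- simulate_two_studies(sim_config(
#'   n_genes = 200, n_signature_up = 20,
#'   n_signature_down = 20, seed = 1
#' ))
#' sim$study_a
#' @export
simulate_two_studies <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    n <- config$n_genes
    genes <- sprintf("g%05d", seq_len(n))
    n_low <- round(config$low_expression_fraction * n)
    low_genes <- sample(genes, n_low)
    baseline <- setNames(
      rnorm(n, config$baseline_mean, config$baseline_sd), genes
    )
    baseline[low_genes] <- rnorm(
      n_low, config$low_expression_mean, config$low_expression_sd
    )
    sig_genes <- sample(genes, config$n_signature_up + config$n_signature_down)
    true_up <- sort(sig_genes[seq_len(config$n_signature_up)])
    true_down <- sort(sig_genes[config$n_signature_up +
      seq_len(config$n_signature_down)])
    base_effect <- setNames(numeric(n), genes)
    base_effect[true_up] <- config$effect_log2
    base_effect[true_down] <- -config$effect_log2
    n_shared <- round(config$platform_shared_fraction * n)
    shared <- sample(genes, n_shared)
    rest <- setdiff(genes, shared)
    private_a <- rest[seq_len(floor(length(rest) / 2))]
    private_b <- setdiff(rest, private_a)
    platform_a <- sort(c(shared, private_a))
    platform_b <- sort(c(shared, private_b))
    realized <- function(platform) {
      eff <- base_effect[platform]
      planted <- eff != 0
      eff[planted] <- eff[planted] +
        rnorm(sum(planted), 0, config$effect_sd_between_studies)
      eff
    }
    delta_a <- realized(platform_a)
    delta_b <- realized(platform_b)
    study_a <- simulate_one_study(
      platform_a, baseline[platform_a], delta_a,
      config$n_pairs_study_a, config$noise_sd, "A"
    )
    study_b <- simulate_one_study(
      platform_b, baseline[platform_b], delta_b,
      config$n_pairs_study_b, config$noise_sd, "B"
    )
    effects <- tibble(
      gene = genes,
      planted = ifelse(genes %in% true_up, "up",
        ifelse(genes %in% true_down, "down", "none")
      ),
      effect_a = unname(delta_a[genes]),
      effect_b = unname(delta_b[genes])
    )
    structure(
      list(
        study_a = study_a,
        study_b = study_b,
        truth = list(true_up = true_up, true_down = true_down, effects = effects),
        platforms = list(study_a = platform_a, study_b = platform_b),
        config = config
      ),
      class = "two_study_simulation"
    )
  })
}

#' @export
print.two_study_simulation <- function(x, ...) {
  cat(sprintf(
    "<two_study_simulation> %d genes (%d shared), signature %d up / %d down, %d + %d pairs\n",
    x$config$n_genes,
    length(intersect(x$platforms$study_a, x$platforms$study_b)),
    x$config$n_signature_up, x$config$n_signature_down,
    x$config$n_pairs_study_a, x$config$n_pairs_study_b
  ))
  invisible(x)
}

#' Draw a random up/down signature
#'
#' Uniform disjoint draws without replacement from a gene universe; the
#' null generator behind connectivity-score p-values.
#'
#' @param universe Character vector of gene identifiers.
#' @param n_up,n_down Set sizes.
#' @param seed Optional integer seed.
#' @param study_name Label for the signature.
#' @return A `deg_signature`.
#' @examples
#' random_signature(paste0("g", 1:100), 5, 5, seed = 1)
#' @export
random_signature <- function(universe, n_up, n_down, seed = NULL,
                             study_name = "random") {
  universe <- as_gene_vector(universe, "universe")
  n_up <- as.integer(n_up)
  n_down <- as.integer(n_down)
  stopifnot(n_up >= 0, n_down >= 0, n_up + n_down >= 1)
  if (n_up + n_down > length(universe)) {
    abort("`n_up + n_down` exceeds the universe size.")
  }
  with_seed_if(seed, {
    draw <- sample(universe, n_up + n_down)
    structure(
      list(
        study = study_name,
        up = sort(draw[seq_len(n_up)]),
        down = sort(draw[n_up + seq_len(n_down)])
      ),
      conflicting = character(),
      class = "deg_signature"
    )
  })
}
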