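test_that("top-k and bottom-k sets reach ES = +1 / -1 exactly", {
  rl <- make_ranking(50, seed = 1)
  for (k in c(1, 5, 20)) {
    top <- enrichment_score(rl, rl$gene[1:k])
    bottom <- enrichment_score(rl, rl$gene[(50 - k + 1):50])
    expect_equal(top$es, 1.0, tolerance = 1e-12)
    expect_equal(bottom$es, -1.0, tolerance = 1e-12)
  }
})

test_that("ES matches the step-by-step oracle on a printed 10-gene case", {
  scores <- c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5)
  rl <- build_ranked_list(stats::setNames(scores, sprintf("g%02d", 1:10)))
  set_genes <- rl$gene[c(1, 3, 10)]
  res <- enrichment_score(rl, set_genes)
  hit <- rl$gene %in% set_genes
  ora <- oracle_es(rl$score, hit, 1)
  expect_equal(res$es, ora$es, tolerance = 1e-12)
  expect_equal(res$running_sum, ora$running, tolerance = 1e-12)
  expect_equal(res$peak_index, ora$peak)
})

test_that("running sum has N steps, ends at zero, and peak defines the ES", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:300, 1)
    rl <- make_ranking(n)
    k <- sample.int(n - 1, 1)
    res <- enrichment_score(rl, sample(rl$gene, k))
    expect_length(res$running_sum, n)
    expect_lt(abs(res$running_sum[n]), 1e-9)
    expect_equal(res$es, res$running_sum[res$peak_index])
    expect_equal(max(abs(res$running_sum)), abs(res$es))
    expect_gte(res$es, -1)
    expect_lte(res$es, 1)
  }
})

test_that("ES is antisymmetric under score negation with list reversal", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(10:100, 1)
    scores <- stats::rnorm(n)
    genes <- sprintf("g%04d", seq_len(n))
    rl <- build_ranked_list(stats::setNames(scores, genes))
    k <- sample.int(n - 2, 1) + 1
    set_genes <- sample(genes, k)
    rl_neg <- build_ranked_list(stats::setNames(-scores, genes))
    expect_equal(
      enrichment_score(rl, set_genes)$es,
      -enrichment_score(rl_neg, set_genes)$es,
      tolerance = 1e-12
    )
  }
})

test_that("ES is invariant to positive rescaling of the scores", {
  rl <- make_ranking(80, seed = 17)
  set_genes <- sample(rl$gene, 12)
  scaled <- build_ranked_list(stats::setNames(rl$score * 37.5, rl$gene))
  expect_equal(
    enrichment_score(rl, set_genes)$es,
    enrichment_score(scaled, set_genes)$es,
    tolerance = 1e-12
  )
})

test_that("weight 0 recovers the classical KS-style statistic", {
  set.seed(19)
  cfg <- es_config(weight_exponent = 0)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    rl <- make_ranking(n)
    k <- sample.int(n - 1, 1)
    set_genes <- sample(rl$gene, k)
    hit <- rl$gene %in% set_genes
    expect_equal(
      enrichment_score(rl, set_genes, cfg)$es,
      oracle_ks_unweighted(hit),
      tolerance = 1e-12
    )
  }
})

test_that("engine equals the brute-force oracle on exhaustive small instances", {
  # every subset of sizes 1..4 on a fixed 12-gene score grid
  scores <- c(6, 5, 4, 3, 2, 1, 0.5, -0.5, -2, -3, -4, -6)
  rl <- build_ranked_list(stats::setNames(scores, sprintf("g%02d", 1:12)))
  for (k in 1:4) {
    combos <- utils::combn(12, k)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      hit <- seq_len(12) %in% idx
      res <- enrichment_score(rl, rl$gene[idx])
      ora <- oracle_es(rl$score, hit, 1)
      expect_es_matches_oracle(res$es, ora)
    }
  }
})

test_that("the fast position-based ES agrees with the full profile", {
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(10:200, 1)
    rl <- make_ranking(n)
    k <- sample.int(min(n - 1, 30), 1)
    pos <- sort(sample.int(n, k))
    full <- enrichment_score(rl, rl$gene[pos])$es
    fast <- sigconnect:::es_fast(pos, abs(rl$score)[pos], n, 1)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("degenerate gene sets are rejected with clear errors", {
  rl <- make_ranking(10, seed = 3)
  expect_error(enrichment_score(rl, c("absent1", "absent2")), "no overlap")
  expect_error(enrichment_score(rl, rl$gene), "whole ranking universe")
})

test_that("null distributions have the right size, range and determinism", {
  rl <- make_ranking(60, seed = 5)
  cfg <- es_config(n_perm = 500, seed = 99)
  nd <- null_distribution(rl, 8, cfg)
  expect_length(nd$es, 500)
  expect_true(all(nd$es >= -1 & nd$es <= 1))
  nd2 <- null_distribution(rl, 8, cfg)
  expect_identical(nd$es, nd2$es)
  expect_error(null_distribution(rl, 60, cfg), "between 1 and")
  expect_error(null_distribution(rl, 0, cfg), "between 1 and")

  # each null sample equals the brute-force ES of its drawn set
  cfg_small <- es_config(n_perm = 50, seed = 7)
  nd3 <- null_distribution(rl, 59, cfg_small)
  expect_true(all(abs(nd3$es) > 0))
})

test_that("NES normalizes by the same-sign null mean magnitude", {
  fake_null <- structure(
    list(es = c(0.4, 0.4, -0.2, -0.6), n_perm = 4, set_size = 3,
         mode = "random-set", seed = NULL),
    class = "null_distribution"
  )
  expect_equal(normalize_es(0.8, fake_null), 2.0)
  expect_equal(normalize_es(-0.8, fake_null), -2.0)
  expect_equal(normalize_es(0, fake_null), 0)
  pos_null <- structure(list(es = c(0.1, 0.2)), class = "null_distribution")
  expect_warning(out <- normalize_es(-0.5, pos_null), "no samples")
  expect_true(is.na(out))
})

test_that("empirical p-values use add-one smoothing and same-sign tails", {
  fake_null <- structure(
    list(es = c(0.1, 0.2, 0.3, -0.5), n_perm = 4),
    class = "null_distribution"
  )
  # es bigger than every same-sign sample: p = 1/(1+3)
  expect_equal(nominal_p(0.9, fake_null), 1 / 4)
  # es below all same-sign samples: p = (1+3)/(1+3) = 1
  expect_equal(nominal_p(0.05, fake_null), 1)
  expect_equal(nominal_p(-0.4, fake_null), (1 + 1) / (1 + 1))

  # a maximal score at n_perm = 10000 is displayed below resolution
  expect_equal(format_pvalue(1 / 10001, 10000), "<1e-04")
  expect_equal(format_pvalue(0.2345, 10000), "0.2345")
})

test_that("planted sets outrank random sets by NES", {
  # planted signal: the set occupies high ranks; its NES should exceed the
  # NES of random same-size sets in nearly all replicates
  set.seed(31)
  cfg <- es_config(n_perm = 200)
  wins <- 0
  n_rep <- 50
  for (rep in seq_len(n_rep)) {
    n <- 150
    scores <- stats::rnorm(n)
    scores[1:10] <- scores[1:10] + 3
    genes <- sprintf("g%04d", seq_len(n))
    rl <- build_ranked_list(stats::setNames(scores, genes))
    planted <- genes[1:10]
    random <- sample(genes, 10)
    nd <- null_distribution(rl, 10, cfg)
    nes_planted <- normalize_es(enrichment_score(rl, planted, cfg)$es, nd)
    nes_random <- normalize_es(enrichment_score(rl, random, cfg)$es, nd)
    if (isTRUE(nes_planted > nes_random)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("gsea_batch scores a collection with per-sign BH adjustment", {
  rl <- make_ranking(100, seed = 41)
  cfg <- es_config(n_perm = 200, seed = 42)
  coll <- list(
    top = rl$gene[1:10],
    bottom = rl$gene[91:100],
    random = sample(rl$gene, 10)
  )
  out <- gsea_batch(rl, coll, cfg)
  expect_equal(nrow(out), 3)
  expect_equal(out$es[out$name == "top"], 1.0)
  expect_equal(out$es[out$name == "bottom"], -1.0)
  # extreme sets beat every null draw: p hits the same-sign resolution floor
  nd <- null_distribution(rl, 10, cfg)
  expect_equal(out$p_value[out$name == "top"], 1 / (1 + sum(nd$es > 0)))
  expect_equal(out$p_value[out$name == "bottom"], 1 / (1 + sum(nd$es < 0)))
  expect_false(is.unsorted(rev(out$nes)))

  # single-set collection: FDR equals the nominal p
  one <- gsea_batch(rl, list(top = rl$gene[1:10]), cfg)
  expect_equal(one$fdr, one$p_value)

  # no-overlap sets are skipped with a warning, not fatal
  expect_warning(
    both <- gsea_batch(rl, list(top = rl$gene[1:10], ghost = c("zz1", "zz2")), cfg),
    "Skipping"
  )
  expect_equal(nrow(both), 1)
})

test_that("random collections rarely reach FDR < 0.05 under the null", {
  # type-I control: 20 random sets vs a random ranking
  set.seed(57)
  cfg <- es_config(n_perm = 150)
  n_rep <- 30
  false_hits <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    rl <- make_ranking(120)
    coll <- lapply(1:20, function(i) sample(rl$gene, 8))
    names(coll) <- paste0("s", 1:20)
    out <- gsea_batch(rl, coll, cfg)
    false_hits[rep] <- sum(out$fdr < 0.05)
  }
  expect_lte(mean(false_hits), 1)
})

test_that("gene-set members outside the universe are dropped and counted", {
  rl <- make_ranking(30, seed = 61)
  res <- enrichment_score(rl, c(rl$gene[1:5], "missing1", "missing2"))
  expect_equal(res$size, 5)
  expect_equal(res$n_dropped, 2)
})

test_that("leading edge contains the set members driving the peak", {
  rl <- make_ranking(40, seed = 67)
  top <- enrichment_score(rl, rl$gene[1:6])
  expect_setequal(top$leading_edge, rl$gene[1:6])
  bottom <- enrichment_score(rl, rl$gene[35:40])
  expect_setequal(bottom$leading_edge, rl$gene[35:40])
})
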