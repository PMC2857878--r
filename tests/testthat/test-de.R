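test_that("paired fold change is the mean within-pair log2 difference", {
  # two pairs with differences (1, 3) for one gene
  exprs <- rbind(
    g1 = c(5, 4, 7, 4),
    g2 = c(6, 6, 6, 6)
  )
  colnames(exprs) <- c("s1L", "s1N", "s2L", "s2N")
  pe <- paired_expression(exprs, data.frame(
    patient = c("p1", "p2"),
    lesional = c("s1L", "s2L"),
    nonlesional = c("s1N", "s2N")
  ))
  fch <- paired_log2_fch(pe)
  expect_equal(fch$log2_fch[fch$feature == "g1"], 2.0)
  expect_equal(fch$log2_fch[fch$feature == "g2"], 0.0)
})

test_that("paired fold change matches a per-gene loop oracle", {
  pe <- make_paired(100, 5, seed = 2)
  fch <- paired_log2_fch(pe)
  les <- pe$exprs[, pe$pairing$lesional]
  nonles <- pe$exprs[, pe$pairing$nonlesional]
  oracle <- vapply(seq_len(100), function(g) mean(les[g, ] - nonles[g, ]), numeric(1))
  expect_equal(fch$log2_fch, oracle)
})

test_that("pairing validation names the offending patient", {
  exprs <- matrix(rnorm(8), 2, 4,
    dimnames = list(c("g1", "g2"), c("a", "b", "c", "d"))
  )
  expect_error(
    paired_expression(exprs, data.frame(
      patient = c("p1", "p2"), lesional = c("a", "c"),
      nonlesional = c("b", "MISSING")
    )),
    "p2"
  )
  expect_error(
    paired_expression(exprs, data.frame(
      patient = c("p1", "p2"), lesional = c("a", "a"),
      nonlesional = c("b", "c")
    )),
    "exactly one pair slot"
  )
  expect_error(
    paired_expression(exprs, data.frame(
      patient = "p1", lesional = "a", nonlesional = "b"
    )),
    "At least 2"
  )
})

test_that("unmoderated paired t equals the closed-form oracle", {
  pe <- make_paired(50, 3, seed = 5)
  out <- moderated_paired_t(pe, moderation = FALSE)
  ora <- oracle_paired_t(
    pe$exprs[, pe$pairing$lesional],
    pe$exprs[, pe$pairing$nonlesional]
  )
  expect_equal(out$log2_fch, unname(ora[, "fch"]))
  expect_equal(out$t, unname(ora[, "t"]), tolerance = 1e-12)
  expect_equal(out$p, unname(ora[, "p"]), tolerance = 1e-12)
  expect_true(all(out$df == 2))

  # cross-check against the standard library implementation
  d <- pe$exprs[, pe$pairing$lesional] - pe$exprs[, pe$pairing$nonlesional]
  tt <- stats::t.test(d[1, ])
  expect_equal(out$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("exactly constant differences are flagged, not propagated as NaN", {
  exprs <- rbind(
    g1 = c(6, 4, 7, 5, 8, 6), # constant difference 2
    g2 = c(6, 4, 7, 6, 5, 6)
  )
  colnames(exprs) <- paste0("s", 1:6)
  pe <- paired_expression(exprs, data.frame(
    patient = paste0("p", 1:3),
    lesional = c("s1", "s3", "s5"),
    nonlesional = c("s2", "s4", "s6")
  ))
  out <- moderated_paired_t(pe, moderation = FALSE)
  expect_true(out$degenerate_variance[1])
  expect_gt(out$p[1], 0)
  expect_lte(out$p[1], 1e-300)
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  pe <- make_paired(400, 6, effects = c(rep(1.5, 20), rep(0, 380)), seed = 7)
  out <- moderated_paired_t(pe)
  d <- pe$exprs[, pe$pairing$lesional] - pe$exprs[, pe$pairing$nonlesional]
  fit <- limma::eBayes(limma::lmFit(d, design = matrix(1, ncol(d), 1)))
  expect_equal(attr(out, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(out, "s0sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(out$t, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(out$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
  expect_equal(out$df, unname(fit$df.total), tolerance = 1e-6)
})

test_that("a huge prior df pins every posterior variance to the prior", {
  pe <- make_paired(100, 4, seed = 11)
  out <- moderated_paired_t(pe, prior = list(d0 = 1e9, s0sq = 0.7))
  n <- 4
  expect_equal(out$t, out$log2_fch / sqrt(0.7 / n), tolerance = 1e-6)
})

test_that("a tiny prior df recovers the classical paired t", {
  pe <- make_paired(80, 5, seed = 13)
  mod <- moderated_paired_t(pe, prior = list(d0 = 1e-12, s0sq = 1))
  unmod <- moderated_paired_t(pe, moderation = FALSE)
  expect_equal(mod$t, unmod$t, tolerance = 1e-10)
})

test_that("all-zero variance is a hard error under moderation", {
  exprs <- matrix(rep(c(6, 4), each = 2, times = 2), nrow = 2, byrow = TRUE)
  exprs <- rbind(g1 = c(6, 4, 6, 4), g2 = c(5, 3, 5, 3))
  colnames(exprs) <- paste0("s", 1:4)
  pe <- paired_expression(exprs, data.frame(
    patient = c("p1", "p2"), lesional = c("s1", "s3"),
    nonlesional = c("s2", "s4")
  ))
  expect_error(moderated_paired_t(pe), "zero variance")
})

test_that("BH adjustment equals the step-up oracle and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(17)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  }
  # permutation invariance of the gene -> q mapping
  p <- stats::runif(50)
  names(p) <- sprintf("g%02d", 1:50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG selection applies strict fold-change and FDR cutoffs", {
  stats_tab <- tibble::tibble(
    feature = paste0("g", 1:6),
    log2_fch = c(1.5, 1.0, -1.2, -1.0, 3.0, 0.2),
    fdr = c(0.04, 0.04, 0.04, 0.04, 0.06, 0.01)
  )
  sig <- select_deg(stats_tab)
  expect_setequal(sig$up, "g1") # g2 sits exactly at the boundary, g5 fails FDR
  expect_setequal(sig$down, "g3") # g4 sits exactly at the boundary
  expect_true(length(intersect(sig$up, sig$down)) == 0)

  # exhaustive rule oracle on random tables
  set.seed(19)
  tab <- tibble::tibble(
    feature = sprintf("g%03d", 1:200),
    log2_fch = stats::rnorm(200, sd = 1.5),
    fdr = stats::runif(200)
  )
  sig2 <- select_deg(tab)
  expect_setequal(sig2$up, tab$feature[tab$fdr < 0.05 & tab$log2_fch > 1])
  expect_setequal(sig2$down, tab$feature[tab$fdr < 0.05 & tab$log2_fch < -1])

  expect_warning(
    empty <- select_deg(tibble::tibble(feature = "g", log2_fch = 0, fdr = 1)),
    "No feature"
  )
  expect_length(empty$up, 0)
})

test_that("low-intensity fractions count samples strictly below threshold", {
  m <- rbind(
    high = rep(8, 10),
    low = rep(2, 10),
    mixed = c(rep(3, 3), rep(5, 7))
  )
  colnames(m) <- paste0("s", 1:10)
  out <- low_intensity_fraction(m)
  expect_equal(out$low_intensity_fraction, c(0, 100, 30))
})

test_that("expression filtering drops low and invariant features", {
  set.seed(23)
  n_pairs <- 5
  pe <- make_paired(50, n_pairs, seed = 23)
  m <- pe$exprs
  m["f0001", ] <- 7 # constant: variance rule
  m["f0002", ] <- c(3, rep(2, ncol(m) - 1)) # low everywhere
  m["f0003", ] <- c(rep(2, 8), rep(8, 2)) # low in 80% < 90% cutoff: retained
  pe2 <- paired_expression(m, pe$pairing)
  kept <- expression_filter(pe2)
  expect_false("f0001" %in% rownames(kept$exprs))
  expect_false("f0002" %in% rownames(kept$exprs))
  expect_true("f0003" %in% rownames(kept$exprs))
  report <- attr(kept, "filter_report")
  expect_equal(sum(report$removed), 2)

  # fully permissive thresholds are the identity
  same <- expression_filter(pe2, 0, 0, 0)
  expect_identical(same$exprs, pe2$exprs)
  expect_error(expression_filter(pe2, 99, 0, 0), "every feature")
})

test_that("log2 fold changes convert to the printed linear fold changes", {
  expect_equal(log2fch_to_linear(0), 1)
  expect_equal(log2fch_to_linear(6.17), 71.87, tolerance = 0.004)
  # printed value 0.36 is rounded to two decimals: half-ulp tolerance
  expect_equal(log2fch_to_linear(-1.45), 0.36, tolerance = 0.02)
  expect_error(log2fch_to_linear(Inf), "finite")
})

test_that("de_stats assembles the full per-feature study table", {
  pe <- make_paired(120, 6, effects = c(rep(2, 10), rep(0, 110)), seed = 29)
  out <- de_stats(pe)
  expect_named(
    out,
    c("feature", "log2_fch", "t", "df", "p", "fdr", "degenerate_variance",
      "low_intensity_fraction")
  )
  expect_equal(out$fdr, bh_adjust(out$p))
  expect_true(all(out$fdr >= 0 & out$fdr <= 1))
  # planted features dominate the top of the fold-change ranking
  expect_gte(mean(rank(-out$log2_fch)[1:10] <= 15), 0.9)
})

test_that("global-null DE keeps the discovery fraction at the FDR level", {
  set.seed(31)
  n_rep <- 20
  frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pe <- make_paired(300, 8)
    st <- de_stats(pe)
    frac[r] <- mean(st$fdr < 0.05)
  }
  expect_lte(mean(frac), 0.05)
})
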