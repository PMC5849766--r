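test_that("CN gain filter applies inclusive thresholds on TNBC frequency", {
  n <- 40
  cn <- rbind(g1 = c(rep(3.0, 5), rep(2.0, n - 5)),   # 12.5% gained
              g2 = rep(2.37, n),                      # just below CN cut
              g3 = c(rep(2.38, 4), rep(2.0, n - 4)),  # exactly 10% at 2.38
              g4 = rep(2.0, n))
  gex <- matrix(stats::rnorm(4 * n), 4, dimnames = list(rownames(cn), NULL))
  prof <- make_profile(cn, gex, rep("TNBC", n))
  res <- cn_gain_filter(prof)
  expect_true(res$pass[res$gene == "g1"])
  expect_false(res$pass[res$gene == "g2"])
  expect_true(res$pass[res$gene == "g3"])   # >= on both CN and frequency
  expect_equal(res$gain_freq[res$gene == "g1"], 5 / 40)

  prof_no_tnbc <- make_profile(cn, gex, rep("ER", n))
  expect_error(cn_gain_filter(prof_no_tnbc), "TNBC")
})

test_that("cis correlation filter requires both rho and p criteria", {
  set.seed(1)
  n <- 30
  cn1 <- 2 + stats::runif(n)
  cn <- rbind(g1 = cn1, g2 = cn1, g3 = rep(2, n))
  gex <- rbind(g1 = cn1^3,                    # monotone transform: rho = 1
               g2 = stats::rnorm(n),          # independent
               g3 = stats::rnorm(n))          # constant CN
  prof <- make_profile(cn, gex, rep("TNBC", n))
  res <- cis_correlation_filter(prof)
  expect_equal(res$rho[res$gene == "g1"], 1)
  expect_true(res$pass[res$gene == "g1"])
  expect_false(res$pass[res$gene == "g2"])
  expect_equal(res$flag[res$gene == "g3"], "constant")
  expect_false(res$pass[res$gene == "g3"])
})

test_that("high-significance correlation below rho 0.3 still fails", {
  # brute-force search for a vector pair with realized Spearman just below
  # the cut at large n, where the t-approximation p is tiny
  set.seed(7)
  n <- 2000
  x <- seq_len(n) + 0
  target <- NA
  for (w in seq(0.16, 0.30, by = 0.002)) {
    y <- w * x + (1 - w) * sample(x)
    r <- stats::cor(x, y, method = "spearman")
    if (r >= 0.27 && r < 0.2999) { target <- y; break }
  }
  expect_false(is.na(target[1]))
  cn <- rbind(g1 = 2 + x / n)
  gex <- rbind(g1 = target)
  prof <- make_profile(cn, gex, rep("TNBC", n))
  res <- cis_correlation_filter(prof)
  expect_lt(res$p[1], 1e-6)          # overwhelmingly significant
  expect_false(res$pass[1])          # but rho below the minimum
})

test_that("Spearman p machinery matches cor.test and exact enumeration", {
  set.seed(2)
  for (i in 1:5) {
    x <- stats::rnorm(25); y <- stats::rnorm(25)
    rho <- stats::cor(x, y, method = "spearman")
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(targetid:::spearman_p_t(rho, 25), ref$p.value,
                 tolerance = 1e-10)
  }
  # exact permutation p is a valid p-value and detects a perfect monotone
  x <- 1:6; y <- c(2, 4, 6, 8, 10, 12)
  expect_equal(targetid:::spearman_p_exact(x, y), 2 / factorial(6))
})

test_that("null cis filter calibration stays within its nominal level", {
  set.seed(5)
  n <- 140; m <- 1000
  cn <- matrix(2 + stats::rnorm(n * m, 0, 0.3), m, n)
  gex <- matrix(stats::rnorm(n * m), m, n)
  rownames(cn) <- rownames(gex) <- sprintf("g%04d", 1:m)
  prof <- make_profile(cn, gex, rep("TNBC", n))
  res <- cis_correlation_filter(prof)
  se <- sqrt(0.01 * 0.99 / m)
  expect_lte(mean(res$pass), 0.01 + 3 * se)
})

test_that("CN-state expression test flags separated states only", {
  n <- 40
  cn <- rbind(g1 = c(rep(2, 20), rep(3, 20)),     # neutral vs gain
              g2 = c(rep(2, 20), rep(3, 20)),
              g3 = rep(2, n))                     # single state
  set.seed(3)
  gex <- rbind(g1 = c(stats::rnorm(20), stats::rnorm(20)),          # no shift
               g2 = c(stats::rnorm(20), stats::rnorm(20) + 5),      # +5 SD
               g3 = stats::rnorm(n))
  prof <- make_profile(cn, gex, rep("TNBC", n))
  res <- cn_state_expression_test(prof)
  expect_false(res$significant[res$gene == "g1"])
  expect_true(res$significant[res$gene == "g2"])
  expect_true(is.na(res$significant[res$gene == "g3"]))
})

test_that("differential expression recovers exact shifts and planted fold changes", {
  set.seed(4)
  k <- 10
  base <- matrix(stats::rnorm(5 * k, 7, 1), 5)
  rownames(base) <- sprintf("g%d", 1:5)
  gex <- cbind(base + 1, base)                   # groupA = groupB + 1 log2
  cn <- matrix(2, 5, 2 * k, dimnames = list(rownames(base), NULL))
  prof <- make_profile(cn, gex, rep(c("TNBC", "normal"), each = k))
  de <- differential_expression(prof, "TNBC", "normal")
  expect_equal(de$fold_change, rep(2, 5), tolerance = 1e-12)

  same <- make_profile(cn, cbind(base, base),
                       rep(c("TNBC", "normal"), each = k))
  de0 <- differential_expression(same, "TNBC", "normal")
  expect_equal(de0$fold_change, rep(1, 5), tolerance = 1e-12)
  expect_true(all(de0$p > 0.99))

  # planted 3-fold genes at n = 20 vs 9, array-like noise
  n1 <- 20; n2 <- 9
  hits <- 0; tot <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    m <- 200
    g <- matrix(stats::rnorm(m * (n1 + n2), 7, 0.5), m)
    rownames(g) <- sprintf("g%03d", 1:m)
    g[1:10, seq_len(n1)] <- g[1:10, seq_len(n1)] + log2(3)
    pr <- make_profile(matrix(2, m, n1 + n2, dimnames = dimnames(g)), g,
                       c(rep("TNBC", n1), rep("normal", n2)))
    d <- differential_expression(pr, "TNBC", "normal")
    hits <- hits + sum(d$p_adj[1:10] < 0.05)
    tot <- tot + 10
  }
  expect_gte(hits / tot, 0.95)
})

test_that("expression-centered selection is strictly greater than the fold cut", {
  n1 <- 10; n2 <- 4
  # linear means are exact powers of two: fold is exact in doubles
  gex <- rbind(g1 = c(rep(4, n1), rep(3, n2)),   # 16 vs 8 = exactly 2-fold
               g2 = c(rep(4.1, n1), rep(3, n2)), # > 2-fold
               g3 = rep(5, n1 + n2))             # flat
  cn <- matrix(2, 3, n1 + n2, dimnames = dimnames(gex))
  prof <- make_profile(cn, gex, c(rep("TNBC", n1), rep("normal", n2)))
  res <- expression_centered_candidates(prof)
  expect_false(res$pass[res$gene == "g1"])
  expect_true(res$pass[res$gene == "g2"])
  expect_false(res$pass[res$gene == "g3"])
  expect_equal(res$fold[res$gene == "g1"], 2)

  no_norm <- make_profile(cn, gex, rep("TNBC", n1 + n2))
  expect_error(expression_centered_candidates(no_norm), "normal")
})

test_that("feature binning follows the three-bin weighted rule", {
  fs <- feature_spec("f", "A_gex", 1, 3, weight = 2)
  expect_equal(as.numeric(bin_feature_score(0.5, fs)), 0)
  expect_equal(as.numeric(bin_feature_score(1, fs)), 2)    # boundary in bin 1
  expect_equal(as.numeric(bin_feature_score(3, fs)), 2)    # upper boundary too
  expect_equal(as.numeric(bin_feature_score(3.01, fs)), 4) # weight 2, score 2
  deg <- feature_spec("f", "A_gex", 2, 2)
  expect_equal(as.numeric(bin_feature_score(2, deg)), 1)   # degenerate middle
  s <- bin_feature_score(c(NA, 5), fs)
  expect_equal(as.numeric(s), c(0, 4))
  expect_equal(attr(s, "missing"), c(TRUE, FALSE))
  expect_error(feature_spec("f", "A_gex", 3, 1))
})

test_that("block scores are capped, normalized and deterministically ranked", {
  fs <- rbind(feature_spec("u", "A_gex", 0, 1, weight = 4),
              feature_spec("v", "A_gex", 0, 1, weight = 2),
              feature_spec("w", "B_cn", 0, 1, weight = 1))
  bs <- rbind(block_spec("A_gex", 8), block_spec("B_cn", 2),
              block_spec("C_cn_gex", 4), block_spec("D_clinical", 2),
              block_spec("E_annotation", 3))
  feats <- data.frame(gene = c("gB", "gA", "gC"),
                      u = c(2, 2, -1), v = c(2, 2, -1), w = c(-1, -1, -1))
  sc <- score_blocks(feats, fs, bs)
  # raw A = 4*2 + 2*2 = 12, cap 8 -> normalized exactly 1
  expect_equal(sc$block_A_gex_raw[sc$gene == "gA"], 12)
  expect_equal(sc$block_A_gex[sc$gene == "gA"], 1)
  expect_true(all(sc$total >= 0 & sc$total <= 5))
  # all-below-threshold gene scores zero
  expect_equal(sc$total[sc$gene == "gC"], 0)
  # identical genes tie; order falls back to lexicographic gene ID
  expect_equal(sc$gene[1:2], c("gA", "gB"))
  expect_equal(sc$total[1], sc$total[2])

  bad <- feature_spec("u", "A_gex", 0, 1)
  expect_error(score_blocks(feats, bad, block_spec("B_cn", 2)),
               "unknown block")
})

test_that("increasing any feature value never lowers a gene total", {
  set.seed(8)
  fs <- default_feature_specs()
  bs <- default_block_specs()
  for (i in 1:30) {
    vals <- stats::setNames(as.list(stats::runif(nrow(fs), -1, 4)), fs$name)
    feats <- cbind(data.frame(gene = "g1"), as.data.frame(vals))
    t0 <- score_blocks(feats, fs, bs)$total
    j <- sample(nrow(fs), 1)
    feats2 <- feats
    feats2[[fs$name[j]]] <- feats2[[fs$name[j]]] + stats::runif(1, 0, 3)
    t1 <- score_blocks(feats2, fs, bs)$total
    expect_gte(t1, t0)
  }
})

test_that("gain and correlation filters commute with intersection", {
  prof <- simulate_cohort(cohort_sim_config(n_genes = 200,
                                            n_cis_driver_genes = 10, seed = 6))
  gain <- cn_gain_filter(prof)
  cis_all <- cis_correlation_filter(prof)
  both_independent <- intersect(gain$gene[gain$pass],
                                cis_all$gene[cis_all$pass])
  cis_after <- cis_correlation_filter(prof, genes = gain$gene[gain$pass])
  both_sequential <- cis_after$gene[cis_after$pass]
  expect_setequal(both_independent, both_sequential)
})

test_that("candidate assembly unions the two arms with provenance", {
  feats <- data.frame(gene = sprintf("G%03d", 1:100),
                      gain_freq = seq(1, 0.01, length.out = 100))
  sc <- score_blocks(feats)
  arm2 <- sprintf("X%02d", 1:45)
  cand <- assemble_candidates(sc, arm2, k_top = 85)
  expect_equal(nrow(cand), 130)            # 85 + 45 disjoint
  expect_equal(sum(cand$provenance == "arm1"), 85)
  expect_equal(sum(cand$provenance == "arm2"), 45)

  cand2 <- assemble_candidates(sc, character(), k_top = 85)
  expect_equal(nrow(cand2), 85)

  shared <- sc$gene[sc$rank == 1]
  cand3 <- assemble_candidates(sc, shared, k_top = 85)
  expect_equal(sum(cand3$gene == shared), 1)
  expect_equal(cand3$provenance[cand3$gene == shared], "both")

  # curated list intersects the expression arm
  cand4 <- assemble_candidates(sc, c("X01", "X02", "X03"),
                               curated = c("X02"), manual = "M1", k_top = 5)
  expect_setequal(cand4$gene[cand4$provenance == "arm2"], c("X02", "M1"))
})
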