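test_that("plate-median normalization targets interior sample wells", {
  p <- make_plate("P1", c(1, 2, 3, 10, 20), c(rep("sample", 3),
                                              "pos_ctrl", "neg_ctrl"))
  out <- plate_median_normalize(p)
  expect_equal(out$normalized_value[1:3], c(0.5, 1, 1.5))
  expect_equal(out$normalized_value[4:5], c(5, 10))  # controls same factor

  # scale invariance: doubling every raw value changes nothing
  p2 <- p; p2$raw_value <- p2$raw_value * 2
  expect_equal(plate_median_normalize(p2)$normalized_value,
               out$normalized_value)

  # all-equal plate normalizes to 1
  p3 <- make_plate("P1", rep(7, 4), rep("sample", 4))
  expect_equal(plate_median_normalize(p3)$normalized_value, rep(1, 4))

  # exterior wells are not part of the median
  p4 <- rbind(p, data.frame(plate_id = "P1", row = 1, col = 1,
                            reagent_type = "sample", gene = "gx",
                            oligo = "pool", cell_line = "BC01", replicate = 1,
                            raw_value = 1e6))
  expect_equal(plate_median_normalize(p4)$normalized_value[1:3],
               c(0.5, 1, 1.5))

  p0 <- make_plate("P1", c(0, 0, 0), rep("sample", 3))
  expect_error(plate_median_normalize(p0), "zero plate median")
})

test_that("NPI hits its formula endpoints and is affine invariant", {
  expect_equal(compute_npi(1.0, mu_pos = 0.2, mu_neg = 1.0), 0)
  expect_equal(compute_npi(0.2, mu_pos = 0.2, mu_neg = 1.0), 100)
  expect_equal(compute_npi(0.5, mu_pos = 0.2, mu_neg = 1.0), 62.5)
  expect_error(compute_npi(0.5, mu_pos = 1, mu_neg = 1), "undefined")

  set.seed(10)
  for (i in 1:20) {
    x <- stats::runif(1); mp <- stats::runif(1); mn <- mp + stats::runif(1)
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1)
    expect_equal(compute_npi(a * x + b, a * mp + b, a * mn + b),
                 compute_npi(x, mp, mn), tolerance = 1e-9)
  }
})

test_that("Z-prime matches its closed forms and bounds", {
  expect_equal(zprime(c(100, 100), c(0, 0))$zprime, 1)
  z <- zprime(c(95, 100, 105), c(-5, 0, 5))     # 100 +/- 5 vs 0 +/- 5
  expect_equal(z$zprime, 0.7)
  expect_true(z$valid)
  z2 <- zprime(c(88, 100, 112), c(-12, 0, 12))  # 100 +/- 12 vs 0 +/- 12
  expect_equal(z2$zprime, 0.28)
  expect_false(z2$valid)
  expect_false(zprime(c(1, 2), c(1, 2))$valid)  # equal means: undefined

  set.seed(11)
  for (i in 1:20) {
    pos <- stats::rnorm(5, 100, stats::runif(1, 0, 10))
    neg <- stats::rnorm(5, 0, stats::runif(1, 0, 10))
    expect_lte(zprime(pos, neg)$zprime, 1)
    # inflating a control spread strictly lowers Z-prime at fixed means
    pos2 <- mean(pos) + (pos - mean(pos)) * 2
    expect_lt(zprime(pos2, neg)$zprime, zprime(pos, neg)$zprime)
  }
})

test_that("replicate QC keeps concordant and drops discordant replicates", {
  set.seed(12)
  signal <- stats::rnorm(60, 0, 10)
  good <- cbind(signal + stats::rnorm(60), signal + stats::rnorm(60),
                signal + stats::rnorm(60))
  q <- replicate_qc(good)
  expect_equal(q$excluded, integer(0) , ignore_attr = TRUE)
  expect_gt(q$overall_mean_r2, 0.9)

  ident <- cbind(signal, signal, signal)
  expect_equal(replicate_qc(ident)$overall_mean_r2, 1)

  # a pure-noise replicate is excluded essentially always
  excl <- vapply(1:20, function(s) {
    set.seed(100 + s)
    sig <- stats::rnorm(60, 0, 10)
    m <- cbind(sig + stats::rnorm(60), sig + stats::rnorm(60),
               stats::rnorm(60, 0, 10))
    3 %in% replicate_qc(m)$excluded
  }, logical(1))
  expect_gte(mean(excl), 0.95)

  # anti-correlated replicates are not concordant despite r^2 = 1
  m <- cbind(signal, -signal)
  qa <- replicate_qc(m)
  expect_true(qa$failed)
})

test_that("hit threshold is mean plus three standard deviations", {
  expect_lt(abs(hit_threshold(mean = 0.18, sd = 5.94) - 18.01), 0.011)
  expect_equal(hit_threshold(mean = 1, sd = 2), 7)
  expect_equal(hit_threshold(rep(5, 10)), 5)       # sd 0
  expect_error(hit_threshold(3), "at least 2")
  x <- c(-3, 0.18, 3.2, -5, 6)
  expect_equal(hit_threshold(x), mean(x) + 3 * stats::sd(x))
})

test_that("primary hit rule matches its published clauses", {
  thr <- 18.01
  mk <- function(hmec, lines) {
    data.frame(gene = "g", cell_line = c("HMEC", paste0("L", seq_along(lines))),
               mean_npi = c(hmec, lines))
  }
  h1 <- call_primary_hits(mk(5, c(20, 25, 3)), thr)
  expect_equal(h1$verdict, "hit"); expect_equal(h1$clause, "A")
  expect_equal(h1$lines_effect, "L1;L2")
  h2 <- call_primary_hits(mk(30, c(2, 5, 40, 50)), thr)
  expect_equal(h2$verdict, "hit"); expect_equal(h2$clause, "B")
  h3 <- call_primary_hits(mk(30, c(20, 25, 30)), thr)
  expect_equal(h3$verdict, "no_hit")
  h4 <- call_primary_hits(
    data.frame(gene = "g", cell_line = c("L1", "L2"), mean_npi = c(30, 30)),
    thr)
  expect_equal(h4$verdict, "fail")   # HMEC missing: cannot call
})

test_that("top-10 validation needs two fully qualifying oligos", {
  thr <- 18.01
  mk <- function(kd, hmec, l1, l2) {
    list(res = data.frame(gene = "g",
                          oligo = rep(paste0("o", seq_along(kd)), each = 3),
                          cell_line = rep(c("HMEC", "L1", "L2"), length(kd)),
                          mean_npi = as.vector(rbind(hmec, l1, l2))),
         kd = data.frame(gene = "g", oligo = paste0("o", seq_along(kd)),
                         kd_percent = kd))
  }
  a <- mk(kd = c(80, 85, 20), hmec = c(3, 6, 2),
          l1 = c(30, 25, 1), l2 = c(22, 40, 0))
  expect_equal(call_top10_hits(a$res, a$kd, thr)$verdict, "validated")
  b <- mk(kd = c(80, 65, 20), hmec = c(3, 6, 2),
          l1 = c(30, 25, 1), l2 = c(22, 40, 0))
  expect_equal(call_top10_hits(b$res, b$kd, thr)$verdict, "no_hit")
  c_ <- mk(kd = c(80, 85, 90), hmec = c(3, 30, 25),
           l1 = c(30, 25, 30), l2 = c(22, 40, 28))
  expect_equal(call_top10_hits(c_$res, c_$kd, thr)$verdict, "no_hit")
  # fewer than 3 oligos with measured knockdown: cannot call
  d <- mk(kd = c(80, NA, NA), hmec = c(3, 6, 2),
          l1 = c(30, 25, 1), l2 = c(22, 40, 0))
  expect_equal(call_top10_hits(d$res, d$kd, thr)$verdict, "fail")
})

test_that("secondary validation applies fail-first precedence", {
  thr <- 18.01
  mk <- function(kd, npi) data.frame(gene = "g", oligo = paste0("o", 1:4),
                                     kd_percent = kd, npi = npi)
  expect_equal(secondary_validation(mk(c(75, 80, 45, 50),
                                       c(5, 3, 30, 25)))$verdict, "fail")
  expect_equal(secondary_validation(mk(c(45, 50, 72, 30),
                                       c(30, 25, 4, 1)))$verdict, "validated")
  expect_equal(secondary_validation(mk(c(30, 35, 20, 10),
                                       c(30, 25, 5, 2)))$verdict,
               "inconclusive")
})

test_that("screen QC report carries Z-prime and replicate exclusions", {
  ph <- data.frame(gene = sprintf("SG%03d", 1:4), line = "BC01",
                   npi_mean = 40, npi_sd = 5)
  sc <- simulate_screen(screen_sim_config(n_genes = 20, n_lines = 2,
                                          planted_hits = ph, seed = 21))
  res <- screen_npi(sc$plates)
  expect_s3_class(res, "screen_result")
  expect_true(all(res$qc$plates$zprime <= 1))
  expect_true(any(res$qc$plates$valid))
  expect_true(all(c("gene", "cell_line", "mean_npi", "sem") %in%
                    names(res$results)))
  # SEM defined for triplicates
  expect_true(all(!is.na(res$results$sem[res$results$n_rep > 1])))
  tmp <- tempfile(fileext = ".json")
  write_qc_report(res, tmp)
  expect_true(jsonlite::validate(paste(readLines(tmp), collapse = "")))
})
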