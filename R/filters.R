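#' Copy-number gain filter
#'
#' Retains genes gained (CN at or above `cn_threshold`) in at least
#' `freq_threshold` of TNBC samples.  Both comparisons are inclusive.
#'
#' @param profile a [gene_profile()].
#' @param cn_threshold gain threshold on the profile's CN scale (default 2.38).
#' @param freq_threshold minimum gain frequency among TNBC samples (default
#'   0.10).
#' @return data.frame with columns `gene`, `gain_freq`, `pass`.
#' @export
cn_gain_filter <- function(profile, cn_threshold = 2.38, freq_threshold = 0.10) {
  stopifnot(inherits(profile, "gene_profile"))
  tnbc <- profile_samples(profile, "TNBC")
  if (!length(tnbc)) stop("no TNBC samples in profile")
  cn <- profile$cn[, tnbc, drop = FALSE]
  has_cn <- colSums(!is.na(cn)) > 0
  if (!any(has_cn)) stop("no TNBC samples carry copy number")
  cn <- cn[, has_cn, drop = FALSE]
  freq <- rowMeans(cn >= cn_threshold, na.rm = TRUE)
  data.frame(gene = rownames(cn), gain_freq = unname(freq),
             pass = unname(freq >= freq_threshold),
             stringsAsFactors = FALSE)
}

## two-sided p for a Spearman rho via the large-sample t approximation
spearman_p_t <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), n - 2)
}

## exact two-sided permutation p by full enumeration (n <= 8)
spearman_p_exact <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  obs <- abs(stats::cor(x, y, method = "spearman"))
  all_p <- perms(y)
  hits <- vapply(all_p, function(py)
    abs(stats::cor(x, py, method = "spearman")) >= obs - 1e-12, logical(1))
  mean(hits)
}

#' Cis copy-number / expression Spearman correlation filter
#'
#' Spearman rank correlation between each gene's CN and expression across
#' TNBC samples; a gene passes when `rho >= rho_min` and `p <= p_max`.
#' The p-value uses the large-sample t approximation, or exact permutation
#' enumeration when `n <= 8` samples are available (or on request).
#'
#' @param profile a [gene_profile()].
#' @param genes genes to test (default: all).
#' @param rho_min minimum correlation (default 0.30).
#' @param p_max maximum p-value (default 0.01).
#' @param exact force exact permutation p (only allowed for n <= 8).
#' @return data.frame `gene`, `rho`, `p`, `pass`, `flag` (`"constant"` for
#'   genes whose CN or expression does not vary; such genes never pass).
#' @export
cis_correlation_filter <- function(profile, genes = NULL,
                                   rho_min = 0.30, p_max = 0.01,
                                   exact = FALSE) {
  stopifnot(inherits(profile, "gene_profile"))
  if (is.null(genes)) genes <- profile$genes
  tnbc <- profile_samples(profile, "TNBC")
  cn <- profile$cn[genes, tnbc, drop = FALSE]
  gex <- profile$gex[genes, tnbc, drop = FALSE]
  res <- data.frame(gene = genes, rho = NA_real_, p = NA_real_,
                    pass = FALSE, flag = "", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    ok <- !is.na(cn[i, ]) & !is.na(gex[i, ])
    x <- cn[i, ok]; y <- gex[i, ok]
    n <- length(x)
    if (n < 3) { res$flag[i] <- "too_few_samples"; next }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      res$flag[i] <- "constant"; next
    }
    rho <- stats::cor(x, y, method = "spearman")
    use_exact <- exact || n <= 8
    if (use_exact && n > 8)
      stop("exact permutation p only supported for n <= 8")
    p <- if (use_exact) spearman_p_exact(x, y) else spearman_p_t(rho, n)
    res$rho[i] <- rho; res$p[i] <- p
    res$pass[i] <- !is.na(p) && rho >= rho_min && p <= p_max
  }
  res
}

#' Discretize copy number into categorical states
#'
#' Boundaries are not part of the published algorithm and are exposed:
#' loss `< boundaries[1]`, neutral `[boundaries[1], boundaries[2])`,
#' gain `[boundaries[2], boundaries[3])`, amplification `>= boundaries[3]`.
#'
#' @param cn numeric vector of CN values.
#' @param boundaries numeric length 3, default `c(1.5, 2.38, 4)`.
#' @return factor with levels loss/neutral/gain/amplification.
#' @export
cn_states <- function(cn, boundaries = c(1.5, 2.38, 4)) {
  stopifnot(length(boundaries) == 3, !is.unsorted(boundaries))
  cut(cn, breaks = c(-Inf, boundaries, Inf), right = FALSE,
      labels = c("loss", "neutral", "gain", "amplification"))
}

#' Copy-number-state expression association (multi Mann-Whitney U)
#'
#' For each gene, expression is compared between the neutral CN state and each
#' populated non-neutral state (>= 2 samples per side) by a two-sided
#' Mann-Whitney U test; the per-gene p is the minimum across comparisons,
#' Bonferroni-corrected by the number of comparisons made for that gene, and
#' p-values are then Benjamini-Hochberg adjusted across genes.  Significance
#' is adjusted p < 0.05.
#'
#' @param profile a [gene_profile()].
#' @param genes genes to test (default all).
#' @param boundaries CN state boundaries, see [cn_states()].
#' @param alpha significance level on the BH-adjusted p (default 0.05).
#' @return data.frame `gene`, `p` (within-gene Bonferroni), `p_adj`
#'   (BH across genes), `n_comparisons`, `significant` (NA when fewer than two
#'   populated states).
#' @export
cn_state_expression_test <- function(profile, genes = NULL,
                                     boundaries = c(1.5, 2.38, 4),
                                     alpha = 0.05) {
  stopifnot(inherits(profile, "gene_profile"))
  if (is.null(genes)) genes <- profile$genes
  tnbc <- profile_samples(profile, "TNBC")
  cn <- profile$cn[genes, tnbc, drop = FALSE]
  gex <- profile$gex[genes, tnbc, drop = FALSE]
  p_raw <- rep(NA_real_, length(genes))
  n_cmp <- integer(length(genes))
  for (i in seq_along(genes)) {
    ok <- !is.na(cn[i, ]) & !is.na(gex[i, ])
    st <- cn_states(cn[i, ok], boundaries)
    y <- gex[i, ok]
    neut <- y[st == "neutral"]
    if (length(neut) < 2) next
    ps <- numeric()
    for (lev in c("loss", "gain", "amplification")) {
      grp <- y[st == lev]
      if (length(grp) < 2) next
      ps <- c(ps, stats::wilcox.test(grp, neut, exact = FALSE)$p.value)
    }
    if (!length(ps)) next
    n_cmp[i] <- length(ps)
    p_raw[i] <- min(1, min(ps) * length(ps))
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  data.frame(gene = genes, p = p_raw, p_adj = p_adj, n_comparisons = n_cmp,
             significant = p_adj < alpha, stringsAsFactors = FALSE)
}

#' Differential expression between two sample groups
#'
#' Welch's t-test on log2 expression with Benjamini-Hochberg adjustment across
#' genes; fold change is the ratio of group geometric means on the linear
#' scale, `2^(mean_A - mean_B)`.
#'
#' @param profile a [gene_profile()].
#' @param groupA,groupB either group labels (`"TNBC"`, `"normal"`, ...) or
#'   character vectors of sample IDs.
#' @param genes genes to test (default all).
#' @return data.frame `gene`, `fold_change`, `log2_fc`, `p`, `p_adj`
#'   (p is NA for zero-variance degenerate genes).
#' @export
differential_expression <- function(profile, groupA, groupB, genes = NULL) {
  stopifnot(inherits(profile, "gene_profile"))
  if (is.null(genes)) genes <- profile$genes
  resolve <- function(g) {
    if (length(g) == 1 && g %in% profile$samples$group)
      profile_samples(profile, g) else as.character(g)
  }
  sa <- resolve(groupA); sb <- resolve(groupB)
  if (length(sa) < 2 || length(sb) < 2)
    stop("need at least 2 samples per group")
  a <- profile$gex[genes, sa, drop = FALSE]
  b <- profile$gex[genes, sb, drop = FALSE]
  l2fc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_along(genes), function(i) {
    tryCatch(stats::t.test(a[i, ], b[i, ])$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(gene = genes, fold_change = 2^l2fc, log2_fc = unname(l2fc),
             p = p, p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Expression-centered candidate selection
#'
#' Selects genes whose mean TNBC expression on the linear scale is strictly
#' more than `fold_min` times the mean in normal breast epithelium.
#'
#' @param profile a [gene_profile()].
#' @param fold_min fold-change threshold (default 2; strict `>`).
#' @return data.frame `gene`, `fold`, `pass`.
#' @export
expression_centered_candidates <- function(profile, fold_min = 2.0) {
  stopifnot(inherits(profile, "gene_profile"))
  tnbc <- profile_samples(profile, "TNBC")
  norm <- profile_samples(profile, "normal")
  if (!length(norm)) stop("no normal samples in profile")
  m_t <- rowMeans(2^profile$gex[, tnbc, drop = FALSE])
  m_n <- rowMeans(2^profile$gex[, norm, drop = FALSE])
  fold <- m_t / m_n
  data.frame(gene = profile$genes, fold = unname(fold),
             pass = unname(fold > fold_min), stringsAsFactors = FALSE)
}
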