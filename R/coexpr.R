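#' Pairwise Pearson correlation with significance flags
#'
#' Pearson correlation and two-sided p-value for every gene pair across the
#' chosen samples (typically the TNBC tumors); pairs with `p > alpha` are
#' flagged insignificant.  Genes with constant expression yield undefined
#' correlations (`NA`) and are flagged.
#'
#' @param gex expression matrix, genes x samples.
#' @param genes genes to correlate (default: all rows; at least 2).
#' @param sample_ids samples to use (default: all columns; at least 3).
#' @param alpha significance level (default 0.05).
#' @return object of class `pairwise_cor`: list with matrices `r`, `p`,
#'   logical `insignificant`, `n`, and `constant_genes`.
#' @export
pairwise_correlation <- function(gex, genes = rownames(gex),
                                 sample_ids = colnames(gex), alpha = 0.05) {
  m <- gex[genes, sample_ids, drop = FALSE]
  n <- ncol(m)
  if (n < 3) stop("need at least 3 samples")
  if (nrow(m) < 2) stop("need at least 2 genes")
  const <- apply(m, 1, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(m)))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  structure(list(r = r, p = p, insignificant = p > alpha, n = n,
                 constant_genes = names(const)[const]),
            class = "pairwise_cor")
}

#' @export
print.pairwise_cor <- function(x, ...) {
  cat("<pairwise_cor> ", nrow(x$r), " genes, n = ", x$n, " samples\n", sep = "")
  off <- x$insignificant[upper.tri(x$insignificant)]
  cat("  insignificant pairs (p > 0.05): ", sum(off, na.rm = TRUE), "/",
      length(off), "\n", sep = "")
  if (length(x$constant_genes))
    cat("  constant (undefined) genes:",
        paste(x$constant_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Ward hierarchical clustering of a correlation structure
#'
#' Agglomerative clustering with Ward linkage on the distance `1 - r`.
#' Undefined correlations are imputed to `r = 0` with a warning.  Flat
#' clusters come from a cut by count (`k`) or height (`h`).
#'
#' @param cr a [pairwise_correlation()] result or a correlation matrix.
#' @param k number of flat clusters (optional).
#' @param h cut height (optional).
#' @param method linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return list `hclust` (dendrogram), `clusters` (named integer vector, or
#'   NULL when no cut was requested).
#' @export
ward_cluster <- function(cr, k = NULL, h = NULL, method = "ward.D2") {
  r <- if (inherits(cr, "pairwise_cor")) cr$r else cr
  if (anyNA(r)) {
    warning("undefined correlations imputed to r = 0 for clustering")
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = method)
  clusters <- if (!is.null(k) || !is.null(h))
    stats::cutree(hc, k = k, h = h) else NULL
  list(hclust = hc, clusters = clusters)
}

#' Multi-gene composite expression score
#'
#' Per-sample mean of per-gene standardized (z-scored) expression over a gene
#' set; standardization is across the chosen samples, so the score is
#' invariant to per-gene affine rescaling.  Samples are dichotomized into
#' high/low by a configurable rule: `"mixture"` (default) splits a
#' two-component Gaussian mixture fitted to the scores and labels the
#' component with the larger mean high; `"median"` uses the score median;
#' `"quantile"` uses `quantile(score, q)`.
#'
#' @param gex expression matrix, genes x samples.
#' @param genes non-empty gene set present in the matrix.
#' @param sample_ids samples to score (default all).
#' @param rule high/low classification rule.
#' @param q quantile for `rule = "quantile"`.
#' @return object of class `composite_score`: data.frame `sample_id`,
#'   `score`, `high`; attributes `fraction_high` and `rule`.
#' @export
composite_score <- function(gex, genes, sample_ids = colnames(gex),
                            rule = c("mixture", "median", "quantile"),
                            q = 0.5) {
  rule <- match.arg(rule)
  genes <- unique(genes)     # a gene set is a set: duplicates carry no weight
  if (!length(genes)) stop("gene set is empty")
  missing <- setdiff(genes, rownames(gex))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  m <- gex[genes, sample_ids, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant gene(s) in set; their z-scores set to 0")
    sds[sds == 0] <- Inf
  }
  z <- (m - rowMeans(m)) / sds
  ## duplicated measurements (identical standardized profiles) carry no
  ## information and contribute once, so redundant gene listings cannot
  ## re-weight the score
  z <- z[!duplicated(z), , drop = FALSE]
  score <- colMeans(z, na.rm = TRUE)
  score[colSums(!is.na(z)) == 0] <- NA
  high <- switch(rule,
    median = score > stats::median(score, na.rm = TRUE),
    quantile = score > stats::quantile(score, q, na.rm = TRUE),
    mixture = {
      mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
      fit <- mclust::Mclust(score[!is.na(score)], G = 2, verbose = FALSE)
      hi_comp <- which.max(fit$parameters$mean)
      out <- rep(NA, length(score))
      out[!is.na(score)] <- fit$classification == hi_comp
      out
    })
  res <- data.frame(sample_id = sample_ids, score = unname(score),
                    high = unname(high), stringsAsFactors = FALSE)
  attr(res, "fraction_high") <- mean(res$high, na.rm = TRUE)
  attr(res, "rule") <- rule
  class(res) <- c("composite_score", "data.frame")
  res
}

#' @export
print.composite_score <- function(x, ...) {
  cat("<composite_score> ", nrow(x), " samples; rule = ", attr(x, "rule"),
      "; fraction high = ", round(attr(x, "fraction_high"), 3), "\n", sep = "")
  invisible(x)
}
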