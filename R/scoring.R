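#' Declare a scoring feature
#'
#' A feature maps a per-gene numeric value into a binned score: values below
#' `threshold1` score 0, values in `[threshold1, threshold2]` score 1, and
#' values above `threshold2` score 2, each multiplied by `weight`.  For
#' `direction = "smaller"` the bins run the other way (below `threshold1`
#' scores 2).
#'
#' @param name feature name; must match a column of the feature-value table.
#' @param block one of `"A_gex"`, `"B_cn"`, `"C_cn_gex"`, `"D_clinical"`,
#'   `"E_annotation"`.
#' @param threshold1,threshold2 bin cut points, `threshold1 <= threshold2`.
#' @param weight positive multiplier.
#' @param direction `"larger"` (default) if larger values are better.
#' @return one-row data.frame usable in a feature-spec table.
#' @export
feature_spec <- function(name, block, threshold1, threshold2, weight = 1,
                         direction = "larger") {
  stopifnot(block %in% c("A_gex", "B_cn", "C_cn_gex", "D_clinical",
                         "E_annotation"),
            threshold1 <= threshold2, weight > 0,
            direction %in% c("larger", "smaller"))
  data.frame(name = name, block = block, threshold1 = threshold1,
             threshold2 = threshold2, weight = weight, direction = direction,
             stringsAsFactors = FALSE)
}

#' Declare a block cap
#'
#' @param block block id.
#' @param cap maximum aggregated block score (the "block limit"); the summed
#'   binned scores of a block are capped here, then divided by it.
#' @return one-row data.frame.
#' @export
block_spec <- function(block, cap) {
  stopifnot(cap > 0)
  data.frame(block = block, cap = cap, stringsAsFactors = FALSE)
}

#' Default feature-spec table
#'
#' Mirrors the five-block structure of the scoring platform: (A) expression
#' (TNBC vs normal fold change and significance, frequency of 2-fold
#' overexpression), (B) copy number (gain frequency, mean TNBC CN, optional
#' precomputed focality), (C) CN-expression association (Spearman rho,
#' CN-state test significance), (D) clinical (recurrence fold change and
#' significance), (E) annotation flags.  The published per-feature weights and
#' limits live in a supplementary table that is data, not algorithm; these
#' defaults are a sensible stand-in and any table of the same shape (e.g.
#' loaded from YAML via [read_feature_specs()]) can be substituted.
#'
#' @return data.frame of feature specs.
#' @export
default_feature_specs <- function() {
  rbind(
    feature_spec("fc_tnbc_normal", "A_gex", 1.5, 2.0, weight = 2),
    feature_spec("de_neglogp", "A_gex", 1.3, 3.0, weight = 1),
    feature_spec("freq_2fold", "A_gex", 0.25, 0.50, weight = 1),
    feature_spec("gain_freq", "B_cn", 0.10, 0.30, weight = 2),
    feature_spec("mean_cn_tnbc", "B_cn", 2.38, 3.0, weight = 1),
    feature_spec("focality", "B_cn", 0.25, 0.75, weight = 1),
    feature_spec("spearman_rho", "C_cn_gex", 0.30, 0.50, weight = 2),
    feature_spec("cn_state_neglogp", "C_cn_gex", 1.3, 3.0, weight = 2),
    feature_spec("rec_fc", "D_clinical", 1.2, 1.5, weight = 1),
    feature_spec("rec_neglogp", "D_clinical", 1.3, 2.0, weight = 1),
    feature_spec("druggable", "E_annotation", 0.5, 1.5, weight = 1),
    feature_spec("kinome", "E_annotation", 0.5, 1.5, weight = 1),
    feature_spec("membranome", "E_annotation", 0.5, 1.5, weight = 1),
    feature_spec("cosmic", "E_annotation", 0.5, 1.5, weight = 1),
    feature_spec("secretome", "E_annotation", 0.5, 1.5, weight = 1),
    feature_spec("can_gene", "E_annotation", 0.5, 1.5, weight = 1))
}

#' Default block caps
#' @return data.frame of block specs.
#' @export
default_block_specs <- function() {
  rbind(block_spec("A_gex", 4), block_spec("B_cn", 3),
        block_spec("C_cn_gex", 4), block_spec("D_clinical", 2),
        block_spec("E_annotation", 3))
}

#' Bin a feature value into its weighted score
#'
#' @param value numeric feature value(s); `NA` contributes 0 (flagged via the
#'   `"missing"` attribute).
#' @param spec one-row feature spec (see [feature_spec()]).
#' @return numeric score(s): `weight * {0, 1, 2}`.
#' @export
bin_feature_score <- function(value, spec) {
  stopifnot(nrow(spec) == 1, spec$threshold1 <= spec$threshold2,
            spec$weight > 0)
  v <- if (identical(spec$direction, "smaller")) {
    ## mirror so the same bin logic applies
    -value
  } else value
  t1 <- if (identical(spec$direction, "smaller")) -spec$threshold2 else spec$threshold1
  t2 <- if (identical(spec$direction, "smaller")) -spec$threshold1 else spec$threshold2
  s <- ifelse(v < t1, 0, ifelse(v <= t2, 1, 2)) * spec$weight
  miss <- is.na(value)
  s[miss] <- 0
  attr(s, "missing") <- miss
  s
}

#' Score genes across capped feature blocks
#'
#' For each gene, every feature value is binned ([bin_feature_score()]),
#' scores are summed within blocks, capped at the block limit, and divided by
#' the limit, giving a normalized block score in `[0, 1]`; the total is the
#' sum over blocks (range `[0, 5]` with the five standard blocks).  Genes are
#' ranked by total; ties break by block C, then A, then B normalized score,
#' then lexicographic gene ID.
#'
#' @param features data.frame of per-gene feature values with a `gene`
#'   column; missing feature columns contribute 0 (e.g. focality when no
#'   precomputed focality is supplied).
#' @param feature_specs spec table (default [default_feature_specs()]).
#' @param block_specs cap table (default [default_block_specs()]); every
#'   feature's block must be declared here.
#' @return a `gene_scorecard` data.frame: gene, per-feature bin scores
#'   (`score_<name>`), per-block raw and normalized scores, `total`, `rank`.
#' @export
score_blocks <- function(features, feature_specs = default_feature_specs(),
                         block_specs = default_block_specs()) {
  stopifnot(is.data.frame(features), "gene" %in% names(features))
  if (!all(feature_specs$block %in% block_specs$block))
    stop("feature references unknown block: ",
         paste(setdiff(feature_specs$block, block_specs$block), collapse = ", "))
  n <- nrow(features)
  sc <- data.frame(gene = as.character(features$gene),
                   stringsAsFactors = FALSE)
  if (n == 0) {
    for (nm in c(paste0("score_", feature_specs$name),
                 paste0("block_", block_specs$block, "_raw"),
                 paste0("block_", block_specs$block), "total"))
      sc[[nm]] <- numeric(0)
    sc$rank <- integer(0)
    class(sc) <- c("gene_scorecard", "data.frame")
    return(sc)
  }
  binned <- matrix(0, n, nrow(feature_specs),
                   dimnames = list(NULL, feature_specs$name))
  for (j in seq_len(nrow(feature_specs))) {
    fs <- feature_specs[j, ]
    val <- if (fs$name %in% names(features)) features[[fs$name]]
           else rep(NA_real_, n)
    binned[, j] <- as.numeric(bin_feature_score(val, fs))
    sc[[paste0("score_", fs$name)]] <- binned[, j]
  }
  for (b in block_specs$block) {
    cols <- feature_specs$name[feature_specs$block == b]
    raw <- if (length(cols)) rowSums(binned[, cols, drop = FALSE]) else rep(0, n)
    cap <- block_specs$cap[block_specs$block == b]
    sc[[paste0("block_", b, "_raw")]] <- raw
    sc[[paste0("block_", b)]] <- pmin(raw, cap) / cap
  }
  norm_cols <- paste0("block_", block_specs$block)
  sc$total <- rowSums(sc[, norm_cols, drop = FALSE])
  tie <- function(col) if (col %in% names(sc)) sc[[col]] else rep(0, n)
  ord <- order(-sc$total, -tie("block_C_cn_gex"), -tie("block_A_gex"),
               -tie("block_B_cn"), sc$gene)
  sc$rank <- NA_integer_
  sc$rank[ord] <- seq_len(n)
  sc <- sc[ord, , drop = FALSE]
  rownames(sc) <- NULL
  class(sc) <- c("gene_scorecard", "data.frame")
  sc
}

#' @export
print.gene_scorecard <- function(x, n = 10, ...) {
  cat("<gene_scorecard> ", nrow(x), " genes; top ", min(n, nrow(x)), ":\n",
      sep = "")
  cols <- intersect(c("gene", grep("^block_.*[^w]$", names(x), value = TRUE),
                      "total", "rank"), names(x))
  print.data.frame(utils::head(x[, cols], n), digits = 3)
  invisible(x)
}

#' Run the full Target ID candidate-identification analysis
#'
#' Applies the CN gain filter and the cis Spearman correlation filter, builds
#' the per-gene feature table on the genes passing both, and scores it with
#' capped blocks.
#'
#' @param profile a [gene_profile()].
#' @param feature_specs,block_specs scoring configuration.
#' @param annotation optional data.frame of per-gene annotation flags
#'   (column `gene` plus 0/1 columns named after E-block features) and/or a
#'   numeric `focality` column.
#' @param cn_threshold,freq_threshold gain-filter parameters.
#' @param rho_min,p_max correlation-filter parameters.
#' @return object of class `target_id_fit`: list with `gain` and `cis` filter
#'   tables, `passing` gene vector, `features`, and the `scorecard`.
#' @export
target_id <- function(profile,
                      feature_specs = default_feature_specs(),
                      block_specs = default_block_specs(),
                      annotation = NULL,
                      cn_threshold = 2.38, freq_threshold = 0.10,
                      rho_min = 0.30, p_max = 0.01) {
  gain <- cn_gain_filter(profile, cn_threshold, freq_threshold)
  cis <- cis_correlation_filter(profile, rho_min = rho_min, p_max = p_max)
  passing <- intersect(gain$gene[gain$pass], cis$gene[cis$pass])
  features <- compute_feature_table(profile, genes = passing,
                                    gain = gain, cis = cis,
                                    annotation = annotation)
  scorecard <- score_blocks(features, feature_specs, block_specs)
  structure(list(gain = gain, cis = cis, passing = passing,
                 features = features, scorecard = scorecard,
                 profile = profile),
            class = "target_id_fit")
}

#' @export
print.target_id_fit <- function(x, ...) {
  cat("<target_id_fit>\n")
  cat("  gain filter:  ", sum(x$gain$pass), "/", nrow(x$gain), " genes\n", sep = "")
  cat("  cis filter:   ", sum(x$cis$pass), "/", nrow(x$cis), " genes\n", sep = "")
  cat("  scored genes: ", nrow(x$scorecard), "\n", sep = "")
  invisible(x)
}

#' @export
summary.target_id_fit <- function(object, n = 10, ...) {
  print(object)
  print(object$scorecard, n = n)
  invisible(object)
}

#' Per-gene feature table feeding the block scorer
#'
#' Computes the numeric feature values of blocks A-D from the profile
#' (differential expression TNBC vs normal, 2-fold overexpression frequency,
#' CN gain frequency and mean, Spearman rho, CN-state test, recurrence
#' differential expression) and joins optional annotation flags/focality.
#' Significance features are carried as `-log10` of the BH-adjusted p.
#'
#' @param profile a [gene_profile()].
#' @param genes genes to tabulate (default all).
#' @param gain,cis optionally precomputed filter tables (recomputed if NULL).
#' @param annotation optional flags/focality data.frame keyed by `gene`.
#' @return data.frame of feature values, one row per gene.
#' @export
compute_feature_table <- function(profile, genes = NULL, gain = NULL,
                                  cis = NULL, annotation = NULL) {
  if (is.null(genes)) genes <- profile$genes
  if (is.null(gain)) gain <- cn_gain_filter(profile)
  if (is.null(cis)) cis <- cis_correlation_filter(profile, genes = genes)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!length(genes)) return(out)
  tnbc <- profile_samples(profile, "TNBC")
  norm <- profile_samples(profile, "normal")

  de <- differential_expression(profile, "TNBC", "normal", genes = genes)
  out$fc_tnbc_normal <- de$fold_change
  out$de_neglogp <- -log10(de$p_adj)

  ## frequency of TNBC samples with expression >= 2x the normal mean (log2 +1)
  ref <- rowMeans(profile$gex[genes, norm, drop = FALSE])
  out$freq_2fold <- rowMeans(profile$gex[genes, tnbc, drop = FALSE] >= ref + 1)

  gi <- match(genes, gain$gene)
  out$gain_freq <- gain$gain_freq[gi]
  out$mean_cn_tnbc <- rowMeans(profile$cn[genes, tnbc, drop = FALSE],
                               na.rm = TRUE)

  ci <- match(genes, cis$gene)
  out$spearman_rho <- cis$rho[ci]
  cst <- cn_state_expression_test(profile, genes = genes)
  out$cn_state_neglogp <- -log10(cst$p_adj)

  if (all(c("recurrence") %in% names(profile$samples)) &&
      length(unique(profile$samples$recurrence[profile$samples$group == "TNBC"])) > 1) {
    rec <- profile$samples$sample_id[profile$samples$group == "TNBC" &
                                       profile$samples$recurrence == 1]
    nonrec <- setdiff(tnbc, rec)
    if (length(rec) >= 2 && length(nonrec) >= 2) {
      rde <- differential_expression(profile, rec, nonrec, genes = genes)
      out$rec_fc <- rde$fold_change
      out$rec_neglogp <- -log10(rde$p_adj)
    }
  }
  if (!is.null(annotation)) {
    ai <- match(genes, annotation$gene)
    for (col in setdiff(names(annotation), "gene"))
      out[[col]] <- annotation[[col]][ai]
  }
  out
}

#' Assemble the final candidate list from both selection arms
#'
#' Union of the top `k_top` genes of the Target ID ranking (arm 1), the
#' intersection of the expression-centered gene set with an
#' annotation-curated list (arm 2), and manual additions, with a provenance
#' label per gene.
#'
#' @param scorecard a `gene_scorecard` (or `target_id_fit`).
#' @param expression_set character vector of expression-centered genes.
#' @param curated character vector of annotation-curated genes intersected
#'   with `expression_set` (default: keep all of `expression_set`).
#' @param manual extra genes added to arm 2 by manual review.
#' @param k_top number of top-ranked genes taken from arm 1 (default 85).
#' @return data.frame `gene`, `provenance` (`"arm1"`, `"arm2"`, `"both"`).
#' @export
assemble_candidates <- function(scorecard, expression_set,
                                curated = NULL, manual = character(),
                                k_top = 85) {
  if (inherits(scorecard, "target_id_fit")) scorecard <- scorecard$scorecard
  arm1 <- utils::head(scorecard$gene[order(scorecard$rank)], k_top)
  arm2 <- if (is.null(curated)) expression_set
          else intersect(expression_set, curated)
  arm2 <- union(arm2, manual)
  all_genes <- union(arm1, arm2)
  data.frame(gene = all_genes,
             provenance = ifelse(all_genes %in% arm1 & all_genes %in% arm2,
                                 "both",
                                 ifelse(all_genes %in% arm1, "arm1", "arm2")),
             stringsAsFactors = FALSE)
}
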