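#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the discovery cohort: 140 TNBC, 21 HER2-positive/ER-negative
#' and 21 ER-positive tumors plus 9 normal breast epithelium samples, with a
#' small set of planted cis-regulated driver genes whose expression tracks copy
#' number, and one planted co-upregulated gene cluster carrying a
#' high-expression subpopulation.
#'
#' @param n_genes total number of genes.
#' @param n_tnbc,n_her2,n_er,n_normal sample counts per group.
#' @param n_cis_driver_genes number of planted genes whose expression tracks CN.
#' @param cis_rho target CN-expression Spearman correlation of planted genes
#'   (in `[0,1]`; realised values land within about 0.1).
#' @param gain_freq fraction of TNBC samples carrying a CN gain at planted
#'   genes (gains are assigned to exactly `ceiling(gain_freq * n_tnbc)`
#'   samples, so the realised frequency is never below the target).
#' @param cn_gain_level CN value at gained loci (absolute-like scale; must sit
#'   at or above the gain threshold 2.38 for the planted genes to be
#'   recoverable by the gain filter).
#' @param cn_noise_sd SD of background CN noise around the diploid level 2.
#' @param noise_sd expression noise SD (log2 units).
#' @param n_coexpr_genes size of the planted co-upregulated cluster.
#' @param coexpr_loading loading of the cluster genes on a shared latent
#'   factor (log2 units).
#' @param coexpr_shift log2 upshift of cluster genes in the high-score
#'   subpopulation.
#' @param coexpr_high_fraction fraction of TNBC samples in the high-score
#'   subpopulation (default 0.88, the proportion the composite score is
#'   expected to isolate).
#' @param recurrence_rate probability a tumor sample has a recurrence event.
#' @param seed integer RNG seed; identical configs reproduce byte-identical
#'   cohorts.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_genes = 2000,
                              n_tnbc = 140, n_her2 = 21, n_er = 21,
                              n_normal = 9,
                              n_cis_driver_genes = 20,
                              cis_rho = 0.8,
                              gain_freq = 0.4,
                              cn_gain_level = 3.5,
                              cn_noise_sd = 0.1,
                              noise_sd = 1.0,
                              n_coexpr_genes = 13,
                              coexpr_loading = 0.8,
                              coexpr_shift = 3,
                              coexpr_high_fraction = 0.88,
                              recurrence_rate = 0.35,
                              seed = 1L) {
  cfg <- list(n_genes = n_genes, n_tnbc = n_tnbc, n_her2 = n_her2,
              n_er = n_er, n_normal = n_normal,
              n_cis_driver_genes = n_cis_driver_genes, cis_rho = cis_rho,
              gain_freq = gain_freq, cn_gain_level = cn_gain_level,
              cn_noise_sd = cn_noise_sd, noise_sd = noise_sd,
              n_coexpr_genes = n_coexpr_genes,
              coexpr_loading = coexpr_loading, coexpr_shift = coexpr_shift,
              coexpr_high_fraction = coexpr_high_fraction,
              recurrence_rate = recurrence_rate, seed = as.integer(seed))
  stopifnot(n_genes > 0, n_tnbc > 0, n_her2 > 0, n_er > 0, n_normal > 0,
            n_cis_driver_genes >= 0, n_coexpr_genes >= 0,
            gain_freq >= 0, gain_freq <= 1,
            cis_rho >= 0, cis_rho <= 1)
  if (cis_rho >= 1 && noise_sd > 0)
    stop("cis_rho = 1 with noise_sd > 0 is unattainable; lower cis_rho or set noise_sd = 0")
  if (n_cis_driver_genes + n_coexpr_genes > n_genes)
    stop("planted gene sets exceed n_genes")
  class(cfg) <- "cohort_sim_config"
  cfg
}

#' Simulate a TNBC-enriched cohort with planted cis-driven genes
#'
#' Generates paired CN/expression matrices with known planted structure:
#' `n_cis_driver_genes` genes gain copies (CN = `cn_gain_level`, upward jitter
#' only, so the gain frequency is guaranteed) in a fixed fraction of TNBC
#' samples and have expression coupled to CN as `gex = a + b * cn + eps`, with
#' `b` solved per gene from the realised CN spread so the CN-expression
#' correlation lands near `cis_rho`.  A further `n_coexpr_genes` genes share a
#' latent factor plus a subpopulation upshift, giving a co-upregulated cluster
#' a composite score can isolate.  Normal samples carry no CN (all `NA`).
#'
#' @param config a [cohort_sim_config()].
#' @return a [gene_profile()] whose `truth` attribute records the planted
#'   cis genes, gained samples per gene, cluster genes and high-score samples.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  g <- config
  n_samp <- g$n_tnbc + g$n_her2 + g$n_er + g$n_normal
  sample_id <- c(sprintf("T%03d", seq_len(g$n_tnbc)),
                 sprintf("H%03d", seq_len(g$n_her2)),
                 sprintf("E%03d", seq_len(g$n_er)),
                 sprintf("N%03d", seq_len(g$n_normal)))
  group <- rep(c("TNBC", "HER2", "ER", "normal"),
               c(g$n_tnbc, g$n_her2, g$n_er, g$n_normal))
  genes <- sprintf("G%04d", seq_len(g$n_genes))
  cis_genes <- if (g$n_cis_driver_genes > 0) genes[seq_len(g$n_cis_driver_genes)] else character()
  coexpr_genes <- if (g$n_coexpr_genes > 0)
    genes[g$n_cis_driver_genes + seq_len(g$n_coexpr_genes)] else character()

  is_tumor <- group != "normal"
  tnbc <- which(group == "TNBC")

  ## CN: diploid background noise; normals lack CN entirely
  cn <- matrix(2 + stats::rnorm(g$n_genes * n_samp, 0, g$cn_noise_sd),
               g$n_genes, n_samp, dimnames = list(genes, sample_id))
  cn[, !is_tumor] <- NA_real_

  n_gain <- ceiling(g$gain_freq * g$n_tnbc)
  gain_samples <- vector("list", length(cis_genes))
  names(gain_samples) <- cis_genes
  for (gn in cis_genes) {
    gained <- sort(sample(tnbc, n_gain))
    ## upward-only jitter keeps every gained CN at or above cn_gain_level
    cn[gn, gained] <- g$cn_gain_level + abs(stats::rnorm(n_gain, 0, 0.25))
    gain_samples[[gn]] <- sample_id[gained]
  }

  ## Expression: per-gene baseline + noise
  mu <- stats::rnorm(g$n_genes, 7, 1)
  gex <- matrix(mu + stats::rnorm(g$n_genes * n_samp, 0, g$noise_sd),
                g$n_genes, n_samp, dimnames = list(genes, sample_id))

  ## cis coupling: gex = mu + b * (cn - 2) + eps.  A Pearson-based slope
  ## understates the Spearman target on mixture-shaped CN, so b is solved by
  ## root-finding on a Monte-Carlo estimate of the expected Spearman (fixed
  ## reusable noise draws keep the objective smooth and deterministic).
  for (gn in cis_genes) {
    cn_t <- cn[gn, tnbc]
    b <- if (g$noise_sd == 0 || g$cis_rho >= 1) 1 else {
      b0 <- g$cis_rho / sqrt(1 - g$cis_rho^2) * g$noise_sd / stats::sd(cn_t)
      eps_cal <- matrix(stats::rnorm(20 * length(cn_t), 0, g$noise_sd), 20)
      f <- function(b) mean(apply(eps_cal, 1, function(e)
        stats::cor(cn_t, b * (cn_t - 2) + e, method = "spearman"))) - g$cis_rho
      if (g$cis_rho == 0) 0
      else stats::uniroot(f, c(b0 / 4, b0 * 8), extendInt = "upX")$root
    }
    add <- b * (cn[gn, ] - 2)
    add[is.na(add)] <- 0            # normals: no CN, expression stays baseline
    gex[gn, ] <- gex[gn, ] + add
  }

  ## planted co-upregulated cluster: shared latent factor + subpop upshift
  high_samples <- character()
  if (length(coexpr_genes)) {
    n_high <- round(g$coexpr_high_fraction * g$n_tnbc)
    high_idx <- sort(sample(tnbc, n_high))
    high_samples <- sample_id[high_idx]
    f <- stats::rnorm(n_samp)
    shift <- numeric(n_samp)
    shift[high_idx] <- g$coexpr_shift
    for (gn in coexpr_genes)
      gex[gn, ] <- gex[gn, ] + g$coexpr_loading * f + shift
  }

  rec <- ifelse(is_tumor, stats::rbinom(n_samp, 1, g$recurrence_rate), 0L)
  rec_time <- round(stats::rexp(n_samp, 1 / 48), 1)

  samples <- data.frame(sample_id = sample_id, group = group,
                        recurrence = rec, recurrence_time = rec_time,
                        stringsAsFactors = FALSE)
  prof <- gene_profile(cn, gex, samples)
  attr(prof, "truth") <- list(cis_genes = cis_genes,
                              gain_samples = gain_samples,
                              coexpr_genes = coexpr_genes,
                              high_samples = high_samples,
                              config = g)
  prof
}
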