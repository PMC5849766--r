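#' Configuration for the synthetic RNAi screen generator
#'
#' Emulates a 96-well viability screen run in triplicate: interior wells only
#' (the outermost rows/columns stay empty to avoid edge effects), multiple
#' positive (cell-killing) and negative (non-silencing) controls per plate, and
#' gene sample wells whose true effects are expressed on the NPI scale.
#' Raw-scale control magnitudes are free parameters; the defaults are
#' fluorescence-like units whose implied negative-control NPI spread matches a
#' mean of 0.18% and SD of 5.94%, so a threshold derived from the simulated
#' controls sits near 18%.
#'
#' @param n_genes number of genes screened (pooled siRNA, one well per gene
#'   per plate).
#' @param n_lines number of malignant cell lines; the non-malignant comparator
#'   `"HMEC"` is always added.
#' @param plate_rows,plate_cols plate layout (default 8 x 12); only interior
#'   wells are used.
#' @param n_pos_ctrl,n_neg_ctrl control wells per plate.
#' @param neg_mean,neg_sd raw-scale negative-control (viable) parameters.
#' @param pos_mean,pos_sd raw-scale positive-control (killed) parameters;
#'   must satisfy `pos_mean < neg_mean`.
#' @param null_npi_mean,null_npi_sd measurement-level NPI distribution of
#'   unplanted gene/line pairs (defaults 0.18 and 5.94, matching the
#'   negative-control spread of the reference screen).
#' @param gene_effect_sd SD of a per gene-by-line baseline effect (NPI
#'   percent), constant across replicates: the essentiality spread that makes
#'   replicate well vectors concordant.  The default 13 yields a mean
#'   replicate r-squared near 0.7; set 0 for an idealized screen whose null
#'   wells are pure measurement noise (no replicate structure).
#' @param planted_hits data.frame with columns `gene`, `line`, `npi_mean`,
#'   `npi_sd`: gene-by-cell-line dependencies to plant.
#' @param n_replicates replicate plates per (gene set, line); must be >= 3.
#' @param n_oligos oligos per gene in the knockdown table.
#' @param kd_mean,kd_sd per-oligo true knockdown distribution (percent).
#' @param plate_scale_sd SD of a per-plate multiplicative scale factor
#'   (removed by plate-median normalization).
#' @param seed integer RNG seed.
#' @return a `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 40, n_lines = 4,
                              plate_rows = 8, plate_cols = 12,
                              n_pos_ctrl = 4, n_neg_ctrl = 4,
                              neg_mean = 50000, neg_sd = 3100,
                              pos_mean = 5000, pos_sd = 800,
                              null_npi_mean = 0.18, null_npi_sd = 5.94,
                              gene_effect_sd = 13,
                              planted_hits = NULL,
                              n_replicates = 3,
                              n_oligos = 4,
                              kd_mean = 75, kd_sd = 12,
                              plate_scale_sd = 0.05,
                              seed = 1L) {
  if (is.null(planted_hits))
    planted_hits <- data.frame(gene = character(), line = character(),
                               npi_mean = numeric(), npi_sd = numeric())
  cfg <- list(n_genes = n_genes, n_lines = n_lines,
              plate_rows = plate_rows, plate_cols = plate_cols,
              n_pos_ctrl = n_pos_ctrl, n_neg_ctrl = n_neg_ctrl,
              neg_mean = neg_mean, neg_sd = neg_sd,
              pos_mean = pos_mean, pos_sd = pos_sd,
              null_npi_mean = null_npi_mean, null_npi_sd = null_npi_sd,
              gene_effect_sd = gene_effect_sd,
              planted_hits = planted_hits,
              n_replicates = n_replicates, n_oligos = n_oligos,
              kd_mean = kd_mean, kd_sd = kd_sd,
              plate_scale_sd = plate_scale_sd, seed = as.integer(seed))
  stopifnot(n_genes > 0, n_lines > 0, plate_rows >= 3, plate_cols >= 3,
            n_pos_ctrl >= 2, n_neg_ctrl >= 2,
            all(c("gene", "line", "npi_mean", "npi_sd") %in% names(planted_hits)))
  if (pos_mean >= neg_mean)
    stop("positive control kills cells: pos_mean must be < neg_mean on the raw scale")
  if (n_replicates < 3) stop("n_replicates must be >= 3")
  n_interior <- (plate_rows - 2) * (plate_cols - 2)
  if (n_interior < n_pos_ctrl + n_neg_ctrl + 1)
    stop("plate layout too small for requested control wells")
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Simulate RNAi screen plates and a per-oligo knockdown table
#'
#' Produces well-level raw viability data for triplicate plates per
#' (gene chunk, cell line): interior wells hold one pooled-siRNA well per gene
#' plus positive/negative control wells; exterior wells are emitted as
#' `empty`.  A sample well's raw value is the negative-control mean displaced
#' by its true NPI (planted effect or null), plus a per-plate multiplicative
#' scale factor.  The knockdown table lists `n_oligos` oligos per gene with
#' true knockdown percentages.
#'
#' @param config a [screen_sim_config()].
#' @return list with elements `plates` (data.frame: plate_id, row, col,
#'   reagent_type, gene, oligo, cell_line, replicate, raw_value; layout dims
#'   kept as attributes), `kd` (gene, oligo, kd_percent) and `truth`
#'   (planted hits and null parameters).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  g <- config
  lines <- c("HMEC", sprintf("BC%02d", seq_len(g$n_lines)))
  genes <- sprintf("SG%03d", seq_len(g$n_genes))

  ## per gene-by-line essentiality baseline, constant across replicates
  e_gl <- matrix(stats::rnorm(g$n_genes * length(lines), 0, g$gene_effect_sd),
                 g$n_genes, length(lines), dimnames = list(genes, lines))

  interior <- expand.grid(row = 2:(g$plate_rows - 1), col = 2:(g$plate_cols - 1))
  capacity <- nrow(interior) - g$n_pos_ctrl - g$n_neg_ctrl
  chunks <- split(genes, ceiling(seq_along(genes) / capacity))

  planted <- g$planted_hits
  key <- function(gene, line) paste(gene, line, sep = "\r")
  pmap <- if (nrow(planted)) {
    stats::setNames(seq_len(nrow(planted)), key(planted$gene, planted$line))
  } else stats::setNames(integer(), character())

  out <- vector("list", length(chunks) * length(lines) * g$n_replicates)
  i <- 0L
  for (ci in seq_along(chunks)) {
    chunk <- chunks[[ci]]
    ## fixed well assignment shared across lines and replicates
    n_use <- length(chunk) + g$n_pos_ctrl + g$n_neg_ctrl
    wells <- interior[seq_len(n_use), , drop = FALSE]
    role <- c(rep("sample", length(chunk)),
              rep("pos_ctrl", g$n_pos_ctrl), rep("neg_ctrl", g$n_neg_ctrl))
    well_gene <- c(chunk, rep(NA_character_, g$n_pos_ctrl + g$n_neg_ctrl))
    for (line in lines) {
      ## per-gene true NPI for this line, shared across replicates in mean
      for (rep_i in seq_len(g$n_replicates)) {
        scale <- exp(stats::rnorm(1, 0, g$plate_scale_sd))
        idx <- pmap[key(chunk, line)]
        npi_mu <- ifelse(is.na(idx), g$null_npi_mean + e_gl[chunk, line],
                         planted$npi_mean[idx])
        npi_sd <- ifelse(is.na(idx), g$null_npi_sd, planted$npi_sd[idx])
        npi <- stats::rnorm(length(chunk), npi_mu, npi_sd)
        raw <- c(g$neg_mean + npi / 100 * (g$pos_mean - g$neg_mean),
                 stats::rnorm(g$n_pos_ctrl, g$pos_mean, g$pos_sd),
                 stats::rnorm(g$n_neg_ctrl, g$neg_mean, g$neg_sd)) * scale
        i <- i + 1L
        out[[i]] <- data.frame(
          plate_id = sprintf("P%02d_%s_r%d", ci, line, rep_i),
          row = wells$row, col = wells$col,
          reagent_type = role, gene = well_gene,
          oligo = ifelse(role == "sample", "pool", NA_character_),
          cell_line = line, replicate = rep_i, raw_value = raw,
          stringsAsFactors = FALSE)
      }
    }
  }
  plates <- do.call(rbind, out)
  attr(plates, "plate_rows") <- g$plate_rows
  attr(plates, "plate_cols") <- g$plate_cols

  kd <- data.frame(
    gene = rep(genes, each = g$n_oligos),
    oligo = rep(sprintf("o%d", seq_len(g$n_oligos)), times = g$n_genes),
    kd_percent = pmin(100, pmax(0, stats::rnorm(g$n_genes * g$n_oligos,
                                                g$kd_mean, g$kd_sd))))
  list(plates = plates, kd = kd,
       truth = list(planted_hits = planted, genes = genes, lines = lines,
                    null_npi_mean = g$null_npi_mean,
                    null_npi_sd = g$null_npi_sd, config = g))
}
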