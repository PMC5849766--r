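#' Read a paired-profile directory into a gene_profile
#'
#' Expects gene-by-sample TSV matrices (first column the gene ID) and a sample
#' metadata TSV.
#'
#' @param cn_file,gex_file paths to CN and expression TSVs.
#' @param meta_file path to the sample metadata TSV (`sample_id`, `group`,
#'   optional `recurrence`, `recurrence_time`).
#' @param cn_scale CN scale declaration (default `"absolute"`).
#' @return a [gene_profile()].
#' @export
read_profile <- function(cn_file, gex_file, meta_file,
                         cn_scale = "absolute") {
  read_mat <- function(f) {
    d <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "double"
    m
  }
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  gene_profile(read_mat(cn_file), read_mat(gex_file), meta,
               cn_scale = cn_scale)
}

#' Write a gene_profile as TSV files
#'
#' @param profile a [gene_profile()].
#' @param dir output directory (created if needed); writes `cn.tsv`,
#'   `gex.tsv`, `meta.tsv`.
#' @return invisibly, the paths written.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cn.tsv", "gex.tsv", "meta.tsv"))
  write_mat <- function(m, f) {
    d <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(profile$cn, paths[1])
  write_mat(profile$gex, paths[2])
  utils::write.table(profile$samples, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read screen plate data from CSV
#'
#' @param file plate CSV (plate_id, row, col, reagent_type, gene, oligo,
#'   cell_line, replicate, raw_value).
#' @param plate_rows,plate_cols layout attached as attributes.
#' @return plate data.frame.
#' @export
read_plates <- function(file, plate_rows = 8, plate_cols = 12) {
  p <- utils::read.csv(file, stringsAsFactors = FALSE)
  attr(p, "plate_rows") <- plate_rows
  attr(p, "plate_cols") <- plate_cols
  p
}

#' Write screen plate data to CSV
#' @param plates plate data.frame.
#' @param file output path.
#' @export
write_plates <- function(plates, file) {
  utils::write.csv(plates, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read feature/block scoring configuration from YAML
#'
#' The YAML carries two lists, `features` (name, block, threshold1,
#' threshold2, weight, optional direction) and `blocks` (block, cap).
#'
#' @param file YAML path.
#' @return list with `feature_specs` and `block_specs` data.frames.
#' @export
read_feature_specs <- function(file) {
  y <- yaml::read_yaml(file)
  fs <- do.call(rbind, lapply(y$features, function(f)
    feature_spec(f$name, f$block, f$threshold1, f$threshold2,
                 weight = f$weight %||% 1,
                 direction = f$direction %||% "larger")))
  bs <- do.call(rbind, lapply(y$blocks, function(b)
    block_spec(b$block, b$cap)))
  list(feature_specs = fs, block_specs = bs)
}

#' Write a scorecard (or any result table) as TSV
#' @param x data.frame.
#' @param file output path.
#' @export
write_result_tsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a screen QC report as JSON
#'
#' @param screen a `screen_result` from [screen_npi()].
#' @param file output path.
#' @export
write_qc_report <- function(screen, file) {
  stopifnot(inherits(screen, "screen_result"))
  rep_r2 <- lapply(screen$qc$replicates, function(q)
    list(mean_r2 = unname(q$mean_r2), excluded = q$excluded,
         overall_mean_r2 = q$overall_mean_r2))
  jsonlite::write_json(
    list(zprime = screen$qc$plates, excluded_plates = screen$qc$excluded,
         replicate_qc = rep_r2, threshold = screen$threshold),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
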