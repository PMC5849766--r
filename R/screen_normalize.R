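#' Plate-median normalization
#'
#' Divides every well of a plate by the median raw value of that plate's
#' interior sample wells (the outermost rows/columns are excluded from use to
#' avoid edge effects); control wells are scaled by the same factor so the
#' normalization targets the sample distribution.
#'
#' @param plates well-level data.frame (plate_id, row, col, reagent_type,
#'   raw_value, ...); plate layout is read from the `plate_rows`/`plate_cols`
#'   attributes or the arguments.
#' @param plate_rows,plate_cols plate dimensions (defaults: attributes on
#'   `plates`, else 8 x 12).
#' @return `plates` with columns `interior` and `normalized_value` added.
#' @export
plate_median_normalize <- function(plates, plate_rows = NULL, plate_cols = NULL) {
  if (is.null(plate_rows)) plate_rows <- attr(plates, "plate_rows") %||% 8
  if (is.null(plate_cols)) plate_cols <- attr(plates, "plate_cols") %||% 12
  plates$interior <- plates$row > 1 & plates$row < plate_rows &
    plates$col > 1 & plates$col < plate_cols
  meds <- tapply(
    plates$raw_value[plates$interior & plates$reagent_type == "sample"],
    plates$plate_id[plates$interior & plates$reagent_type == "sample"],
    stats::median)
  if (any(is.na(meds)) || length(meds) == 0)
    stop("plate without interior sample wells")
  if (any(meds == 0)) stop("zero plate median; cannot normalize")
  m <- meds[as.character(plates$plate_id)]
  if (anyNA(m)) stop("plate without interior sample wells")
  plates$normalized_value <- plates$raw_value / as.numeric(m)
  plates
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-plate control statistics
#'
#' @param plates normalized plate data ([plate_median_normalize()]).
#' @return data.frame per plate: `plate_id`, `mu_pos`, `sd_pos`, `mu_neg`,
#'   `sd_neg`, `n_pos`, `n_neg` of normalized control values.
#' @export
control_stats <- function(plates) {
  stopifnot("normalized_value" %in% names(plates))
  ids <- unique(plates$plate_id)
  out <- lapply(ids, function(id) {
    p <- plates[plates$plate_id == id, ]
    pos <- p$normalized_value[p$reagent_type == "pos_ctrl"]
    neg <- p$normalized_value[p$reagent_type == "neg_ctrl"]
    data.frame(plate_id = id,
               mu_pos = mean(pos), sd_pos = stats::sd(pos),
               mu_neg = mean(neg), sd_neg = stats::sd(neg),
               n_pos = length(pos), n_neg = length(neg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalized percent inhibition
#'
#' `NPI = (x - mu_neg) / (mu_pos - mu_neg) * 100`, where the control means
#' come from the same plate (or declared normalization scope).  The value is
#' not clamped and may fall below 0 or exceed 100.
#'
#' @param x normalized viability value(s).
#' @param mu_pos,mu_neg positive / negative control means.
#' @return NPI in percent.
#' @export
compute_npi <- function(x, mu_pos, mu_neg) {
  if (any(mu_pos == mu_neg))
    stop("mu_pos equals mu_neg: NPI undefined, plate rejected")
  (x - mu_neg) / (mu_pos - mu_neg) * 100
}

#' Add per-well NPI to normalized plate data
#'
#' @param plates normalized plate data.
#' @param stats optional precomputed [control_stats()].
#' @return `plates` with an `npi` column.
#' @export
npi_wells <- function(plates, stats = NULL) {
  if (is.null(stats)) stats <- control_stats(plates)
  i <- match(plates$plate_id, stats$plate_id)
  plates$npi <- compute_npi(plates$normalized_value,
                            stats$mu_pos[i], stats$mu_neg[i])
  plates
}

#' Summarize per gene x cell line NPI across replicates
#'
#' @param plates plate data carrying `npi` ([npi_wells()]).
#' @param exclude optional data.frame (`plate_id`) of excluded plates, or a
#'   character vector of plate IDs.
#' @return data.frame `gene`, `cell_line`, `n_rep`, `mean_npi`, `sem`
#'   (SEM is NA with a single replicate), plus per-oligo rows when oligos
#'   other than `"pool"` are present (column `oligo`).
#' @export
summarize_gene_line <- function(plates, exclude = NULL) {
  stopifnot("npi" %in% names(plates))
  if (!is.null(exclude)) {
    ids <- if (is.data.frame(exclude)) exclude$plate_id else exclude
    plates <- plates[!plates$plate_id %in% ids, ]
  }
  s <- plates[plates$reagent_type == "sample" & !is.na(plates$gene), ]
  key <- interaction(s$gene, s$oligo, s$cell_line, drop = TRUE)
  agg <- lapply(split(s, key), function(d) {
    ## replicate-level means first, then across replicates
    reps <- tapply(d$npi, d$replicate, mean)
    data.frame(gene = d$gene[1], oligo = d$oligo[1], cell_line = d$cell_line[1],
               n_rep = length(reps), mean_npi = mean(reps),
               sem = if (length(reps) > 1) stats::sd(reps) / sqrt(length(reps))
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$gene, out$cell_line), ]
}
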