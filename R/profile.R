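#' Paired copy-number / expression profile of a breast cancer cohort
#'
#' Bundles a gene-by-sample absolute-copy-number-like matrix, a gene-by-sample
#' log2-like expression matrix and a sample metadata table into a validated
#' container used by all downstream Target ID operations.
#'
#' Normal-tissue samples are allowed to lack copy number (their CN columns are
#' `NA`); this mirrors cohorts where normals contribute expression only.
#'
#' @param cn numeric matrix, genes x samples; absolute-copy-number-like scale
#'   centred at 2 (the threshold semantics apply to whatever gene-centric scale
#'   the input declares via `cn_scale`).
#' @param gex numeric matrix, genes x samples, log2-like expression.
#' @param samples data.frame with columns `sample_id`, `group` (one of
#'   `"TNBC"`, `"HER2"`, `"ER"`, `"normal"`), and optionally `recurrence`
#'   (0/1) and `recurrence_time`.
#' @param cn_scale character tag recording the CN scale of `cn`
#'   (default `"absolute"`).
#' @return an object of class `gene_profile`.
#' @export
gene_profile <- function(cn, gex, samples, cn_scale = "absolute") {
  stopifnot(is.matrix(cn), is.matrix(gex), is.data.frame(samples))
  if (is.null(rownames(cn)) || is.null(rownames(gex)))
    stop("cn and gex must have gene IDs as rownames")
  if (anyDuplicated(rownames(cn)) || anyDuplicated(rownames(gex)))
    stop("duplicated gene IDs are not allowed")
  if (!identical(rownames(cn), rownames(gex)))
    stop("cn and gex must share an identical gene index")
  if (!identical(colnames(cn), colnames(gex)))
    stop("cn and gex must share an identical sample index")
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples needs at least columns 'sample_id' and 'group'")
  if (!identical(colnames(cn), as.character(samples$sample_id)))
    stop("sample metadata must match matrix columns (same order)")
  bad <- setdiff(unique(as.character(samples$group)),
                 c("TNBC", "HER2", "ER", "normal"))
  if (length(bad))
    stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  structure(
    list(cn = cn, gex = gex, samples = samples,
         genes = rownames(cn), cn_scale = cn_scale),
    class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("<gene_profile> ", length(x$genes), " genes x ",
      nrow(x$samples), " samples\n", sep = "")
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  CN scale:", x$cn_scale)
  ncn <- sum(colSums(!is.na(x$cn)) == 0)
  if (ncn) cat("  (", ncn, " samples lack CN)", sep = "")
  cat("\n")
  invisible(x)
}

#' Sample IDs of a profile belonging to a group
#' @param profile a `gene_profile`.
#' @param group group label, e.g. `"TNBC"`.
#' @return character vector of sample IDs.
#' @export
profile_samples <- function(profile, group) {
  as.character(profile$samples$sample_id[profile$samples$group == group])
}
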