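#' Z-prime plate quality factor
#'
#' `Z' = 1 - (3 * SD_pos + 3 * SD_neg) / (mean_pos - mean_neg)`, computed in
#' NPI space where the positive-control mean exceeds the negative-control
#' mean; no absolute value is taken in the denominator.  A plate is valid
#' when `Z' >= valid_min`.
#'
#' @param pos,neg numeric vectors of positive / negative control values
#'   (NPI scale), at least 2 each.
#' @param valid_min validity threshold (default 0.3).
#' @return list `zprime`, `valid` (`NA`/invalid when control means are equal).
#' @export
zprime <- function(pos, neg, valid_min = 0.3) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  denom <- mean(pos) - mean(neg)
  if (denom == 0) return(list(zprime = NA_real_, valid = FALSE))
  z <- 1 - (3 * stats::sd(pos) + 3 * stats::sd(neg)) / denom
  list(zprime = z, valid = !is.na(z) && z >= valid_min)
}

#' Replicate concordance quality control
#'
#' Pairwise Pearson correlation between replicate well vectors (matched
#' wells).  A replicate is excluded when its mean r-squared against the other
#' replicates falls below `r2_min`; a replicate whose mean correlation is
#' negative fails regardless of the squared magnitude (anti-correlated
#' replicates are not concordant).
#'
#' @param rep_matrix numeric matrix, wells x replicates.
#' @param r2_min exclusion threshold on mean pairwise r^2 (default 0.5).
#' @param rule `"mean"` (default) excludes on the mean pairwise r^2;
#'   `"any"` requires every pairwise r^2 to reach `r2_min`.
#' @return list `kept` (column indices), `excluded`, `r` (pairwise correlation
#'   matrix), `mean_r2` (per replicate), `overall_mean_r2`, `failed`
#'   (TRUE when every replicate was excluded).
#' @export
replicate_qc <- function(rep_matrix, r2_min = 0.5, rule = c("mean", "any")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(rep_matrix), ncol(rep_matrix) >= 2)
  k <- ncol(rep_matrix)
  r <- stats::cor(rep_matrix)
  diag(r) <- NA
  r2 <- r^2
  ## signed handling: negative correlation disqualifies the pair outright
  r2[r < 0] <- 0
  mean_r2 <- rowMeans(r2, na.rm = TRUE)
  keep <- if (rule == "mean") mean_r2 >= r2_min
          else apply(r2, 1, function(x) all(x[!is.na(x)] >= r2_min))
  list(kept = which(keep), excluded = which(!keep), r = r,
       mean_r2 = mean_r2,
       overall_mean_r2 = mean(r2[upper.tri(r2)], na.rm = TRUE),
       failed = !any(keep))
}

#' Screen-wide hit threshold from negative-control NPIs
#'
#' Three standard deviations above the negative-control mean.  The printed
#' negative-control summary of the reference screen (mean 0.18%, SD 5.94)
#' yields 18.0, matching the published 18.01% cut to within rounding.
#'
#' @param neg_npi numeric vector of negative-control NPI values, or `NULL`
#'   when `mean`/`sd` summaries are given directly.
#' @param mean,sd optional summary statistics used instead of raw values.
#' @return threshold in percent NPI.
#' @export
hit_threshold <- function(neg_npi = NULL, mean = NULL, sd = NULL) {
  if (is.null(neg_npi)) {
    if (is.null(mean) || is.null(sd))
      stop("supply raw negative-control NPIs or both mean and sd")
  } else {
    if (length(neg_npi) < 2) stop("need at least 2 values to estimate the SD")
    mean <- base::mean(neg_npi)
    sd <- stats::sd(neg_npi)
  }
  mean + 3 * sd
}

#' End-to-end screen NPI pipeline with quality control
#'
#' Normalizes plates against the plate median, computes per-plate control
#' statistics and Z-prime (plates below `zprime_min` are excluded), runs
#' replicate concordance QC within each (cell line, gene set) plate group,
#' and summarizes kept wells into per gene x line NPIs.
#'
#' @param plates raw plate data (see [simulate_screen()] for the format).
#' @param zprime_min plate validity threshold (default 0.3).
#' @param r2_min replicate-exclusion threshold; `NULL` disables replicate QC.
#' @return object of class `screen_result`: `results` (gene x line summary),
#'   `qc` (per-plate Z-prime table, excluded plates, per-group mean r^2),
#'   `threshold` (derived from all kept negative-control NPIs).
#' @export
screen_npi <- function(plates, zprime_min = 0.3, r2_min = 0.5) {
  plates <- plate_median_normalize(plates)
  cs <- control_stats(plates)
  plates <- npi_wells(plates, cs)
  ## Z' in NPI space per plate
  zp <- vapply(cs$plate_id, function(id) {
    p <- plates[plates$plate_id == id, ]
    zprime(p$npi[p$reagent_type == "pos_ctrl"],
           p$npi[p$reagent_type == "neg_ctrl"],
           valid_min = zprime_min)$zprime
  }, numeric(1))
  qc <- data.frame(plate_id = cs$plate_id, zprime = zp,
                   valid = !is.na(zp) & zp >= zprime_min,
                   stringsAsFactors = FALSE)
  excluded <- qc$plate_id[!qc$valid]

  rep_report <- list()
  if (!is.null(r2_min)) {
    keep <- !plates$plate_id %in% excluded & plates$reagent_type == "sample"
    s <- plates[keep, ]
    s$grp <- sub("_r[0-9]+$", "", s$plate_id)
    for (g in unique(s$grp)) {
      d <- s[s$grp == g, ]
      wide <- tapply(d$npi, list(paste(d$row, d$col), d$replicate), mean)
      if (ncol(wide) < 2) next
      qr <- replicate_qc(wide, r2_min = r2_min)
      rep_report[[g]] <- qr
      if (length(qr$excluded))
        excluded <- c(excluded,
                      paste0(g, "_r", colnames(wide)[qr$excluded]))
    }
  }
  results <- summarize_gene_line(plates, exclude = excluded)
  neg <- plates$npi[plates$reagent_type == "neg_ctrl" &
                      !plates$plate_id %in% excluded]
  structure(list(results = results,
                 qc = list(plates = qc, excluded = excluded,
                           replicates = rep_report),
                 threshold = hit_threshold(neg)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x$results), " gene x line summaries\n", sep = "")
  cat("  plates: ", sum(x$qc$plates$valid), "/", nrow(x$qc$plates),
      " valid (Z' >= 0.3); ", length(x$qc$excluded), " excluded\n", sep = "")
  cat("  derived hit threshold: ", round(x$threshold, 2), "% NPI\n", sep = "")
  invisible(x)
}
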