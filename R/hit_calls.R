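#' Primary screen hit calling
#'
#' A gene is a hit when, on per-line mean NPI: (clause A) HMEC shows no effect
#' (`NPI < threshold`) and at least two malignant lines show an effect
#' (`NPI >= threshold`); or (clause B) HMEC shows an effect but at least two
#' malignant lines show no effect *and* at least two show an effect
#' (heterogeneous dependency, not an obligate requirement of all dividing
#' cells).
#'
#' @param results gene x line summary (columns `gene`, `cell_line`,
#'   `mean_npi`), e.g. from [summarize_gene_line()] or `screen_npi()$results`.
#' @param threshold NPI hit threshold (default 18.01, the published constant,
#'   used when no control-derived value is supplied).
#' @param hmec name of the non-malignant comparator line (default `"HMEC"`).
#' @return data.frame of class `hit_calls`: `gene`, `verdict` (`"hit"`,
#'   `"no_hit"` or `"fail"` when HMEC is missing), `clause`, `hmec_npi`,
#'   `n_lines_effect`, `n_lines_no_effect`, `lines_effect`,
#'   `lines_no_effect` (semicolon-separated evidence).
#' @export
call_primary_hits <- function(results, threshold = 18.01, hmec = "HMEC") {
  stopifnot(all(c("gene", "cell_line", "mean_npi") %in% names(results)))
  out <- lapply(split(results, results$gene), function(d) {
    h <- d$mean_npi[d$cell_line == hmec]
    m <- d[d$cell_line != hmec, ]
    eff <- m$cell_line[m$mean_npi >= threshold]
    noeff <- m$cell_line[m$mean_npi < threshold]
    if (!length(h)) {
      verdict <- "fail"; clause <- "missing_hmec"; h <- NA_real_
    } else {
      h <- mean(h)
      a <- h < threshold && length(eff) >= 2
      b <- h >= threshold && length(noeff) >= 2 && length(eff) >= 2
      verdict <- if (a || b) "hit" else "no_hit"
      clause <- if (a) "A" else if (b) "B" else ""
    }
    data.frame(gene = d$gene[1], verdict = verdict, clause = clause,
               hmec_npi = h, n_lines_effect = length(eff),
               n_lines_no_effect = length(noeff),
               lines_effect = paste(eff, collapse = ";"),
               lines_no_effect = paste(noeff, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hit_calls", "data.frame")
  attr(out, "rule_set") <- "primary"
  out
}

#' Top-10 prioritized validation calling
#'
#' A gene is validated when at least two of its individual siRNA oligos each
#' have knockdown `>= kd_min` percent, show no effect in HMEC
#' (`NPI < threshold`), and show an effect (`NPI >= threshold`) in at least
#' two malignant lines.
#'
#' @param oligo_results per-oligo NPI table (columns `gene`, `oligo`,
#'   `cell_line`, `mean_npi`).
#' @param kd knockdown table (columns `gene`, `oligo`, `kd_percent`).
#' @param threshold NPI hit threshold.
#' @param kd_min knockdown requirement (default 70).
#' @param hmec non-malignant comparator line.
#' @return data.frame of class `hit_calls`: `gene`, `verdict`
#'   (`"validated"`, `"no_hit"`, or `"fail"` when fewer than 3 oligos carry a
#'   measured knockdown), `n_qualifying_oligos`, `oligos` (evidence).
#' @export
call_top10_hits <- function(oligo_results, kd, threshold = 18.01,
                            kd_min = 70, hmec = "HMEC") {
  stopifnot(all(c("gene", "oligo", "cell_line", "mean_npi") %in%
                  names(oligo_results)),
            all(c("gene", "oligo", "kd_percent") %in% names(kd)))
  out <- lapply(split(oligo_results, oligo_results$gene), function(d) {
    gkd <- kd[kd$gene == d$gene[1] & !is.na(kd$kd_percent), ]
    if (nrow(gkd) < 3)
      return(data.frame(gene = d$gene[1], verdict = "fail",
                        n_qualifying_oligos = NA_integer_, oligos = "",
                        stringsAsFactors = FALSE))
    qual <- vapply(unique(d$oligo), function(o) {
      kd_o <- gkd$kd_percent[gkd$oligo == o]
      if (!length(kd_o) || kd_o[1] < kd_min) return(FALSE)
      od <- d[d$oligo == o, ]
      h <- od$mean_npi[od$cell_line == hmec]
      m <- od$mean_npi[od$cell_line != hmec]
      length(h) > 0 && mean(h) < threshold && sum(m >= threshold) >= 2
    }, logical(1))
    data.frame(gene = d$gene[1],
               verdict = if (sum(qual) >= 2) "validated" else "no_hit",
               n_qualifying_oligos = sum(qual),
               oligos = paste(names(qual)[qual], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hit_calls", "data.frame")
  attr(out, "rule_set") <- "top10"
  out
}

#' Secondary (deconvolution) validation of pooled hits
#'
#' Each pooled hit's four oligos are tested individually.  A gene *fails* when
#' two or more oligos achieve knockdown `>= 70` percent yet show no viability
#' effect (`NPI < threshold`) - the pooled phenotype was likely off-target.
#' Otherwise it is *validated* when at least two oligos with knockdown
#' `>= 40` percent show an effect (`NPI >= threshold`); anything else is
#' *inconclusive*.  The fail clause takes precedence over validation.
#'
#' @param oligo_table per-oligo table (columns `gene`, `oligo`, `kd_percent`,
#'   `npi`).
#' @param threshold NPI hit threshold.
#' @param kd_fail,kd_validate knockdown cuts of the two clauses (70 / 40).
#' @return data.frame of class `hit_calls`: `gene`, `verdict` (`"fail"`,
#'   `"validated"`, `"inconclusive"`), `n_discordant_oligos`,
#'   `n_validating_oligos`, `oligos_discordant`, `oligos_validating`.
#' @export
secondary_validation <- function(oligo_table, threshold = 18.01,
                                 kd_fail = 70, kd_validate = 40) {
  stopifnot(all(c("gene", "oligo", "kd_percent", "npi") %in%
                  names(oligo_table)))
  out <- lapply(split(oligo_table, oligo_table$gene), function(d) {
    disc <- d$kd_percent >= kd_fail & d$npi < threshold
    val <- d$kd_percent >= kd_validate & d$npi >= threshold
    verdict <- if (sum(disc) >= 2) "fail"
               else if (sum(val) >= 2) "validated"
               else "inconclusive"
    data.frame(gene = d$gene[1], verdict = verdict,
               n_discordant_oligos = sum(disc),
               n_validating_oligos = sum(val),
               oligos_discordant = paste(d$oligo[disc], collapse = ";"),
               oligos_validating = paste(d$oligo[val], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hit_calls", "data.frame")
  attr(out, "rule_set") <- "secondary"
  out
}

#' @export
print.hit_calls <- function(x, ...) {
  cat("<hit_calls> rule set: ", attr(x, "rule_set") %||% "?", "\n", sep = "")
  print(table(x$verdict))
  invisible(x)
}
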