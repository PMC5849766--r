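#' Centrosome amplification score
#'
#' Percentage of cells that are centrosome-amplified: a cell counts as
#' amplified if any of its centrosomes bears more than two centriole markers
#' and/or it has more than two centrosomes.
#'
#' @param cells data.frame with one row per centrosome: `case_id`, `cell_id`,
#'   `centriole_count` (and any centrosome identifier).
#' @return data.frame per case: `case_id`, `n_cells`, `n_amplified`,
#'   `ca_score` (percent).
#' @export
ca_score <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("case_id", "cell_id", "centriole_count") %in% names(cells)))
  if (!nrow(cells)) stop("empty cell table")
  key <- interaction(cells$case_id, cells$cell_id, drop = TRUE)
  n_centro <- tapply(cells$centriole_count, key, length)
  max_centri <- tapply(cells$centriole_count, key, max)
  case_of <- tapply(as.character(cells$case_id), key, `[`, 1)
  amplified <- n_centro > 2 | max_centri > 2
  out <- lapply(split(amplified, unlist(case_of)), function(a)
    data.frame(n_cells = length(a), n_amplified = sum(a),
               ca_score = 100 * mean(a)))
  res <- do.call(rbind, out)
  res <- data.frame(case_id = rownames(res), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$case_id), ]
}

#' Pericentrin abnormality (PCAB) score
#'
#' A stained body is abnormal when its area strictly exceeds `size_cutoff`
#' (7 square microns is itself the largest normal size).  The PCAB score is
#' the percentage of abnormal bodies over all bodies of a case; cases with
#' fewer than `min_bodies` scored bodies are flagged invalid and receive no
#' score.  Rows with non-positive areas are dropped with a warning.
#'
#' @param bodies data.frame: `case_id`, `area` (square microns), optionally
#'   `intensity` (carried, not used).
#' @param size_cutoff upper limit of normal body area (default 7).
#' @param min_bodies minimum bodies per case for a valid score (default 20).
#' @return data.frame of class `case_scores`: `case_id`, `n_bodies`,
#'   `n_abnormal`, `pcab` (percent, `NA` when invalid), `valid`.
#' @export
pcab_score <- function(bodies, size_cutoff = 7.0, min_bodies = 20) {
  stopifnot(is.data.frame(bodies),
            all(c("case_id", "area") %in% names(bodies)))
  bad <- !is.na(bodies$area) & bodies$area <= 0
  if (any(bad)) {
    warning(sum(bad), " body rows with non-positive area dropped")
    bodies <- bodies[!bad, ]
  }
  out <- lapply(split(bodies$area, as.character(bodies$case_id)), function(a) {
    n <- length(a)
    ab <- sum(a > size_cutoff)
    data.frame(n_bodies = n, n_abnormal = ab,
               pcab = if (n >= min_bodies) 100 * ab / n else NA_real_,
               valid = n >= min_bodies)
  })
  res <- do.call(rbind, out)
  res <- data.frame(case_id = rownames(res), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  res <- res[order(res$case_id), ]
  class(res) <- c("case_scores", "data.frame")
  res
}

#' Associations of the PCAB score with dependency and outcome
#'
#' Ordinary least squares of knockdown NPI on PCAB (slope, r-squared);
#' dichotomization of cases at the PCAB cut (high when `pcab > cutoff`,
#' strict); Kaplan-Meier recurrence-free-survival curves per group with a
#' log-rank test.  Only valid cases (enough scored bodies) enter.
#'
#' @param scores a [pcab_score()] table, optionally augmented with columns
#'   `npi` and/or `recurrence_time` + `recurrence_event` (e.g. merged from a
#'   case covariate table).
#' @param cutoff dichotomization cut in percent (default 20, strict `>`).
#' @return object of class `pcab_assoc`: list with `regression` (slope,
#'   intercept, r_squared, n; NULL when `npi` absent), `survival` (survfit
#'   object, log-rank chi-squared and p, group sizes; NULL when outcome
#'   columns absent), `fraction_above`, `cutoff`.
#' @export
pcab_associations <- function(scores, cutoff = 20) {
  stopifnot(inherits(scores, "data.frame"), "pcab" %in% names(scores))
  d <- scores[!is.na(scores$pcab), ]
  high <- d$pcab > cutoff
  regression <- NULL
  if ("npi" %in% names(d)) {
    dd <- d[!is.na(d$npi), ]
    if (nrow(dd) >= 3) {
      if (stats::sd(dd$pcab) == 0)
        stop("zero-variance PCAB: regression undefined")
      fit <- stats::lm(npi ~ pcab, data = dd)
      regression <- list(slope = unname(stats::coef(fit)[2]),
                         intercept = unname(stats::coef(fit)[1]),
                         r_squared = summary(fit)$r.squared,
                         n = nrow(dd))
    }
  }
  surv <- NULL
  if (all(c("recurrence_time", "recurrence_event") %in% names(d))) {
    if (length(unique(high)) == 2) {
      sf <- survival::survfit(
        survival::Surv(recurrence_time, recurrence_event) ~ high, data = d)
      sd_ <- survival::survdiff(
        survival::Surv(recurrence_time, recurrence_event) ~ high, data = d)
      surv <- list(fit = sf, chisq = sd_$chisq,
                   p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
                   n_high = sum(high), n_low = sum(!high))
    }
  }
  structure(list(regression = regression, survival = surv,
                 fraction_above = mean(high), cutoff = cutoff,
                 n_cases = nrow(d)),
            class = "pcab_assoc")
}

#' @export
print.pcab_assoc <- function(x, ...) {
  cat("<pcab_assoc> ", x$n_cases, " valid cases; ",
      round(100 * x$fraction_above, 1), "% above the ", x$cutoff,
      "% PCAB cut\n", sep = "")
  if (!is.null(x$regression))
    cat(sprintf("  NPI ~ PCAB: slope %.3f, r^2 = %.3f (n = %d)\n",
                x$regression$slope, x$regression$r_squared, x$regression$n))
  if (!is.null(x$survival))
    cat(sprintf("  log-rank: chi^2 = %.2f, p = %.4g (high n=%d, low n=%d)\n",
                x$survival$chisq, x$survival$p,
                x$survival$n_high, x$survival$n_low))
  invisible(x)
}

#' Kaplan-Meier plot of the PCAB dichotomization
#'
#' @param x a `pcab_assoc` with a survival component.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pcab_assoc <- function(x, ...) {
  if (is.null(x$survival)) stop("no survival component to plot")
  graphics::plot(x$survival$fit, col = c("black", "red"), lwd = 2,
                 xlab = "Time (months)", ylab = "Recurrence-free survival",
                 ...)
  graphics::legend("bottomleft",
                   legend = c(sprintf("PCAB <= %g%%", x$cutoff),
                              sprintf("PCAB > %g%%", x$cutoff)),
                   col = c("black", "red"), lwd = 2, bty = "n")
  invisible(x)
}
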