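# Independent oracles used to cross-check the package implementations.
# Each is a literal, standalone translation of the published rule or textbook
# procedure, kept free of package internals.

# Primary hit rule: clause A or clause B on per-line mean NPIs.
oracle_primary <- function(hmec, lines, thr) {
  a <- hmec < thr && sum(lines >= thr) >= 2
  b <- hmec >= thr && sum(lines < thr) >= 2 && sum(lines >= thr) >= 2
  if (a || b) "hit" else "no_hit"
}

# Top-10 rule: >=2 oligos each with KD >= 70, HMEC NPI < thr and effect in
# >=2 malignant lines.  `lines_npi` is an oligo x line matrix.
oracle_top10 <- function(kd, hmec, lines_npi, thr) {
  ok <- kd >= 70 & hmec < thr & rowSums(lines_npi >= thr) >= 2
  if (sum(ok) >= 2) "validated" else "no_hit"
}

# Secondary deconvolution rule, fail clause first.
oracle_secondary <- function(kd, npi, thr) {
  if (sum(kd >= 70 & npi < thr) >= 2) return("fail")
  if (sum(kd >= 40 & npi >= thr) >= 2) return("validated")
  "inconclusive"
}

# Benjamini-Hochberg step-up adjusted p-values, hand-stepped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# Two-group log-rank chi-squared, hand-stepped over distinct event times.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    o_minus_e <- o_minus_e + (d1 - e1)
  }
  o_minus_e^2 / v
}

# Minimal profile builder for hand-constructed matrices.
make_profile <- function(cn, gex, groups, recurrence = NULL,
                         recurrence_time = NULL) {
  ids <- sprintf("S%03d", seq_along(groups))
  colnames(cn) <- colnames(gex) <- ids
  if (is.null(rownames(cn)))
    rownames(cn) <- rownames(gex) <- sprintf("g%03d", seq_len(nrow(cn)))
  meta <- data.frame(sample_id = ids, group = groups,
                     stringsAsFactors = FALSE)
  if (!is.null(recurrence)) meta$recurrence <- recurrence
  if (!is.null(recurrence_time)) meta$recurrence_time <- recurrence_time
  gene_profile(cn, gex, meta)
}

# Well-level plate builder (interior wells of an 8x12 plate).
make_plate <- function(plate_id, values, roles,
                       genes = NULL, cell_line = "BC01", replicate = 1) {
  n <- length(values)
  pos <- expand.grid(row = 2:7, col = 2:11)[seq_len(n), ]
  data.frame(plate_id = plate_id, row = pos$row, col = pos$col,
             reagent_type = roles,
             gene = if (is.null(genes))
               ifelse(roles == "sample", paste0("g", seq_len(n)), NA) else genes,
             oligo = ifelse(roles == "sample", "pool", NA),
             cell_line = cell_line, replicate = replicate,
             raw_value = values, stringsAsFactors = FALSE)
}
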