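#' Configuration for the synthetic centrosome object generator
#'
#' Emulates per-case pericentrin-stained body tables (area in square microns)
#' and per-cell centriole/centrosome count tables.  Normal bodies follow a
#' lognormal area distribution around the 1.44 um^2 typical size of a normal
#' breast centrosome, truncated at the 7 um^2 upper limit of normal; abnormal
#' bodies are strictly larger than 7 um^2 (shifted gamma).
#'
#' @param n_cases number of cases (tumors or cell-line pellets).
#' @param bodies_per_case stained bodies per case (default 440, a realistic
#'   per-case average; must be >= 20 for a case to receive a valid score).
#' @param abnormal_fraction per-case fraction of abnormal bodies (scalar or
#'   length-`n_cases` vector, each in `[0,1]`).
#' @param normal_meanlog,normal_sdlog lognormal parameters of normal body
#'   areas (um^2), truncated above at `size_cutoff`.
#' @param abnormal_shape,abnormal_rate gamma parameters of the abnormal area
#'   excess over `size_cutoff`.
#' @param size_cutoff upper limit of normal body area (um^2).
#' @param cells_per_case cells per case in the count table.
#' @param amplified_cell_fraction per-case fraction of centrosome-amplified
#'   cells (scalar or vector).
#' @param npi_intercept,npi_slope,npi_sd per-case knockdown NPI generated as
#'   a linear function of the true abnormal percentage plus noise, for
#'   regression-association demonstrations.
#' @param hazard_ratio_high recurrence hazard multiplier for cases whose true
#'   abnormal percentage exceeds `pcab_cutoff`.
#' @param baseline_rate baseline exponential recurrence hazard (per month).
#' @param censor_time administrative censoring time (months).
#' @param pcab_cutoff dichotomization cut (percent) used when planting the
#'   survival difference.
#' @param seed integer RNG seed.
#' @return a `centrosome_sim_config` list.
#' @export
centrosome_sim_config <- function(n_cases = 20, bodies_per_case = 440,
                                  abnormal_fraction = 0.2,
                                  normal_meanlog = log(1.44), normal_sdlog = 0.45,
                                  abnormal_shape = 2, abnormal_rate = 0.5,
                                  size_cutoff = 7,
                                  cells_per_case = 200,
                                  amplified_cell_fraction = 0.2,
                                  npi_intercept = 5, npi_slope = 0.8, npi_sd = 8,
                                  hazard_ratio_high = 1.95,
                                  baseline_rate = 1 / 60, censor_time = 60,
                                  pcab_cutoff = 20,
                                  seed = 1L) {
  cfg <- list(n_cases = n_cases, bodies_per_case = bodies_per_case,
              abnormal_fraction = rep_len(abnormal_fraction, n_cases),
              normal_meanlog = normal_meanlog, normal_sdlog = normal_sdlog,
              abnormal_shape = abnormal_shape, abnormal_rate = abnormal_rate,
              size_cutoff = size_cutoff, cells_per_case = cells_per_case,
              amplified_cell_fraction = rep_len(amplified_cell_fraction, n_cases),
              npi_intercept = npi_intercept, npi_slope = npi_slope,
              npi_sd = npi_sd, hazard_ratio_high = hazard_ratio_high,
              baseline_rate = baseline_rate, censor_time = censor_time,
              pcab_cutoff = pcab_cutoff, seed = as.integer(seed))
  stopifnot(n_cases > 0, bodies_per_case > 0, cells_per_case > 0,
            all(cfg$abnormal_fraction >= 0), all(cfg$abnormal_fraction <= 1),
            all(cfg$amplified_cell_fraction >= 0),
            all(cfg$amplified_cell_fraction <= 1),
            size_cutoff > 0)
  class(cfg) <- "centrosome_sim_config"
  cfg
}

## lognormal truncated above at `upper` via inverse-CDF sampling
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  p_up <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, p_up), meanlog, sdlog)
}

#' Simulate pericentrin body tables and per-cell centrosome count tables
#'
#' Each case receives exactly `round(abnormal_fraction * bodies_per_case)`
#' abnormal bodies (area strictly above the size cutoff) so the planted truth
#' is recoverable by direct recount.  Amplified cells are drawn either with
#' supernumerary centrosomes (>2 per cell) or with a centrosome bearing >2
#' centrioles.  Per-case covariates (knockdown NPI linear in the true abnormal
#' percentage; recurrence times with a planted hazard split at the PCAB cut)
#' support association reports.
#'
#' @param config a [centrosome_sim_config()].
#' @return list with `bodies` (case_id, body_id, area, intensity), `cells`
#'   (case_id, cell_id, centrosome_id, centriole_count; one row per
#'   centrosome), `cases` (case_id, npi, recurrence_time, recurrence_event)
#'   and `truth` (planted fractions).
#' @export
simulate_centrosome_objects <- function(config) {
  stopifnot(inherits(config, "centrosome_sim_config"))
  set.seed(config$seed)
  g <- config
  case_id <- sprintf("C%03d", seq_len(g$n_cases))

  bodies <- vector("list", g$n_cases)
  cells <- vector("list", g$n_cases)
  for (i in seq_len(g$n_cases)) {
    nb <- g$bodies_per_case
    n_ab <- round(g$abnormal_fraction[i] * nb)
    area <- c(rlnorm_trunc(nb - n_ab, g$normal_meanlog, g$normal_sdlog,
                           g$size_cutoff),
              g$size_cutoff + stats::rgamma(n_ab, g$abnormal_shape,
                                            g$abnormal_rate))
    area <- sample(area)                       # shuffle normal/abnormal rows
    bodies[[i]] <- data.frame(case_id = case_id[i],
                              body_id = sprintf("b%04d", seq_len(nb)),
                              area = area,
                              intensity = stats::rlnorm(nb, log(80), 0.3))

    nc <- g$cells_per_case
    n_amp <- round(g$amplified_cell_fraction[i] * nc)
    amp <- c(rep(TRUE, n_amp), rep(FALSE, nc - n_amp))
    rows <- vector("list", nc)
    for (ci in seq_len(nc)) {
      if (amp[ci]) {
        if (stats::runif(1) < 0.5) {           # supernumerary centrosomes
          k <- sample(3:5, 1)
          centrioles <- sample(1:2, k, replace = TRUE)
        } else {                               # one over-duplicated centrosome
          k <- 2L
          centrioles <- c(sample(3:4, 1), sample(1:2, 1))
        }
      } else {
        k <- sample(1:2, 1)
        centrioles <- sample(1:2, k, replace = TRUE)
      }
      rows[[ci]] <- data.frame(case_id = case_id[i],
                               cell_id = sprintf("c%04d", ci),
                               centrosome_id = seq_len(k),
                               centriole_count = centrioles)
    }
    cells[[i]] <- do.call(rbind, rows)
  }
  bodies <- do.call(rbind, bodies)
  cells <- do.call(rbind, cells)

  true_pcab <- 100 * round(g$abnormal_fraction * g$bodies_per_case) /
    g$bodies_per_case
  npi <- g$npi_intercept + g$npi_slope * true_pcab +
    stats::rnorm(g$n_cases, 0, g$npi_sd)
  rate <- g$baseline_rate * ifelse(true_pcab > g$pcab_cutoff,
                                   g$hazard_ratio_high, 1)
  t_ev <- stats::rexp(g$n_cases, rate)
  cases <- data.frame(case_id = case_id, npi = npi,
                      recurrence_time = pmin(t_ev, g$censor_time),
                      recurrence_event = as.integer(t_ev <= g$censor_time))

  list(bodies = bodies, cells = cells, cases = cases,
       truth = list(abnormal_fraction = g$abnormal_fraction,
                    true_pcab = true_pcab,
                    amplified_cell_fraction = g$amplified_cell_fraction,
                    config = g))
}
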