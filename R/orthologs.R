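#' Chi-square test of co-cycling between ortholog pairs
#'
#' Builds the 2x2 cycling-A x cycling-B contingency table over ortholog
#' pairs, computes expected cells from the marginal products and the 1-df
#' chi-square statistic (no continuity correction by default), and reports
#' the observed and independence-expected co-cycling percentages.
#'
#' @param pairs data.frame with logical columns `cyclingA`, `cyclingB`.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List: `table` (2x2 observed counts), `expected`, `chisq`, `df`,
#'   `p`, `observed_pct` and `expected_pct` (co-cycling percentages, one
#'   decimal), `n`.
#' @export
co_cycling_contingency_test <- function(pairs, correct = FALSE) {
  tab <- table(cyclingA = factor(pairs$cyclingA, c(TRUE, FALSE)),
               cyclingB = factor(pairs$cyclingB, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: a species has no (or only) cycling genes")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  n <- sum(tab)
  list(table = unclass(tab), expected = ct$expected,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       observed_pct = round(100 * tab[1, 1] / n, 1),
       expected_pct = round(100 * ct$expected[1, 1] / n, 1),
       n = n)
}

#' Cross-species agreement of amplitude and phase among co-cycling orthologs
#'
#' For ortholog pairs cycling in both species, reports the squared Pearson
#' correlation of log amplitudes (amplitudes are positive and span orders of
#' magnitude) and of raw phases (linear ZT values), each with its
#' correlation-test p-value, plus a circular phase correlation
#' (Fisher-Lee) as a diagnostic that respects the 24-h ring.
#'
#' @param pairs data.frame with `cyclingA`, `cyclingB`, `amplitudeA`,
#'   `amplitudeB`, `phaseA`, `phaseB`.
#' @param layout A [sampling_layout()] (for the circular conversion).
#' @return List: `n_co_cycling`, `amplitude_r2`, `amplitude_p`, `phase_r2`,
#'   `phase_p`, `circular_phase_r`.
#' @export
cross_species_parameter_agreement <- function(pairs,
                                              layout = sampling_layout()) {
  co <- pairs$cyclingA & pairs$cyclingB
  if (sum(co) < 3) stop("need >= 3 co-cycling pairs")
  la <- log(pairs$amplitudeA[co]); lb <- log(pairs$amplitudeB[co])
  pa <- pairs$phaseA[co]; pb <- pairs$phaseB[co]
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stop("zero-variance amplitudes")
  amp <- stats::cor.test(la, lb)
  ph_r2 <- ph_p <- NA_real_
  if (stats::sd(pa) > 0 && stats::sd(pb) > 0) {
    ph <- stats::cor.test(pa, pb)
    ph_r2 <- unname(ph$estimate)^2; ph_p <- ph$p.value
  }
  list(n_co_cycling = sum(co),
       amplitude_r2 = unname(amp$estimate)^2, amplitude_p = amp$p.value,
       phase_r2 = ph_r2, phase_p = ph_p,
       circular_phase_r = circular_correlation(
         2 * pi * pa / layout$day_length_hours,
         2 * pi * pb / layout$day_length_hours))
}

# Fisher-Lee circular correlation coefficient of two angle vectors
circular_correlation <- function(a, b) {
  num <- sum(sin(a - mean_angle(a)) * sin(b - mean_angle(b)))
  den <- sqrt(sum(sin(a - mean_angle(a))^2) * sum(sin(b - mean_angle(b))^2))
  if (den == 0) return(NA_real_)
  num / den
}

mean_angle <- function(a) atan2(mean(sin(a)), mean(cos(a)))
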