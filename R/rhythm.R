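#' Upper-quartile normalization of an expression matrix
#'
#' Scales each sample (column) so that its upper quartile, computed over
#' genes with nonzero expression in that sample, equals a common reference
#' value — by default the mean of the per-sample upper quartiles, so the
#' overall scale of the data is preserved.
#'
#' @param expr Numeric matrix, genes x samples, nonnegative.
#' @param reference Common target upper-quartile value, or `NULL` for the
#'   mean of per-sample upper quartiles.
#' @return The rescaled matrix, same dimnames.
#' @export
upper_quartile_normalize <- function(expr, reference = NULL) {
  uq <- apply(expr, 2, function(col) {
    pos <- col[col > 0]
    if (!length(pos)) stop("all-zero sample: upper quartile undefined")
    stats::quantile(pos, 0.75, names = FALSE)
  })
  if (is.null(reference)) reference <- mean(uq)
  sweep(expr, 2, uq / reference, "/")
}

#' Discrete Fourier transform and power spectrum of a segment
#'
#' Computes `y_k = sum_n x_n exp(-i 2 pi k n / M)` of a mean-centred segment
#' and the one-sided power spectrum `|y_k|^2` for `k = 0..floor(M/2)` (the
#' real-input half; component 0 is zero after mean-centering).
#'
#' @param segment Numeric vector of length >= 2.
#' @param center Mean-centre before transforming (default TRUE).
#' @return List: `coefficients` (complex, length M) and `power` (numeric,
#'   `|y_k|^2`, names "0".."floor(M/2)").
#' @export
dft_spectrum <- function(segment, center = TRUE) {
  M <- length(segment)
  if (M < 2) stop("segment must have length >= 2")
  if (center) segment <- segment - mean(segment)
  y <- stats::fft(segment)
  k <- 0:(M %/% 2)
  power <- Mod(y[k + 1])^2
  names(power) <- k
  list(coefficients = y, power = power)
}

# min-max normalization onto [0,1]; constant input maps to all zeros
minmax <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

# start indices of day-length Welch segments for a layout; overlap NULL
# means maximal overlap (every day-length window, step 1)
welch_segments <- function(layout, overlap = NULL) {
  M <- layout$points_per_day
  N <- layout$n_samples
  step <- if (is.null(overlap)) 1L else
    max(1L, as.integer(round(M * (1 - overlap))))
  starts <- seq(1L, N - M + 1L, by = step)
  lapply(starts, function(s) s:(s + M - 1L))
}

#' Cyclic score of an expression vector
#'
#' The cyclic score is the Welch-averaged, min-max-normalized power at the
#' one-cycle-per-day frequency. The vector is split into day-length segments
#' (every day-length window by default); each segment is mean-centred, transformed
#' (see [dft_spectrum()]) and its power spectrum over the nonzero
#' frequencies `k = 1..floor(M/2)` is min-max normalized onto [0, 1]; the
#' normalized spectra are averaged across segments and the score is the
#' averaged value at the component whose period equals the day length
#' (k = 1 for a day-length segment). A gene whose power is maximal at the
#' daily frequency in every segment therefore scores exactly 1; a constant
#' vector scores 0.
#'
#' @param x Numeric expression vector covering at least one full day.
#' @param layout A [sampling_layout()].
#' @param overlap Fractional overlap of consecutive Welch segments.
#'   `NULL` (the default) averages every day-length window (step 1, the
#'   densest subset choice); 0.5 gives classic half-overlapping windows and
#'   0 the non-overlapping days.
#' @return Score in [0, 1].
#' @export
cyclic_score <- function(x, layout = sampling_layout(), overlap = NULL) {
  if (length(x) < layout$points_per_day)
    stop("vector shorter than one day")
  segs <- welch_segments(layout, overlap)
  norm_at_k1 <- vapply(segs, function(idx) {
    p <- dft_spectrum(x[idx])$power[-1]   # drop k = 0
    minmax(p)[1]                          # k = 1: one cycle per day
  }, numeric(1))
  mean(norm_at_k1)
}

#' Permutation null distribution of cyclic scores
#'
#' Builds the null by repeatedly picking a gene row, permuting its values
#' uniformly over sample positions, and recording the cyclic score of the
#' permuted row.
#'
#' @param expr Genes x samples matrix.
#' @param n_permutations Number of permuted rows to score.
#' @param layout A [sampling_layout()].
#' @param overlap Welch overlap passed to [cyclic_score()].
#' @param seed Integer seed.
#' @return Object of class `null_distribution`: list with sorted `scores`,
#'   `n_permutations`, `seed`.
#' @export
null_score_distribution <- function(expr, n_permutations = 1000,
                                    layout = sampling_layout(),
                                    overlap = NULL, seed = 1L) {
  if (nrow(expr) < 1) stop("empty expression matrix")
  stopifnot(n_permutations >= 1)
  set.seed(seed)
  rows <- sample.int(nrow(expr), n_permutations, replace = TRUE)
  scores <- vapply(rows, function(i) {
    cyclic_score(sample(expr[i, ]), layout, overlap)
  }, numeric(1))
  structure(list(scores = sort(scores), n_permutations = n_permutations,
                 seed = seed),
            class = "null_distribution")
}

#' Cyclic-score threshold at a top percentile of the null
#'
#' Returns the score exceeded-or-met by `top_pct` percent of null scores:
#' the k-th largest null score with `k = ceiling(n * top_pct / 100)`. Genes
#' called at this threshold have an expected false-positive rate of
#' `top_pct / 100` under the null.
#'
#' @param null A `null_distribution` (or bare numeric vector of null scores).
#' @param top_pct Percentage in (0, 100); e.g. 2 reproduces a P-value cutoff
#'   of 0.02.
#' @return Numeric score threshold.
#' @export
threshold_at_top_percentile <- function(null, top_pct = 2) {
  stopifnot(top_pct > 0, top_pct < 100)
  scores <- if (inherits(null, "null_distribution")) null$scores else
    sort(null)
  n <- length(scores)
  k <- ceiling(n * top_pct / 100)
  if (n * top_pct / 100 < 1)
    warning("null too small for requested percentile; using largest score")
  scores[n - k + 1L]
}

#' Call cycling genes at a score threshold
#'
#' @param scores Named numeric vector of per-gene cyclic scores.
#' @param threshold Score cutoff in [0, 1]; a gene is cycling iff
#'   `score >= threshold`.
#' @param null Optional `null_distribution` for empirical p-values,
#'   add-one smoothed: `p = (r + 1) / (n + 1)` with r the number of null
#'   scores >= the gene's score.
#' @return data.frame: `gene_id`, `score`, `is_cycling`, `p` (NA without a
#'   null).
#' @export
call_cycling <- function(scores, threshold, null = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- rep(NA_real_, length(scores))
  if (!is.null(null)) {
    ns <- if (inherits(null, "null_distribution")) null$scores else sort(null)
    n <- length(ns)
    # ns is sorted ascending: r = n - (number strictly below score)
    r <- n - findInterval(scores, ns, left.open = TRUE)
    p <- (r + 1) / (n + 1)
  }
  data.frame(gene_id = if (is.null(names(scores)))
               sprintf("g%04d", seq_along(scores)) else names(scores),
             score = unname(scores), is_cycling = unname(scores >= threshold),
             p = p, stringsAsFactors = FALSE)
}

#' Estimate period, amplitude and phase of a cycling gene
#'
#' Uses the full-length mean-centred spectrum: the period is the total span
#' T divided by the dominant frequency index, refined by quadratic
#' interpolation on log-power over the peak and its two neighbours (raw DFT
#' bins of a 16-point, 48-h vector can only be 48, 24, 16, ... h; the
#' interpolated peak gives a continuous period estimate). The amplitude is
#' `2 |y_k*| / N` and the phase is the ZT at which the fitted cosine peaks.
#'
#' @param x Expression vector of length N (all samples).
#' @param layout A [sampling_layout()].
#' @return List: `period` (h), `amplitude` (expression units), `phase` (ZT
#'   hours in [0, day length)), `k` (dominant integer bin), `interpolated`,
#'   `at_edge` (TRUE when the peak sits at the first or Nyquist bin, where
#'   no interpolation is possible).
#' @export
fit_cyclic_parameters <- function(x, layout = sampling_layout()) {
  N <- length(x)
  spec <- dft_spectrum(x)
  pw <- spec$power[-1]                      # k = 1..floor(N/2)
  k_star <- which.max(pw)                   # integer frequency index
  total_T <- N * layout$interval_hours
  k_ref <- k_star
  at_edge <- k_star == 1L || k_star == length(pw)
  interpolated <- FALSE
  # interpolate only off the spectrum edges and when the neighbours carry
  # real power (a numerically pure tone needs no refinement)
  if (!at_edge && all(pw[k_star + c(-1L, 1L)] > pw[k_star] * 1e-9)) {
    lp <- log(pw[k_star + c(-1L, 0L, 1L)])
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (denom < 0) {
      k_ref <- k_star + 0.5 * (lp[1] - lp[3]) / denom
      interpolated <- TRUE
    }
  }
  yk <- spec$coefficients[k_star + 1L]
  amplitude <- if (k_star == N %/% 2 && N %% 2 == 0)
    Mod(yk) / N else 2 * Mod(yk) / N
  t0 <- (-Arg(yk)) * total_T / (2 * pi * k_star)
  list(period = unname(total_T / k_ref),
       amplitude = unname(amplitude),
       phase = unname(t0 %% layout$day_length_hours),
       k = k_star, interpolated = interpolated, at_edge = at_edge)
}

#' Assign a gene to a phase cluster (ZT bin of peak expression)
#'
#' The appended days are averaged per ZT and the cluster is the ZT of the
#' maximum averaged value; exact ties go to the earlier ZT.
#'
#' @param x Expression vector of length `layout$n_samples`.
#' @param layout A [sampling_layout()].
#' @return ZT bin label (numeric hours).
#' @export
assign_phase_cluster <- function(x, layout = sampling_layout()) {
  m <- matrix(x, nrow = layout$points_per_day)  # column per day
  day_mean <- rowMeans(m)
  zt_bins(layout)[which.max(day_mean)]
}

#' Detect cycling genes in an expression matrix
#'
#' End-to-end rhythm detection: scores every gene ([cyclic_score()]), builds
#' a permutation null ([null_score_distribution()]), sets the threshold at
#' the requested top percentile, calls cycling genes, and estimates period,
#' amplitude, phase and phase cluster for the called genes.
#'
#' @param expr Genes x samples matrix (rownames = gene ids).
#' @param layout A [sampling_layout()].
#' @param top_pct Top percentile of the null used as cutoff (default 2, a
#'   P-value of 0.02).
#' @param n_permutations Permutations for the null (default 2000).
#' @param overlap Welch segment overlap.
#' @param seed Integer seed.
#' @return List with `fits` (data.frame: gene_id, score, p, is_cycling,
#'   period, amplitude, phase, phase_cluster — parameter columns NA for
#'   noncycling genes), `threshold`, and `null`.
#' @export
detect_cycling <- function(expr, layout = sampling_layout(), top_pct = 2,
                           n_permutations = 2000, overlap = NULL, seed = 1L) {
  scores <- apply(expr, 1, cyclic_score, layout = layout, overlap = overlap)
  null <- null_score_distribution(expr, n_permutations, layout, overlap,
                                  seed = seed)
  thr <- threshold_at_top_percentile(null, top_pct)
  calls <- call_cycling(scores, thr, null)
  n <- nrow(expr)
  fits <- cbind(calls,
                data.frame(period = NA_real_, amplitude = NA_real_,
                           phase = NA_real_, phase_cluster = NA_real_))
  for (i in which(calls$is_cycling)) {
    fp <- fit_cyclic_parameters(expr[i, ], layout)
    fits$period[i] <- fp$period
    fits$amplitude[i] <- fp$amplitude
    fits$phase[i] <- fp$phase
    fits$phase_cluster[i] <- assign_phase_cluster(expr[i, ], layout)
  }
  list(fits = fits, threshold = thr, null = null)
}
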