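#' Per-Ks-bin cycling-state frequencies of duplicate pairs
#'
#' Bins duplicate pairs by synonymous substitution rate (Ks) into half-open
#' bins `[0, w), [w, 2w), ...` and reports the frequency of each cycling
#' state — CC (both cycling), NN (both noncycling), D (diverged) — per bin.
#'
#' @param pairs data.frame with columns `ks` and `state` ("CC"/"NN"/"D"),
#'   e.g. from [generate_duplicate_pairs()] or [join_pair_states()].
#' @param bin_width Ks bin width (default 0.3).
#' @return data.frame: `bin` (index), `ks_lo`, `ks_hi`, `n`, `f_CC`, `f_NN`,
#'   `f_D`. Bins with zero pairs are omitted.
#' @export
state_frequencies_by_ks <- function(pairs, bin_width = 0.3) {
  if (any(pairs$ks < 0)) stop("negative Ks")
  bin <- floor(pairs$ks / bin_width) + 1L
  out <- lapply(sort(unique(bin)), function(b) {
    st <- pairs$state[bin == b]
    n <- length(st)
    data.frame(bin = b, ks_lo = (b - 1) * bin_width, ks_hi = b * bin_width,
               n = n, f_CC = mean(st == "CC"), f_NN = mean(st == "NN"),
               f_D = mean(st == "D"))
  })
  do.call(rbind, out)
}

#' Derive pair cycling states from per-gene cycling calls
#'
#' @param pairs data.frame with `gene1`, `gene2` (and typically `ks`).
#' @param is_cycling Named logical vector of per-gene cycling calls.
#' @return `pairs` with added `cycling1`, `cycling2`, `state` columns.
#' @export
join_pair_states <- function(pairs, is_cycling) {
  c1 <- unname(is_cycling[pairs$gene1])
  c2 <- unname(is_cycling[pairs$gene2])
  pairs$cycling1 <- c1
  pairs$cycling2 <- c2
  pairs$state <- ifelse(c1 & c2, "CC", ifelse(!c1 & !c2, "NN", "D"))
  pairs
}

#' Construct a three-state duplicate-divergence model
#'
#' A difference-equation model of how the cycling state of a duplicate pair
#' evolves per Ks step: identical pairs (CC or NN) become diverged (D) at a
#' common rate `d`; diverged pairs revert to an identical state at a common
#' rate `s`, landing in CC with probability `alpha` (default 0.5,
#' symmetric).
#'
#' @param d Per-step identical-to-divergent probability in [0, 1].
#' @param s Per-step divergent-to-identical probability in [0, 1].
#' @param alpha Fraction of reversions landing in CC (default 0.5).
#' @return Object of class `divergence_model`.
#' @export
divergence_model <- function(d, s, alpha = 0.5) {
  if (d < 0 || d > 1 || s < 0 || s > 1)
    stop("d and s must be in [0, 1]")
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(d = d, s = s, alpha = alpha), class = "divergence_model")
}

#' @export
print.divergence_model <- function(x, ...) {
  cat(sprintf("divergence_model: d = %g, s = %g, alpha = %g\n",
              x$d, x$s, x$alpha))
  invisible(x)
}

#' One step of the divergence model
#'
#' Applies the three difference equations to a state-frequency vector
#' `f = (f_CC, f_NN, f_D)`:
#' \deqn{f_{CC}' = f_{CC}(1-d) + \alpha s f_D}
#' \deqn{f_{NN}' = f_{NN}(1-d) + (1-\alpha) s f_D}
#' \deqn{f_D' = f_D(1-s) + d (f_{CC} + f_{NN})}
#'
#' @param model A [divergence_model()].
#' @param f Numeric length-3 probability vector `(CC, NN, D)`.
#' @return Next frequency vector (sums to 1 exactly up to float error).
#' @export
step_divergence_model <- function(model, f) {
  if (abs(sum(f) - 1) > 1e-8) stop("f must sum to 1")
  d <- model$d; s <- model$s; a <- model$alpha
  c(CC = f[[1]] * (1 - d) + a * s * f[[3]],
    NN = f[[2]] * (1 - d) + (1 - a) * s * f[[3]],
    D  = f[[3]] * (1 - s) + d * (f[[1]] + f[[2]]))
}

#' @rdname step_divergence_model
#' @param n_steps Number of steps to iterate.
#' @return `iterate_divergence_model()`: matrix with `n_steps + 1` rows (the
#'   trajectory including the start).
#' @export
iterate_divergence_model <- function(model, f, n_steps) {
  out <- matrix(NA_real_, n_steps + 1, 3,
                dimnames = list(NULL, c("CC", "NN", "D")))
  out[1, ] <- f
  for (i in seq_len(n_steps)) out[i + 1, ] <- step_divergence_model(model, out[i, ])
  out
}

#' Equilibrium frequencies of the divergence model
#'
#' Closed form: the diverged fraction tends to `d / (d + s)` and the
#' remaining mass splits `alpha : (1 - alpha)` between CC and NN.
#'
#' @param model A [divergence_model()].
#' @return Named length-3 vector `(CC, NN, D)`. With `d = s = 0` every
#'   distribution is stationary; `NA`s are returned with a warning.
#' @export
steady_state <- function(model) {
  d <- model$d; s <- model$s
  if (d + s == 0) {
    warning("d = s = 0: every frequency vector is stationary")
    return(c(CC = NA_real_, NN = NA_real_, D = NA_real_))
  }
  fD <- d / (d + s)
  c(CC = model$alpha * (1 - fD), NN = (1 - model$alpha) * (1 - fD), D = fD)
}

#' Fit divergence rates from two consecutive state-frequency vectors
#'
#' Inverts the difference equations with a symmetric reversion split
#' (`alpha = 0.5`): `d = 1 - (f_CC' - f_NN') / (f_CC - f_NN)` and
#' `s = (f_D - f_D' + d (1 - f_D)) / f_D`. Exactly round-trips with
#' [step_divergence_model()] wherever identifiable.
#'
#' @param f_t,f_t1 State frequencies at consecutive Ks bins (each sums
#'   to 1).
#' @return A [divergence_model()] with the fitted `d`, `s` (clipped to
#'   [0, 1] with a warning if the observed change implies rates outside).
#' @export
fit_divergence_rates <- function(f_t, f_t1) {
  if (abs(sum(f_t) - 1) > 1e-8 || abs(sum(f_t1) - 1) > 1e-8)
    stop("frequency vectors must sum to 1")
  if (abs(f_t[[1]] - f_t[[2]]) < 1e-12)
    stop("f_CC = f_NN: d is unidentifiable from these frequencies")
  if (f_t[[3]] <= 0)
    stop("f_D = 0: s is unidentifiable from these frequencies")
  d <- 1 - (f_t1[[1]] - f_t1[[2]]) / (f_t[[1]] - f_t[[2]])
  s <- (f_t[[3]] - f_t1[[3]] + d * (1 - f_t[[3]])) / f_t[[3]]
  clip <- function(x) min(max(x, 0), 1)
  if (d < 0 || d > 1 || s < 0 || s > 1) {
    warning(sprintf("fitted rates outside [0,1] (d = %.3g, s = %.3g); clipped",
                    d, s))
    d <- clip(d); s <- clip(s)
  }
  divergence_model(d, s)
}

#' Random-pairing significance test for retention between duplicates
#'
#' Compares an observed retention statistic among real duplicate pairs to a
#' null built by randomly re-pairing the gene2 members across pairs
#' (shuffling the second column while the first stays fixed).
#' Statistics: `"state"` counts pairs whose members share the cycling call;
#' `"phase"` counts co-cycling pairs whose members share the phase bin
#' (shuffling is then restricted to co-cycling pairs, matching a null of
#' random association among cycling duplicates).
#'
#' @param pairs data.frame with `cycling1`, `cycling2` and (for the phase
#'   statistic) `phase1`, `phase2`.
#' @param statistic "state" or "phase".
#' @param n_resamples Number of random re-pairings (default 100000).
#' @param seed Integer seed.
#' @return List: `observed`, `null_mean`, `null_sd`, `Z`, `p` (two-sided
#'   empirical, add-one smoothed), `n_resamples`.
#' @export
random_pairing_test <- function(pairs, statistic = c("state", "phase"),
                                n_resamples = 100000, seed = 1L) {
  statistic <- match.arg(statistic)
  set.seed(seed)
  if (statistic == "state") {
    a <- pairs$cycling1; b <- pairs$cycling2
    stat <- function(bb) sum(a == bb)
  } else {
    co <- pairs$cycling1 & pairs$cycling2
    a <- pairs$phase1[co]; b <- pairs$phase2[co]
    stat <- function(bb) sum(a == bb)
  }
  if (length(a) < 2) stop("need >= 2 pairs")
  obs <- stat(b)
  null <- vapply(seq_len(n_resamples), function(i) stat(sample(b)),
                 numeric(1))
  mu <- mean(null); sdev <- stats::sd(null)
  if (sdev == 0) {
    warning("zero null variance")
    z <- 0
    p <- 1 / (n_resamples + 1)
  } else {
    z <- (obs - mu) / sdev
    p <- (sum(abs(null - mu) >= abs(obs - mu)) + 1) / (n_resamples + 1)
  }
  list(observed = obs, null_mean = mu, null_sd = sdev, Z = z, p = p,
       n_resamples = n_resamples)
}

#' Phase-shift enrichment among co-cycling duplicate pairs
#'
#' Builds the observed phase1 x phase2 count matrix over co-cycling pairs,
#' the expected matrix under random re-pairing of the gene2 phases, the
#' per-|delta-phase| enrichment (observed / expected, with phase distance
#' circular on the day ring, max 12 h for a 24-h day), and an ordinary
#' least-squares fit of enrichment on |delta phase|.
#'
#' @param pairs data.frame with `cycling1`, `cycling2`, `phase1`, `phase2`.
#' @param n_resamples Re-pairings for the expected counts (default 10000).
#' @param layout A [sampling_layout()].
#' @param seed Integer seed.
#' @return List: `observed` and `expected` (phase x phase matrices),
#'   `shift_enrichment` (data.frame `delta`, `observed`, `expected`,
#'   `enrichment`), `slope`, `r_squared`, `degenerate` (TRUE when all pairs
#'   share one phase and the regression is meaningless).
#' @export
phase_shift_enrichment <- function(pairs, n_resamples = 10000,
                                   layout = sampling_layout(), seed = 1L) {
  set.seed(seed)
  co <- pairs$cycling1 & pairs$cycling2
  p1 <- pairs$phase1[co]; p2 <- pairs$phase2[co]
  if (length(p1) < 2) stop("need >= 2 co-cycling pairs with phases")
  bins <- zt_bins(layout)
  D <- layout$day_length_hours
  f1 <- factor(p1, levels = bins); f2 <- factor(p2, levels = bins)
  observed <- table(phase1 = f1, phase2 = f2)
  expected <- matrix(0, length(bins), length(bins),
                     dimnames = dimnames(observed))
  for (i in seq_len(n_resamples))
    expected <- expected + table(f1, factor(sample(p2), levels = bins))
  expected <- expected / n_resamples
  circ <- function(a, b) { x <- abs(a - b) %% D; pmin(x, D - x) }
  delta_mat <- outer(bins, bins, circ)
  deltas <- sort(unique(as.vector(delta_mat)))
  se <- do.call(rbind, lapply(deltas, function(dl) {
    sel <- delta_mat == dl
    data.frame(delta = dl, observed = sum(observed[sel]),
               expected = sum(expected[sel]))
  }))
  se$enrichment <- ifelse(se$expected > 0, se$observed / se$expected,
                          NA_real_)
  degenerate <- length(unique(p1)) == 1 && length(unique(p2)) == 1
  slope <- r2 <- NA_real_
  ok <- is.finite(se$enrichment)
  if (!degenerate && sum(ok) >= 2) {
    fit <- stats::lm(enrichment ~ delta, data = se[ok, ])
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  list(observed = unclass(observed), expected = expected,
       shift_enrichment = se, slope = slope, r_squared = r2,
       degenerate = degenerate)
}
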