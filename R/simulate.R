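#' Simulate a diel expression time course with known truth
#'
#' Generates a gene x sample expression matrix emulating a two-day diel
#' RNA-seq design. Cycling genes follow
#' `mean * (1 + a * cos(2*pi*(t - phase)/period))` with multiplicative
#' lognormal noise; the appended days are independent noisy realizations of
#' the same underlying one-day curve, mimicking appended biological
#' replicates. Flat (noncycling) genes are the mean plus the same noise.
#'
#' Defaults emulate the study conditions the package targets: amplitude equal
#' to half the mean, a bimodal phase distribution with peaks near dawn (ZT 0)
#' and dusk (ZT 12), and a 10% coefficient of variation.
#'
#' @param n_cycling,n_flat Numbers of cycling and noncycling genes.
#' @param layout A [sampling_layout()].
#' @param amplitude_ratio Amplitude as a fraction of the gene mean, in (0, 1].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 = noiseless).
#' @param period_hours True period of cycling genes (default: the layout's
#'   day length).
#' @param mean_meanlog,mean_sdlog Lognormal parameters for gene mean
#'   expression (FPKM-like units).
#' @param phase_weights Mixture weights `c(dawn, dusk, uniform)` of the phase
#'   distribution; dawn/dusk components are wrapped normals (sd
#'   `phase_sd_hours`) centred at ZT 0 and ZT `day_length/2`.
#' @param phase_sd_hours Spread of the dawn/dusk phase components.
#' @param fixed_phase Optional single phase (ZT hours) forced on all cycling
#'   genes, overriding the phase distribution.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `expression` (numeric matrix, genes x samples, column
#'   names from [sample_labels()]) and `truth` (data.frame: `gene_id`,
#'   `is_cycling`, `true_period`, `true_phase`, `true_amplitude`,
#'   `true_mean`).
#' @examples
#' sim <- generate_expression(5, 5, seed = 1)
#' dim(sim$expression)
#' head(sim$truth)
#' @export
generate_expression <- function(n_cycling, n_flat,
                                layout = sampling_layout(),
                                amplitude_ratio = 0.5,
                                noise_cv = 0.1,
                                period_hours = layout$day_length_hours,
                                mean_meanlog = log(10), mean_sdlog = 1,
                                phase_weights = c(0.4, 0.3, 0.3),
                                phase_sd_hours = 1.5,
                                fixed_phase = NULL,
                                seed = 1L) {
  stopifnot(n_cycling + n_flat >= 1, noise_cv >= 0)
  if (amplitude_ratio <= 0 || amplitude_ratio > 1)
    stop("amplitude_ratio must be in (0, 1]: larger values force negative expression")
  set.seed(seed)
  n <- n_cycling + n_flat
  gene_id <- sprintf("g%04d", seq_len(n))
  means <- stats::rlnorm(n, mean_meanlog, mean_sdlog)
  if (any(means <= 0)) stop("nonpositive gene means")
  is_cycling <- rep(c(TRUE, FALSE), c(n_cycling, n_flat))

  D <- layout$day_length_hours
  phases <- rep(NA_real_, n)
  if (n_cycling > 0) {
    if (!is.null(fixed_phase)) {
      phases[is_cycling] <- fixed_phase %% D
    } else {
      w <- phase_weights / sum(phase_weights)
      comp <- sample.int(3, n_cycling, replace = TRUE, prob = w)
      ph <- numeric(n_cycling)
      ph[comp == 1] <- stats::rnorm(sum(comp == 1), 0, phase_sd_hours)
      ph[comp == 2] <- stats::rnorm(sum(comp == 2), D / 2, phase_sd_hours)
      ph[comp == 3] <- stats::runif(sum(comp == 3), 0, D)
      phases[is_cycling] <- ph %% D
    }
  }
  amp <- ifelse(is_cycling, amplitude_ratio * means, NA_real_)

  tt <- sample_times(layout)
  expr <- matrix(0, n, layout$n_samples,
                 dimnames = list(gene_id, sample_labels(layout)))
  for (i in seq_len(n)) {
    mu <- if (is_cycling[i]) {
      means[i] * (1 + amplitude_ratio *
                    cos(2 * pi * (tt - phases[i]) / period_hours))
    } else rep(means[i], layout$n_samples)
    expr[i, ] <- mu * rlnorm_cv(layout$n_samples, noise_cv)
  }
  truth <- data.frame(gene_id = gene_id, is_cycling = is_cycling,
                      true_period = ifelse(is_cycling, period_hours, NA_real_),
                      true_phase = phases, true_amplitude = amp,
                      true_mean = means, stringsAsFactors = FALSE)
  list(expression = expr, truth = truth, layout = layout)
}

# unit-mean multiplicative lognormal noise with a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate promoter sequences with planted motif instances
#'
#' Draws i.i.d. background DNA at a given GC content and, for genes assigned
#' to a phase with a motif in the plant plan, inserts one consensus instance
#' of that phase's motif at a uniform random position with the configured
#' probability.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param gene_phase Named vector (names = gene ids) giving each gene's phase
#'   label, or `NULL` for no phase structure.
#' @param plant_plan Named list keyed by phase label; each element is a list
#'   with `pwm` (4 x L probability matrix, rows A,C,G,T) and
#'   `plant_frequency` in [0, 1].
#' @param length Promoter length in bp (default 1000).
#' @param gc_content Background GC fraction (default 0.5).
#' @param seed Integer seed.
#' @return A list with `sequences` (a [Biostrings::DNAStringSet]) and `sites`
#'   (data.frame of planted sites: `gene_id`, `phase`, `start`, `width`,
#'   `seq`).
#' @export
generate_promoters <- function(gene_ids, gene_phase = NULL, plant_plan = list(),
                               length = 1000, gc_content = 0.5, seed = 1L) {
  set.seed(seed)
  base_prob <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                 G = gc_content / 2, T = (1 - gc_content) / 2)
  for (p in plant_plan) {
    check_pwm(p$pwm)
    if (ncol(p$pwm) > length) stop("motif longer than promoter")
    if (p$plant_frequency < 0 || p$plant_frequency > 1)
      stop("plant_frequency must be in [0, 1]")
  }
  seqs <- character(base::length(gene_ids))
  sites <- list()
  for (i in seq_along(gene_ids)) {
    s <- sample(names(base_prob), length, replace = TRUE, prob = base_prob)
    ph <- if (!is.null(gene_phase)) as.character(gene_phase[[gene_ids[i]]]) else NA
    if (!is.na(ph) && ph %in% names(plant_plan)) {
      plan <- plant_plan[[ph]]
      if (stats::runif(1) < plan$plant_frequency) {
        cons <- pwm_consensus(plan$pwm)
        L <- nchar(cons)
        pos <- sample.int(length - L + 1, 1)
        s[pos:(pos + L - 1)] <- strsplit(cons, "")[[1]]
        sites[[base::length(sites) + 1]] <-
          data.frame(gene_id = gene_ids[i], phase = ph, start = pos,
                     width = L, seq = cons, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  sites <- if (base::length(sites)) do.call(rbind, sites) else
    data.frame(gene_id = character(), phase = character(), start = integer(),
               width = integer(), seq = character(), stringsAsFactors = FALSE)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- gene_ids
  list(sequences = out, sites = sites)
}

#' Simulate duplicate-gene pairs under the three-state divergence model
#'
#' Each pair starts in a state drawn from `initial_freqs` (both cycling CC,
#' both noncycling NN, or diverged D) and takes one stochastic model step per
#' Ks bin: identical pairs diverge with probability `d`; diverged pairs
#' revert with probability `s`, landing in CC with probability `alpha`.
#' Pairs in bin b have taken b - 1 steps, so empirical per-bin state
#' frequencies converge to the deterministic trajectory of
#' [step_divergence_model()] as `pairs_per_bin` grows. Co-cycling pairs get
#' gene2's phase from gene1's phase plus a circular shift drawn from
#' `shift_kernel`; the cycling member of a diverged pair gets a uniform
#' phase.
#'
#' @param n_bins Number of Ks bins of width `bin_width`.
#' @param pairs_per_bin Pairs simulated per bin.
#' @param d,s,alpha Model rates; see [step_divergence_model()].
#' @param initial_freqs Length-3 probability vector `c(CC, NN, D)`.
#' @param bin_width Ks bin width (default 0.3).
#' @param shift_kernel Named probability vector over phase shifts in hours
#'   (names like "0", "3", "-3", ...); must sum to 1. Default favours
#'   retention of the same or a +/- one-interval phase.
#' @param layout A [sampling_layout()] defining the phase bins.
#' @param seed Integer seed.
#' @return data.frame: `gene1`, `gene2`, `ks`, `state` ("CC"/"NN"/"D"),
#'   `cycling1`, `cycling2`, `phase1`, `phase2`.
#' @export
generate_duplicate_pairs <- function(n_bins = 6, pairs_per_bin = 200,
                                     d = 0.42, s = 0.53, alpha = 0.5,
                                     initial_freqs = c(0.25, 0.6, 0.15),
                                     bin_width = 0.3,
                                     shift_kernel = default_shift_kernel(),
                                     layout = sampling_layout(),
                                     seed = 1L) {
  stopifnot(d >= 0, d <= 1, s >= 0, s <= 1, alpha >= 0, alpha <= 1)
  if (abs(sum(initial_freqs) - 1) > 1e-8)
    stop("initial_freqs must sum to 1")
  if (abs(sum(shift_kernel) - 1) > 1e-8)
    stop("shift_kernel probabilities must sum to 1")
  set.seed(seed)
  bins <- zt_bins(layout)
  D_len <- layout$day_length_hours
  states <- c("CC", "NN", "D")
  res <- vector("list", n_bins * pairs_per_bin)
  k <- 0
  for (b in seq_len(n_bins)) {
    for (j in seq_len(pairs_per_bin)) {
      st <- sample(states, 1, prob = initial_freqs)
      for (step in seq_len(b - 1)) {
        if (st %in% c("CC", "NN")) {
          if (stats::runif(1) < d) st <- "D"
        } else if (stats::runif(1) < s) {
          st <- if (stats::runif(1) < alpha) "CC" else "NN"
        }
      }
      ks <- stats::runif(1, (b - 1) * bin_width, b * bin_width)
      ph1 <- ph2 <- NA_real_
      if (st == "CC") {
        ph1 <- sample(bins, 1)
        shift <- as.numeric(sample(names(shift_kernel), 1,
                                   prob = shift_kernel))
        ph2 <- (ph1 + shift) %% D_len
      } else if (st == "D") {
        ph1 <- sample(bins, 1)  # gene1 taken as the cycling member
      }
      k <- k + 1
      res[[k]] <- data.frame(
        gene1 = sprintf("dupA%05d", k), gene2 = sprintf("dupB%05d", k),
        ks = ks, state = st,
        cycling1 = st != "NN", cycling2 = st == "CC",
        phase1 = ph1, phase2 = ph2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' @rdname generate_duplicate_pairs
#' @param p0 Probability of a zero phase shift.
#' @param p_adj Probability of each +/- one-interval shift.
#' @return `default_shift_kernel()`: the default named kernel
#'   (P(0) = 0.4, P(+/-3 h) = 0.2 each, remainder uniform).
#' @export
default_shift_kernel <- function(layout = sampling_layout(), p0 = 0.4,
                                 p_adj = 0.2) {
  D <- layout$day_length_hours
  iv <- layout$interval_hours
  shifts <- seq(-D / 2 + iv, D / 2, by = iv)
  p <- stats::setNames(rep(0, length(shifts)), as.character(shifts))
  p["0"] <- p0
  p[as.character(c(-iv, iv))] <- p_adj
  rest <- setdiff(names(p), as.character(c(0, -iv, iv)))
  p[rest] <- (1 - p0 - 2 * p_adj) / length(rest)
  p
}

#' Simulate a gene-to-term annotation table
#'
#' Builds phase-linked terms (most members drawn from one phase's genes) and
#' background terms (members drawn uniformly), for exercising phase
#' enrichment with known truth.
#'
#' @param gene_phase Named vector mapping gene id to phase label (NA for
#'   genes outside any phase cluster).
#' @param terms_per_phase Number of phase-linked terms per phase.
#' @param genes_per_term Members per term (>= 2).
#' @param background_terms Number of unlinked terms.
#' @param purity Fraction of a phase-linked term's members drawn from its
#'   phase (default 0.9).
#' @param seed Integer seed.
#' @return data.frame `gene_id`, `term_id`, plus attribute `term_truth`
#'   (data.frame `term_id`, `phase`).
#' @export
generate_annotations <- function(gene_phase, terms_per_phase = 1,
                                 genes_per_term = 20, background_terms = 0,
                                 purity = 0.9, seed = 1L) {
  stopifnot(genes_per_term >= 2)
  set.seed(seed)
  genes <- names(gene_phase)
  phases <- sort(unique(stats::na.omit(gene_phase)))
  rows <- list(); truth <- list()
  add_term <- function(id, members, phase) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene_id = members, term_id = id, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <<- data.frame(
      term_id = id, phase = phase, stringsAsFactors = FALSE)
  }
  for (ph in if (terms_per_phase > 0) phases else character()) {
    in_ph <- genes[!is.na(gene_phase) & gene_phase == ph]
    out_ph <- setdiff(genes, in_ph)
    for (t in seq_len(terms_per_phase)) {
      n_in <- min(round(purity * genes_per_term), length(in_ph))
      n_out <- genes_per_term - n_in
      if (n_out > length(out_ph)) stop("requested term larger than gene pool")
      add_term(sprintf("term_phase%s_%d", ph, t),
               c(sample(in_ph, n_in), sample(out_ph, n_out)),
               as.character(ph))
    }
  }
  for (t in seq_len(background_terms)) {
    if (genes_per_term > length(genes))
      stop("requested term larger than gene pool")
    add_term(sprintf("term_bg_%d", t), sample(genes, genes_per_term), NA)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), term_id = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "term_truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(term_id = character(), phase = character(),
               stringsAsFactors = FALSE)
  out
}

#' Simulate ortholog pairs of two species
#'
#' Produces pairs with configurable marginal cycling rates, an excess of
#' co-cycling pairs over independence, a log-scale amplitude correlation and
#' a fraction of phase-matched pairs, for exercising the cross-species
#' comparison with known truth.
#'
#' @param n_pairs Number of ortholog pairs.
#' @param p_cycling_a,p_cycling_b Marginal cycling probabilities.
#' @param co_cycling_excess Added probability mass on the both-cycling cell
#'   relative to independence (0 = independent).
#' @param amplitude_cor Correlation of log amplitudes among co-cycling pairs.
#' @param phase_match_prob Probability a co-cycling pair shares gene A's
#'   phase bin exactly; otherwise gene B's phase is uniform.
#' @param layout A [sampling_layout()].
#' @param seed Integer seed.
#' @return data.frame: `geneA`, `geneB`, `cyclingA`, `cyclingB`,
#'   `amplitudeA`, `amplitudeB`, `phaseA`, `phaseB`.
#' @export
generate_ortholog_pairs <- function(n_pairs = 1000, p_cycling_a = 0.45,
                                    p_cycling_b = 0.3,
                                    co_cycling_excess = 0.024,
                                    amplitude_cor = 0.55,
                                    phase_match_prob = 0.2,
                                    layout = sampling_layout(), seed = 1L) {
  set.seed(seed)
  p11 <- p_cycling_a * p_cycling_b + co_cycling_excess
  p10 <- p_cycling_a - p11; p01 <- p_cycling_b - p11
  p00 <- 1 - p11 - p10 - p01
  if (min(p11, p10, p01, p00) < 0) stop("infeasible cell probabilities")
  cell <- sample(c("11", "10", "01", "00"), n_pairs, replace = TRUE,
                 prob = c(p11, p10, p01, p00))
  cycA <- cell %in% c("11", "10"); cycB <- cell %in% c("11", "01")
  la <- stats::rnorm(n_pairs); z <- stats::rnorm(n_pairs)
  lb <- amplitude_cor * la + sqrt(1 - amplitude_cor^2) * z
  bins <- zt_bins(layout)
  phA <- ifelse(cycA, sample(bins, n_pairs, replace = TRUE), NA_real_)
  phB <- rep(NA_real_, n_pairs)
  co <- which(cycA & cycB)
  match <- stats::runif(length(co)) < phase_match_prob
  phB[co[match]] <- phA[co[match]]
  phB[co[!match]] <- sample(bins, sum(!match), replace = TRUE)
  only_b <- which(!cycA & cycB)
  phB[only_b] <- sample(bins, length(only_b), replace = TRUE)
  data.frame(geneA = sprintf("spA%05d", seq_len(n_pairs)),
             geneB = sprintf("spB%05d", seq_len(n_pairs)),
             cyclingA = cycA, cyclingB = cycB,
             amplitudeA = ifelse(cycA, exp(la + 1), NA_real_),
             amplitudeB = ifelse(cycB, exp(lb + 1), NA_real_),
             phaseA = phA, phaseB = phB, stringsAsFactors = FALSE)
}
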