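test_that("upper-quartile normalization matches hand-computed scaling", {
  m <- cbind(A = c(1, 2, 3, 4, 5), B = 2 * c(1, 2, 3, 4, 5),
             C = c(0, 1, 2, 3, 4))
  rownames(m) <- paste0("g", 1:5)
  out <- upper_quartile_normalize(m)
  # per-sample upper quartiles over nonzero genes: 4, 8, 3.25; common
  # reference = mean = 5.083333; each column scaled by reference / uq
  ref <- mean(c(4, 8, 3.25))
  expect_equal(out[, "A"], m[, "A"] * ref / 4)
  expect_equal(out[, "B"], m[, "B"] * ref / 8)
  expect_equal(out[, "C"], m[, "C"] * ref / 3.25)
  # a doubled sample becomes identical to the original after normalization
  expect_equal(out[, "A"], out[, "B"], ignore_attr = TRUE)
  expect_error(upper_quartile_normalize(cbind(c(0, 0), c(1, 2))),
               "all-zero")
})

test_that("dft_spectrum equals brute-force evaluation and closed forms", {
  # constant segment: all power zero after mean-centering
  expect_true(all(dft_spectrum(rep(5, 8))$power == 0))
  # pure cosine of one cycle in 8 points: |y_1| = M/2, other bins 0
  x <- cos(2 * pi * (0:7) / 8)
  pw <- dft_spectrum(x)$power
  expect_equal(unname(pw["1"]), 16, tolerance = 1e-10)  # (8/2)^2
  expect_lt(max(pw[c("0", "2", "3", "4")]), 1e-20)
  # arbitrary vectors match the naive O(M^2) sum
  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(8)
    got <- dft_spectrum(v, center = FALSE)$coefficients
    expect_equal(got, brute_dft(v), tolerance = 1e-10)
  }
  expect_error(dft_spectrum(3), "length >= 2")
})

test_that("Parseval identity holds for mean-centred segments", {
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(8); v <- v - mean(v)
    y <- dft_spectrum(v, center = FALSE)$coefficients
    expect_equal(sum(v^2), sum(Mod(y)^2) / 8, tolerance = 1e-10)
  }
})

test_that("cyclic score is 1 for daily cosines, ~0 for half-day cosines, 0 for constants", {
  lay <- study_layout()
  tt <- sample_times(lay)
  expect_equal(cyclic_score(10 * (1 + 0.5 * cos(2 * pi * (tt - 3) / 24)), lay), 1)
  expect_lt(cyclic_score(10 * (1 + 0.5 * cos(2 * pi * tt / 12)), lay), 1e-12)
  expect_equal(cyclic_score(rep(7, 16), lay), 0)
})

test_that("cyclic score matches an independent step-by-step reimplementation", {
  lay <- study_layout()
  set.seed(3)
  for (i in 1:100) {
    v <- rlnorm(16)
    expect_equal(cyclic_score(v, lay), brute_cyclic_score(v, lay),
                 tolerance = 1e-10)
  }
  # and for the half-overlap configuration
  v <- rlnorm(16)
  expect_equal(cyclic_score(v, lay, overlap = 0.5),
               brute_cyclic_score(v, lay, overlap = 0.5), tolerance = 1e-10)
})

test_that("cyclic score is invariant to positive affine transforms", {
  lay <- study_layout()
  set.seed(4)
  for (i in 1:20) {
    v <- rlnorm(16)
    expect_equal(cyclic_score(3.7 * v + 11, lay), cyclic_score(v, lay),
                 tolerance = 1e-9)
  }
})

test_that("normalized segment spectra attain exactly 0 and 1", {
  set.seed(5)
  v <- rnorm(8)
  pw <- dft_spectrum(v)$power[-1]
  nm <- (pw - min(pw)) / (max(pw) - min(pw))
  expect_equal(max(nm), 1)
  expect_equal(min(nm), 0)
})

test_that("permutation null is reproducible and bounded in [0,1]", {
  expr <- generate_expression(20, 20, seed = 6)$expression
  n1 <- null_score_distribution(expr, 200, seed = 10)
  n2 <- null_score_distribution(expr, 200, seed = 10)
  expect_identical(n1$scores, n2$scores)
  expect_true(all(n1$scores >= 0 & n1$scores <= 1))
  expect_error(null_score_distribution(expr[0, , drop = FALSE], 10), "empty")
})

test_that("sampled null percentiles match exhaustive permutation enumeration", {
  lay <- tiny_layout()   # 6 samples: 720 permutations enumerable
  v <- c(2.1, 0.4, 3.3, 0.9, 5.0, 1.2)
  perms <- matrix(unlist(combinat_perms(6)), ncol = 6, byrow = TRUE)
  exact <- apply(perms, 1, function(p) cyclic_score(v[p], lay))
  expr <- matrix(v, 1, dimnames = list("g1", NULL))
  sampled <- null_score_distribution(expr, 4000, lay, seed = 12)$scores
  for (q in c(0.5, 0.9, 0.95)) {
    expect_lt(abs(quantile(sampled, q) - quantile(exact, q)), 0.05)
  }
})

test_that("top-percentile threshold follows the order-statistic rule", {
  scores <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  # top 20% of 10 scores: the 2nd-largest
  expect_equal(threshold_at_top_percentile(scores, 20), 0.8)
  expect_equal(threshold_at_top_percentile(scores, 10), 0.9)
  # fraction of null at/above the top-2% threshold is ~2%
  set.seed(13)
  ns <- replicate(3000, cyclic_score(rlnorm(16), study_layout()))
  thr <- threshold_at_top_percentile(ns, 2)
  expect_equal(mean(ns >= thr), 0.02, tolerance = 0.35)
  expect_warning(threshold_at_top_percentile(c(0.1, 0.2), 2), "too small")
})

test_that("cycling calls respect the threshold and planted truth", {
  sc <- c(a = 0.1, b = 0.95, c = 0.5)
  expect_equal(call_cycling(sc, 0)$is_cycling, c(TRUE, TRUE, TRUE))
  expect_equal(call_cycling(sc, 0.9)$is_cycling, c(FALSE, TRUE, FALSE))
  sim <- generate_expression(100, 200, seed = 14)
  det <- detect_cycling(sim$expression, study_layout(),
                        n_permutations = 1500, seed = 15)
  sens <- mean(det$fits$is_cycling[sim$truth$is_cycling])
  fpr <- mean(det$fits$is_cycling[!sim$truth$is_cycling])
  expect_gt(sens, 0.95)
  expect_lt(fpr, 0.07)
  # empirical p is add-one smoothed, so never 0
  expect_true(all(det$fits$p > 0))
})

test_that("parameter fits recover noiseless planted parameters exactly", {
  lay <- study_layout()
  tt <- sample_times(lay)
  fp <- fit_cyclic_parameters(4 + 2 * cos(2 * pi * (tt - 6) / 24), lay)
  expect_equal(fp$period, 24)
  expect_equal(fp$amplitude, 2)
  expect_equal(fp$phase, 6)
  # shifting the input by one 3-h sample shifts the phase by 3 h
  x0 <- 4 + 2 * cos(2 * pi * tt / 24)
  expect_equal(fit_cyclic_parameters(x0, lay)$phase, 0)
  x3 <- 4 + 2 * cos(2 * pi * (tt - 3) / 24)
  expect_equal(fit_cyclic_parameters(x3, lay)$phase, 3)
})

test_that("a spectral peak at Nyquist is flagged and not interpolated", {
  lay <- study_layout()
  tt <- sample_times(lay)
  x <- 4 + cos(2 * pi * tt / 6)   # 6-h period = Nyquist at 3-h sampling
  fp <- fit_cyclic_parameters(x, lay)
  expect_true(fp$at_edge)
  expect_false(fp$interpolated)
  expect_equal(fp$period, 6)
})

test_that("phase error on noisy planted cohorts is small", {
  lay <- study_layout()
  sim <- generate_expression(150, 0, seed = 16)
  truth <- sim$truth
  err <- vapply(seq_len(150), function(i) {
    est <- fit_cyclic_parameters(sim$expression[i, ], lay)$phase
    d <- abs(est - truth$true_phase[i]) %% 24
    min(d, 24 - d)
  }, numeric(1))
  expect_lte(median(err), 1.5)
})

test_that("phase clusters follow the day-averaged peak with early-ZT ties", {
  lay <- study_layout()
  x <- rep(0, 16); x[8] <- x[16] <- 5      # ZT21 peak on both days
  expect_equal(assign_phase_cluster(x, lay), 21)
  x2 <- rep(0, 16); x2[1] <- x2[5] <- 3    # exact tie ZT0 vs ZT12
  x2[9] <- x2[13] <- 3
  expect_equal(assign_phase_cluster(x2, lay), 0)
  # a noiseless planted ZT21 cohort lands in cluster 21 without exception
  sim <- generate_expression(30, 0, noise_cv = 0, fixed_phase = 21,
                             seed = 17)
  cl <- apply(sim$expression, 1, assign_phase_cluster, layout = lay)
  expect_true(all(cl == 21))
})
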