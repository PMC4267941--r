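test_that("cycling genes have amplitude equal to half the mean and correct layout", {
  sim <- generate_expression(30, 20, seed = 7)
  expect_equal(dim(sim$expression), c(50, 16))
  expect_identical(colnames(sim$expression), sample_labels(study_layout()))
  cyc <- sim$truth[sim$truth$is_cycling, ]
  expect_equal(cyc$true_amplitude, 0.5 * cyc$true_mean)
  expect_true(all(cyc$true_phase >= 0 & cyc$true_phase < 24))
  expect_true(all(is.na(sim$truth$true_phase[!sim$truth$is_cycling])))
  # amplitude <= mean keeps expression nonnegative
  expect_true(all(sim$expression >= 0))
})

test_that("noiseless cycling gene peaks at its planted phase on both days", {
  sim <- generate_expression(1, 0, noise_cv = 0, fixed_phase = 6, seed = 1)
  x <- sim$expression[1, ]
  expect_equal(unname(which.max(x[1:8])), 3)    # ZT6 is the 3rd sample
  expect_equal(unname(which.max(x[9:16])), 3)
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_expression(100, 100, seed = 42)
  b <- generate_expression(100, 100, seed = 42)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  p1 <- generate_promoters(c("g1", "g2"), seed = 9)
  p2 <- generate_promoters(c("g1", "g2"), seed = 9)
  expect_identical(as.character(p1$sequences), as.character(p2$sequences))
  d1 <- generate_duplicate_pairs(3, 50, seed = 5)
  d2 <- generate_duplicate_pairs(3, 50, seed = 5)
  expect_identical(d1, d2)
})

test_that("amplitude ratio above 1 and empty cohorts are rejected", {
  expect_error(generate_expression(5, 5, amplitude_ratio = 1.5),
               "amplitude_ratio")
  expect_error(generate_expression(0, 0), "n_cycling")
})

test_that("true amplitude and mean are tightly coupled under defaults", {
  sim <- generate_expression(300, 0, seed = 3)
  cyc <- sim$truth[sim$truth$is_cycling, ]
  r2 <- cor(cyc$true_amplitude, cyc$true_mean)^2
  expect_gt(r2, 0.7)
})

test_that("phase distribution is bimodal near dawn and dusk", {
  sim <- generate_expression(2000, 0, seed = 8)
  ph <- sim$truth$true_phase[sim$truth$is_cycling]
  near_dawn <- mean(pmin(ph, 24 - ph) <= 2)
  near_dusk <- mean(abs(ph - 12) <= 2)
  # 40% dawn and 30% dusk components plus uniform spill-over
  expect_gt(near_dawn, 0.35)
  expect_gt(near_dusk, 0.25)
  expect_lt(near_dawn + near_dusk, 0.95)
})

test_that("promoter generator plants consensus sites as configured", {
  ids <- sprintf("g%02d", 1:20)
  phase <- setNames(rep(c("0", "12"), each = 10), ids)
  plan <- list("0" = list(pwm = toy_pwm(), plant_frequency = 1.0))
  pr <- generate_promoters(ids, phase, plan, length = 300, seed = 2)
  cons <- pwm_consensus(toy_pwm())
  hits <- vapply(as.character(pr$sequences[1:10]),
                 function(s) grepl(cons, s), logical(1))
  expect_true(all(hits))
  expect_true(all(pr$sites$gene_id %in% ids[1:10]))
  # plant frequency 0 -> empty truth table
  pr0 <- generate_promoters(ids, phase,
                            list("0" = list(pwm = toy_pwm(),
                                            plant_frequency = 0)),
                            length = 300, seed = 2)
  expect_equal(nrow(pr0$sites), 0)
})

test_that("background GC content matches the configured fraction", {
  pr <- generate_promoters(sprintf("g%d", 1:10), length = 1000,
                           gc_content = 0.64, seed = 4)
  freq <- colSums(Biostrings::alphabetFrequency(pr$sequences)[, c("C", "G")])
  gc <- sum(freq) / (10 * 1000)
  # binomial 99% bounds around 0.64 for n = 10000 bases
  half <- 2.576 * sqrt(0.64 * 0.36 / 10000)
  expect_lt(abs(gc - 0.64), half)
})

test_that("motif longer than promoter is rejected", {
  plan <- list("0" = list(pwm = toy_pwm(), plant_frequency = 1))
  expect_error(generate_promoters("g1", c(g1 = "0"), plan, length = 4),
               "longer than promoter")
})

test_that("duplicate pairs keep their initial state when d = s = 0", {
  pairs <- generate_duplicate_pairs(5, 100, d = 0, s = 0,
                                    initial_freqs = c(0.3, 0.4, 0.3),
                                    seed = 11)
  freqs <- state_frequencies_by_ks(pairs)
  # per-bin frequencies stay near the initial mix in every bin
  expect_true(all(abs(freqs$f_CC - 0.3) < 0.15))
  expect_true(all(abs(freqs$f_D - 0.3) < 0.15))
})

test_that("simulated state frequencies track the model trajectory", {
  d <- 0.42; s <- 0.53
  f0 <- c(0.3, 0.35, 0.35)
  n_bins <- 5
  pairs <- generate_duplicate_pairs(n_bins, 4000, d = d, s = s,
                                    initial_freqs = f0, seed = 21)
  freqs <- state_frequencies_by_ks(pairs)
  traj <- iterate_divergence_model(divergence_model(d, s), f0, n_bins - 1)
  expect_lt(max(abs(freqs$f_D - traj[, "D"])), 0.03)
  expect_lt(max(abs(freqs$f_CC - traj[, "CC"])), 0.03)
})

test_that("a point-mass shift kernel yields identical phases in co-cycling pairs", {
  kern <- c("0" = 1)
  pairs <- generate_duplicate_pairs(3, 100, shift_kernel = kern, seed = 3)
  co <- pairs$state == "CC"
  expect_true(all(pairs$phase1[co] == pairs$phase2[co]))
})

test_that("annotation generator produces phase-linked and background terms", {
  sim <- generate_expression(200, 0, seed = 13)
  gp <- setNames(sample(c(0, 12), 200, replace = TRUE), sim$truth$gene_id)
  ann <- generate_annotations(gp, terms_per_phase = 1, genes_per_term = 30,
                              background_terms = 2, seed = 6)
  expect_setequal(unique(ann$term_id),
                  c("term_phase0_1", "term_phase12_1", "term_bg_1",
                    "term_bg_2"))
  expect_true(all(table(ann$term_id) == 30))
  # phase-linked term draws most members from its own phase
  m0 <- ann$gene_id[ann$term_id == "term_phase0_1"]
  expect_gte(mean(gp[m0] == 0), 0.8)
  # zero terms -> empty table
  empty <- generate_annotations(gp, terms_per_phase = 0, genes_per_term = 5,
                                background_terms = 0)
  expect_equal(nrow(empty), 0)
})
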