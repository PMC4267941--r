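#!/usr/bin/env Rscript
# Stage 4: cycling-state conservation between duplicate pairs across Ks
# bins, the three-state divergence model fit, and randomization tests of
# state and phase retention.

suppressPackageStartupMessages(library(dielcycle))
seed <- 4L
pairs <- read_tsv("results/synthetic/duplicate_pairs.tsv")

freqs <- state_frequencies_by_ks(pairs, bin_width = 0.3)
write_tsv(freqs, "results/ks_state_frequencies.tsv")
message(paste(capture.output(print(freqs, digits = 3)), collapse = "\n"))

# fit d and s from the change between the Ks 0.6-0.9 and 0.9-1.2 bins
i <- match(3, freqs$bin); j <- match(4, freqs$bin)
fit <- fit_divergence_rates(unlist(freqs[i, c("f_CC", "f_NN", "f_D")]),
                            unlist(freqs[j, c("f_CC", "f_NN", "f_D")]))
ss <- steady_state(fit)
message(sprintf("fitted rates: d = %.3f, s = %.3f; asymptotic f_D = %.3f",
                fit$d, fit$s, ss[["D"]]))
traj <- iterate_divergence_model(fit, unlist(freqs[1, c("f_CC", "f_NN",
                                                        "f_D")]),
                                 nrow(freqs) - 1)
write_tsv(as.data.frame(traj), "results/model_trajectory.tsv")
message(sprintf("trajectory RMSE vs observed f_D: %.3f",
                sqrt(mean((traj[, "D"] - freqs$f_D)^2))))

st <- random_pairing_test(pairs, "state", n_resamples = 100000, seed = seed)
ph <- random_pairing_test(pairs, "phase", n_resamples = 100000,
                          seed = seed + 1L)
message(sprintf("state retention: obs %d, null %.1f +/- %.1f, Z = %.1f, p = %.2g",
                st$observed, st$null_mean, st$null_sd, st$Z, st$p))
message(sprintf("phase retention: obs %d, null %.1f +/- %.1f, Z = %.1f, p = %.2g",
                ph$observed, ph$null_mean, ph$null_sd, ph$Z, ph$p))

shift <- phase_shift_enrichment(pairs, n_resamples = 10000, seed = seed + 2L)
write_tsv(shift$shift_enrichment, "results/phase_shift_enrichment.tsv")
message(sprintf("shift-enrichment slope %.3f, r^2 = %.2f",
                shift$slope, shift$r_squared))
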