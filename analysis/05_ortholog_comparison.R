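#!/usr/bin/env Rscript
# Stage 5: association of cycling state between ortholog pairs of two
# species and agreement of amplitude and phase among co-cycling pairs.

suppressPackageStartupMessages(library(dielcycle))
orth <- read_tsv("results/synthetic/ortholog_pairs.tsv")

ct <- co_cycling_contingency_test(orth)
message(sprintf("co-cycling: %.1f%% observed vs %.1f%% expected (chi^2 = %.1f, p = %.2g)",
                ct$observed_pct, ct$expected_pct, ct$chisq, ct$p))

agr <- cross_species_parameter_agreement(orth)
message(sprintf("amplitude r^2 = %.2f (p = %.2g); phase r^2 = %.3f (circular r = %.3f)",
                agr$amplitude_r2, agr$amplitude_p, agr$phase_r2,
                agr$circular_phase_r))
write_tsv(data.frame(
  n_pairs = ct$n, observed_pct = ct$observed_pct,
  expected_pct = ct$expected_pct, chisq = ct$chisq, p = ct$p,
  amplitude_r2 = agr$amplitude_r2, phase_r2 = agr$phase_r2,
  circular_phase_r = agr$circular_phase_r),
  "results/ortholog_summary.tsv")
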