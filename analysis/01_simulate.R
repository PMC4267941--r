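#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known ground truth.
# Emulates the diel design: 8 ZT points at 3-h intervals, two biological
# replicates appended as two consecutive days; cycling genes with
# amplitude = half the mean and a bimodal phase distribution; duplicate
# pairs evolved under the three-state model; ortholog pairs with a planted
# amplitude correlation; promoters with phase-specific planted motifs.

suppressPackageStartupMessages(library(dielcycle))
seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
lay <- sampling_layout()

sim <- generate_expression(n_cycling = 800, n_flat = 1200, layout = lay,
                           amplitude_ratio = 0.5, noise_cv = 0.1,
                           seed = seed)
write_expression_tsv(sim$expression, file.path(out, "expression.tsv"))
write_tsv(sim$truth, file.path(out, "truth.tsv"))
message(sprintf("expression: %d genes x %d samples (%d cycling planted)",
                nrow(sim$expression), ncol(sim$expression),
                sum(sim$truth$is_cycling)))

pairs <- generate_duplicate_pairs(n_bins = 6, pairs_per_bin = 3000,
                                  d = 0.42, s = 0.53,
                                  initial_freqs = c(0.2, 0.65, 0.15),
                                  seed = seed + 1L)
write_tsv(pairs, file.path(out, "duplicate_pairs.tsv"))
message(sprintf("duplicates: %d pairs in 6 Ks bins", nrow(pairs)))

orth <- generate_ortholog_pairs(n_pairs = 11845, p_cycling_a = 0.47,
                                p_cycling_b = 0.28,
                                co_cycling_excess = 0.024,
                                amplitude_cor = 0.55, seed = seed + 2L)
write_tsv(orth, file.path(out, "ortholog_pairs.tsv"))
message(sprintf("orthologs: %d pairs, %d co-cycling", nrow(orth),
                sum(orth$cyclingA & orth$cyclingB)))

# promoters for the cycling genes, with one planted motif per focal phase
cyc <- sim$truth[sim$truth$is_cycling, ]
gene_phase <- setNames(as.character(3 * round(cyc$true_phase / 3) %% 24),
                       cyc$gene_id)
plan <- list("0"  = list(pwm = pwm_from_consensus("ACGTACGTC", 0.9),
                         plant_frequency = 0.8),
             "12" = list(pwm = pwm_from_consensus("TTGACGTCA", 0.9),
                         plant_frequency = 0.8))
prom <- generate_promoters(cyc$gene_id, gene_phase, plan, length = 1000,
                           gc_content = 0.64, seed = seed + 3L)
Biostrings::writeXStringSet(prom$sequences,
                            file.path(out, "promoters.fasta"))
write_tsv(prom$sites, file.path(out, "planted_sites.tsv"))
write_meme_motifs(lapply(plan, `[[`, "pwm") |>
                    setNames(c("dawn_box", "dusk_box")),
                  file.path(out, "motifs.meme"))
message(sprintf("promoters: %d sequences, %d planted sites",
                length(prom$sequences), nrow(prom$sites)))

ann <- generate_annotations(gene_phase, terms_per_phase = 2,
                            genes_per_term = 40, background_terms = 5,
                            seed = seed + 4L)
write_tsv(ann, file.path(out, "annotations.tsv"))
write_tsv(attr(ann, "term_truth"), file.path(out, "term_truth.tsv"))
message(sprintf("annotations: %d gene-term links, %d terms",
                nrow(ann), length(unique(ann$term_id))))
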