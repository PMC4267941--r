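#!/usr/bin/env Rscript
# Stage 6: scan promoters with the motif set at an exact p-value
# threshold, merge redundant motifs, assign motifs to phases by
# enrichment, and predict expression phase with naive and max-margin
# classifiers.

suppressPackageStartupMessages(library(dielcycle))
seed <- 6L
prom <- Biostrings::readDNAStringSet("results/synthetic/promoters.fasta")
motifs <- read_meme_motifs("results/synthetic/motifs.meme")
fits <- read_tsv("results/fits.tsv")
cyc <- fits[fits$is_cycling, ]
gp <- setNames(cyc$phase_cluster, cyc$gene_id)
gp <- gp[names(gp) %in% names(prom)]

motifs <- merge_motifs_upgma(motifs)
message(sprintf("motifs after UPGMA merge: %d", length(motifs)))

scan <- scan_promoters(motifs, prom, p = 1e-05)
message(sprintf("presence matrix: %d genes x %d motifs; %d hits",
                nrow(scan$presence), ncol(scan$presence), nrow(scan$hits)))

enr <- pcre_enrichment(scan$presence, gp)
write_tsv(enr$assignment, "results/motif_phase_assignment.tsv")
message(paste(capture.output(print(enr$assignment)), collapse = "\n"))

naive <- naive_phase_classifier(scan$presence, enr$assignment, gp)
write_tsv(naive, "results/naive_classifier.tsv")
message(paste(capture.output(print(naive, digits = 3)), collapse = "\n"))

genes <- intersect(rownames(scan$presence), names(gp))
svm_rows <- lapply(unique(enr$assignment$phase), function(ph) {
  fit <- svm_phase_classifier(scan$presence[genes, , drop = FALSE],
                              gp[genes] == ph, folds = 10, seed = seed)
  data.frame(phase = ph, auc = fit$cv_auc, f_measure = fit$cv_f_measure,
             best_C = fit$best_C, best_R = fit$best_R)
})
svm_report <- do.call(rbind, svm_rows)
write_tsv(svm_report, "results/svm_classifier.tsv")
message(paste(capture.output(print(svm_report, digits = 3)),
              collapse = "\n"))

# phase-expression cluster survey
subs <- read_tsv("results/subclusters.tsv")
subs <- subs[subs$gene_id %in% genes, ]
clusters <- split(subs$gene_id,
                  paste0("ZT", subs$phase_cluster, ".", subs$subcluster))
survey <- cluster_classification_survey(clusters,
                                        scan$presence[genes, , drop = FALSE],
                                        universe = genes,
                                        C_grid = c(0.1, 1), R_grid = c(1, 2),
                                        folds = 5, seed = seed + 1L)
write_tsv(survey$survey, "results/cluster_survey.tsv")
message(sprintf("clusters with AUC > 0.7: %d of %d, covering %d genes (%.2f%% of cycling)",
                survey$n_above, sum(!survey$survey$skipped),
                survey$genes_above, 100 * survey$coverage))
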