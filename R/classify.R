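#' Ranking and operating-point metrics for a binary predictor
#'
#' AUC-ROC is computed from the rank statistic with tie correction
#' (equivalent to the Mann-Whitney U divided by `n_pos * n_neg`, and to
#' trapezoidal integration of the ROC curve). The F-measure (harmonic mean
#' of precision and recall) is evaluated at the decision threshold
#' `score >= cutoff`.
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param labels Logical (or 0/1) true labels; both classes must be present
#'   for the AUC.
#' @param cutoff Decision threshold for the F-measure (default: predict
#'   positive when `score > 0`).
#' @return List: `auc`, `f_measure`, `precision`, `recall`, `n_pos`,
#'   `n_neg`.
#' @export
rank_metrics <- function(scores, labels, cutoff = 0) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)                    # midranks handle ties
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- scores > cutoff
  tp <- sum(pred & labels)
  precision <- if (sum(pred) > 0) tp / sum(pred) else 0
  recall <- tp / n_pos
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(auc = auc, f_measure = f, precision = precision, recall = recall,
       n_pos = n_pos, n_neg = n_neg)
}

#' Naive motif-count phase classifier
#'
#' For each phase, scores every gene by the number of that phase's assigned
#' motifs present in its promoter. The AUC uses this count as the ranking
#' score; the F-measure uses the literal rule "predict the phase for every
#' gene with >= 1 of its motifs present".
#'
#' @param presence Logical genes x motifs matrix.
#' @param assignment data.frame `motif_id`, `phase` (from
#'   [pcre_enrichment()]).
#' @param gene_phase Named vector of true phase labels for the genes.
#' @return data.frame, one row per phase with >= 1 assigned motif: `phase`,
#'   `n_motifs`, `auc`, `f_measure`, `n_pos`, `n_neg`.
#' @export
naive_phase_classifier <- function(presence, assignment, gene_phase) {
  genes <- intersect(rownames(presence), names(gene_phase))
  rows <- lapply(unique(assignment$phase), function(ph) {
    motifs <- assignment$motif_id[assignment$phase == ph]
    motifs <- intersect(motifs, colnames(presence))
    if (!length(motifs)) return(NULL)
    score <- rowSums(presence[genes, motifs, drop = FALSE])
    labels <- gene_phase[genes] == ph
    if (!any(labels) || all(labels)) return(NULL)
    m <- rank_metrics(score, labels, cutoff = 0)   # >= 1 motif -> positive
    data.frame(phase = ph, n_motifs = length(motifs), auc = m$auc,
               f_measure = m$f_measure, n_pos = m$n_pos, n_neg = m$n_neg)
  })
  do.call(rbind, rows)
}

# stratified fold assignment: 1..folds within each class, shuffled
stratified_folds <- function(labels, folds) {
  f <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Cross-validated linear max-margin phase classifier
#'
#' One-vs-rest linear SVM over binary motif-presence features, with a grid
#' search over the margin cost `C` and the negative:positive training ratio
#' `R`. `R` is implemented by downsampling negatives in each training fold
#' to `R` times the number of positives (folds whose negatives already
#' number fewer are used as-is). Folds are stratified; each parameter pair
#' is scored by the mean AUC of its held-out folds and the best pair is
#' refit on all data to obtain feature weights.
#'
#' @param features Numeric/logical genes x features matrix.
#' @param labels Logical vector (positives = the target phase/cluster).
#' @param C_grid,R_grid Parameter grids (defaults
#'   `c(0.01, 0.1, 0.5, 1, 1.5, 2)` and `c(0.25, 0.5, 1, 1.5, 2, 2.5, 3,
#'   3.5, 4)`).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment and downsampling).
#' @return List: `best_C`, `best_R`, `cv_auc` (best pair's mean held-out
#'   AUC), `cv_f_measure`, `grid` (data.frame C, R, auc, f_measure),
#'   `weights` (named vector from the final refit), `n_pos`, `n_neg`. When
#'   a class has fewer members than `folds`, the fold count is reduced with
#'   a warning.
#' @export
svm_phase_classifier <- function(features, labels,
                                 C_grid = c(0.01, 0.1, 0.5, 1, 1.5, 2),
                                 R_grid = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3,
                                            3.5, 4),
                                 folds = 10, seed = 1L) {
  set.seed(seed)
  labels <- as.logical(labels)
  X <- as.matrix(features) * 1
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (min(n_pos, n_neg) < 2) stop("need >= 2 examples of each class")
  if (min(n_pos, n_neg) < folds) {
    folds <- max(2L, min(n_pos, n_neg))
    warning(sprintf("class smaller than fold count; using %d folds", folds))
  }
  fold_id <- stratified_folds(labels, folds)
  # collinear duplicated features: flagged, weights split across copies
  collinear <- anyDuplicated(t(X)) > 0

  eval_pair <- function(C, R) {
    aucs <- fs <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold_id != k; te <- !tr
      pos <- which(tr & labels); neg <- which(tr & !labels)
      n_keep <- min(length(neg), max(1L, round(R * length(pos))))
      neg <- sample(neg)[seq_len(n_keep)]
      idx <- c(pos, neg)
      fit <- e1071::svm(X[idx, , drop = FALSE],
                        factor(labels[idx], c(TRUE, FALSE)),
                        kernel = "linear", cost = C, scale = FALSE)
      pred <- stats::predict(fit, X[te, , drop = FALSE],
                             decision.values = TRUE)
      dvm <- attr(pred, "decision.values")
      dv <- dvm[, 1]
      if (colnames(dvm)[1] == "FALSE/TRUE") dv <- -dv
      m <- rank_metrics(dv, labels[te], cutoff = 0)
      aucs[k] <- m$auc; fs[k] <- m$f_measure
    }
    c(auc = mean(aucs), f = mean(fs))
  }
  grid <- expand.grid(C = C_grid, R = R_grid)
  res <- t(apply(grid, 1, function(g) eval_pair(g[["C"]], g[["R"]])))
  grid$auc <- res[, "auc"]; grid$f_measure <- res[, "f"]
  best <- which.max(grid$auc)
  # final refit on all data at the best pair for feature weights
  pos <- which(labels); neg <- which(!labels)
  n_keep <- min(length(neg), max(1L, round(grid$R[best] * length(pos))))
  idx <- c(pos, sample(neg)[seq_len(n_keep)])
  fit <- e1071::svm(X[idx, , drop = FALSE],
                    factor(labels[idx], c(TRUE, FALSE)),
                    kernel = "linear", cost = grid$C[best], scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  dvm <- attr(stats::predict(fit, X[idx[1, drop = FALSE], , drop = FALSE],
                             decision.values = TRUE), "decision.values")
  if (colnames(dvm)[1] == "FALSE/TRUE") w <- -w  # orient: positive = TRUE
  list(best_C = grid$C[best], best_R = grid$R[best],
       cv_auc = grid$auc[best], cv_f_measure = grid$f_measure[best],
       grid = grid, weights = w, n_pos = n_pos, n_neg = n_neg,
       collinear_features = collinear, folds = folds)
}

#' Survey classifiability of gene clusters from motif features
#'
#' Runs [svm_phase_classifier()] for every cluster (positives = the
#' cluster's genes, negatives = the remaining genes in `universe`) and
#' counts the clusters whose cross-validated AUC exceeds `auc_threshold`,
#' with the fraction of the universe those clusters cover.
#'
#' @param clusters Named list of gene-id vectors (phase-expression or
#'   phase-function clusters).
#' @param features Genes x motifs presence matrix.
#' @param universe Gene ids forming the background (default: rownames of
#'   `features`).
#' @param auc_threshold AUC cutoff for "classifiable" (default 0.7).
#' @param min_positives Clusters with fewer members are skipped
#'   (default 8).
#' @param folds,seed Passed to [svm_phase_classifier()].
#' @param ... Further arguments (grids) passed on.
#' @return List: `survey` (data.frame: cluster, n, auc, f_measure, best_C,
#'   best_R, skipped, reason), `n_above`, `genes_above`,
#'   `coverage` (genes in above-threshold clusters / universe size).
#' @export
cluster_classification_survey <- function(clusters, features,
                                          universe = rownames(features),
                                          auc_threshold = 0.7,
                                          min_positives = 8, folds = 10,
                                          seed = 1L, ...) {
  rows <- list(); above_genes <- character(0)
  for (nm in names(clusters)) {
    members <- intersect(clusters[[nm]], universe)
    if (length(members) < min_positives) {
      rows[[nm]] <- data.frame(cluster = nm, n = length(members),
                               auc = NA_real_, f_measure = NA_real_,
                               best_C = NA_real_, best_R = NA_real_,
                               skipped = TRUE, reason = "below minimum size",
                               stringsAsFactors = FALSE)
      next
    }
    labels <- universe %in% members
    fit <- svm_phase_classifier(features[universe, , drop = FALSE], labels,
                                folds = folds, seed = seed, ...)
    rows[[nm]] <- data.frame(cluster = nm, n = length(members),
                             auc = fit$cv_auc, f_measure = fit$cv_f_measure,
                             best_C = fit$best_C, best_R = fit$best_R,
                             skipped = FALSE, reason = "",
                             stringsAsFactors = FALSE)
    if (fit$cv_auc > auc_threshold)
      above_genes <- union(above_genes, members)
  }
  survey <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(), n = integer(), auc = numeric(),
               f_measure = numeric(), best_C = numeric(), best_R = numeric(),
               skipped = logical(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(survey) <- NULL
  list(survey = survey,
       n_above = sum(!survey$skipped & survey$auc > auc_threshold),
       genes_above = length(above_genes),
       coverage = length(above_genes) / length(universe))
}
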