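#' Fisher-exact term enrichment with Benjamini-Hochberg correction
#'
#' Tests each annotation term for over- (or under-) representation in a
#' foreground gene set relative to a background, using the exact
#' hypergeometric test on the 2x2 table (foreground/background x
#' annotated/not), and adjusts the p-values across all tested terms with
#' the Benjamini-Hochberg step-up procedure.
#'
#' @param foreground Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of gene ids (the universe).
#' @param annotation data.frame with columns `gene_id`, `term_id`.
#' @param alternative "greater" (overrepresentation, default), "less", or
#'   "two.sided".
#' @param alpha Adjusted-p significance cutoff recorded in the `significant`
#'   column (default 0.05).
#' @return data.frame, one row per term with >= 1 annotated background gene:
#'   `term_id`, `fg_annotated`, `fg_total`, `bg_annotated`, `bg_total`,
#'   `odds_ratio` (sample OR of the 2x2 table), `p`, `p_adj`, `significant`.
#' @export
fisher_enrichment <- function(foreground, background, annotation,
                              alternative = c("greater", "less", "two.sided"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (!length(foreground)) stop("empty foreground")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  terms <- unique(annotation$term_id)
  fg <- unique(foreground); bg <- unique(background)
  n_fg <- length(fg); n_bg <- length(bg)
  rows <- lapply(terms, function(tm) {
    ann <- unique(annotation$gene_id[annotation$term_id == tm])
    a <- sum(ann %in% fg)             # foreground, annotated
    b <- n_fg - a                     # foreground, not annotated
    cc <- length(ann) - a             # rest of background, annotated
    d <- (n_bg - n_fg) - cc
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = alternative)
    or <- (a * d) / (b * cc)          # sample odds ratio (may be Inf/NaN)
    data.frame(term_id = tm, fg_annotated = a, fg_total = n_fg,
               bg_annotated = length(ann), bg_total = n_bg,
               odds_ratio = or, p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$p), ]
}

#' Per-phase enrichment of terms within cycling genes
#'
#' Runs [fisher_enrichment()] once per phase cluster (foreground = the
#' cluster's genes, background = all cycling genes, BH correction within
#' each phase's family of terms) and binds the results.
#'
#' @param gene_phase Named vector mapping cycling gene id to phase label.
#' @param annotation data.frame `gene_id`, `term_id`.
#' @param alternative Passed to [fisher_enrichment()].
#' @param alpha Significance cutoff.
#' @return data.frame of per-phase enrichment rows with an extra `phase`
#'   column.
#' @export
phase_enrichment <- function(gene_phase, annotation,
                             alternative = "greater", alpha = 0.05) {
  background <- names(gene_phase)
  phases <- sort(unique(unname(gene_phase)))
  out <- lapply(phases, function(ph) {
    fg <- names(gene_phase)[gene_phase == ph]
    res <- fisher_enrichment(fg, background, annotation, alternative, alpha)
    if (nrow(res)) cbind(phase = ph, res) else NULL
  })
  do.call(rbind, out)
}

#' Phase-specificity summary of enriched terms
#'
#' Counts, for every term, in how many phases it is significantly enriched
#' and whether multi-phase enrichments are confined to circularly adjacent
#' ZT bins (e.g. ZT 21 and ZT 0 are adjacent on a 24-h day).
#'
#' @param enrichment Output of [phase_enrichment()] (needs `phase`,
#'   `term_id`, `significant`).
#' @param layout A [sampling_layout()] defining the phase ring.
#' @return data.frame: `term_id`, `n_phases_enriched`, `phases`
#'   (comma-separated), `adjacent_only` (NA for terms enriched in < 2
#'   phases).
#' @export
phase_specificity_summary <- function(enrichment,
                                      layout = sampling_layout()) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  bins <- zt_bins(layout)
  D <- layout$day_length_hours
  iv <- layout$interval_hours
  terms <- unique(enrichment$term_id)
  rows <- lapply(terms, function(tm) {
    ph <- sort(as.numeric(sig$phase[sig$term_id == tm]))
    adj <- NA
    if (length(ph) >= 2) {
      # adjacent iff all enriched phases fit in a circular window spanning
      # (n_enriched - 1) sampling intervals
      gaps <- diff(c(ph, ph[1] + D))
      adj <- (D - max(gaps)) <= (length(ph) - 1) * iv
    }
    data.frame(term_id = tm, n_phases_enriched = length(ph),
               phases = paste(ph, collapse = ","), adjacent_only = adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate per-phase enrichment into functional groups
#'
#' Averages the -log10 raw enrichment p-values of a group's terms in each
#' phase, producing the group x phase matrix used to display broad
#' functional programs across the day.
#'
#' @param term_group data.frame with columns `term_id`, `group`.
#' @param enrichment Output of [phase_enrichment()].
#' @return Numeric matrix, groups x phases, of mean `-log10(p)`.
#' @export
functional_group_aggregate <- function(term_group, enrichment) {
  phases <- sort(unique(as.numeric(enrichment$phase)))
  groups <- unique(term_group$group)
  m <- matrix(NA_real_, length(groups), length(phases),
              dimnames = list(groups, as.character(phases)))
  for (g in groups) {
    terms <- term_group$term_id[term_group$group == g]
    sub <- enrichment[enrichment$term_id %in% terms, , drop = FALSE]
    if (!nrow(sub)) stop(sprintf("group '%s' has no tested terms", g))
    if (!all(terms %in% sub$term_id))
      stop(sprintf("group '%s': some terms untested", g))
    for (ph in phases) {
      pv <- sub$p[as.numeric(sub$phase) == ph]
      m[g, as.character(ph)] <- mean(-log10(pv))
    }
  }
  m
}
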