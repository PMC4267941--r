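#' Read and write expression matrices as TSV
#'
#' The expression TSV has a `gene_id` column and one column per sample,
#' headers encoding Zeitgeber time and day as `ZT<h>_day<d>`. On reading,
#' genes with any missing value are dropped (with a warning reporting the
#' count) and negative values are clamped to zero; the sampling layout is
#' reconstructed from the headers.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: list with `expression` (matrix) and
#'   `layout` (a [sampling_layout()]).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("malformed header: expected gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
  hdr <- names(df)[-1]
  m <- regmatches(hdr, regexec("^ZT([0-9.]+)_day([0-9]+)$", hdr))
  if (any(lengths(m) != 3)) stop("malformed sample headers")
  zt <- as.numeric(vapply(m, `[`, "", 2))
  day <- as.integer(vapply(m, `[`, "", 3))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  miss <- rowSums(is.na(mat)) > 0
  if (any(miss)) {
    warning(sprintf("%d gene(s) with missing values dropped", sum(miss)))
    mat <- mat[!miss, , drop = FALSE]
  }
  mat[mat < 0] <- 0
  ppd <- length(unique(zt))
  iv <- if (ppd > 1) diff(sort(unique(zt)))[1] else 24
  layout <- sampling_layout(interval_hours = iv,
                            day_length_hours = iv * ppd,
                            n_days = length(unique(day)))
  ord <- order(day, zt)
  list(expression = mat[, ord, drop = FALSE], layout = layout)
}

#' @rdname read_expression_tsv
#' @param expr Genes x samples matrix with `ZT<h>_day<d>` column names.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Standard writer for fits, cluster assignments, enrichment tables and
#' pair tables.
#'
#' @param df A data.frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Default pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one named list that
#' can be serialized to YAML next to the outputs.
#'
#' @param seed Global integer seed.
#' @return Named list of settings.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    layout = list(interval_hours = 3, day_length_hours = 24, n_days = 2,
                  light_hours = 12),
    simulate = list(n_cycling = 400, n_flat = 600, amplitude_ratio = 0.5,
                    noise_cv = 0.1),
    detect = list(top_pct = 2, n_permutations = 2000, overlap = NULL),
    cluster = list(size_min = 10, size_max = 90, target_size = 60,
                   n_restarts = 10),
    enrich = list(alpha = 0.05),
    duplicates = list(bin_width = 0.3, alpha = 0.5, n_resamples = 10000),
    motifs = list(p_value = 1e-05, pseudocount = 0.01,
                  merge_threshold = 0.25),
    classify = list(C_grid = c(0.01, 0.1, 0.5, 1, 1.5, 2),
                    R_grid = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
                    folds = 10, auc_threshold = 0.7, min_positives = 8))
}

#' Run the core pipeline on an expression matrix
#'
#' Executes the main stages in order — upper-quartile normalization,
#' rhythm detection, phase clustering with k-means subclusters, and (when
#' an annotation is supplied) per-phase functional enrichment — writing
#' each output table under `out_dir` together with the serialized
#' configuration and a JSON run manifest.
#'
#' @param expr Genes x samples matrix.
#' @param layout A [sampling_layout()].
#' @param config A configuration list (see [default_config()]).
#' @param annotation Optional data.frame `gene_id`, `term_id`.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return List: `fits`, `threshold`, `subclusters`, `enrichment` (NULL
#'   without annotation), `manifest`.
#' @export
run_pipeline <- function(expr, layout = sampling_layout(),
                         config = default_config(), annotation = NULL,
                         out_dir = NULL) {
  expr <- upper_quartile_normalize(expr)
  det <- detect_cycling(expr, layout,
                        top_pct = config$detect$top_pct,
                        n_permutations = config$detect$n_permutations,
                        overlap = config$detect$overlap,
                        seed = config$seed)
  fits <- det$fits
  cyc <- fits[fits$is_cycling, ]
  sub <- lapply(split(cyc$gene_id, cyc$phase_cluster), function(g) {
    two_round_kmeans(expr[g, , drop = FALSE],
                     size_min = config$cluster$size_min,
                     size_max = config$cluster$size_max,
                     target_size = config$cluster$target_size,
                     n_restarts = config$cluster$n_restarts,
                     seed = config$seed)
  })
  subclusters <- do.call(rbind, lapply(names(sub), function(ph)
    data.frame(gene_id = sub[[ph]]$gene_id, phase_cluster = as.numeric(ph),
               subcluster = sub[[ph]]$subcluster,
               stringsAsFactors = FALSE)))
  enr <- NULL
  if (!is.null(annotation)) {
    gp <- stats::setNames(cyc$phase_cluster, cyc$gene_id)
    enr <- phase_enrichment(gp, annotation, alpha = config$enrich$alpha)
  }
  manifest <- list(package = "dielcycle",
                   version = as.character(utils::packageVersion("dielcycle")),
                   seed = config$seed,
                   threshold = det$threshold,
                   n_genes = nrow(expr),
                   n_cycling = sum(fits$is_cycling),
                   stages = c("normalize", "detect", "cluster",
                              if (!is.null(enr)) "enrich"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(fits, file.path(out_dir, "fits.tsv"))
    write_tsv(subclusters, file.path(out_dir, "subclusters.tsv"))
    if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(fits = fits, threshold = det$threshold, subclusters = subclusters,
       enrichment = enr, manifest = manifest)
}
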