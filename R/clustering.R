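#' Min-max normalize an expression profile
#'
#' Maps a gene's expression row onto [0, 1] so profiles of different
#' absolute level are comparable (the convention used for display heatmaps
#' and for clustering). A constant row, whose shape is undefined, is mapped
#' to an all-0.5 profile and flagged via the `"constant"` attribute.
#'
#' @param x Numeric vector.
#' @return Normalized vector in [0, 1]; attribute `constant` is TRUE for a
#'   degenerate row.
#' @export
normalize_profile <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    out <- rep(0.5, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (x - r[1]) / (r[2] - r[1])
  attr(out, "constant") <- FALSE
  out
}

#' Two-round k-means subclustering of a phase cluster
#'
#' Splits the min-max-normalized profiles of one phase cluster into
#' expression subclusters: round 1 runs Lloyd k-means with
#' `k = ceiling(n / target_size)`; any cluster larger than `size_max` is
#' re-clustered once (round 2) with `k = ceiling(size / target_size)`;
#' clusters smaller than `size_min` are merged into the nearest remaining
#' centroid (Euclidean distance).
#'
#' @param profiles Numeric matrix, genes x samples (rownames = gene ids);
#'   rows are min-max normalized internally.
#' @param size_min,size_max Target bounds on final cluster sizes
#'   (default 10 and 90).
#' @param target_size Average size aimed for when choosing k (default 60).
#' @param n_restarts Random restarts per k-means run (best by total
#'   within-cluster sum of squares).
#' @param seed Integer seed.
#' @return data.frame: `gene_id`, `subcluster` (integer label). Attribute
#'   `centroids`: matrix of cluster mean profiles. If fewer than `size_min`
#'   genes are supplied a single cluster is returned with a warning.
#' @export
two_round_kmeans <- function(profiles, size_min = 10, size_max = 90,
                             target_size = 60, n_restarts = 10, seed = 1L) {
  set.seed(seed)
  norm <- t(apply(profiles, 1, function(r) as.numeric(normalize_profile(r))))
  rownames(norm) <- rownames(profiles)
  n <- nrow(norm)
  if (n < size_min) {
    warning("fewer genes than size_min; returning a single cluster")
    out <- data.frame(gene_id = rownames(norm), subcluster = 1L,
                      stringsAsFactors = FALSE)
    attr(out, "centroids") <- matrix(colMeans(norm), 1)
    return(out)
  }
  run_km <- function(m, k) {
    k <- min(k, nrow(unique(m)))
    if (k <= 1) return(rep(1L, nrow(m)))
    stats::kmeans(m, centers = k, iter.max = 100, nstart = n_restarts,
                  algorithm = "Lloyd")$cluster
  }
  assign1 <- run_km(norm, ceiling(n / target_size))
  # round 2: re-cluster oversized clusters once
  labels <- character(n)
  for (cl in unique(assign1)) {
    idx <- which(assign1 == cl)
    if (length(idx) > size_max) {
      sub <- run_km(norm[idx, , drop = FALSE],
                    ceiling(length(idx) / target_size))
      labels[idx] <- paste(cl, sub, sep = ".")
    } else labels[idx] <- as.character(cl)
  }
  # merge undersized clusters into nearest centroid among the rest
  repeat {
    sizes <- table(labels)
    centroids <- do.call(rbind, lapply(names(sizes), function(l)
      colMeans(norm[labels == l, , drop = FALSE])))
    rownames(centroids) <- names(sizes)
    small <- names(sizes)[sizes < size_min]
    if (!length(small) || length(sizes) == 1) break
    l <- small[which.min(sizes[small])]
    others <- setdiff(names(sizes), l)
    d <- vapply(others, function(o)
      sum((centroids[l, ] - centroids[o, ])^2), numeric(1))
    labels[labels == l] <- others[which.min(d)]
  }
  final <- as.integer(factor(labels, levels = unique(labels)))
  out <- data.frame(gene_id = rownames(norm), subcluster = final,
                    stringsAsFactors = FALSE)
  centroids <- do.call(rbind, lapply(sort(unique(final)), function(l)
    colMeans(norm[final == l, , drop = FALSE])))
  attr(out, "centroids") <- centroids
  out
}

#' Hierarchical display ordering of expression profiles
#'
#' Average-linkage (UPGMA) hierarchical clustering on Euclidean distances of
#' min-max-normalized profiles, returning the leaf order for heatmap
#' display. When all profiles are identical (all distances zero) the input
#' order is kept.
#'
#' @param profiles Numeric matrix, genes x samples.
#' @return Integer permutation of row indices.
#' @export
hierarchical_order <- function(profiles) {
  n <- nrow(profiles)
  if (n < 2) return(seq_len(n))
  norm <- t(apply(profiles, 1, function(r) as.numeric(normalize_profile(r))))
  d <- stats::dist(norm)
  if (all(d == 0)) return(seq_len(n))
  stats::hclust(d, method = "average")$order
}
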