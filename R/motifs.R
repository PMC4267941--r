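BASES <- c("A", "C", "G", "T")

# validate a 4 x L probability matrix (rows A,C,G,T; columns sum to 1)
check_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4)
    stop("PWM must be a 4 x L matrix (rows A, C, G, T)")
  if (is.null(rownames(pwm))) rownames(pwm) <- BASES
  if (!identical(rownames(pwm), BASES)) stop("PWM rows must be A, C, G, T")
  if (any(pwm < 0) || any(abs(colSums(pwm) - 1) > 1e-6))
    stop("PWM columns must be probabilities summing to 1")
  invisible(pwm)
}

#' Consensus sequence of a PWM
#'
#' @param pwm 4 x L probability matrix (rows A, C, G, T).
#' @return Character string of per-column argmax bases (ties to the first
#'   base in A, C, G, T order).
#' @export
pwm_consensus <- function(pwm) {
  check_pwm(pwm)
  paste(BASES[apply(pwm, 2, which.max)], collapse = "")
}

#' Build a PWM from a consensus sequence
#'
#' @param consensus DNA string over A, C, G, T.
#' @param strength Probability mass on the consensus base per column
#'   (default 0.9; the rest is split evenly).
#' @return 4 x nchar(consensus) probability matrix.
#' @export
pwm_from_consensus <- function(consensus, strength = 0.9) {
  ch <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(ch %in% BASES), strength > 0.25, strength <= 1)
  L <- length(ch)
  m <- matrix((1 - strength) / 3, 4, L, dimnames = list(BASES, NULL))
  for (j in seq_len(L)) m[ch[j], j] <- strength
  m
}

#' Read / write motifs in MEME minimal format
#'
#' A plain-text exchange format: a `MEME version 4` header, an `ALPHABET=
#' ACGT` line, and per motif a `MOTIF <id>` line followed by a
#' `letter-probability matrix:` block with one line per position (columns
#' A, C, G, T).
#'
#' @param path File path.
#' @return `read_meme_motifs()`: named list of 4 x L probability matrices.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\b", lines)
  if (!length(idx)) stop("no MOTIF records found")
  out <- list()
  for (i in seq_along(idx)) {
    id <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines)
    hdr <- hdr[hdr > idx[i]][1]
    end <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
    block <- lines[(hdr + 1):end]
    block <- block[grepl("^\\s*[0-9.eE+-]", block)]
    m <- t(vapply(block, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4)))
    pwm <- t(m)
    rownames(pwm) <- BASES
    out[[id]] <- check_pwm(pwm / rep(colSums(pwm), each = 4))
  }
  out
}

#' @rdname read_meme_motifs
#' @param motifs Named list of PWMs.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (id in names(motifs)) {
    pwm <- check_pwm(motifs[[id]])
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(pwm)), con)
    writeLines(apply(pwm, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# log-odds score matrix of a PWM against a 0-order background,
# with pseudocounts added to the probabilities
pwm_logodds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  check_pwm(pwm)
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-6)
  p <- pwm + pseudocount
  p <- p / rep(colSums(p), each = 4)
  log2(p / background)
}

#' Exact PWM score threshold for a target p-value
#'
#' Computes the exact distribution of the PWM log-odds score of a random
#' L-mer drawn from a 0-order background, by dynamic programming over
#' discretized scores (granularity `granularity` on the log-odds scale),
#' and returns the smallest score whose upper-tail probability is <= `p`.
#'
#' @param pwm 4 x L probability matrix.
#' @param background Base frequencies (A, C, G, T), positive, summing to 1.
#' @param p Target per-site p-value (default 1e-05).
#' @param pseudocount Added to PWM probabilities before log-odds
#'   (default 0.01).
#' @param granularity Score discretization step (default 1e-3); the returned
#'   threshold is accurate to `L * granularity`.
#' @return List: `threshold` (log-odds score), `attained_p` (exact tail
#'   probability at the threshold), `max_score`. Errors when even the
#'   best-scoring L-mer has background probability > `p` ("unattainable p").
#' @export
pwm_pvalue_threshold <- function(pwm, background = rep(0.25, 4), p = 1e-05,
                                 pseudocount = 0.01, granularity = 1e-3) {
  lo <- pwm_logodds(pwm, background, pseudocount)
  S <- round(lo / granularity)              # integer scores per (base, pos)
  L <- ncol(S)
  # min attainable tail = P(best L-mer); check feasibility first
  best <- prod(background[apply(S, 2, which.max)])
  if (best > p)
    stop(sprintf("unattainable p: best single site has probability %.3g > %.3g",
                 best, p))
  offset <- sum(apply(S, 2, min))           # shift so indices start at 1
  width <- sum(apply(S, 2, max)) - offset + 1L
  dist <- numeric(width); dist[1] <- 1      # score distribution, shifted
  reach <- 1L
  for (j in seq_len(L)) {
    nxt <- numeric(width)
    sj <- S[, j] - min(S[, j])
    for (b in 1:4) {
      idx <- seq_len(reach) + sj[b]
      nxt[idx] <- nxt[idx] + dist[seq_len(reach)] * background[b]
    }
    reach <- reach + max(sj)
    dist <- nxt
  }
  tail <- rev(cumsum(rev(dist)))
  i <- which(tail <= p)[1]
  list(threshold = (i - 1 + offset) * granularity,
       attained_p = tail[i],
       max_score = (width - 1 + offset) * granularity,
       score_distribution = dist,
       score_values = (seq_len(width) - 1 + offset) * granularity)
}

# integer-encode a DNA string (A=1..T=4; other letters NA)
dna_to_int <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], BASES)
}

# best log-odds window score on one strand; -Inf when shorter than motif
scan_strand <- function(ints, lo) {
  L <- ncol(lo)
  n <- length(ints) - L + 1
  if (n < 1) return(list(best = -Inf, scores = numeric(0)))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[, j][ints[j:(j + n - 1)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  list(best = max(sc), scores = sc)
}

#' Scan promoters for motif occurrences
#'
#' Scores every window of every promoter on both strands with each motif's
#' log-odds matrix and records presence when at least one window meets the
#' motif's exact p-value threshold ([pwm_pvalue_threshold()]).
#'
#' @param motifs Named list of PWMs.
#' @param promoters Named [Biostrings::DNAStringSet] (or named character
#'   vector) of promoter sequences.
#' @param background 0-order base frequencies; `NULL` (default) estimates
#'   them from the promoter set being scanned.
#' @param p Per-site p-value threshold (default 1e-05).
#' @param pseudocount PWM pseudocount.
#' @return List: `presence` (logical genes x motifs matrix), `hits`
#'   (data.frame: `gene_id`, `motif_id`, `start`, `strand`, `score`),
#'   `thresholds` (named numeric).
#' @export
scan_promoters <- function(motifs, promoters, background = NULL, p = 1e-05,
                           pseudocount = 0.01) {
  seqs <- stats::setNames(as.character(promoters), names(promoters))
  if (is.null(names(seqs))) stop("promoters must be named")
  if (is.null(background)) {
    counts <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(seqs))[, BASES, drop = FALSE])
    background <- counts / sum(counts)
  }
  fwd <- lapply(seqs, dna_to_int)
  rev_ <- lapply(seqs, function(s) dna_to_int(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  presence <- matrix(FALSE, length(seqs), length(motifs),
                     dimnames = list(names(seqs), names(motifs)))
  thresholds <- numeric(length(motifs)); names(thresholds) <- names(motifs)
  hits <- list()
  for (m in names(motifs)) {
    lo <- pwm_logodds(motifs[[m]], background, pseudocount)
    thr <- pwm_pvalue_threshold(motifs[[m]], background, p,
                                pseudocount)$threshold
    thresholds[m] <- thr
    L <- ncol(lo)
    for (g in names(seqs)) {
      n_seq <- length(fwd[[g]])
      for (strand in c("+", "-")) {
        ints <- if (strand == "+") fwd[[g]] else rev_[[g]]
        res <- scan_strand(ints, lo)
        ok <- which(res$scores >= thr)
        if (length(ok)) {
          presence[g, m] <- TRUE
          start <- if (strand == "+") ok else n_seq - L + 2 - ok
          hits[[length(hits) + 1]] <- data.frame(
            gene_id = g, motif_id = m, start = start, strand = strand,
            score = res$scores[ok], stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(), motif_id = character(),
               start = integer(), strand = character(), score = numeric(),
               stringsAsFactors = FALSE)
  list(presence = presence, hits = hits, thresholds = thresholds,
       background = background)
}

# best-offset alignment similarity of two PWMs: mean Pearson correlation of
# aligned columns, maximized over offsets with >= min_overlap columns
pwm_similarity <- function(a, b, min_overlap = 4) {
  La <- ncol(a); Lb <- ncol(b)
  best <- NA_real_; best_offset <- 0L
  for (off in (-(Lb - min_overlap)):(La - min_overlap)) {
    ia <- max(1, 1 + off):min(La, Lb + off)
    ib <- ia - off
    if (length(ia) < min_overlap) next
    cc <- vapply(seq_along(ia), function(j) {
      x <- a[, ia[j]]; y <- b[, ib[j]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      stats::cor(x, y)
    }, numeric(1))
    m <- mean(cc)
    if (is.na(best) || m > best) { best <- m; best_offset <- off }
  }
  list(similarity = if (is.na(best)) -1 else best, offset = best_offset)
}

#' Merge redundant motifs by UPGMA
#'
#' Builds a UPGMA (average-linkage) tree on pairwise motif distances
#' `1 - best-offset mean column Pearson correlation`, cuts it at
#' `merge_threshold`, and replaces each group by the position-wise average
#' PWM at the best alignment offsets (non-overlapping flanks padded with
#' the uniform distribution). Motif pairs with no alignment of at least
#' `min_overlap` columns get distance 1.
#'
#' @param motifs Named list of PWMs (>= 1).
#' @param merge_threshold Tree cut height (distance; default 0.25, i.e.
#'   motifs with mean column PCC >= 0.75 merge).
#' @param min_overlap Minimum aligned columns (default 4).
#' @return Named list of merged PWMs; names concatenate member ids with
#'   `"+"`. Attribute `groups` records the membership.
#' @export
merge_motifs_upgma <- function(motifs, merge_threshold = 0.25,
                               min_overlap = 4) {
  n <- length(motifs)
  if (n < 2) return(motifs)
  ids <- names(motifs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  off <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sim <- pwm_similarity(motifs[[i]], motifs[[j]], min_overlap)
    d[i, j] <- d[j, i] <- max(0, 1 - sim$similarity)
    off[i, j] <- sim$offset; off[j, i] <- -sim$offset
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(tree, h = merge_threshold)
  out <- list(); groups <- list()
  for (g in sort(unique(grp))) {
    members <- ids[grp == g]
    if (length(members) == 1) {
      merged <- motifs[[members]]
    } else {
      # align every member to the first by its pairwise best offset
      seed <- members[1]
      offs <- vapply(members, function(m)
        if (m == seed) 0L else off[seed, m], integer(1))
      lo_pos <- min(1 + offs)
      hi_pos <- max(vapply(members, function(m) ncol(motifs[[m]]),
                           integer(1)) + offs)
      width <- hi_pos - lo_pos + 1
      acc <- matrix(0, 4, width); cnt <- numeric(width)
      for (m in members) {
        cols <- seq_len(ncol(motifs[[m]])) + offs[[m]] - lo_pos + 1
        acc[, cols] <- acc[, cols] + motifs[[m]]
        cnt[cols] <- cnt[cols] + 1
      }
      pad <- cnt == 0
      merged <- sweep(acc, 2, pmax(cnt, 1), "/")
      merged[, pad] <- 0.25
      rownames(merged) <- BASES
    }
    nm <- paste(members, collapse = "+")
    out[[nm]] <- merged
    groups[[nm]] <- members
  }
  attr(out, "groups") <- groups
  out
}

#' Assign motifs to phases by enrichment
#'
#' Tests each motif's presence for overrepresentation in the promoters of
#' each phase cluster against all cycling genes with promoters (Fisher
#' exact + BH within phase, via [fisher_enrichment()]), and assigns each
#' significantly enriched motif to the phase where its adjusted p is
#' smallest (ties to the earlier ZT).
#'
#' @param presence Logical genes x motifs matrix from [scan_promoters()].
#' @param gene_phase Named vector mapping gene id to phase label (the
#'   cycling genes; the background is all of them).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return List: `enrichment` (long data.frame: phase, motif rows as
#'   term_id, counts, p, p_adj, significant), `assignment` (data.frame
#'   `motif_id`, `phase`, `p_adj` for motifs significant somewhere).
#' @export
pcre_enrichment <- function(presence, gene_phase, alpha = 0.05) {
  genes <- intersect(rownames(presence), names(gene_phase))
  if (!length(genes)) stop("no overlap between presence matrix and phases")
  if (any(colSums(presence[genes, , drop = FALSE]) == 0))
    warning("some motifs present in zero promoters")
  ann <- do.call(rbind, lapply(colnames(presence), function(m) {
    hit <- genes[presence[genes, m]]
    if (!length(hit)) return(NULL)
    data.frame(gene_id = hit, term_id = m, stringsAsFactors = FALSE)
  }))
  enr <- phase_enrichment(gene_phase[genes], ann, alternative = "greater",
                          alpha = alpha)
  sig <- enr[enr$significant, , drop = FALSE]
  assignment <- NULL
  if (nrow(sig)) {
    sig <- sig[order(sig$term_id, sig$p_adj, as.numeric(sig$phase)), ]
    assignment <- sig[!duplicated(sig$term_id),
                      c("term_id", "phase", "p_adj")]
    names(assignment)[1] <- "motif_id"
    rownames(assignment) <- NULL
  } else {
    assignment <- data.frame(motif_id = character(), phase = numeric(),
                             p_adj = numeric(), stringsAsFactors = FALSE)
  }
  list(enrichment = enr, assignment = assignment)
}
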