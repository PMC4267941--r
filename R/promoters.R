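#' Extract promoter sequences from a genome and gene models
#'
#' The promoter of a gene is the region up to `length` bp immediately
#' upstream of its transcription start site (the 5' end of the gene on its
#' strand), less any bases that overlap another annotated gene body: the
#' interval is truncated at the nearest overlapping gene on the TSS side.
#' Minus-strand promoters are reverse-complemented so that all returned
#' sequences read 5' to 3' toward the TSS. Promoters shorter than
#' `min_length` after truncation (including genes at a contig edge) are
#' dropped with a warning.
#'
#' @param gff Path to a GFF3 file, or a [GenomicRanges::GRanges] of gene
#'   features (needs an ID; `type == "gene"` rows are used from a file).
#' @param genome Path to a genome FASTA, or a named
#'   [Biostrings::DNAStringSet].
#' @param length Maximum promoter length in bp (default 1000).
#' @param min_length Minimum kept length (default 50).
#' @return Named [Biostrings::DNAStringSet] of promoter sequences. Attribute
#'   `intervals`: data.frame of the extracted genomic windows (`gene_id`,
#'   `seqnames`, `start`, `end` 1-based inclusive, `strand`).
#' @export
extract_promoters <- function(gff, genome, length = 1000, min_length = 50) {
  genes <- if (is.character(gff)) {
    gr <- rtracklayer::import(gff)
    gr[gr$type == "gene"]
  } else gff
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  ids <- if (!is.null(genes$ID)) genes$ID else names(genes)
  if (is.null(ids)) stop("gene models carry no ID")
  if (anyDuplicated(ids)) stop("duplicate gene IDs")
  if (!all(as.character(GenomicRanges::seqnames(genes)) %in% names(genome)))
    stop("missing contig in genome FASTA")

  st <- as.character(GenomicRanges::strand(genes))
  gstart <- GenomicRanges::start(genes); gend <- GenomicRanges::end(genes)
  chr <- as.character(GenomicRanges::seqnames(genes))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))

  keep <- character(0); seqs <- character(0); iv <- list()
  for (i in seq_along(genes)) {
    if (st[i] == "+") {
      e <- gstart[i] - 1L
      s <- max(1L, gstart[i] - length)
    } else {
      s <- gend[i] + 1L
      e <- min(clen[[chr[i]]], gend[i] + length)
    }
    if (e < s) next
    # truncate at overlapping gene bodies (any other gene)
    others <- which(chr == chr[i] & seq_along(genes) != i &
                      gend >= s & gstart <= e)
    for (j in others) {
      if (st[i] == "+") s <- max(s, gend[j] + 1L)
      else e <- min(e, gstart[j] - 1L)
    }
    w <- e - s + 1L
    if (w < min_length) next
    sq <- Biostrings::subseq(genome[[chr[i]]], s, e)
    if (st[i] == "-") sq <- Biostrings::reverseComplement(sq)
    keep <- c(keep, ids[i]); seqs <- c(seqs, as.character(sq))
    iv[[base::length(iv) + 1]] <- data.frame(
      gene_id = ids[i], seqnames = chr[i], start = s, end = e,
      strand = st[i], stringsAsFactors = FALSE)
  }
  n_dropped <- base::length(genes) - base::length(keep)
  if (n_dropped > 0)
    warning(sprintf("%d promoter(s) shorter than %d bp dropped",
                    n_dropped, min_length))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- keep
  attr(out, "intervals") <- if (base::length(iv)) do.call(rbind, iv) else
    data.frame(gene_id = character(), seqnames = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  out
}
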