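test_that("MEME-minimal motifs round-trip through write and read", {
  motifs <- list(m1 = toy_pwm(), m2 = pwm_from_consensus("TTGACG", 0.95))
  path <- tempfile(fileext = ".meme")
  write_meme_motifs(motifs, path)
  back <- read_meme_motifs(path)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(back$m1, toy_pwm(), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("PWM p-value DP matches exhaustive enumeration", {
  for (pwm in list(toy_pwm(), pwm_from_consensus("ACGTACG", 0.7))) {
    L <- ncol(pwm)
    bg <- c(0.2, 0.3, 0.3, 0.2)
    lo <- log2((pwm + 0.01) / rep(colSums(pwm + 0.01), each = 4) / bg)
    # enumerate all 4^L words at the DP's score discretization: the DP tail
    # must match these exhaustive tail sums exactly
    S <- round(lo / 1e-3)
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    scores <- rowSums(matrix(S[cbind(as.vector(words),
                                     rep(seq_len(L), each = nrow(words)))],
                             nrow(words)))
    probs <- apply(words, 1, function(w) prod(bg[w]))
    for (p_target in c(1e-2, 1e-3)) {
      got <- pwm_pvalue_threshold(pwm, bg, p = p_target)
      thr_int <- round(got$threshold / 1e-3)
      exact_tail <- sum(probs[scores >= thr_int])
      expect_equal(exact_tail, got$attained_p, tolerance = 1e-12)
      expect_lte(exact_tail, p_target)
      # one granularity step lower would exceed the target
      expect_gt(sum(probs[scores >= thr_int - 1]), p_target)
    }
  }
})

test_that("unattainably small p-values raise an error", {
  pwm <- pwm_from_consensus("ACGT", 0.97)
  # best 4-mer has background probability (1/4)^4 ~ 3.9e-3 > 1e-5
  expect_error(pwm_pvalue_threshold(pwm, p = 1e-5), "unattainable")
})

test_that("near-consensus PWM at its minimum attainable p matches only the consensus", {
  pwm <- pwm_from_consensus("ACGTAC", 0.97)
  res <- pwm_pvalue_threshold(pwm, p = (1 / 4)^6 * 1.01)
  # only the consensus word clears the threshold
  lo <- log2((pwm + 0.01) / rep(colSums(pwm + 0.01), each = 4) / 0.25)
  words <- as.matrix(expand.grid(rep(list(1:4), 6)))
  scores <- rowSums(matrix(lo[cbind(as.vector(words),
                                    rep(1:6, each = nrow(words)))],
                           nrow(words)))
  expect_equal(sum(scores >= res$threshold - 1e-6), 1)
  scan <- scan_promoters(list(m = pwm),
                         c(hit = "TTTACGTACTTT", miss = "TTTACGAACTTT"),
                         background = rep(0.25, 4), p = (1 / 4)^6 * 1.01)
  expect_true(scan$presence["hit", "m"])
  expect_false(scan$presence["miss", "m"])
})

test_that("scanning is strand-symmetric and reports planted sites", {
  set.seed(70)
  pr <- generate_promoters(sprintf("g%d", 1:6),
                           setNames(rep("0", 6), sprintf("g%d", 1:6)),
                           list("0" = list(pwm = toy_pwm(),
                                           plant_frequency = 1)),
                           length = 200, seed = 71)
  scan <- scan_promoters(list(m = toy_pwm()), pr$sequences,
                         background = rep(0.25, 4), p = 1e-3)
  expect_true(all(scan$presence[, "m"]))
  # reverse-complemented promoters give identical presence
  rc <- Biostrings::reverseComplement(pr$sequences)
  names(rc) <- names(pr$sequences)
  scan_rc <- scan_promoters(list(m = toy_pwm()), rc,
                            background = rep(0.25, 4), p = 1e-3)
  expect_equal(scan$presence, scan_rc$presence)
  # promoter shorter than the motif is absent by definition
  short <- scan_promoters(list(m = toy_pwm()), c(s = "ACG"),
                          background = rep(0.25, 4), p = 1e-3)
  expect_false(short$presence["s", "m"])
})

test_that("background hit rate is near the nominal per-site p-value", {
  set.seed(72)
  n <- 150; len <- 400
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("r%03d", seq_len(n))
  p <- 1e-3
  scan <- scan_promoters(list(m = toy_pwm()), seqs,
                         background = rep(0.25, 4), p = p)
  L <- ncol(toy_pwm())
  attained <- pwm_pvalue_threshold(toy_pwm(), rep(0.25, 4), p)$attained_p
  expected <- 2 * (len - L + 1) * n * attained
  observed <- nrow(scan$hits)
  # Poisson 99.5% bounds around the expected count
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 3)
})

test_that("identical motifs merge and dissimilar motifs are retained", {
  m1 <- toy_pwm()
  merged <- merge_motifs_upgma(list(a = m1, b = m1))
  expect_equal(length(merged), 1)
  expect_equal(merged[[1]], m1, ignore_attr = TRUE)
  m2 <- pwm_from_consensus("GGGGGG", 0.9)
  kept <- merge_motifs_upgma(list(a = m1, b = m2))
  expect_equal(length(kept), 2)
  # three-motif set: two near-identical merge, the outlier stays
  m1b <- m1; m1b[, 1] <- c(0.7, 0.1, 0.1, 0.1)
  res <- merge_motifs_upgma(list(a = m1, b = m1b, c = m2))
  expect_equal(length(res), 2)
  groups <- attr(res, "groups")
  expect_setequal(groups[[which(lengths(groups) == 2)]], c("a", "b"))
})

test_that("promoters are extracted with truncation, strand and edge handling", {
  # contig of 6000 bp with a plus-strand gene at 5001..5500 and a
  # neighbour at 4001..4600; promoter = 1-kb upstream truncated at 4601
  set.seed(73)
  contig <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", contig), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t5001\t5500\t.\t+\t.\tID=geneA",
               "chr1\ttest\tgene\t4001\t4600\t.\t+\t.\tID=geneB"), gff)
  pr <- extract_promoters(gff, fa)
  iv <- attr(pr, "intervals")
  a <- iv[iv$gene_id == "geneA", ]
  expect_equal(c(a$start, a$end), c(4601, 5000))
  expect_equal(nchar(as.character(pr[["geneA"]])), 400)
  expect_equal(as.character(pr[["geneA"]]), substr(contig, 4601, 5000))
})

test_that("minus-strand promoters are reverse-complemented and short ones dropped", {
  contig <- "ACGTACGTACGTACGTACGA"
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c", contig), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tt\tgene\t1\t8\t.\t-\t.\tID=gm"), gff)
  pr <- extract_promoters(gff, fa, length = 10, min_length = 5)
  # upstream of a minus-strand gene ending at 8: bases 9..18, then RC
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 9, 18))))
  expect_equal(as.character(pr[["gm"]]), expected)
  # TSS at the contig start on + strand leaves no promoter: dropped
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tt\tgene\t1\t8\t.\t+\t.\tID=gp"), gff2)
  expect_warning(pr2 <- extract_promoters(gff2, fa, length = 10,
                                          min_length = 5), "dropped")
  expect_equal(length(pr2), 0)
})

test_that("motif-phase assignment follows minimum adjusted p with early-ZT ties", {
  set.seed(74)
  genes <- sprintf("g%03d", 1:120)
  gp <- setNames(rep(c(0, 12), each = 60), genes)
  presence <- matrix(FALSE, 120, 2, dimnames = list(genes, c("mA", "mU")))
  presence[1:60, "mA"] <- runif(60) < 0.8    # phase-0 specific
  presence[61:120, "mA"] <- runif(60) < 0.05
  presence[, "mU"] <- runif(120) < 0.5       # uninformative
  res <- pcre_enrichment(presence, gp)
  expect_equal(res$assignment$motif_id, "mA")
  expect_equal(as.numeric(res$assignment$phase), 0)
})
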