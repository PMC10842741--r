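test_that("threshold segmentation finds, merges and drops runs", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 1, end = 1000,
                                  value = 5))
  tus <- segment_tus(tr, threshold = 1, strand = "+")
  expect_equal(c(start(tus), end(tus)), c(1, 1000))

  ## two runs separated by a 100-bp gap merge under max_gap = 200
  tr2 <- coverage_track(data.frame(chrom = "chr1", start = c(1, 601),
                                   end = c(500, 1100), value = 5))
  tus2 <- segment_tus(tr2, threshold = 1, max_gap = 200, strand = "+")
  expect_length(tus2, 1)
  expect_equal(width(tus2), 1100)

  ## a 150-bp run is dropped at min_len = 200
  tr3 <- coverage_track(data.frame(chrom = "chr1", start = 101, end = 250,
                                   value = 5))
  expect_length(segment_tus(tr3, threshold = 1, min_len = 200), 0)
})

## shared fixture: one + transcript [2001,3000], an enhancer, a TSS at 2001
tu_fixture <- function() {
  list(tx = GRanges("chr1", IRanges(2001, 3000), strand = "+",
                    tx_id = "t1", gene_id = "g1", n_exons = 1L),
       enh = GRanges("chr1", IRanges(50001, 50500)))
}

test_that("TU filter cascade applies its rules at the printed thresholds", {
  fx <- tu_fixture()
  ## (1) TU fully containing a same-strand transcript
  tu <- GRanges("chr1", IRanges(1, 10000), strand = "+", tu_id = "a")
  lab <- classify_tus(tu, fx$tx, fx$enh)
  expect_equal(mcols(lab)$label, "genic")
  expect_equal(mcols(lab)$discard_reason, "contains_transcript")
  ## antisense containment does not trigger the rule
  tu_anti <- GRanges("chr1", IRanges(1, 10000), strand = "-", tu_id = "a")
  expect_equal(mcols(classify_tus(tu_anti, fx$tx, fx$enh))$discard_reason,
               "none")

  ## (2) aggregate overlap: >= 3000 bp, or >= 25% of the TU length;
  ## the transcript sticks out of the TU so rule (1) never fires
  big_tx <- GRanges("chr1", IRanges(1, 5000), strand = "+", tx_id = "t",
                    gene_id = "g", n_exons = 1L)
  ## 10-kb TU overlapping the transcript by exactly 3000 bp -> genic
  tu3k <- GRanges("chr1", IRanges(2001, 12000), strand = "+", tu_id = "x")
  expect_equal(mcols(classify_tus(tu3k, big_tx, fx$enh))$discard_reason,
               "overlap_3kb_or_25pct")
  ## 2999 bp overlap on a 10334-bp TU: 29% -> still genic via the fraction
  tu29 <- GRanges("chr1", IRanges(2002, 12335), strand = "+", tu_id = "x")
  expect_equal(mcols(classify_tus(tu29, big_tx, fx$enh))$discard_reason,
               "overlap_3kb_or_25pct")
  ## 2400 bp overlap on a 10-kb TU (24%) -> retained
  tu24 <- GRanges("chr1", IRanges(2601, 12600), strand = "+", tu_id = "x")
  expect_equal(mcols(classify_tus(tu24, big_tx, fx$enh))$discard_reason,
               "none")

  ## merged transcript cover prevents isoform double counting
  iso <- c(big_tx, GRanges("chr1", IRanges(1, 5000), strand = "+",
                           tx_id = "t2", gene_id = "g", n_exons = 1L))
  expect_equal(mcols(classify_tus(tu24, iso, fx$enh))$discard_reason, "none")
})

test_that("PROMPT and eRNA distance rules are inclusive and ordered", {
  fx <- tu_fixture()
  ## retained - TU ending 800 bp upstream of the + TSS at 2001 -> PROMPT
  tu <- GRanges("chr1", IRanges(401, 1200), strand = "-", tu_id = "p")
  lab <- classify_tus(tu, fx$tx, fx$enh)
  expect_equal(mcols(lab)$label, "PROMPT")
  expect_equal(mcols(lab)$d_antisense_tss, 800)

  ## same TU 1500 bp away but 300 bp from an enhancer -> eRNA
  tu2 <- GRanges("chr1", IRanges(49001, 49700), strand = "-", tu_id = "e")
  lab2 <- classify_tus(tu2, fx$tx, fx$enh)
  expect_equal(mcols(lab2)$label, "eRNA")
  expect_equal(mcols(lab2)$d_enhancer, 300)

  ## boundary: exactly 1000 bp counts as PROMPT, 1001 does not
  at1000 <- GRanges("chr1", IRanges(401, 1000), strand = "-", tu_id = "b")
  expect_equal(mcols(classify_tus(at1000, fx$tx, fx$enh))$label, "PROMPT")
  at1001 <- GRanges("chr1", IRanges(400, 999), strand = "-", tu_id = "b")
  expect_equal(mcols(classify_tus(at1001, fx$tx, fx$enh))$label, "other")
  ## boundary: exactly 500 bp from the enhancer is eRNA, 501 is not
  e500 <- GRanges("chr1", IRanges(49001, 49500), strand = "-", tu_id = "b")
  expect_equal(mcols(classify_tus(e500, fx$tx, fx$enh))$label, "eRNA")
  e501 <- GRanges("chr1", IRanges(49000, 49499), strand = "-", tu_id = "b")
  expect_equal(mcols(classify_tus(e501, fx$tx, fx$enh))$label, "other")

  ## PROMPT precedence when both conditions hold
  both <- GRanges("chr1", IRanges(1401, 1800), strand = "-", tu_id = "b")
  enh_near <- GRanges("chr1", IRanges(1850, 1900))
  expect_equal(mcols(classify_tus(both, fx$tx, enh_near))$label, "PROMPT")

  expect_error(classify_tus(GRanges("chr1", IRanges(1, 10), strand = "*"),
                            fx$tx, fx$enh), "stranded")
})

test_that("classification is invariant to TU input order", {
  sim <- simulate_genome(n_genes = 60, seed = 31)
  tus <- simulate_tus(sim, n_prompt = 30, n_erna = 15, n_other = 15)
  lab1 <- classify_tus(tus, sim$genes, sim$enhancers)
  perm <- sample(length(tus))
  lab2 <- classify_tus(tus[perm], sim$genes, sim$enhancers)
  m <- match(mcols(lab1)$tu_id, mcols(lab2)$tu_id)
  expect_equal(mcols(lab1)$label, mcols(lab2)$label[m])
})

test_that("TU tabulation counts labels and joins DE tables", {
  tus <- GRanges("chr1", IRanges(seq(1, by = 2000, length.out = 5),
                                 width = c(100, 200, 300, 400, 500)),
                 strand = "+",
                 tu_id = paste0("tu", 1:5),
                 label = c("PROMPT", "PROMPT", "PROMPT", "eRNA", "eRNA"))
  s <- tu_summary(tus)
  expect_equal(as.vector(s$counts[c("PROMPT", "eRNA")]), c(3L, 2L))
  expect_equal(as.vector(s$counts[c("genic", "other")]), c(0L, 0L))

  de <- data.frame(feature_id = c("tu1", "tu4"), feature_kind = "tu",
                   biotype = "tu", base_mean = 1, log2fc = c(1, -1),
                   stat = c(2, -2), pvalue = 0.1, padj = 0.2)
  s2 <- tu_summary(tus, de)
  expect_equal(s2$joined$stat, c(2, NA, NA, -2, NA))

  dup <- tus
  mcols(dup)$tu_id <- rep("same", 5)
  expect_error(tu_summary(dup), "duplicate")

  s0 <- tu_summary(tus[0])
  expect_true(all(s0$counts == 0))
})
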