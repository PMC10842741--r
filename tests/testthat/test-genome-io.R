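test_that("BED6 parsing maps fields, validates, and reports line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tMT2_Mm|LTR\t0\t+",
               "chr1\t600\t5600\tMERVL-int|LTR\t0\t-"), f)
  te <- read_bed(f, kind = "te")
  expect_equal(start(te), c(101, 601)) # 0-based -> 1-based
  expect_equal(end(te), c(200, 5600))
  expect_equal(mcols(te)$family, c("MT2_Mm", "MERVL-int"))
  expect_equal(mcols(te)$te_class, c("LTR", "LTR"))
  expect_equal(as.character(strand(te)), c("+", "-"))

  writeLines(c("chr1\t100\t200\tx|LTR\t0\t+",
               "chr1\t300\t300\ty|LTR\t0\t+"), f)
  expect_error(read_bed(f, kind = "te"), "line 2")
  writeLines("chr1\t100\t200\tz|RNA\t0\t+", f)
  expect_error(read_bed(f, kind = "te"), "te_class")
  writeLines("chr1\t100\t200\tnopipe\t0\t+", f)
  expect_error(read_bed(f, kind = "te"), "family")
})

test_that("termination-site BED records carry status and count", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1000\tpA+,-\t3\t+",
               "chr1\t5000\t5001\tpA+\t1\t-"), f)
  sites <- read_bed(f, kind = "termination")
  expect_equal(mcols(sites)$pa_status, c("pA+,-", "pA+"))
  expect_equal(mcols(sites)$count, c(3L, 1L))
  expect_equal(start(sites), c(1000, 5001))
  writeLines("chr1\t10\t12\tpA+\t1\t+", f)
  expect_error(read_bed(f, kind = "termination"), "single-base")
  writeLines("chr1\t10\t11\tpolyA\t1\t+", f)
  expect_error(read_bed(f, kind = "termination"), "status")
})

test_that("BED round trips are lossless for all three record kinds", {
  f <- withr::local_tempfile(fileext = ".bed")
  g <- withr::local_tempfile(fileext = ".bed")
  for (kind in c("interval", "te", "termination")) {
    lines <- switch(kind,
      interval = c("chr1\t0\t100\tpeak1\t7\t+", "chr2\t50\t80\tpeak2\t0\t."),
      te = c("chr1\t100\t200\tMT2_Mm|LTR\t0\t+", "chr2\t0\t90\tL1Md|LINE\t0\t-"),
      termination = c("chr1\t999\t1000\tpA+,-\t3\t+", "chr2\t10\t11\tpA+\t2\t-"))
    writeLines(lines, f)
    write_bed(read_bed(f, kind = kind), g)
    expect_identical(readLines(g), lines)
  }
})

test_that("bedGraph reading validates and writing coalesces and round-trips", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t10\t2", "chr1\t10\t30\t2", "chr1\t50\t60\t1.5"), f)
  tr <- read_bedgraph(f)
  expect_equal(region_mean(tr, GRanges("chr1", IRanges(1, 30))), 2)
  g <- withr::local_tempfile()
  write_bedgraph(tr, g)
  expect_identical(readLines(g), c("chr1\t0\t30\t2", "chr1\t50\t60\t1.5"))
  h <- withr::local_tempfile()
  write_bedgraph(read_bedgraph(g), h) # idempotent after first round trip
  expect_identical(readLines(g), readLines(h))

  writeLines(c("chr1\t0\t10\t2", "chr1\t5\t15\t1"), f)
  expect_error(read_bedgraph(f), "overlap")
  writeLines("chr1\t0\t10\t-1", f)
  expect_error(read_bedgraph(f), "negative")
})

test_that("region_mean averages per bp, zero-fills, and is linear", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 1, end = 100,
                                  value = 2))
  expect_equal(region_mean(tr, GRanges("chr1", IRanges(11, 20))), 2)
  tr2 <- coverage_track(data.frame(chrom = "chr1", start = 1, end = 50,
                                   value = 4))
  expect_equal(region_mean(tr2, GRanges("chr1", IRanges(1, 100))), 2)
  expect_equal(region_mean(tr2, GRanges("chr9", IRanges(1, 100))), 0)

  ## invariance to re-splitting an identical step function + linearity
  a <- coverage_track(data.frame(chrom = "chr1", start = c(1, 41),
                                 end = c(40, 100), value = c(3, 3)))
  b <- coverage_track(data.frame(chrom = "chr1", start = 1, end = 100,
                                 value = 3))
  w <- GRanges("chr1", IRanges(c(1, 17, 90), c(100, 63, 120)))
  expect_equal(region_mean(a, w), region_mean(b, w))
  expect_equal(region_mean(track_add(a, b), w), 2 * region_mean(b, w))
  expect_equal(region_mean(track_scale(b, 2.5), w), 2.5 * region_mean(b, w))

  lay <- genome_layout(c(chr1 = 100))
  trl <- coverage_track(data.frame(chrom = "chr1", start = 1, end = 100,
                                   value = 1), layout = lay)
  expect_error(region_mean(trl, GRanges("chr1", IRanges(90, 120))), "beyond")
})

test_that("overlap_length follows chromosome and strand rules", {
  a <- GRanges("chr1", IRanges(1, 10), strand = "+")   # [0,10) in BED
  b <- GRanges("chr1", IRanges(6, 20), strand = "+")   # [5,20)
  expect_equal(overlap_length(a, b), 5L)
  expect_equal(overlap_length(a, GRanges("chr2", IRanges(6, 20))), 0L)
  bm <- GRanges("chr1", IRanges(1, 10), strand = "-")
  expect_equal(overlap_length(a, bm, same_strand_only = TRUE), 0L)
  expect_equal(overlap_length(a, bm, same_strand_only = FALSE), 10L)
})

test_that("gene models read from BED12 and GTF with strand-aware TSS/TES", {
  f <- withr::local_tempfile(fileext = ".bed")
  ## 3-block plus-strand isoform and a single-exon minus-strand gene
  writeLines(c(paste0("chr1\t1000\t2000\tgA|gA.t1\t0\t+\t1000\t2000\t0\t3\t",
                      "100,100,200,\t0,400,800,"),
               "chr1\t1000\t2000\tgB|gB.t1\t0\t-\t1000\t2000\t0\t1\t1000,\t0,"),
             f)
  gm <- read_gene_models(f, "bed12")
  gm <- select_major_isoform(gm)
  expect_equal(gm$tx$n_exons, c(3L, 1L))
  sp <- gene_spans(gm)
  ## minus-strand [1000,2000) in BED: TSS = 1999 (0-based) = 2000 (1-based)
  expect_equal(mcols(sp)$tss[mcols(sp)$gene_id == "gB"], 2000)
  expect_equal(mcols(sp)$tes[mcols(sp)$gene_id == "gB"], 1001)

  g <- withr::local_tempfile(fileext = ".bed12")
  write_bed12(gm, g)
  gm2 <- read_gene_models(g, "bed12")
  expect_equal(gm2$tx, gm$tx)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t1501\t2000\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\ttranscript\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t2";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t2";'),
    gtf)
  gmg <- read_gene_models(gtf, "gtf")
  expect_equal(nrow(gmg$tx), 2L) # two isoforms of one gene
  expect_equal(sort(gmg$tx$n_exons), c(1L, 2L))

  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.tX";'),
    gtf)
  expect_error(read_gene_models(gtf, "gtf"), "zero exons")

  ## mixed strands within one gene
  ex <- GRanges("chr1", IRanges(c(1, 100), c(50, 150)),
                strand = c("+", "-"),
                tx_id = c("t1", "t2"), gene_id = c("g", "g"))
  expect_error(gene_model_set(ex), "mixed strands")
})

test_that("reversing a gene's strand swaps TSS and TES", {
  sp <- GRanges("chr1", IRanges(1001, 5000), strand = "+", gene_id = "g")
  sm <- sp
  strand(sm) <- "-"
  expect_equal(start(tss_sites(sp)), start(tes_sites(sm)))
  expect_equal(start(tes_sites(sp)), start(tss_sites(sm)))
})

test_that("DE tables validate the BH and sign invariants on read", {
  df <- data.frame(feature_id = c("a", "b"), feature_kind = "gene",
                   biotype = "protein_coding", base_mean = c(10, 20),
                   log2fc = c(1, -2), stat = c(2, -4),
                   pvalue = c(0.01, 0.02), padj = c(0.02, 0.02))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(df, f)
  expect_equal(read_de_table(f)$log2fc, df$log2fc)

  bad <- df
  bad$padj <- c(0.005, 0.02) # padj < pvalue
  expect_error(validate_de_table(bad), "BH")
  bad <- df
  bad$stat <- c(-2, -4) # sign mismatch with log2fc
  expect_error(validate_de_table(bad), "sign")
})
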