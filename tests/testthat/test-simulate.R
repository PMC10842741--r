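test_that("identical seeds reproduce every simulation stage exactly", {
  args <- list(n_genes = 40, n_families = 6, copies_per_family = 55,
               n_enhancers = 10, enriched_folds = c(TEF002 = 4),
               asymmetry_slope = 0.3, pausing_defect = 0.05,
               premature_rate = 0.1, noise_sd = 1, seed = 11)
  a <- do.call(simulate_genome, args)
  b <- do.call(simulate_genome, args)
  expect_identical(a$layout, b$layout)
  expect_identical(as.data.frame(a$te), as.data.frame(b$te))
  expect_identical(a$genes$tx, b$genes$tx)
  expect_identical(as.data.frame(a$enhancers), as.data.frame(b$enhancers))
  expect_identical(simulate_de_table(a), simulate_de_table(b))
  expect_identical(as.data.frame(simulate_termination_sites(a)$sites),
                   as.data.frame(simulate_termination_sites(b)$sites))
  expect_identical(as.data.frame(simulate_tus(a)), as.data.frame(simulate_tus(b)))
  ta <- simulate_coverage(a, "cKO", "RNAPII")
  tb <- simulate_coverage(b, "cKO", "RNAPII")
  expect_identical(lapply(ta$cov, runValue), lapply(tb$cov, runValue))
})

test_that("exon-count mix is respected and capacity overflow errors", {
  sim <- simulate_genome(n_genes = 60, exon_count_mix = c("1" = 0.5, "12" = 0.5),
                         seed = 2)
  expect_true(all(mcols(gene_spans(sim$genes))$n_exons %in% c(1L, 12L)))
  expect_error(simulate_genome(n_chroms = 1, chrom_len = 5e4, n_genes = 500,
                               seed = 1),
               "capacity")
})

test_that("a 49-copy family is recorded in truth but fails the filter", {
  sim <- simulate_genome(n_families = 3, copies_per_family = c(49, 60, 60),
                         n_genes = 10, seed = 4)
  expect_true("TEF001" %in% names(sim$truth$enriched_families))
  kept <- filter_te_annotation(sim$te, min_len = 1, min_copies = 50)
  expect_false("TEF001" %in% mcols(kept)$family)
  expect_setequal(unique(mcols(kept)$family), c("TEF002", "TEF003"))
})

test_that("noise-free tracks hit the analytic promoter/body and fold values", {
  sim <- simulate_genome(n_genes = 30, n_families = 4, copies_per_family = 55,
                         enriched_folds = c(TEF001 = 4), noise_sd = 0,
                         seed = 7)
  trk <- simulate_coverage(sim, "WT", "RNAPII", promoter_height = 10,
                           body_height = 2)
  pr <- pausing_ratio(trk, sim$genes)
  expect_true(all(abs(pr$ratio[pr$passed] - 5) < 1e-9))

  k27 <- simulate_coverage(sim, "WT", "H3K27ac")
  fe <- family_enrichment(k27, filter_te_annotation(sim$te, min_copies = 50),
                          sim$layout, seed = 3, pseudocount = 0)
  expect_equal(fe$log2_enrichment[fe$family == "TEF001"], 2,
               tolerance = 0.02) # background may graze planted plateaus
  expect_true(all(abs(fe$log2_enrichment[fe$family != "TEF001"]) < 0.1))
})

test_that("a zero pausing defect leaves WT and cKO body signal equivalent", {
  sim <- simulate_genome(n_genes = 60, seed = 5, noise_sd = 1,
                         pausing_defect = 0)
  wt <- simulate_coverage(sim, "WT", "RNAPII")
  ko <- simulate_coverage(sim, "cKO", "RNAPII")
  pb <- pausing_regions(gene_spans(sim$genes))
  bw <- region_mean(wt, pb$body[pb$ok])
  bk <- region_mean(ko, pb$body[pb$ok])
  expect_gt(t.test(bw, bk, paired = TRUE)$p.value, 0.01)
})

test_that("DE generator nulls out cleanly and its padj matches step-up BH", {
  sim0 <- simulate_genome(n_genes = 25, seed = 9, noise_sd = 0,
                          asymmetry_slope = 0)
  de0 <- simulate_de_table(sim0)
  expect_true(all(de0$log2fc == 0))
  expect_true(all(de0$pvalue == 1))

  sim <- simulate_genome(n_genes = 80, seed = 10, noise_sd = 0.8,
                         asymmetry_slope = 0.3,
                         enriched_folds = c(TEF001 = 32))
  de <- simulate_de_table(sim)
  expect_equal(de$padj, oracle_bh(de$pvalue), tolerance = 1e-12)
  ## a strongly planted family clears the FDR < 0.05 / log2FC > 5 filter
  ## (a fold of exactly 32 sits on the log2FC = 5 boundary, which the
  ## strict '>' excludes, so the planted fold must exceed it)
  sim64 <- simulate_genome(n_genes = 80, seed = 10, noise_sd = 0,
                           enriched_folds = c(TEF001 = 64, TEF002 = 32))
  de64 <- simulate_de_table(sim64)
  expect_true("TEF001" %in% define_signature(de64))
  expect_false("TEF002" %in% define_signature(de64))
})

test_that("termination sites scale with expression and stay TSS-proximal", {
  sim <- simulate_genome(n_genes = 500, n_chroms = 6, chrom_len = 3e6,
                         seed = 13, premature_rate = 0.3,
                         exon_count_mix = c("3" = 1))
  gid <- sim$genes$genes$gene_id
  expr <- setNames(rep(c(1, 2), length.out = length(gid)), gid)
  res <- simulate_termination_sites(sim, expression = expr)
  sp <- gene_spans(sim$genes)
  tss <- setNames(mcols(sp)$tss, mcols(sp)$gene_id)
  str <- setNames(as.character(strand(sp)), mcols(sp)$gene_id)
  pre <- res$sites[mcols(res$sites)$pa_status == "pA+,-"]
  asn <- assign_sites(pre, sim$genes)
  d <- asn$d_tss[!is.na(asn$gene_id)]
  expect_true(all(d >= 0 & d < 500))
  ## doubling expression doubles the expected count (Poisson mean identity)
  counts <- table(factor(asn$gene_id, levels = gid))
  lenkb <- setNames(width(sp) / 1000, mcols(sp)$gene_id)
  rate1 <- sum(counts[expr[gid] == 1]) / sum(lenkb[expr[gid] == 1])
  rate2 <- sum(counts[expr[gid] == 2]) / sum(lenkb[expr[gid] == 2])
  expect_equal(rate2 / rate1, 2, tolerance = 0.1)

  ## premature_rate = 0 plants nothing
  sim0 <- simulate_genome(n_genes = 30, seed = 3, premature_rate = 0)
  res0 <- simulate_termination_sites(sim0)
  expect_length(res0$premature_genes, 0)
  expect_false(any(mcols(res0$sites)$pa_status == "pA+,-"))
})

test_that("simulated PROMPTs are antisense to their gene", {
  sim <- simulate_genome(n_genes = 80, seed = 21)
  tus <- simulate_tus(sim, n_prompt = 40)
  prompts <- tus[mcols(tus)$truth_label == "PROMPT"]
  tss <- tss_sites(gene_spans(sim$genes))
  dn <- GenomicRanges::distanceToNearest(prompts, tss, ignore.strand = TRUE)
  near <- tss[subjectHits(dn)]
  expect_true(all(as.character(strand(prompts)) !=
                    as.character(strand(near))))
  expect_true(all(mcols(dn)$distance <= 1000))
})
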