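## Fixture builders and independent oracles used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## non-overlapping random step-function segments on one chromosome
random_step_segments <- function(n = 30, max_width = 80, max_gap = 60,
                                 chrom = "chr1") {
  w <- sample(seq_len(max_width), n, replace = TRUE)
  g <- sample(0:max_gap, n, replace = TRUE)
  st <- 1 + cumsum(g + c(0, head(w, -1) + 1))
  data.frame(chrom = chrom, start = st, end = st + w - 1,
             value = round(runif(n, 0, 10), 3))
}

## independent scale-regions oracle: closed-form integration of the step
## function over real-valued bin edges (never touches CoverageTrack)
oracle_metagene_row <- function(segs, region_start, region_end, strand,
                                body_bins, flank_bp, flank_bins) {
  s_ext <- region_start - flank_bp
  L <- region_end - region_start + 1
  edges <- unique(c(
    if (flank_bins > 0) seq(0, flank_bp, length.out = flank_bins + 1) else 0,
    flank_bp + L * seq(0, body_bins) / body_bins,
    if (flank_bins > 0) flank_bp + L + seq(0, flank_bp,
                                           length.out = flank_bins + 1)
    else flank_bp + L))
  integ <- function(a, b) {
    tot <- 0
    for (k in seq_len(nrow(segs))) {
      lo <- segs$start[k] - s_ext
      hi <- segs$end[k] - s_ext + 1
      tot <- tot + segs$value[k] * max(0, min(b, hi) - max(a, lo))
    }
    tot
  }
  vals <- vapply(seq_len(length(edges) - 1), function(i)
    integ(edges[i], edges[i + 1]) / (edges[i + 1] - edges[i]), 0)
  if (strand == "-") rev(vals) else vals
}

## textbook BH step-up, straight from the definition:
## adj_(i) = min_{j >= i} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, 0)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

## brute-force weighted running-sum enrichment score
oracle_es <- function(scores, in_set, weight = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  nr <- sum(abs(scores[in_set])^weight)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (in_set[i]) abs(scores[i])^weight / nr else
      -1 / (n - nh)
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

## a tiny hand-built gene model set: coordinates 1-based closed
toy_gene_models <- function() {
  exons <- GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2"),
    IRanges(start = c(1001, 1501, 1001, 8001, 2001),
            end = c(1200, 2000, 1200, 9000, 3000)),
    strand = c("+", "+", "+", "-", "-"),
    tx_id = c("gA.t1", "gA.t1", "gA.t2", "gB.t1", "gC.t1"),
    gene_id = c("gA", "gA", "gA", "gB", "gC"))
  select_major_isoform(gene_model_set(exons))
}

flat_track <- function(value, len = 10000, chroms = "chr1") {
  coverage_track(data.frame(chrom = chroms, start = 1, end = len,
                            value = value))
}
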