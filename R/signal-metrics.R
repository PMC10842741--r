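#' Promoter-proximal and gene-body windows of genes
#'
#' The promoter-proximal window spans TSS-30 bp to TSS+300 bp and the gene
#' body TSS+300 bp to the TES, both in transcript orientation (mirrored in
#' genomic coordinates on the minus strand). Genes whose TES lies at or
#' before TSS+300 have no body (`ok = FALSE`).
#'
#' @param spans stranded `GRanges` of gene spans (e.g. [gene_spans()]).
#' @return list with `promoter` (`GRanges`), `body` (`GRanges`; zero-width
#'   placeholder where invalid) and `ok` (logical).
#' @export
pausing_regions <- function(spans) {
  stopifnot(is(spans, "GRanges"))
  str <- as.character(strand(spans))
  if (any(str == "*")) stop("gene spans must be stranded", call. = FALSE)
  plus <- str == "+"
  tss <- ifelse(plus, start(spans), end(spans))
  prom_s <- ifelse(plus, tss - 30L, tss - 299L)
  prom_e <- ifelse(plus, tss + 299L, tss + 30L)
  body_s <- ifelse(plus, tss + 300L, start(spans))
  body_e <- ifelse(plus, end(spans), tss - 300L)
  ok <- body_e >= body_s
  promoter <- GRanges(seqnames(spans), IRanges(prom_s, prom_e), strand = str)
  body <- GRanges(seqnames(spans),
                  IRanges(ifelse(ok, body_s, prom_s),
                          ifelse(ok, body_e, prom_s - 1L)),
                  strand = str)
  list(promoter = promoter, body = body, ok = ok)
}

#' RNAPII pausing ratio per gene
#'
#' Ratio of the mean promoter-proximal signal to the mean gene-body signal
#' ([pausing_regions()]; means via [region_mean()]). A gene passes only if
#' both means are nonzero and — when a peak set is supplied — a peak
#' overlaps the single TSS base. The ratio is invariant to global track
#' scaling.
#'
#' @param track a `CoverageTrack`.
#' @param genes a `GeneModelSet` (major isoforms set) or a stranded
#'   `GRanges` with a `gene_id` metadata column.
#' @param peaks optional unstranded `GRanges` of significant peaks.
#' @return a `data.frame`: `gene_id`, `prom_mean`, `body_mean`, `ratio`
#'   (NA unless passed), `passed`, `fail_reason` (one of `body_too_short`,
#'   `zero_promoter`, `zero_body`, `no_tss_peak`, `none`).
#' @export
pausing_ratio <- function(track, genes, peaks = NULL) {
  spans <- if (is(genes, "GeneModelSet")) gene_spans(genes) else genes
  gid <- mcols(spans)$gene_id %||% as.character(seq_along(spans))
  pb <- pausing_regions(spans)
  prom <- region_mean(track, pb$promoter)
  body <- rep(0, length(spans))
  body[pb$ok] <- region_mean(track, pb$body[pb$ok])
  reason <- rep("none", length(spans))
  reason[body == 0] <- "zero_body"
  reason[prom == 0] <- "zero_promoter"
  reason[!pb$ok] <- "body_too_short"
  if (!is.null(peaks)) {
    at_tss <- overlapsAny(tss_sites(spans), peaks, ignore.strand = TRUE)
    reason[reason == "none" & !at_tss] <- "no_tss_peak"
  }
  passed <- reason == "none"
  data.frame(gene_id = gid, prom_mean = prom, body_mean = body,
             ratio = ifelse(passed, prom / body, NA_real_),
             passed = passed, fail_reason = reason, stringsAsFactors = FALSE)
}

#' Compare pausing ratios between conditions, by exon-count group
#'
#' Only genes passing in both conditions are compared. Per group: the
#' median ratio in each condition and a two-sided unpaired Wilcoxon
#' rank-sum p-value of the KO vs WT ratios, Benjamini-Hochberg adjusted
#' across groups. Groups with fewer than 3 genes report `NA` p-values.
#'
#' @param wt_records,ko_records [pausing_ratio()] tables sharing gene ids.
#' @param exon_counts named integer vector gene_id -> exon count of the
#'   major isoform.
#' @param edges exon-count bin edges (see [exon_count_bins()]).
#' @return a `data.frame` per group: `group`, `n`, `median_wt`,
#'   `median_ko`, `pvalue`, `padj`.
#' @export
compare_pausing <- function(wt_records, ko_records, exon_counts,
                            edges = default_exon_edges()) {
  m <- merge(wt_records[wt_records$passed, c("gene_id", "ratio")],
             ko_records[ko_records$passed, c("gene_id", "ratio")],
             by = "gene_id", suffixes = c("_wt", "_ko"))
  if (!all(m$gene_id %in% names(exon_counts)))
    stop("exon_counts missing for some genes", call. = FALSE)
  bins <- bin_exon_counts(exon_counts[m$gene_id], edges)
  out <- lapply(levels(bins), function(b) {
    i <- bins == b
    p <- if (sum(i) >= 3) rank_sum_p(m$ratio_ko[i], m$ratio_wt[i]) else NA_real_
    data.frame(group = b, n = sum(i),
               median_wt = if (any(i)) median(m$ratio_wt[i]) else NA_real_,
               median_ko = if (any(i)) median(m$ratio_ko[i]) else NA_real_,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$padj <- NA_real_
  ok <- !is.na(out$pvalue)
  out$padj[ok] <- bh_adjust(out$pvalue[ok])
  out
}

## real-valued bin edges of the scale-regions grid, relative to the start
## of the flank-extended window: flank bins of fixed width, body bins of
## width L/body_bins (bins may share base pairs for short regions).
scale_region_edges <- function(L, body_bins, flank_bp, flank_bins) {
  left <- if (flank_bins > 0) seq(0, flank_bp, length.out = flank_bins + 1) else 0
  body <- flank_bp + L * seq(0, body_bins) / body_bins
  right <- if (flank_bins > 0)
    flank_bp + L + seq(0, flank_bp, length.out = flank_bins + 1) else flank_bp + L
  unique(c(left, body, right))
}

## integral of per-bp vector v over [0, x] with fractional end, x real
cum_integral_at <- function(C, v, x) {
  f <- pmin(pmax(floor(x), 0), length(v))
  frac <- x - f
  extra <- ifelse(f < length(v), frac * v[pmin(f + 1, length(v))], 0)
  C[f + 1] + extra
}

#' Scale-regions metagene matrix
#'
#' Each region's body is rescaled to `body_bins` equal-width genomic
#' sub-windows (real-valued bin edges, so bins of regions shorter than
#' `body_bins` bp share base pairs) and flanked by `flank_bins` fixed-width
#' bins covering `flank_bp` on each side; every bin holds the per-bp mean
#' signal over its span (positions beyond the covered genome contribute 0).
#' Minus-strand rows are reversed so column 1 is always the 5' end.
#'
#' @param track a `CoverageTrack`.
#' @param regions a `GRanges` (strand `*` treated as `+`).
#' @param body_bins,flank_bp,flank_bins grid geometry.
#' @return an object of class `MetageneMatrix`: list with `matrix`
#'   (regions x bins), `summary` (column means), `bin_type` (factor:
#'   upstream/body/downstream) and the grid parameters.
#' @export
metagene <- function(track, regions, body_bins = 100, flank_bp = 2000,
                     flank_bins = 40) {
  stopifnot(body_bins >= 1, flank_bins >= 0, flank_bp >= 0)
  if (flank_bins == 0) flank_bp <- 0
  n_bins <- body_bins + 2 * flank_bins
  mat <- matrix(0, nrow = length(regions), ncol = n_bins)
  chr <- as.character(seqnames(regions))
  str <- as.character(strand(regions))
  for (i in seq_along(regions)) {
    s <- start(regions)[i] - flank_bp
    e <- end(regions)[i] + flank_bp
    v <- region_values(track, chr[i], s, e)
    C <- c(0, cumsum(v))
    edges <- scale_region_edges(width(regions)[i], body_bins, flank_bp,
                                flank_bins)
    I <- cum_integral_at(C, v, edges)
    row <- diff(I) / diff(edges)
    if (str[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rn <- mcols(regions)$gene_id %||% mcols(regions)$name %||%
    as.character(seq_along(regions))
  rownames(mat) <- make.unique(as.character(rn))
  bin_type <- factor(rep(c("upstream", "body", "downstream"),
                         c(flank_bins, body_bins, flank_bins)),
                     levels = c("upstream", "body", "downstream"))
  structure(list(matrix = mat, summary = colMeans(mat), bin_type = bin_type,
                 body_bins = body_bins, flank_bp = flank_bp,
                 flank_bins = flank_bins), class = "MetageneMatrix")
}

#' @export
print.MetageneMatrix <- function(x, ...) {
  cat(sprintf("MetageneMatrix: %d region(s) x %d bin(s) (%d+%d+%d)\n",
              nrow(x$matrix), ncol(x$matrix), x$flank_bins, x$body_bins,
              x$flank_bins))
  invisible(x)
}

#' Write a metagene matrix as TSV (summary row first)
#' @param mg a `MetageneMatrix`.
#' @param path output path.
#' @param header optional `#` comment lines.
#' @export
write_metagene <- function(mg, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("region", paste0("bin", seq_len(ncol(mg$matrix)))),
                   collapse = "\t"), con)
  writeLines(paste(c("summary", sprintf("%.10g", mg$summary)), collapse = "\t"),
             con)
  writeLines(paste(rownames(mg$matrix),
                   apply(mg$matrix, 1, function(r)
                     paste(sprintf("%.10g", r), collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}
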