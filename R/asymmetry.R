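#' Default exon-count bin edges
#'
#' Bins 1 / 2-3 / 4-10 / 11+, placing the biologically motivated
#' more-than-3-exons boundary at a bin edge.
#'
#' @return a list of `c(lo, hi)` pairs.
#' @export
default_exon_edges <- function() {
  list(c(1, 1), c(2, 3), c(4, 10), c(11, Inf))
}

## validate edges (contiguous, non-overlapping, ascending) and label them
edge_labels <- function(edges) {
  lo <- vapply(edges, `[`, 0, 1)
  hi <- vapply(edges, `[`, 0, 2)
  if (any(lo > hi) || any(lo[-1] != hi[-length(hi)] + 1))
    stop("bin edges must be contiguous and non-overlapping", call. = FALSE)
  ifelse(is.infinite(hi), paste0(lo, "+"),
         ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)))
}

bin_exon_counts <- function(counts, edges) {
  labs <- edge_labels(edges)
  lo <- vapply(edges, `[`, 0, 1)
  hi <- vapply(edges, `[`, 0, 2)
  idx <- findInterval(counts, lo)
  idx[counts < lo[1] | counts > hi[length(hi)]] <- NA
  factor(labs[idx], levels = labs)
}

#' Bin genes by major-isoform exon count
#'
#' @param gm a `GeneModelSet` with major isoforms set.
#' @param edges bin edges as a list of `c(lo, hi)` pairs
#'   ([default_exon_edges()]); must be contiguous and non-overlapping.
#' @return named factor gene_id -> bin label.
#' @export
exon_count_bins <- function(gm, edges = default_exon_edges()) {
  spans <- gene_spans(gm)
  setNames(bin_exon_counts(mcols(spans)$n_exons, edges),
           mcols(spans)$gene_id)
}

#' Gene-length / exon-count expression asymmetry summary
#'
#' Groups the DE statistic by exon-count bin (major isoform), by
#' gene-length quantile (major-isoform genomic span, TSS to TES), or by
#' the DE table's biotype column, and reports per-group medians, a
#' two-sided unpaired Wilcoxon rank-sum test of each group against the
#' first (reference) group with Benjamini-Hochberg adjustment, and a
#' Spearman trend of group order against the group median statistic.
#'
#' @param de_table a DE table (see [read_de_table()]).
#' @param gm a `GeneModelSet` (ignored for biotype grouping of non-gene
#'   features).
#' @param grouping `"exon_count"`, `"length_quantile"` or `"biotype"`.
#' @param edges exon-count bin edges.
#' @param n_quantiles number of length quantiles.
#' @return an `AsymmetrySummary`: list with `table` (per-group `n`,
#'   `median_stat`, `median_log2fc`, `pvalue`, `padj`), `trend_rho`,
#'   `trend_p` and `grouping`. Groups with fewer than 3 members report NA
#'   p-values.
#' @export
asymmetry_summary <- function(de_table, gm,
                              grouping = c("exon_count", "length_quantile",
                                           "biotype"),
                              edges = default_exon_edges(),
                              n_quantiles = 5) {
  grouping <- match.arg(grouping)
  validate_de_table(de_table)
  if (grouping == "biotype") {
    df <- de_table
    groups <- factor(df$biotype, levels = sort(unique(df$biotype)))
  } else {
    spans <- gene_spans(gm)
    gid <- mcols(spans)$gene_id
    df <- de_table[de_table$feature_id %in% gid, , drop = FALSE]
    m <- match(df$feature_id, gid)
    groups <- if (grouping == "exon_count") {
      bin_exon_counts(mcols(spans)$n_exons[m], edges)
    } else {
      len <- width(spans)[m]
      br <- unique(quantile(len, probs = seq(0, 1,
                                             length.out = n_quantiles + 1)))
      cut(len, breaks = br, include.lowest = TRUE,
          labels = paste0("Q", seq_len(length(br) - 1)))
    }
  }
  keep <- !is.na(groups)
  df <- df[keep, , drop = FALSE]
  groups <- droplevels(groups[keep])
  ref <- levels(groups)[1]
  tab <- do.call(rbind, lapply(levels(groups), function(g) {
    i <- groups == g
    p <- if (g != ref && sum(i) >= 3 && sum(groups == ref) >= 3)
      rank_sum_p(df$stat[i], df$stat[groups == ref]) else NA_real_
    data.frame(group = g, n = sum(i), median_stat = median(df$stat[i]),
               median_log2fc = median(df$log2fc[i]), pvalue = p,
               stringsAsFactors = FALSE)
  }))
  tab$padj <- NA_real_
  ok <- !is.na(tab$pvalue)
  tab$padj[ok] <- bh_adjust(tab$pvalue[ok])
  trend <- if (nrow(tab) >= 2 && length(unique(tab$median_stat)) > 1) {
    suppressWarnings(cor.test(seq_len(nrow(tab)), tab$median_stat,
                              method = "spearman"))
  } else NULL
  structure(list(table = tab,
                 trend_rho = if (is.null(trend)) NA_real_ else
                   unname(trend$estimate),
                 trend_p = if (is.null(trend)) NA_real_ else trend$p.value,
                 grouping = grouping, reference = ref),
            class = "AsymmetrySummary")
}

#' @export
print.AsymmetrySummary <- function(x, ...) {
  cat(sprintf("AsymmetrySummary (%s; reference group '%s')\n", x$grouping,
              x$reference))
  print(x$table, row.names = FALSE)
  cat(sprintf("trend: Spearman rho = %.3f, p = %.3g\n", x$trend_rho,
              x$trend_p))
  invisible(x)
}
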