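#' Assign termination sites to genes
#'
#' A site is assigned to a same-strand gene whose flank-extended span
#' contains it; among multiple candidates the gene with the nearest TSS
#' wins (ties broken by lexicographically smaller gene_id). `d_tss` is the
#' strand-aware signed distance from the TSS (positive downstream);
#' `rel_pos` maps the TSS..TES span to `[0, 1]` and is NA for sites
#' assigned within a flank.
#'
#' @param sites a termination-site `GRanges` (see [read_bed()]).
#' @param genes a `GeneModelSet` or stranded `GRanges` of gene spans with
#'   a `gene_id` column.
#' @param upstream_flank,downstream_flank span extensions in bp,
#'   transcript orientation.
#' @return a `data.frame`, one row per input site in input order: `chrom`,
#'   `pos` (1-based), `strand`, `pa_status`, `count`, `gene_id` (NA when
#'   unassigned), `strand_match`, `d_tss`, `rel_pos`.
#' @export
assign_sites <- function(sites, genes, upstream_flank = 0,
                         downstream_flank = 0) {
  spans <- if (is(genes, "GeneModelSet")) gene_spans(genes) else genes
  str <- as.character(strand(spans))
  if (any(str == "*")) stop("genes must be stranded", call. = FALSE)
  gid <- as.character(mcols(spans)$gene_id)
  plus <- str == "+"
  ext <- GRanges(seqnames(spans),
                 IRanges(pmax(1L, start(spans) -
                                ifelse(plus, upstream_flank, downstream_flank)),
                         end(spans) +
                           ifelse(plus, downstream_flank, upstream_flank)),
                 strand = str)
  tss <- ifelse(plus, start(spans), end(spans))
  glen <- width(spans)

  hits <- findOverlaps(sites, ext, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  same <- as.character(strand(sites))[q] == str[s]
  q <- q[same]; s <- s[same]
  pos <- start(sites)[q]
  d <- ifelse(plus[s], pos - tss[s], tss[s] - pos)
  ## nearest-TSS rule, ties by gene_id
  o <- order(q, abs(d), gid[s], method = "radix")
  first <- !duplicated(q[o])
  qa <- q[o][first]; sa <- s[o][first]; da <- d[o][first]

  n <- length(sites)
  out <- data.frame(chrom = as.character(seqnames(sites)),
                    pos = start(sites),
                    strand = as.character(strand(sites)),
                    pa_status = mcols(sites)$pa_status %||% rep(NA, n),
                    count = mcols(sites)$count %||% rep(1L, n),
                    gene_id = NA_character_, strand_match = FALSE,
                    d_tss = NA_real_, rel_pos = NA_real_,
                    stringsAsFactors = FALSE)
  out$gene_id[qa] <- gid[sa]
  out$strand_match[qa] <- TRUE
  out$d_tss[qa] <- da
  rel <- ifelse(glen[sa] > 1, da / (glen[sa] - 1), 0)
  out$rel_pos[qa] <- ifelse(rel >= 0 & rel <= 1, rel, NA_real_)
  out
}

#' Premature-termination gene sets
#'
#' The premature set: expressed genes harboring at least one assigned site
#' of the given poly(A) status with `0 <= d_tss <= window` (the boundary is
#' inclusive); the background set is the remaining expressed genes.
#'
#' @param assignments output of [assign_sites()].
#' @param pa_status poly(A) status to count (default `"pA+,-"`).
#' @param window TSS-proximal window in bp (default 500).
#' @param expressed_genes character vector of expressed gene ids (e.g.
#'   genes with nonzero `base_mean` in a DE table).
#' @return list of class `PrematureSets`: `premature`, `background`,
#'   `pa_status`, `window`.
#' @export
premature_sets <- function(assignments, pa_status = "pA+,-", window = 500,
                           expressed_genes) {
  if (missing(expressed_genes) || length(expressed_genes) == 0)
    stop("expressed_genes must be a non-empty gene set", call. = FALSE)
  hit <- !is.na(assignments$gene_id) &
    assignments$pa_status == pa_status &
    assignments$d_tss >= 0 & assignments$d_tss <= window
  premature <- intersect(expressed_genes, unique(assignments$gene_id[hit]))
  structure(list(premature = sort(premature),
                 background = sort(setdiff(expressed_genes, premature)),
                 pa_status = pa_status, window = window),
            class = "PrematureSets")
}

#' @export
print.PrematureSets <- function(x, ...) {
  cat(sprintf("PrematureSets: %d premature / %d background (%s within %d bp)\n",
              length(x$premature), length(x$background), x$pa_status,
              x$window))
  invisible(x)
}

#' Per-bin frequency of unique termination sites along genes
#'
#' Sites are deduplicated at (chrom, pos, strand, pa_status), then counted
#' into the scale-regions grid of [metagene()] over each same-strand gene
#' (flank-extended); minus-strand genes are reversed so bin 1 is the 5'
#' flank. Profiles are returned per poly(A) status.
#'
#' @param sites a termination-site `GRanges`.
#' @param genes a `GeneModelSet` or stranded span `GRanges`.
#' @param body_bins,flank_bp,flank_bins grid geometry (see [metagene()]).
#' @return list with `profile` (matrix: pa_status x bins), `bin_type` and
#'   `n_sites` (unique in-grid site count per status).
#' @export
site_frequency_profile <- function(sites, genes, body_bins = 100,
                                   flank_bp = 2000, flank_bins = 40) {
  spans <- if (is(genes, "GeneModelSet")) gene_spans(genes) else genes
  key <- paste(seqnames(sites), start(sites), strand(sites),
               mcols(sites)$pa_status)
  sites <- sites[!duplicated(key)]
  statuses <- sort(unique(mcols(sites)$pa_status))
  n_bins <- body_bins + 2 * flank_bins
  prof <- matrix(0, nrow = length(statuses), ncol = n_bins,
                 dimnames = list(statuses, NULL))
  n_in <- setNames(numeric(length(statuses)), statuses)
  ext <- resize_both(granges(spans), flank_bp)
  strand(ext) <- strand(spans)
  hits <- findOverlaps(sites, ext, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  same <- as.character(strand(sites))[q] == as.character(strand(spans))[s]
  q <- q[same]; s <- s[same]
  counted <- rep(FALSE, length(sites))
  for (i in seq_along(q)) {
    g <- s[i]
    edges <- scale_region_edges(width(spans)[g], body_bins, flank_bp,
                                flank_bins)
    x <- start(sites)[q[i]] - (start(spans)[g] - flank_bp) + 0.5
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    if (b < 1 || b > n_bins) next
    if (as.character(strand(spans))[g] == "-") b <- n_bins + 1 - b
    st <- mcols(sites)$pa_status[q[i]]
    prof[st, b] <- prof[st, b] + 1
    counted[q[i]] <- TRUE
  }
  for (st in statuses)
    n_in[st] <- sum(counted & mcols(sites)$pa_status == st)
  bin_type <- factor(rep(c("upstream", "body", "downstream"),
                         c(flank_bins, body_bins, flank_bins)),
                     levels = c("upstream", "body", "downstream"))
  list(profile = prof, bin_type = bin_type, n_sites = n_in)
}

#' TSS-proximal termination counts stratified by gene length and expression
#'
#' Genes are cut into length x expression quantile cells; each cell
#' reports the mean TSS-proximal site count. Monotone trends are
#' summarised per covariate by a Spearman correlation of the per-gene
#' count against the covariate.
#'
#' @param assignments output of [assign_sites()].
#' @param genes a `GeneModelSet` or span `GRanges` with `gene_id`.
#' @param expression named non-negative vector keyed by gene_id.
#' @param n_quantiles quantile bins per covariate.
#' @param pa_status,window which sites count as TSS-proximal.
#' @return list with `cell_means` (length-quantile x expression-quantile
#'   matrix), `spearman_length`, `spearman_expression` (each: `rho`, `p`),
#'   and the per-gene `counts`.
#' @export
termination_vs_covariates <- function(assignments, genes, expression,
                                      n_quantiles = 5, pa_status = "pA+,-",
                                      window = 500) {
  spans <- if (is(genes, "GeneModelSet")) gene_spans(genes) else genes
  gid <- as.character(mcols(spans)$gene_id)
  if (length(gid) < n_quantiles)
    stop("fewer genes than quantiles", call. = FALSE)
  if (!all(gid %in% names(expression)))
    stop("expression missing for some genes", call. = FALSE)
  hit <- !is.na(assignments$gene_id) & assignments$pa_status == pa_status &
    assignments$d_tss >= 0 & assignments$d_tss <= window
  counts <- setNames(numeric(length(gid)), gid)
  tab <- table(assignments$gene_id[hit])
  counts[names(tab)] <- as.numeric(tab)
  len <- setNames(width(spans), gid)
  expr <- as.numeric(expression[gid])

  qcut <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_quantiles + 1)))
    if (length(br) < 2) return(rep(1L, length(x))) # degenerate covariate
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  lq <- qcut(len)
  eq <- qcut(expr)
  cell <- tapply(counts, list(length_q = lq, expr_q = eq), mean)
  sp <- function(x) {
    if (length(unique(x)) < 2 || length(unique(counts)) < 2)
      return(list(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(counts, x, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(cell_means = cell, spearman_length = sp(as.numeric(len)),
       spearman_expression = sp(expr), counts = counts)
}
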