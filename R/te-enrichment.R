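#' Filter a TE annotation by copy length and family copy number
#'
#' Mirrors the standard RepeatMasker pre-filter for family-level enrichment
#' work: copies shorter than `min_len` are removed first, then any family
#' left with fewer than `min_copies` surviving copies is dropped entirely.
#' Input order is preserved and the operation is idempotent.
#'
#' @param copies a TE `GRanges` (metadata columns `family`, `te_class`).
#' @param min_len minimum copy length in bp (default 50).
#' @param min_copies minimum surviving copies per family (default 50).
#' @return the filtered `GRanges` (possibly empty).
#' @export
filter_te_annotation <- function(copies, min_len = 50, min_copies = 50) {
  stopifnot(is(copies, "GRanges"))
  keep <- width(copies) >= min_len
  copies <- copies[keep]
  fam <- mcols(copies)$family
  tab <- table(fam)
  copies[fam %in% names(tab)[tab >= min_copies]]
}

#' Place length-matched random intervals across the genome
#'
#' The shuffled-interval background: every input interval is replaced by
#' one (or `n_draws`) intervals of identical length and strand placed
#' uniformly at random genome-wide — the chromosome is chosen with
#' probability proportional to its number of valid start positions
#' (`chrom_len - len + 1`) and the start uniformly among them. Mutual
#' overlaps are permitted, as with a default bedtools shuffle.
#'
#' @param copies a `GRanges`.
#' @param layout a [genome_layout()].
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param n_draws background draws per input interval.
#' @return a `GRanges` of `length(copies) * n_draws` shuffled intervals,
#'   carrying the input metadata columns (recycled per draw).
#' @export
shuffle_intervals <- function(copies, layout, seed = NULL, n_draws = 1) {
  stopifnot(is(copies, "GRanges"), n_draws >= 1)
  if (length(copies) && max(width(copies)) > max(layout))
    stop("copy longer than every chromosome", call. = FALSE)
  with_seed_or_stream(seed, {
    idx <- rep(seq_along(copies), n_draws)
    len <- width(copies)[idx]
    n <- length(len)
    if (n == 0) return(copies)
    ## vectorised placement: cumulative capacity over chromosomes
    caps <- outer(as.numeric(layout), len, function(L, w) pmax(L - w + 1, 0))
    tot <- colSums(caps)
    u <- runif(n) * tot
    cum <- matrix(apply(caps, 2, cumsum), nrow = nrow(caps))
    ci <- colSums(cum < rep(u, each = nrow(caps))) + 1L
    prior <- cum - caps # capacity before this chromosome
    offset <- u - prior[cbind(ci, seq_len(n))]
    start <- as.integer(ceiling(offset))
    out <- GRanges(names(layout)[ci], IRanges(start, width = len),
                   strand = strand(copies)[idx])
    mcols(out) <- mcols(copies)[idx, , drop = FALSE]
    out
  })
}

#' TE family enrichment against a shuffled-interval background
#'
#' For every family: the observed per-copy mean signal ([region_mean()])
#' is compared with the mean over length-matched shuffled intervals.
#' `log2_enrichment = log2((mean(obs) + eps) / (mean(bg) + eps))`, the
#' p-value is a two-sided unpaired Wilcoxon rank-sum of the per-copy
#' observed vs background values (normal approximation with tie and
#' continuity correction), and `padj` is Benjamini-Hochberg across
#' families.
#'
#' @param track a `CoverageTrack`.
#' @param copies TE `GRanges`, already passed [filter_te_annotation()].
#' @param layout a [genome_layout()].
#' @param seed seed for the shuffle.
#' @param pseudocount eps added to both means before the ratio (bounds the
#'   log-ratio on zero-signal families).
#' @param n_draws background draws per copy.
#' @return a `data.frame` with columns `family`, `n_copies`, `obs_mean`,
#'   `bg_mean`, `log2_enrichment`, `pvalue`, `padj`, ordered by family.
#'   Families with fewer than 2 copies are excluded with a warning.
#' @export
family_enrichment <- function(track, copies, layout, seed = NULL,
                              pseudocount = 1e-3, n_draws = 1) {
  stopifnot(is(copies, "GRanges"))
  assert_number(pseudocount, "pseudocount", lower = 0)
  fam <- mcols(copies)$family
  if (is.null(fam)) stop("copies need a 'family' column", call. = FALSE)
  small <- names(which(table(fam) < 2))
  if (length(small)) {
    warning("excluding families with < 2 copies: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(fam %in% small)
    copies <- copies[keep]
    fam <- fam[keep]
  }
  bg <- shuffle_intervals(copies, layout, seed = seed, n_draws = n_draws)
  obs_v <- region_mean(track, copies)
  bg_v <- region_mean(track, bg)
  bg_fam <- rep(fam, n_draws)
  families <- sort(unique(fam))
  res <- lapply(families, function(f) {
    o <- obs_v[fam == f]
    b <- bg_v[bg_fam == f]
    p <- rank_sum_p(o, b)
    data.frame(family = f, n_copies = length(o), obs_mean = mean(o),
               bg_mean = mean(b),
               log2_enrichment = log2((mean(o) + pseudocount) /
                                        (mean(b) + pseudocount)),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pvalue)
  out
}

#' Stratify TE families by basal chromatin state
#'
#' Given family-level enrichment tables for H3K9me3 and H3K27ac
#' ([family_enrichment()] output), each family is labeled `K9` if its
#' H3K9me3 record passes both cutoffs (`log2_enrichment > lfc_min` and
#' `padj < padj_max`, both strict), else `K27AC` if the H3K27ac record
#' passes, else `NEITHER`. H3K9me3 precedence makes the classes mutually
#' exclusive.
#'
#' @param k9_table,k27ac_table enrichment tables covering the same families.
#' @param lfc_min,padj_max stratification cutoffs.
#' @return a `data.frame` with columns `family` and `chromatin_class`.
#' @export
stratify_families <- function(k9_table, k27ac_table, lfc_min = 0.5,
                              padj_max = 0.05) {
  if (!setequal(k9_table$family, k27ac_table$family))
    stop("tables must cover the same families", call. = FALSE)
  k27 <- k27ac_table[match(k9_table$family, k27ac_table$family), ]
  pass9 <- k9_table$log2_enrichment > lfc_min & k9_table$padj < padj_max
  pass27 <- k27$log2_enrichment > lfc_min & k27$padj < padj_max
  data.frame(family = k9_table$family,
             chromatin_class = ifelse(pass9, "K9",
                                      ifelse(pass27, "K27AC", "NEITHER")),
             stringsAsFactors = FALSE)
}

#' Classify MERVL copies into full-length elements and solo LTRs
#'
#' A full-length element is an internal copy with a same-strand LTR within
#' `max_gap` bp (edge-to-edge) of its 5' edge and another within `max_gap`
#' of its 3' edge. Internals are processed in genomic order and each picks
#' its nearest unassigned qualifying LTR per side, so no LTR flanks two
#' elements and the result is invariant to input ordering. Solo LTRs are
#' those neither assigned as flanks nor lying within `max_gap` of a
#' full-length element's span.
#'
#' @param ltr_copies,internal_copies stranded TE `GRanges` (e.g. `MT2_Mm`
#'   and `MERVL-int` copies).
#' @param max_gap maximum edge-to-edge gap in bp (default 1000).
#' @return list with `full_length` (a `data.frame`: internal/5'/3' indices
#'   into the *sorted* inputs plus coordinates), `elements` (`GRanges`
#'   spanning 5' LTR start to 3' LTR end) and `solo_ltrs` (`GRanges`).
#' @export
classify_mervl_structure <- function(ltr_copies, internal_copies,
                                     max_gap = 1000) {
  stopifnot(is(ltr_copies, "GRanges"), is(internal_copies, "GRanges"))
  ltr <- sort(ltr_copies)
  int <- sort(internal_copies)
  used <- logical(length(ltr))
  rows <- list()
  lchr <- as.character(seqnames(ltr)); lstr <- as.character(strand(ltr))
  for (i in seq_along(int)) {
    ch <- as.character(seqnames(int))[i]
    st <- as.character(strand(int))[i]
    cand <- which(lchr == ch & lstr == st & !used)
    if (!length(cand)) next
    gap_left <- start(int)[i] - end(ltr)[cand] - 1L   # LTR upstream in genome
    gap_right <- start(ltr)[cand] - end(int)[i] - 1L  # LTR downstream
    left_ok <- cand[gap_left >= 0 & gap_left <= max_gap]
    right_ok <- cand[gap_right >= 0 & gap_right <= max_gap]
    if (!length(left_ok) || !length(right_ok)) next
    li <- left_ok[which.min(start(int)[i] - end(ltr)[left_ok])]
    ri <- right_ok[which.min(start(ltr)[right_ok] - end(int)[i])]
    used[c(li, ri)] <- TRUE
    ## 5' flank is the genomically-left LTR on +, the right one on -
    five <- if (st == "-") ri else li
    three <- if (st == "-") li else ri
    rows[[length(rows) + 1L]] <-
      data.frame(internal = i, ltr5 = five, ltr3 = three, chrom = ch,
                 start = start(ltr)[li], end = end(ltr)[ri], strand = st,
                 stringsAsFactors = FALSE)
  }
  fl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(internal = integer(0), ltr5 = integer(0), ltr3 = integer(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  elements <- GRanges(fl$chrom, IRanges(fl$start, fl$end), strand = fl$strand)
  free <- ltr[!used]
  near_fl <- overlapsAny(resize_both(free, max_gap), elements,
                         ignore.strand = TRUE)
  list(full_length = fl, elements = elements, solo_ltrs = free[!near_fl])
}
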