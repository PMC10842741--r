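#' Segment a coverage track into transcription units
#'
#' A deliberately simple threshold segmenter (not a hidden-Markov
#' segmentation): maximal runs with signal at or above `threshold`, runs
#' separated by fewer than `max_gap` bp merged, results shorter than
#' `min_len` dropped. Apply per strand to a strand-resolved track pair.
#'
#' @param track a `CoverageTrack`.
#' @param threshold signal cutoff (> 0).
#' @param min_len minimum TU length in bp.
#' @param max_gap merge runs separated by fewer than this many bp.
#' @param strand strand stamped on the output (`"+"`, `"-"` or `"*"`).
#' @return a `GRanges` of unlabeled TUs with a `tu_id` column.
#' @export
segment_tus <- function(track, threshold, min_len = 200, max_gap = 200,
                        strand = "*") {
  assert_number(threshold, "threshold")
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  out <- GRanges()
  for (ch in names(track$cov)) {
    ir <- ranges(slice(track$cov[[ch]], lower = threshold,
                       includeLower = TRUE))
    if (max_gap > 1) ir <- reduce(ir, min.gapwidth = max_gap)
    ir <- ir[width(ir) >= min_len]
    if (length(ir))
      out <- c(out, GRanges(ch, ir, strand = strand))
  }
  if (length(out)) mcols(out)$tu_id <- sprintf("TU%04d", seq_along(out))
  out
}

#' Classify transcription units into genic, PROMPT, eRNA and other
#'
#' The filter cascade, applied in a fixed order: (1) TUs fully containing
#' at least one same-strand transcript are genic (reason
#' `contains_transcript`); (2) TUs whose total same-strand overlap with
#' the merged transcript cover is at least `genic_bp` bp *or* at least
#' `genic_frac` of the TU length are genic (reason
#' `overlap_3kb_or_25pct`); among survivors, (3) a TU within `prompt_dist`
#' bp (edge-to-edge, boundary inclusive) of a TSS on the antisense strand
#' is a PROMPT, (4) else a TU within `enh_dist` bp of an enhancer is an
#' eRNA, (5) else `other`. PROMPT takes precedence over eRNA; both
#' evidence distances are reported so users can re-label.
#'
#' @param tus stranded `GRanges` of TUs (unstranded input is an error).
#' @param transcripts a `GeneModelSet` or stranded `GRanges` of transcript
#'   spans.
#' @param enhancers `GRanges` of enhancer intervals.
#' @param tss optional `GRanges` of TSS points; derived from `transcripts`
#'   when NULL.
#' @param genic_bp,genic_frac,enh_dist,prompt_dist cascade thresholds.
#' @return the TUs with metadata columns `label`, `discard_reason`,
#'   `d_antisense_tss` and `d_enhancer` added.
#' @export
classify_tus <- function(tus, transcripts, enhancers, tss = NULL,
                         genic_bp = 3000, genic_frac = 0.25,
                         enh_dist = 500, prompt_dist = 1000) {
  if (any(as.character(strand(tus)) == "*"))
    stop("TUs must be stranded", call. = FALSE)
  tx <- if (is(transcripts, "GeneModelSet")) tx_spans(transcripts) else transcripts
  if (any(as.character(strand(tx)) == "*"))
    stop("transcripts must be stranded", call. = FALSE)
  tss <- tss %||% tss_sites(tx)
  n <- length(tus)

  ## (1) full same-strand containment of a transcript (query-within-subject,
  ## so transcripts are the query here)
  hit <- findOverlaps(tx, tus, type = "within", ignore.strand = TRUE)
  same <- as.character(strand(tx))[queryHits(hit)] ==
    as.character(strand(tus))[subjectHits(hit)]
  contains <- logical(n)
  contains[unique(subjectHits(hit)[same])] <- TRUE

  ## (2) aggregate same-strand overlap against the merged transcript cover
  ov_bp <- numeric(n)
  for (s in c("+", "-")) {
    cover <- reduce(granges(tx)[as.character(strand(tx)) == s],
                    ignore.strand = TRUE)
    i <- which(as.character(strand(tus)) == s)
    if (!length(i)) next
    h <- findOverlaps(tus[i], cover, ignore.strand = TRUE)
    if (length(h)) {
      w <- width(pintersect(ranges(tus[i])[queryHits(h)],
                            ranges(cover)[subjectHits(h)]))
      ov_bp[i] <- ov_bp[i] +
        as.numeric(tapply(w, factor(queryHits(h), seq_along(i)), sum,
                          default = 0))
    }
  }
  substantial <- !contains &
    (ov_bp >= genic_bp | ov_bp >= genic_frac * width(tus))

  ## evidence distances (edge-to-edge gaps; 0 when overlapping)
  d_tss <- rep(NA_real_, n)
  for (s in c("+", "-")) {
    anti <- tss[as.character(strand(tss)) != s]
    i <- which(as.character(strand(tus)) == s)
    if (!length(i) || !length(anti)) next
    dn <- distanceToNearest(tus[i], anti, ignore.strand = TRUE)
    d_tss[i[queryHits(dn)]] <- mcols(dn)$distance
  }
  d_enh <- rep(NA_real_, n)
  if (length(enhancers)) {
    dn <- distanceToNearest(tus, enhancers, ignore.strand = TRUE)
    d_enh[queryHits(dn)] <- mcols(dn)$distance
  }

  label <- rep("other", n)
  reason <- rep("none", n)
  label[contains] <- "genic"; reason[contains] <- "contains_transcript"
  label[substantial] <- "genic"; reason[substantial] <- "overlap_3kb_or_25pct"
  free <- label == "other"
  is_prompt <- free & !is.na(d_tss) & d_tss <= prompt_dist
  label[is_prompt] <- "PROMPT"
  is_erna <- free & !is_prompt & !is.na(d_enh) & d_enh <= enh_dist
  label[is_erna] <- "eRNA"

  out <- tus
  mcols(out)$label <- label
  mcols(out)$discard_reason <- reason
  mcols(out)$d_antisense_tss <- d_tss
  mcols(out)$d_enhancer <- d_enh
  out
}

#' Tabulate labeled transcription units
#'
#' @param tus labeled TUs from [classify_tus()] (with a `tu_id` column).
#' @param de_table optional DE table joined on `tu_id` = `feature_id`.
#' @return list with `counts` (label table), `lengths` (per-label n,
#'   median and mean width) and, when a DE table is given, `joined` (one
#'   row per TU; missing features carry NA statistics).
#' @export
tu_summary <- function(tus, de_table = NULL) {
  ids <- mcols(tus)$tu_id
  if (!is.null(ids) && anyDuplicated(ids))
    stop("duplicate TU ids", call. = FALSE)
  lab <- factor(mcols(tus)$label,
                levels = c("genic", "PROMPT", "eRNA", "other"))
  counts <- table(label = lab)
  lengths <- do.call(rbind, lapply(levels(lab), function(l) {
    w <- width(tus)[lab == l]
    data.frame(label = l, n = length(w),
               median_len = if (length(w)) median(w) else NA_real_,
               mean_len = if (length(w)) mean(w) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(counts = counts, lengths = lengths)
  if (!is.null(de_table)) {
    m <- match(ids, de_table$feature_id)
    out$joined <- data.frame(tu_id = ids, label = as.character(lab),
                             log2fc = de_table$log2fc[m],
                             stat = de_table$stat[m],
                             padj = de_table$padj[m],
                             stringsAsFactors = FALSE)
  }
  out
}
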