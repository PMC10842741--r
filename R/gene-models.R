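#' Multi-isoform gene models
#'
#' A `GeneModelSet` holds exon-resolved transcript structures grouped by
#' gene, with strand-aware TSS/TES accessors. All isoforms of a gene live
#' on one chromosome and strand; each isoform's exons are sorted and
#' non-overlapping. The transcription start site of a minus-strand gene is
#' the *last* base of its span.
#'
#' @param exons a `GRanges` with metadata columns `tx_id` and `gene_id`,
#'   one range per exon.
#' @param biotype a single biotype applied to all genes, or a named vector
#'   keyed by gene_id. Default `"protein_coding"`.
#' @param major_isoform optional named character vector gene_id -> tx_id;
#'   see [select_major_isoform()].
#' @return a `GeneModelSet`.
#' @export
gene_model_set <- function(exons, biotype = "protein_coding",
                           major_isoform = NULL) {
  stopifnot(is(exons, "GRanges"))
  mc <- mcols(exons)
  if (!all(c("tx_id", "gene_id") %in% names(mc)))
    stop("exons need 'tx_id' and 'gene_id' metadata columns", call. = FALSE)
  if (length(exons) == 0) stop("no exons given", call. = FALSE)
  if (any(as.character(strand(exons)) == "*"))
    stop("gene models must be stranded (+ or -)", call. = FALSE)
  o <- order(mc$tx_id, start(exons))
  exons <- exons[o]
  mc <- mcols(exons)
  tx_id <- as.character(mc$tx_id)
  gene_id <- as.character(mc$gene_id)

  chr <- as.character(seqnames(exons))
  str <- as.character(strand(exons))
  first <- !duplicated(tx_id)
  tx_chr <- chr[first]; names(tx_chr) <- tx_id[first]
  tx_str <- str[first]; names(tx_str) <- tx_id[first]
  if (any(chr != tx_chr[tx_id]) || any(str != tx_str[tx_id]))
    stop("isoform with exons on mixed chromosomes or strands", call. = FALSE)
  ## non-overlap within each (sorted) isoform
  same_tx <- tx_id[-1] == tx_id[-length(tx_id)]
  if (any(same_tx & start(exons)[-1] <= end(exons)[-length(exons)]))
    stop("overlapping or unsorted exons within an isoform", call. = FALSE)

  tx <- data.frame(
    tx_id = tx_id[first],
    gene_id = gene_id[first],
    chrom = tx_chr[tx_id[first]],
    strand = tx_str[tx_id[first]],
    start = as.integer(tapply(start(exons), tx_id, min)[tx_id[first]]),
    end = as.integer(tapply(end(exons), tx_id, max)[tx_id[first]]),
    n_exons = as.integer(table(tx_id)[tx_id[first]]),
    row.names = NULL, stringsAsFactors = FALSE)
  dup <- duplicated(paste(tx$gene_id, tx$tx_id))
  if (any(dup)) stop("duplicate tx_id within a gene", call. = FALSE)

  gfirst <- !duplicated(tx$gene_id)
  genes <- data.frame(gene_id = tx$gene_id[gfirst], chrom = tx$chrom[gfirst],
                      strand = tx$strand[gfirst], row.names = NULL,
                      stringsAsFactors = FALSE)
  mixed <- tapply(tx$strand, tx$gene_id, function(s) length(unique(s)) > 1) |
    tapply(tx$chrom, tx$gene_id, function(s) length(unique(s)) > 1)
  if (any(mixed))
    stop("gene with isoforms on mixed strands or chromosomes: ",
         names(mixed)[which(mixed)[1]], call. = FALSE)
  genes$biotype <- if (length(biotype) == 1L && is.null(names(biotype)))
    rep(biotype, nrow(genes)) else unname(biotype[genes$gene_id])
  genes$major_isoform <- if (is.null(major_isoform)) NA_character_ else
    unname(major_isoform[genes$gene_id])

  structure(list(genes = genes, tx = tx, exons = exons),
            class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat(sprintf("GeneModelSet: %d gene(s), %d isoform(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$tx), length(x$exons)))
  invisible(x)
}

#' Transcript and gene spans
#'
#' `tx_spans` returns one range per isoform. `gene_spans` returns one range
#' per gene, taken from the major isoform (which must have been set, e.g.
#' by [select_major_isoform()]), with `n_exons`, `biotype` and the
#' strand-aware `tss`/`tes` base positions in the metadata columns.
#'
#' @param gm a `GeneModelSet`.
#' @return a `GRanges`.
#' @export
tx_spans <- function(gm) {
  GRanges(gm$tx$chrom, IRanges(gm$tx$start, gm$tx$end), strand = gm$tx$strand,
          tx_id = gm$tx$tx_id, gene_id = gm$tx$gene_id,
          n_exons = gm$tx$n_exons)
}

#' @rdname tx_spans
#' @export
gene_spans <- function(gm) {
  if (anyNA(gm$genes$major_isoform))
    stop("major isoform not set; call select_major_isoform() first",
         call. = FALSE)
  tx <- gm$tx[match(gm$genes$major_isoform, gm$tx$tx_id), ]
  gr <- GRanges(tx$chrom, IRanges(tx$start, tx$end), strand = tx$strand,
                gene_id = gm$genes$gene_id, tx_id = tx$tx_id,
                n_exons = tx$n_exons, biotype = gm$genes$biotype)
  mcols(gr)$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  mcols(gr)$tes <- ifelse(tx$strand == "+", tx$end, tx$start)
  gr
}

#' Strand-aware TSS / TES points of stranded spans
#'
#' On the plus strand the TSS is the first base of the span; on the minus
#' strand it is the last base. The TES is the opposite boundary.
#'
#' @param spans a stranded `GRanges`.
#' @return a width-1 `GRanges` carrying the input metadata columns.
#' @export
tss_sites <- function(spans) {
  pos <- ifelse(as.character(strand(spans)) == "+", start(spans), end(spans))
  out <- GRanges(seqnames(spans), IRanges(pos, pos), strand = strand(spans))
  mcols(out) <- mcols(spans)
  out
}

#' @rdname tss_sites
#' @export
tes_sites <- function(spans) {
  pos <- ifelse(as.character(strand(spans)) == "+", end(spans), start(spans))
  out <- GRanges(seqnames(spans), IRanges(pos, pos), strand = strand(spans))
  mcols(out) <- mcols(spans)
  out
}

#' Select the major isoform of every gene
#'
#' With isoform expression: the highest-expressed isoform, ties broken by
#' longer genomic span, then lexicographically smaller tx_id. Without
#' expression: longest span, ties broken by smaller tx_id.
#'
#' @param gm a `GeneModelSet`.
#' @param isoform_expression optional named numeric vector keyed by tx_id.
#' @return the `GeneModelSet` with `major_isoform` filled in.
#' @export
select_major_isoform <- function(gm, isoform_expression = NULL) {
  tx <- gm$tx
  expr <- if (is.null(isoform_expression)) rep(0, nrow(tx)) else {
    e <- isoform_expression[tx$tx_id]
    if (anyNA(e)) stop("expression missing for some isoforms", call. = FALSE)
    as.numeric(e)
  }
  span <- tx$end - tx$start + 1L
  o <- order(tx$gene_id, -expr, -span, tx$tx_id, method = "radix")
  best <- tx[o, ][!duplicated(tx$gene_id[o]), ]
  gm$genes$major_isoform <- best$tx_id[match(gm$genes$gene_id, best$gene_id)]
  gm
}

#' Read gene models from BED12 or GTF
#'
#' BED12 block structure becomes exons; the name field may encode
#' `gene_id|tx_id` (a bare name is used as both). GTF input is restricted
#' to `transcript`/`exon` features with `gene_id`/`transcript_id`
#' attributes; its 1-based inclusive coordinates are handled by the
#' importer. A transcript declared without exons, or a gene whose isoforms
#' sit on both strands, is an error.
#'
#' @param path input file.
#' @param format `"bed12"` or `"gtf"`.
#' @param biotype default biotype for BED12 input (GTF may carry
#'   `gene_biotype`).
#' @return a `GeneModelSet`.
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf"),
                             biotype = "protein_coding") {
  format <- match.arg(format)
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(mcols(gr)$blocks))
      stop("not a BED12 file (no block structure): ", path, call. = FALSE)
    ids <- parse_gene_tx(mcols(gr)$name)
    blocks <- mcols(gr)$blocks
    per_tx <- elementNROWS(blocks)
    if (any(per_tx == 0)) stop("transcript with zero exons", call. = FALSE)
    rel <- unlist(blocks)
    exons <- GRanges(rep(seqnames(gr), per_tx),
                     IRanges(rep(start(gr), per_tx) + start(rel) - 1L,
                             rep(start(gr), per_tx) + end(rel) - 1L),
                     strand = rep(strand(gr), per_tx),
                     tx_id = rep(ids$tx_id, per_tx),
                     gene_id = rep(ids$gene_id, per_tx))
    gene_model_set(exons, biotype = biotype)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- mcols(gr)
    ex <- gr[mc$type == "exon"]
    declared <- unique(as.character(mcols(gr)$transcript_id[mc$type == "transcript"]))
    missing_ex <- setdiff(declared, unique(as.character(mcols(ex)$transcript_id)))
    if (length(missing_ex))
      stop("transcript with zero exons: ", missing_ex[1], call. = FALSE)
    if (length(ex) == 0) stop("no exon features in GTF", call. = FALSE)
    bt <- if ("gene_biotype" %in% names(mcols(ex))) {
      b <- as.character(mcols(ex)$gene_biotype)
      b[is.na(b)] <- biotype
      setNames(b, as.character(mcols(ex)$gene_id))
    } else biotype
    exons <- GRanges(seqnames(ex), ranges(ex), strand = strand(ex),
                     tx_id = as.character(mcols(ex)$transcript_id),
                     gene_id = as.character(mcols(ex)$gene_id))
    gene_model_set(exons, biotype = bt)
  }
}

parse_gene_tx <- function(name) {
  parts <- strsplit(as.character(name), "|", fixed = TRUE)
  tx <- vapply(parts, function(p) p[length(p)], "")
  gene <- vapply(parts, `[`, "", 1L)
  list(gene_id = gene, tx_id = tx)
}

#' Write a `GeneModelSet` as BED12
#'
#' One row per isoform, name field `gene_id|tx_id`.
#'
#' @param gm a `GeneModelSet`.
#' @param path output path.
#' @export
write_bed12 <- function(gm, path) {
  rows <- character(nrow(gm$tx))
  ex_tx <- as.character(mcols(gm$exons)$tx_id)
  for (i in seq_len(nrow(gm$tx))) {
    t <- gm$tx[i, ]
    ex <- gm$exons[ex_tx == t$tx_id]
    sizes <- paste0(paste(width(ex), collapse = ","), ",")
    starts <- paste0(paste(start(ex) - t$start, collapse = ","), ",")
    rows[i] <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                       t$chrom, t$start - 1L, t$end, t$gene_id, t$tx_id,
                       t$strand, t$start - 1L, t$end, t$n_exons, sizes, starts)
  }
  writeLines(rows, path)
  invisible(path)
}
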