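#' Genome layout: chromosome names and lengths
#'
#' A minimal stand-in for a chromosome-sizes file: a named vector mapping
#' chromosome name to length in bp.
#'
#' @param lengths named numeric vector of positive chromosome lengths.
#' @return a `GenomeLayout` (named integer-valued numeric vector).
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)) ||
      any(!nzchar(names(lengths))))
    stop("chromosome names must be present and unique", call. = FALSE)
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers", call. = FALSE)
  structure(as.double(lengths), names = names(lengths), class = "GenomeLayout")
}

#' @rdname genome_layout
#' @param path two-column TSV (chrom, length), no header.
#' @export
read_genome_layout <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "length"))
  genome_layout(setNames(x$length, x$chrom))
}

#' @rdname genome_layout
#' @param layout a `GenomeLayout`.
#' @export
write_genome_layout <- function(layout, path) {
  writeLines(sprintf("%s\t%d", names(layout), as.integer(layout)), path)
  invisible(path)
}

check_against_layout <- function(gr, layout, what = "interval") {
  if (is.null(layout)) return(invisible(gr))
  chr <- as.character(seqnames(gr))
  bad <- !(chr %in% names(layout))
  if (any(bad))
    stop(sprintf("%s on unknown chromosome '%s'", what, chr[which(bad)[1]]),
         call. = FALSE)
  over <- end(gr) > layout[chr]
  if (any(over))
    stop(sprintf("%s extends beyond chromosome end (%s:%d-%d)", what,
                 chr[which(over)[1]], start(gr)[which(over)[1]],
                 end(gr)[which(over)[1]]), call. = FALSE)
  invisible(gr)
}

TE_CLASSES <- c("LTR", "LINE", "SINE", "DNA", "other")
PA_STATUSES <- c("pA+", "pA+,-")

#' Read a BED6 file into a `GRanges`
#'
#' Three record kinds share the BED6 layout. `kind = "te"` expects the name
#' field to encode `family|class` (RepeatMasker-style metadata; class one of
#' LTR, LINE, SINE, DNA, other). `kind = "termination"` expects single-base
#' records whose name field is the poly(A) status (`pA+` or `pA+,-`) and
#' whose score is the read count. BED coordinates (0-based half-open) are
#' converted to the 1-based closed `GRanges` convention on read.
#'
#' @param path BED6 file; `#`/`track` lines and blank lines are skipped.
#' @param kind one of `"interval"`, `"te"`, `"termination"`.
#' @param layout optional [genome_layout()]; when given, records must lie
#'   within their chromosome.
#' @return `GRanges` with metadata columns `name`/`score` (interval),
#'   `family`/`te_class` (te) or `pa_status`/`count` (termination).
#' @export
read_bed <- function(path, kind = c("interval", "te", "termination"),
                     layout = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (!length(idx)) return(empty_bed(kind))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop_at_line(path, idx[which(nf < 6)[1]], "expected at least 6 BED columns")
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) stop_at_line(path, idx[which(bad)[1]], "non-numeric coordinates")
  bad <- start0 < 0 | start0 >= end0
  if (any(bad))
    stop_at_line(path, idx[which(bad)[1]], "requires 0 <= start < end")
  strand <- m[, 6]
  bad <- !(strand %in% c("+", "-", "."))
  if (any(bad)) stop_at_line(path, idx[which(bad)[1]], "bad strand field")
  score <- suppressWarnings(as.numeric(m[, 5]))
  bad <- is.na(score)
  if (any(bad)) stop_at_line(path, idx[which(bad)[1]], "non-numeric score")
  gr <- GRanges(m[, 1], IRanges(start0 + 1, end0),
                strand = ifelse(strand == ".", "*", strand))
  if (kind == "te") {
    parts <- strsplit(m[, 4], "|", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop_at_line(path, idx[which(bad)[1]],
                   "TE name must encode 'family|class'")
    fam <- vapply(parts, `[`, "", 1L)
    cls <- vapply(parts, `[`, "", 2L)
    bad <- !nzchar(fam)
    if (any(bad)) stop_at_line(path, idx[which(bad)[1]], "empty TE family")
    bad <- !(cls %in% TE_CLASSES)
    if (any(bad))
      stop_at_line(path, idx[which(bad)[1]],
                   paste0("unknown te_class (expected one of ",
                          paste(TE_CLASSES, collapse = ", "), ")"))
    mcols(gr)$family <- fam
    mcols(gr)$te_class <- cls
  } else if (kind == "termination") {
    bad <- width(gr) != 1L
    if (any(bad))
      stop_at_line(path, idx[which(bad)[1]],
                   "termination sites must be single-base (end = start + 1)")
    bad <- !(m[, 4] %in% PA_STATUSES)
    if (any(bad))
      stop_at_line(path, idx[which(bad)[1]],
                   "poly(A) status must be 'pA+' or 'pA+,-'")
    bad <- score < 0 | score != floor(score)
    if (any(bad))
      stop_at_line(path, idx[which(bad)[1]], "count must be a non-negative integer")
    mcols(gr)$pa_status <- m[, 4]
    mcols(gr)$count <- as.integer(score)
  } else {
    mcols(gr)$name <- m[, 4]
    mcols(gr)$score <- score
  }
  check_against_layout(gr, layout, "BED record")
  gr
}

empty_bed <- function(kind) {
  gr <- GRanges()
  if (kind == "te") {
    mcols(gr)$family <- character(0)
    mcols(gr)$te_class <- character(0)
  } else if (kind == "termination") {
    mcols(gr)$pa_status <- character(0)
    mcols(gr)$count <- integer(0)
  } else {
    mcols(gr)$name <- character(0)
    mcols(gr)$score <- numeric(0)
  }
  gr
}

#' Write a `GRanges` as BED6
#'
#' The record kind is inferred from the metadata columns (see [read_bed()]);
#' `write_bed(read_bed(f), g)` reproduces `f` up to whitespace.
#'
#' @param gr a `GRanges` as returned by [read_bed()].
#' @param path output path.
#' @param header optional character vector written as `#` comment lines.
#' @export
write_bed <- function(gr, path, header = NULL) {
  mc <- mcols(gr)
  if ("family" %in% names(mc)) {
    name <- paste0(mc$family, "|", mc$te_class)
    score <- rep(0, length(gr))
  } else if ("pa_status" %in% names(mc)) {
    name <- mc$pa_status
    score <- mc$count
  } else {
    name <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", length(gr))
    score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  }
  strand <- as.character(strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", as.character(seqnames(gr)),
                   start(gr) - 1L, end(gr), name, format_num(score), strand)
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

## stable numeric formatting shared by all writers (deterministic output)
format_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[x == floor(x) & abs(x) < 1e15] <-
    sprintf("%d", as.integer(x[x == floor(x) & abs(x) < 1e15]))
  out
}

#' Read and write differential-expression tables
#'
#' The table layout mirrors a DESeq2 result dump with explicit feature
#' typing: columns `feature_id`, `feature_kind` (gene / te_family / tu),
#' `biotype`, `base_mean`, `log2fc`, `stat`, `pvalue`, `padj`. Invariants
#' checked on read: `padj >= pvalue` (the step-up property of
#' Benjamini-Hochberg), and `stat` agreeing in sign with `log2fc` when both
#' are nonzero.
#'
#' @param path TSV file with a header (`#` comment lines allowed).
#' @return a `data.frame` with the columns above.
#' @export
read_de_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        skip = find_skip(path)))
  validate_de_table(df)
}

find_skip <- function(path) {
  lines <- readLines(path, n = 50L)
  sum(cumprod(startsWith(lines, "#")))
}

#' @rdname read_de_table
#' @param df a DE table.
#' @export
validate_de_table <- function(df) {
  need <- c("feature_id", "feature_kind", "biotype", "base_mean", "log2fc",
            "stat", "pvalue", "padj")
  if (!identical(names(df)[seq_along(need)], need))
    stop("DE table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id", call. = FALSE)
  if (!all(df$feature_kind %in% c("gene", "te_family", "tu")))
    stop("feature_kind must be gene, te_family or tu", call. = FALSE)
  if (any(df$base_mean < 0)) stop("base_mean must be >= 0", call. = FALSE)
  ok <- is.finite(df$pvalue) & is.finite(df$padj)
  if (any(df$pvalue[ok] < 0 | df$pvalue[ok] > 1 | df$padj[ok] < 0 | df$padj[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(df$padj[ok] < df$pvalue[ok] - 1e-12))
    stop("padj < pvalue violates the BH step-up property", call. = FALSE)
  nz <- df$stat != 0 & df$log2fc != 0
  if (any(sign(df$stat[nz]) != sign(df$log2fc[nz])))
    stop("stat and log2fc disagree in sign", call. = FALSE)
  df
}

#' @rdname read_de_table
#' @param header optional character vector written as `#` comment lines.
#' @export
write_de_table <- function(df, path, header = NULL) {
  validate_de_table(df)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Pairwise overlap length between two interval vectors
#'
#' Elementwise (recycled) overlap in bp between `a[i]` and `b[i]`: zero when
#' chromosomes differ or, with `same_strand_only`, when strands differ.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @param same_strand_only require identical strand for a nonzero overlap.
#' @return integer vector of overlap widths.
#' @export
overlap_length <- function(a, b, same_strand_only = FALSE) {
  assert_flag(same_strand_only, "same_strand_only")
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ov[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  if (same_strand_only)
    ov[as.character(strand(a)) != as.character(strand(b))] <- 0L
  ov
}
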