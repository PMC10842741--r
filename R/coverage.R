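#' Coverage tracks: non-negative step functions over the genome
#'
#' A `CoverageTrack` stores, per chromosome, a run-length encoded step
#' function (the in-memory abstraction of a bedGraph/BigWig). Values are
#' non-negative, finite signal densities per bp; uncovered positions have
#' implicit value 0. Strand-resolved signal is represented as two tracks
#' (conventionally a `.plus`/`.minus` file pair); unstranded analyses use
#' their sum via [track_add()].
#'
#' @param segments a `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based, closed) and `value`, or a `GRanges` with a `value` (or
#'   `score`) metadata column. Segments must be non-overlapping.
#' @param layout optional [genome_layout()] fixing chromosome lengths;
#'   without it each chromosome extends to the last covered base.
#' @return a `CoverageTrack`.
#' @export
coverage_track <- function(segments, layout = NULL) {
  if (is(segments, "GRanges")) {
    val <- mcols(segments)$value %||% mcols(segments)$score
    if (is.null(val)) stop("GRanges needs a 'value' or 'score' column", call. = FALSE)
    segments <- data.frame(chrom = as.character(seqnames(segments)),
                           start = start(segments), end = end(segments),
                           value = as.numeric(val))
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segments)))
  if (any(!is.finite(segments$value)) || any(segments$value < 0))
    stop("coverage values must be finite and >= 0", call. = FALSE)
  if (any(segments$start < 1 | segments$end < segments$start))
    stop("bad segment coordinates", call. = FALSE)
  cov <- list()
  chroms <- unique(segments$chrom)
  if (!is.null(layout)) {
    bad <- setdiff(chroms, names(layout))
    if (length(bad)) stop("segment on unknown chromosome: ", bad[1], call. = FALSE)
  }
  for (ch in chroms) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", ch, call. = FALSE)
    len <- if (!is.null(layout)) layout[[ch]] else max(s$end)
    if (max(s$end) > len)
      stop("segment beyond chromosome end on ", ch, call. = FALSE)
    ## interleave zero-valued gaps with the segments, then run-length encode
    gap_w <- s$start - c(0, head(s$end, -1)) - 1
    vals <- c(as.vector(rbind(0, s$value)), 0)
    widths <- c(as.vector(rbind(gap_w, s$end - s$start + 1)), len - max(s$end))
    keep <- widths > 0
    cov[[ch]] <- Rle(vals[keep], widths[keep])
  }
  if (!is.null(layout)) {
    for (ch in setdiff(names(layout), chroms))
      cov[[ch]] <- Rle(0, layout[[ch]])
    cov <- cov[names(layout)]
  }
  structure(list(cov = cov, layout = layout), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$cov), "chromosome(s)\n")
  for (ch in names(x$cov))
    cat(sprintf("  %s: length %d, %d run(s), mean %.4g\n", ch,
                length(x$cov[[ch]]), nrun(x$cov[[ch]]), mean(x$cov[[ch]])))
  invisible(x)
}

## build a track directly from per-chromosome Rle vectors (internal)
track_from_rle <- function(rle_list, layout = NULL) {
  structure(list(cov = rle_list, layout = layout), class = "CoverageTrack")
}

#' Sum of two coverage tracks
#'
#' Used to combine the two strands of a strand-resolved track pair for
#' unstranded analyses.
#'
#' @param a,b `CoverageTrack`s over the same genome.
#' @return a `CoverageTrack`.
#' @export
track_add <- function(a, b) {
  chroms <- union(names(a$cov), names(b$cov))
  cov <- list()
  for (ch in chroms) {
    ra <- a$cov[[ch]]
    rb <- b$cov[[ch]]
    if (is.null(ra)) { cov[[ch]] <- rb; next }
    if (is.null(rb)) { cov[[ch]] <- ra; next }
    n <- max(length(ra), length(rb))
    pad <- function(r) if (length(r) < n) c(r, Rle(0, n - length(r))) else r
    cov[[ch]] <- pad(ra) + pad(rb)
  }
  track_from_rle(cov, a$layout %||% b$layout)
}

#' Scale a coverage track by a positive constant
#' @param track a `CoverageTrack`.
#' @param factor positive scalar.
#' @return a `CoverageTrack`.
#' @export
track_scale <- function(track, factor) {
  assert_number(factor, "factor", lower = 0)
  track_from_rle(lapply(track$cov, function(r) r * factor), track$layout)
}

#' Read and write bedGraph files
#'
#' Reading validates that segments do not overlap and values are
#' non-negative. Writing emits sorted segments, coalesces adjacent
#' equal-value runs, and omits zero-valued runs (uncovered positions are
#' implicit), so a written file re-reads to the identical track.
#'
#' @param path a 4-column bedGraph file.
#' @param layout optional [genome_layout()].
#' @return [read_bedgraph()]: a `CoverageTrack`.
#' @export
read_bedgraph <- function(path, layout = NULL) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "value"))
  if (any(x$value < 0)) stop("negative bedGraph value", call. = FALSE)
  coverage_track(data.frame(chrom = x$chrom, start = x$start + 1,
                            end = x$end, value = x$value), layout = layout)
}

#' @rdname read_bedgraph
#' @param track a `CoverageTrack`.
#' @param header optional character vector written as `#` comment lines.
#' @export
write_bedgraph <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    ends <- cumsum(runLength(r))
    starts <- c(0, head(ends, -1L))
    vals <- runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                       as.integer(ends[keep]), format_num(vals[keep])), con)
  }
  invisible(path)
}

#' Mean signal over genomic intervals
#'
#' The per-bp mean of the track over each interval (integral divided by
#' interval width) — the semantics of deepTools' `multiBigwigSummary`.
#' Intervals over uncovered ground, or on chromosomes absent from the
#' track, have mean 0.
#'
#' @param track a `CoverageTrack`.
#' @param regions a `GRanges`.
#' @return numeric vector, one mean per region.
#' @export
region_mean <- function(track, regions) {
  check_against_layout(regions, track$layout, "region")
  out <- numeric(length(regions))
  chr <- as.character(seqnames(regions))
  for (ch in unique(chr)) {
    r <- track$cov[[ch]]
    if (is.null(r)) next
    i <- which(chr == ch)
    s <- pmax(start(regions)[i], 1L)
    e <- pmin(end(regions)[i], length(r))
    ok <- s <= e
    if (any(ok)) {
      v <- Views(r, start = s[ok], end = e[ok])
      out[i[ok]] <- viewSums(v) / width(regions)[i[ok]]
    }
  }
  out
}

## per-bp values over [start, end] (1-based closed), zero-padded outside
## the track; used by the metagene machinery.
region_values <- function(track, chrom, start, end) {
  n <- end - start + 1
  out <- numeric(n)
  r <- track$cov[[chrom]]
  if (is.null(r)) return(out)
  s <- max(start, 1L)
  e <- min(end, length(r))
  if (s <= e)
    out[(s - start + 1):(e - start + 1)] <- as.numeric(window(r, s, e))
  out
}
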