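## Synthetic-genome generators with planted, recorded ground truth.
##
## Every stage derives its own child seed from the global seed (see
## derive_seed), so stages reproduce independently. Fixed stage indices:
##   0 TE copies, 1 genes, 2 enhancers, 3x coverage (per condition/assay),
##   4 DE table, 5 termination sites, 6 transcription units.

#' Simulate a genome with TE families, gene models and enhancers
#'
#' Generates a compact genome carrying the structures the downstream
#' analyses consume: TE copies placed uniformly (chromosome chosen with
#' probability proportional to the number of valid start positions), genes
#' placed without overlap and with at least 2 kb intergenic gaps (so
#' PROMPT/eRNA distance rules are unambiguous), and enhancer intervals kept
#' clear of genes. Planted effect sizes are recorded in the returned
#' `truth` component and drive [simulate_coverage()], [simulate_de_table()],
#' [simulate_termination_sites()] and [simulate_tus()].
#'
#' @param n_chroms,chrom_len number and length (bp) of chromosomes.
#' @param n_families number of TE families (`TEF001`, ...).
#' @param copies_per_family scalar or per-family vector of copy counts.
#' @param copy_len_range min/max TE copy length (bp).
#' @param n_genes number of genes.
#' @param exon_count_mix named probability vector: names are exon counts,
#'   values their frequencies (normalised internally).
#' @param n_enhancers number of enhancer intervals.
#' @param enriched_folds named numeric vector family -> planted signal fold
#'   (> 0) for chromatin assays and the TE rows of the DE table; families
#'   not named are at fold 1. Unnamed vectors are assigned to the first
#'   families in order.
#' @param asymmetry_slope planted downregulation per log2(exon count) unit
#'   in the DE table (log2FC units).
#' @param pausing_defect per-kb multiplicative gene-body attenuation in the
#'   cKO condition; applied to genes with more than 3 exons, mirroring a
#'   splicing-coupled elongation defect (mono/oligo-exonic genes are left
#'   untouched).
#' @param premature_rate expected TSS-proximal pA+,- site count per gene,
#'   per kb of gene length and unit of expression.
#' @param noise_sd noise scale: 0 disables noise everywhere (analytically
#'   exact tracks and DE values); 1 gives Poisson-distributed per-bin
#'   coverage counts and unit-SD log2FC noise.
#' @param minor_isoform_frac fraction of genes given a second, shorter
#'   isoform (exercises major-isoform selection).
#' @param seed integer seed; identical seeds give identical output.
#' @return an object of class `nrd_sim`: list with `layout`
#'   ([genome_layout()]), `te` (`GRanges` of TE copies), `genes`
#'   (`GeneModelSet`, major isoforms set), `enhancers` (`GRanges`) and
#'   `truth` (recorded parameters, class `SimTruth`).
#' @export
simulate_genome <- function(n_chroms = 4, chrom_len = 2e6, n_families = 20,
                            copies_per_family = 60,
                            copy_len_range = c(80, 400), n_genes = 160,
                            exon_count_mix = c("1" = 0.25, "3" = 0.25,
                                               "6" = 0.25, "15" = 0.25),
                            n_enhancers = 25, enriched_folds = NULL,
                            asymmetry_slope = 0, pausing_defect = 0,
                            premature_rate = 0, noise_sd = 1,
                            minor_isoform_frac = 0.2, seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_len > 0, n_families >= 1, n_genes >= 1,
            length(copy_len_range) == 2, copy_len_range[1] >= 1,
            copy_len_range[1] <= copy_len_range[2])
  assert_number(asymmetry_slope, "asymmetry_slope")
  assert_number(pausing_defect, "pausing_defect", lower = 0)
  assert_number(premature_rate, "premature_rate", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  chrom_len <- as.integer(round(chrom_len / 10) * 10)
  layout <- genome_layout(setNames(rep(chrom_len, n_chroms),
                                   sprintf("chr%d", seq_len(n_chroms))))
  families <- sprintf("TEF%03d", seq_len(n_families))
  if (length(copies_per_family) == 1L)
    copies_per_family <- rep(copies_per_family, n_families)
  stopifnot(length(copies_per_family) == n_families)

  folds <- setNames(rep(1, n_families), families)
  if (!is.null(enriched_folds)) {
    if (any(enriched_folds <= 0)) stop("folds must be > 0", call. = FALSE)
    if (is.null(names(enriched_folds)))
      names(enriched_folds) <- families[seq_along(enriched_folds)]
    if (!all(names(enriched_folds) %in% families))
      stop("enriched_folds names unknown families", call. = FALSE)
    folds[names(enriched_folds)] <- enriched_folds
  }

  te <- with_seed_or_stream(derive_seed(seed, 0), {
    fam_class <- sample(TE_CLASSES, n_families, replace = TRUE,
                        prob = c(0.5, 0.2, 0.15, 0.1, 0.05))
    fam <- rep(families, copies_per_family)
    cls <- rep(fam_class, copies_per_family)
    n <- length(fam)
    len <- floor(runif(n, copy_len_range[1], copy_len_range[2] + 1))
    place_uniform(len, layout, strand = sample(c("+", "-"), n, TRUE),
                  family = fam, te_class = cls)
  })

  gm <- with_seed_or_stream(derive_seed(seed, 1), {
    build_genes(n_genes, exon_count_mix, layout, minor_isoform_frac)
  })
  gm <- select_major_isoform(gm)
  spans <- gene_spans(gm)

  enhancers <- with_seed_or_stream(derive_seed(seed, 2), {
    place_clear(n_enhancers, width_range = c(500, 1500), layout = layout,
                avoid = resize_both(spans, 2500), what = "enhancer")
  })
  mcols(enhancers)$name <- sprintf("ENH%03d", seq_along(enhancers))
  mcols(enhancers)$score <- rep(0, length(enhancers))

  truth <- structure(list(seed = as.integer(seed), enriched_families = folds,
                          asymmetry_slope = asymmetry_slope,
                          pausing_defect = pausing_defect,
                          premature_rate = premature_rate,
                          noise_sd = noise_sd, tu_labels = NULL,
                          premature_genes = NULL), class = "SimTruth")
  structure(list(layout = layout, te = te, genes = gm, enhancers = enhancers,
                 truth = truth), class = "nrd_sim")
}

#' @export
print.nrd_sim <- function(x, ...) {
  cat(sprintf(paste0("nrd_sim: %d chromosome(s) x %g bp, %d TE copies ",
                     "(%d families), %d genes, %d enhancers, seed %d\n"),
              length(x$layout), unname(x$layout[1]), length(x$te),
              length(unique(mcols(x$te)$family)), nrow(x$genes$genes),
              length(x$enhancers), x$truth$seed))
  invisible(x)
}

## uniform genome-wide placement of intervals of given lengths:
## P(chrom) proportional to (chrom_len - len + 1), start uniform.
place_uniform <- function(len, layout, strand = "*", ...) {
  n <- length(len)
  if (any(len > max(layout)))
    stop("interval longer than every chromosome", call. = FALSE)
  chrom <- character(n)
  start <- integer(n)
  for (i in seq_len(n)) {
    w <- pmax(layout - len[i] + 1, 0)
    chrom[i] <- sample(names(layout), 1, prob = w)
    start[i] <- floor(runif(1, 1, layout[[chrom[i]]] - len[i] + 2))
  }
  GRanges(factor(chrom, levels = names(layout)), IRanges(start, width = len),
          strand = strand, ...)
}

resize_both <- function(gr, flank) {
  GRanges(seqnames(gr), IRanges(pmax(start(gr) - flank, 1), end(gr) + flank),
          strand = strand(gr))
}

## rejection-sample intervals clear of `avoid`
place_clear <- function(n, width_range, layout, avoid, what,
                        max_iter = 20000L) {
  out <- GRanges()
  iter <- 0L
  while (length(out) < n) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("could not place all ", what, "s: genome too crowded", call. = FALSE)
    w <- floor(runif(1, width_range[1], width_range[2] + 1))
    cand <- place_uniform(w, layout)
    hit <- suppressWarnings(
      length(findOverlaps(cand, avoid, ignore.strand = TRUE)) ||
        length(findOverlaps(cand, out, ignore.strand = TRUE)))
    if (!hit) out <- suppressWarnings(c(out, cand))
  }
  out
}

## genes: exon counts from the mix; exons 600-1000 bp, introns 1-3 kb;
## sequential placement with 2-5 kb gaps and 2 kb chromosome margins.
build_genes <- function(n_genes, exon_count_mix, layout, minor_frac) {
  counts <- as.integer(names(exon_count_mix))
  if (anyNA(counts) || any(counts < 1))
    stop("exon_count_mix names must be positive integers", call. = FALSE)
  n_ex <- counts[sample.int(length(counts), n_genes, replace = TRUE,
                            prob = exon_count_mix / sum(exon_count_mix))]
  ex_chrom <- character(0); ex_start <- integer(0); ex_end <- integer(0)
  ex_tx <- character(0); ex_gene <- character(0)
  chrom_i <- 1L
  cursor <- 2001L
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  gstrand <- character(n_genes)
  for (g in seq_len(n_genes)) {
    e <- n_ex[g]
    ex_len <- floor(runif(e, 600, 1001))
    in_len <- if (e > 1) floor(runif(e - 1, 1000, 3001)) else integer(0)
    glen <- sum(ex_len) + sum(in_len)
    gap <- floor(runif(1, 2000, 5001))
    while (cursor + glen - 1L > layout[[chrom_i]] - 2000L) {
      chrom_i <- chrom_i + 1L
      if (chrom_i > length(layout))
        stop("requested genes exceed genome capacity", call. = FALSE)
      cursor <- 2001L
    }
    gid <- sprintf("G%04d", g)
    tid <- paste0(gid, ".t1")
    starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
    ends <- starts + ex_len - 1L
    ex_chrom <- c(ex_chrom, rep(names(layout)[chrom_i], e))
    ex_start <- c(ex_start, starts)
    ex_end <- c(ex_end, ends)
    ex_tx <- c(ex_tx, rep(tid, e))
    ex_gene <- c(ex_gene, rep(gid, e))
    gstrand[g] <- strands[g]
    if (e > 1 && runif(1) < minor_frac) {
      k <- max(1L, floor(e / 2))
      keep <- if (strands[g] == "+") seq_len(k) else (e - k + 1L):e
      tid2 <- paste0(gid, ".t2")
      ex_chrom <- c(ex_chrom, rep(names(layout)[chrom_i], k))
      ex_start <- c(ex_start, starts[keep])
      ex_end <- c(ex_end, ends[keep])
      ex_tx <- c(ex_tx, rep(tid2, k))
      ex_gene <- c(ex_gene, rep(gid, k))
    }
    cursor <- as.integer(cursor + glen + gap)
  }
  strand_by_gene <- setNames(gstrand, sprintf("G%04d", seq_len(n_genes)))
  exons <- GRanges(ex_chrom, IRanges(ex_start, ex_end),
                   strand = strand_by_gene[ex_gene],
                   tx_id = ex_tx, gene_id = ex_gene)
  gene_model_set(exons)
}

#' Simulate a coverage track for one condition and assay
#'
#' Builds an analytically exact step function and then (for
#' `noise_sd > 0`) replaces it with Poisson-distributed counts on
#' `bin_width`-bp bins converted back to density, so disabling noise keeps
#' closed-form expectations exact.
#'
#' For `RNAPII`/`nascentRNA`: a promoter rectangle of height
#' `promoter_height` over the promoter-proximal window (TSS-30 bp to
#' TSS+300 bp, transcript orientation) and a gene-body plateau of height
#' `body_height` over TSS+300..TES; in the `cKO` condition the body of
#' every gene with more than 3 exons is attenuated by
#' `exp(-pausing_defect * body_kb)`. For `H3K9me3`/`H3K27ac`: plateaus of
#' `baseline * fold` over the copies of each planted family.
#'
#' @param sim an `nrd_sim` from [simulate_genome()].
#' @param condition `"WT"` or `"cKO"`.
#' @param assay one of `"RNAPII"`, `"nascentRNA"`, `"H3K27ac"`, `"H3K9me3"`.
#' @param baseline,promoter_height,body_height signal densities (per bp).
#' @param bin_width Poisson bin width in bp.
#' @param enriched_families optional named fold vector overriding the
#'   planted `truth$enriched_families` (chromatin assays only).
#' @return a `CoverageTrack`.
#' @export
simulate_coverage <- function(sim, condition = c("WT", "cKO"),
                              assay = c("RNAPII", "nascentRNA", "H3K27ac",
                                        "H3K9me3"),
                              baseline = 1, promoter_height = 10,
                              body_height = 2, bin_width = 10,
                              enriched_families = NULL) {
  condition <- match.arg(condition)
  assay <- match.arg(assay)
  truth <- sim$truth
  cov <- lapply(sim$layout, function(len) Rle(baseline, as.integer(len)))
  if (assay %in% c("RNAPII", "nascentRNA")) {
    spans <- gene_spans(sim$genes)
    pb <- pausing_regions(spans)
    att <- rep(1, length(spans))
    if (condition == "cKO" && truth$pausing_defect > 0) {
      multi <- mcols(spans)$n_exons > 3
      body_kb <- width(pb$body) / 1000
      att[multi] <- exp(-truth$pausing_defect * body_kb[multi])
    }
    for (i in seq_along(spans)) {
      ch <- as.character(seqnames(spans))[i]
      if (!is.na(pb$ok[i]) && pb$ok[i])
        cov[[ch]] <- rle_set(cov[[ch]], start(pb$body)[i], end(pb$body)[i],
                             body_height * att[i])
      cov[[ch]] <- rle_set(cov[[ch]], start(pb$promoter)[i],
                           end(pb$promoter)[i], promoter_height)
    }
  } else {
    folds <- enriched_families %||% truth$enriched_families
    fam <- mcols(sim$te)$family
    hot <- names(folds)[folds != 1]
    for (f in hot) {
      copies <- sim$te[fam == f]
      for (i in seq_along(copies)) {
        ch <- as.character(seqnames(copies))[i]
        cov[[ch]] <- rle_set(cov[[ch]], start(copies)[i], end(copies)[i],
                             baseline * folds[[f]])
      }
    }
  }
  track <- track_from_rle(cov, sim$layout)
  if (truth$noise_sd > 0) {
    cseed <- derive_seed(truth$seed,
                         300 + match(condition, c("WT", "cKO")) +
                           10 * match(assay, c("RNAPII", "nascentRNA",
                                               "H3K27ac", "H3K9me3")))
    track <- with_seed_or_stream(cseed,
                                 poissonize_track(track, bin_width,
                                                  truth$noise_sd))
  }
  track
}

rle_set <- function(r, from, to, value) {
  from <- max(1L, from)
  to <- min(length(r), to)
  if (from > to) return(r)
  r[from:to] <- value
  r
}

## per-bin Poisson noise: counts ~ Pois(mu * w / s^2), density counts*s^2/w.
## mean preserved; variance mu * s^2 / w. s is the noise_sd dial.
poissonize_track <- function(track, bin_width, s) {
  cov <- lapply(track$cov, function(r) {
    len <- length(r)
    starts <- seq(1L, len, by = bin_width)
    ends <- pmin(starts + bin_width - 1L, len)
    w <- ends - starts + 1L
    mu <- viewMeans(Views(r, start = starts, end = ends))
    val <- rpois(length(mu), mu * w / s^2) * s^2 / w
    Rle(val, w)
  })
  track_from_rle(cov, track$layout)
}

#' Simulate a differential-expression table with planted structure
#'
#' Per-gene `log2fc = -asymmetry_slope * log2(exon_count) + N(0, noise_sd)`
#' (the monotone exon-count map is `log2`); per-TE-family
#' `log2fc = log2(fold) + N(0, noise_sd)`. `stat = log2fc / se`, p-values
#' are two-sided normal tails, and `padj` is Benjamini-Hochberg across the
#' whole table (via [bh_adjust()]).
#'
#' @param sim an `nrd_sim`.
#' @param se reported standard error of `log2fc` (constant).
#' @param seed optional override of the stage seed.
#' @return a DE `data.frame` (see [read_de_table()]).
#' @export
simulate_de_table <- function(sim, se = 0.1, seed = NULL) {
  truth <- sim$truth
  spans <- gene_spans(sim$genes)
  gid <- mcols(spans)$gene_id
  nex <- mcols(spans)$n_exons
  folds <- truth$enriched_families
  with_seed_or_stream(seed %||% derive_seed(truth$seed, 4), {
    g_lfc <- -truth$asymmetry_slope * log2(nex) +
      rnorm(length(gid), 0, truth$noise_sd)
    t_lfc <- log2(folds) + rnorm(length(folds), 0, truth$noise_sd)
    fam_class <- mcols(sim$te)$te_class[match(names(folds),
                                              mcols(sim$te)$family)]
    df <- data.frame(
      feature_id = c(gid, names(folds)),
      feature_kind = c(rep("gene", length(gid)),
                       rep("te_family", length(folds))),
      biotype = c(mcols(spans)$biotype, fam_class),
      base_mean = exp(rnorm(length(gid) + length(folds), log(100), 1)),
      log2fc = c(g_lfc, unname(t_lfc)),
      stringsAsFactors = FALSE)
    df$stat <- df$log2fc / se
    df$pvalue <- 2 * pnorm(-abs(df$stat))
    df$padj <- bh_adjust(df$pvalue)
    validate_de_table(df)
  })
}

#' Simulate poly(A)-site termination events
#'
#' Each gene emits TSS-proximal `pA+,-` sites with expected count
#' `premature_rate * gene_length_kb * expression`, placed uniformly over
#' the first 500 bp downstream of the TSS (transcript orientation), plus
#' one `pA+` site at the TES with a small inward jitter. All sites share
#' the gene's strand. The set of genes that actually received at least one
#' TSS-proximal site is recorded as the planted premature-termination set.
#'
#' @param sim an `nrd_sim`.
#' @param expression named non-negative vector keyed by gene_id
#'   (default: 1 for every gene).
#' @param window size (bp) of the TSS-proximal placement window.
#' @param seed optional override of the stage seed.
#' @return list with `sites` (a termination-site `GRanges`, see
#'   [read_bed()]) and `premature_genes` (character vector).
#' @export
simulate_termination_sites <- function(sim, expression = NULL, window = 500,
                                       seed = NULL) {
  truth <- sim$truth
  spans <- gene_spans(sim$genes)
  gid <- mcols(spans)$gene_id
  expr <- if (is.null(expression)) setNames(rep(1, length(gid)), gid) else expression
  if (!all(gid %in% names(expr)))
    stop("expression missing for some genes", call. = FALSE)
  expr <- pmax(as.numeric(expr[gid]), 0)
  len_kb <- width(spans) / 1000
  str <- as.character(strand(spans))
  tss <- mcols(spans)$tss
  tes <- mcols(spans)$tes
  with_seed_or_stream(seed %||% derive_seed(truth$seed, 5), {
    n_pre <- rpois(length(gid), truth$premature_rate * len_kb * expr)
    wmax <- pmin(window, width(spans)) # keep sites inside short genes
    off <- floor(runif(sum(n_pre), 0, rep(wmax, n_pre)))
    dir <- rep(ifelse(str == "+", 1L, -1L), n_pre)
    pre_pos <- rep(tss, n_pre) + dir * off
    pre <- GRanges(rep(seqnames(spans), n_pre), IRanges(pre_pos, pre_pos),
                   strand = rep(str, n_pre),
                   pa_status = rep("pA+,-", sum(n_pre)),
                   count = rep(1L, sum(n_pre)))
    jit <- floor(runif(length(gid), 0, 21))
    pa_pos <- tes - ifelse(str == "+", 1L, -1L) * jit
    pa <- GRanges(seqnames(spans), IRanges(pa_pos, pa_pos), strand = str,
                  pa_status = rep("pA+", length(gid)),
                  count = rep(1L, length(gid)))
    list(sites = sort(c(pre, pa)), premature_genes = gid[n_pre > 0])
  })
}

#' Simulate labeled transcription units
#'
#' Emits four TU populations with recorded labels: `genic` TUs covering
#' each gene's major isoform (span plus 50 bp margins), antisense `PROMPT`
#' TUs starting 100-500 bp upstream of a sampled gene's TSS, `eRNA` TUs
#' within 500 bp of a sampled enhancer (and, by construction of enhancer
#' placement, more than 1 kb from every TSS), and `other` TUs in gene
#' deserts. On a noise-free genome [classify_tus()] recovers these labels
#' exactly.
#'
#' @param sim an `nrd_sim`.
#' @param n_prompt,n_erna,n_other population sizes (genic TUs are one per
#'   gene). `n_prompt` and `n_erna` are capped at the number of genes and
#'   enhancers.
#' @param seed optional override of the stage seed.
#' @return a `GRanges` with metadata columns `tu_id` and `truth_label`.
#' @export
simulate_tus <- function(sim, n_prompt = 60, n_erna = 25, n_other = 30,
                         seed = NULL) {
  spans <- gene_spans(sim$genes)
  layout <- sim$layout
  with_seed_or_stream(seed %||% derive_seed(sim$truth$seed, 6), {
    genic <- GRanges(seqnames(spans),
                     IRanges(pmax(start(spans) - 50L, 1L),
                             pmin(end(spans) + 50L,
                                  layout[as.character(seqnames(spans))])),
                     strand = strand(spans))

    idx <- sample(seq_along(spans), min(n_prompt, length(spans)))
    gap <- floor(runif(length(idx), 100, 501))
    wid <- floor(runif(length(idx), 400, 1001))
    str <- as.character(strand(spans))[idx]
    tss <- mcols(spans)$tss[idx]
    p_end <- ifelse(str == "+", tss - gap - 1L, tss + gap + wid)
    p_start <- ifelse(str == "+", tss - gap - wid, tss + gap + 1L)
    prompt <- GRanges(seqnames(spans)[idx], IRanges(p_start, p_end),
                      strand = ifelse(str == "+", "-", "+"))

    eidx <- sample(seq_along(sim$enhancers), min(n_erna, length(sim$enhancers)))
    egap <- floor(runif(length(eidx), 0, 301))
    ewid <- floor(runif(length(eidx), 300, 801))
    eside <- sample(c(-1, 1), length(eidx), replace = TRUE)
    enh <- sim$enhancers[eidx]
    e_start <- ifelse(eside > 0, end(enh) + egap + 1L,
                      start(enh) - egap - ewid)
    erna <- GRanges(seqnames(enh), IRanges(e_start, e_start + ewid - 1L),
                    strand = sample(c("+", "-"), length(eidx), TRUE))

    avoid <- c(resize_both(granges(spans), 2500),
               resize_both(granges(sim$enhancers), 1500))
    other <- place_clear(n_other, width_range = c(300, 2000), layout = layout,
                         avoid = avoid, what = "desert TU")
    strand(other) <- sample(c("+", "-"), length(other), TRUE)

    tus <- c(genic, prompt, erna, other)
    labels <- c(rep("genic", length(genic)), rep("PROMPT", length(prompt)),
                rep("eRNA", length(erna)), rep("other", length(other)))
    mcols(tus)$tu_id <- sprintf("TU%04d", seq_along(tus))
    mcols(tus)$truth_label <- labels
    tus
  })
}
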