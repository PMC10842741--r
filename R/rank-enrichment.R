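#' Benjamini-Hochberg step-up adjustment
#'
#' The textbook step-up: sort p ascending, multiply by n/rank, enforce
#' monotonicity from the largest p down, cap at 1. Output is elementwise
#' at least the input and order is preserved.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[order(o)]
}

#' Define an upregulation signature from a DE table
#'
#' Feature ids passing `padj < padj_max` and `log2fc > log2fc_min`, both
#' strict (the convention of an FDR < 0.05, log2FC > 5 signature).
#'
#' @param de_table a DE table.
#' @param padj_max,log2fc_min strict thresholds.
#' @return character vector of feature ids.
#' @export
define_signature <- function(de_table, padj_max = 0.05, log2fc_min = 5) {
  keep <- is.finite(de_table$padj) & de_table$padj < padj_max &
    de_table$log2fc > log2fc_min
  de_table$feature_id[keep]
}

#' Rank features by the differential-expression statistic
#'
#' Descending by `stat`, ties broken lexicographically by feature id so
#' the ranking is deterministic across platforms.
#'
#' @param de_table a DE table (one record per feature).
#' @return named numeric vector of scores, names are feature ids, sorted
#'   for use with [gsea_preranked()].
#' @export
rank_by_stat <- function(de_table) {
  if (anyDuplicated(de_table$feature_id))
    stop("duplicate feature ids", call. = FALSE)
  if (any(!is.finite(de_table$stat)))
    stop("ranking scores must be finite", call. = FALSE)
  o <- order(-de_table$stat, de_table$feature_id, method = "radix")
  setNames(de_table$stat[o], de_table$feature_id[o])
}

## weighted running-sum enrichment score; returns ES, the extremum
## position and the running sum itself
running_es <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / nh, n)
  step <- ifelse(hit, inc, 0) - ifelse(hit, 0, if (n > nh) 1 / (n - nh) else 0)
  run <- cumsum(step)
  k <- which.max(abs(run))
  list(es = run[k], at = k, run = run)
}

#' Preranked gene-set enrichment (ES / NES, permutation null)
#'
#' The classical weighted running-sum statistic: walking down the ranked
#' list, set members increment the sum by `|score|^weight` (normalised to
#' 1 over the set) and non-members decrement it by `1/(N - set size)`; the
#' enrichment score ES is the extreme deviation. The null distribution
#' comes from random same-size sets drawn without replacement from the
#' ranked universe. The p-value is one-sided on the sign of ES,
#' `(1 + #same-sign |ES_null| >= |ES|) / (1 + #same-sign)`, and
#' `NES = ES / mean(|ES_null|)` over same-sign nulls. The leading edge is
#' the set members at or before the ES extremum (at or after it for
#' negative ES).
#'
#' @param ranked named score vector from [rank_by_stat()].
#' @param set character vector of feature ids (restricted to the universe;
#'   a disjoint set is an error).
#' @param weight running-sum weight (default 1).
#' @param n_perm number of null sets (>= 100) for `null = "sample"`.
#' @param seed seed for the permutation draw.
#' @param null `"sample"` (Monte-Carlo) or `"exhaustive"` (all same-size
#'   subsets; only feasible for small universes).
#' @return list of class `GSEAResult`: `set_size`, `ES`, `NES`, `pvalue`,
#'   `leading_edge`, `n_null`.
#' @export
gsea_preranked <- function(ranked, set, weight = 1, n_perm = 1000,
                           seed = NULL, null = c("sample", "exhaustive")) {
  null <- match.arg(null)
  if (is.null(names(ranked))) stop("ranked must be named", call. = FALSE)
  o <- order(-ranked, names(ranked), method = "radix")
  ranked <- ranked[o]
  if (all(ranked == 0)) stop("all ranking scores are zero", call. = FALSE)
  ids <- names(ranked)
  hit <- ids %in% set
  nh <- sum(hit)
  if (nh == 0) stop("set is disjoint from the ranked universe", call. = FALSE)
  n <- length(ranked)
  obs <- running_es(ranked, hit, weight)
  es <- obs$es
  lead <- if (es >= 0) ids[hit & seq_len(n) <= obs$at] else
    ids[hit & seq_len(n) >= obs$at]

  null_es <- if (null == "exhaustive") {
    if (choose(n, nh) > 1e5)
      stop("exhaustive null infeasible for this universe", call. = FALSE)
    apply(utils::combn(n, nh), 2, function(idx) {
      h <- logical(n); h[idx] <- TRUE
      running_es(ranked, h, weight)$es
    })
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
    with_seed_or_stream(seed, {
      vapply(seq_len(n_perm), function(b) {
        h <- logical(n)
        h[sample.int(n, nh)] <- TRUE
        running_es(ranked, h, weight)$es
      }, 0)
    })
  }
  same <- null_es[sign(null_es) == sign(es)]
  pvalue <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  structure(list(set_size = nh, ES = es, NES = nes, pvalue = pvalue,
                 leading_edge = lead, n_null = length(null_es)),
            class = "GSEAResult")
}

#' @export
print.GSEAResult <- function(x, ...) {
  cat(sprintf("GSEA: size %d, ES %.4f, NES %.3f, p %.4g (%d nulls, %d in leading edge)\n",
              x$set_size, x$ES, x$NES, x$pvalue, x$n_null,
              length(x$leading_edge)))
  invisible(x)
}

#' Run preranked GSEA over several gene sets with BH adjustment
#'
#' @param ranked named score vector.
#' @param sets named list of feature-id vectors.
#' @inheritParams gsea_preranked
#' @return a `data.frame`: `set`, `set_size`, `ES`, `NES`, `pvalue`,
#'   `padj` (Benjamini-Hochberg across the sets).
#' @export
gsea_preranked_sets <- function(ranked, sets, weight = 1, n_perm = 1000,
                                seed = NULL) {
  res <- lapply(seq_along(sets), function(i) {
    r <- gsea_preranked(ranked, sets[[i]], weight = weight, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else
                          derive_seed(seed, i))
    data.frame(set = names(sets)[i] %||% as.character(i),
               set_size = r$set_size, ES = r$ES, NES = r$NES,
               pvalue = r$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pvalue)
  out
}

#' Read and write GMT gene-set files
#'
#' @param path GMT file (set name, description, then member ids, tab
#'   separated).
#' @return [read_gmt()]: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}
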