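`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from a global seed
#'
#' Each simulation stage consumes its own child seed so that stages can be
#' re-run independently and still reproduce. The derivation is a fixed
#' affine map kept inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) + 10007 * as.double(stage)) %% 2147483647)
}

## run `code` under `seed` without disturbing the caller's RNG stream;
## NULL seed means "use the current stream".
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

stop_at_line <- function(path, line_no, msg) {
  stop(sprintf("%s: line %d: %s", path, line_no, msg), call. = FALSE)
}

## two-sided unpaired Wilcoxon rank-sum (normal approximation with tie and
## continuity correction); degenerate all-tied samples give p = 1
rank_sum_p <- function(x, y) {
  if (length(unique(c(x, y))) < 2) return(1)
  p <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                    correct = TRUE)$p.value)
  if (!is.finite(p)) 1 else p
}

## strict scalar checks used across the API
assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
}
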