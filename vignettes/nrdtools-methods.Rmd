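---
title: "Methods: models, parameters and design choices in nrdtools"
author: "nrdtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrdtools)
```

# Scope

`nrdtools` quantifies the genomic phenotypes of impaired nuclear RNA
catabolism in mESCs: transposable-element (TE) de-repression, RNAPII
promoter-proximal pausing and elongation defects, unstable non-coding
transcription (PROMPTs, eRNAs), premature poly(A)-site termination, and
the resulting gene-length-dependent expression asymmetry. The package
deliberately starts downstream of read processing: coverage tracks,
annotations, peak/enhancer calls and differential-expression (DE) tables
are inputs, not products. Alignment, peak calling, DE model fitting and
enhancer calling belong to the established upstream tools.

Coordinates are handled on `GRanges` (1-based, closed) and converted at
the file boundary from the 0-based half-open convention of BED/bedGraph;
one conversion point avoids off-by-one drift. Coverage is a per-chromosome
run-length-encoded step function; uncovered ground has value 0.

# TE enrichment against a shuffled-interval null

The annotation is first filtered to copies of at least 50 bp, then to
families retaining at least 50 copies — the standard pre-filter for
family-level work on RepeatMasker-style annotations. For each family the
observed per-copy mean signal (per-bp mean over the copy, i.e.
`multiBigwigSummary` semantics) is compared with the signal over
length-matched intervals placed uniformly at random genome-wide: the
chromosome is drawn with probability proportional to its number of valid
start positions and the start uniformly among them. Mutual overlaps of
shuffled intervals are permitted and no exclusion list is applied — the
defaults of a plain `bedtools shuffle`. Whether shuffling should be
per-chromosome or exclude overlaps is genuinely open; the genome-wide,
overlap-permitting variant was adopted once and is surfaced in the
configuration echoed by the CLI.

The enrichment is `log2((mean_obs + eps)/(mean_bg + eps))` with
`eps = 1e-3` by default. The pseudocount is not part of the published
ratio definition; it exists to bound the log-ratio on zero-signal
families and is configurable (tests that check exact arithmetic set it
to 0). Significance is a two-sided unpaired Wilcoxon rank-sum test of the
per-copy observed versus background values, using the normal
approximation with tie and continuity correction throughout — family
sizes are at least 50 by construction of the filter, where the
approximation is accurate. Degenerate, all-tied comparisons (possible on
exactly flat fixtures) report p = 1. Benjamini–Hochberg adjustment runs
across families.

Chromatin stratification labels a family `K9` when its H3K9me3 enrichment
record passes `log2FC > 0.5` and `padj < 0.05` (both strict), otherwise
`K27AC` by the same test on H3K27ac, otherwise `NEITHER`. H3K9me3 takes
precedence so the classes partition the families.

MERVL structure: an internal copy is full-length when a same-strand LTR
lies within `max_gap` (default 1000 bp, edge-to-edge) of each edge.
Internals are processed in genomic order, each consuming its nearest
unassigned qualifying LTR per side, which makes the output invariant to
input order and prevents one LTR from flanking two elements. Unassigned
LTRs within `max_gap` of a full-length element are in its ambit and are
neither flanks nor solo; the remainder are solo LTRs. The proximity
distance is not published; 1 kb is the package default and is echoed in
the output header.

# Pausing ratio and metagenes

The promoter-proximal window is TSS−30 bp to TSS+300 bp and the gene body
TSS+300 bp to the TES, in transcript orientation; a gene whose TES lies
at or before TSS+300 has no body and is excluded (`body_too_short`).
"Signal" is the per-bp mean in each window, making the ratio invariant to
global track scaling. Genes must have nonzero signal in both windows;
when a peak set is provided, the peak must overlap the single TSS base —
the literal reading of a peak "overlapping the gene's TSS". Condition
contrasts are Wilcoxon rank-sum tests of KO versus WT ratios per
exon-count bin, BH-adjusted across bins; bins under 3 genes report NA.

Metagene profiles use the scale-regions layout: `flank_bins` fixed-width
bins per side covering `flank_bp`, and a body rescaled to `body_bins`
sub-windows with real-valued bin edges, so regions shorter than
`body_bins` bp are still representable (bins then share base pairs —
stable and documented rather than an error). Each bin is the exact
integral of the step function between its real edges divided by the bin
width; flank bins reaching past the chromosome integrate the covered part
and divide by the full bin width. Minus-strand rows are reversed so
column 1 is always 5′. The unit tests hold this machinery to a
brute-force per-segment integration oracle at 1e-9.

# Transcription-unit classification

`segment_tus` is a threshold segmenter — maximal runs of signal at or
above a cutoff, runs separated by fewer than `max_gap` bp merged, results
under `min_len` dropped — and is documented as exactly that: a simple,
explicit stand-in for HMM-based segmentation of continuous transcription,
with its two parameters exposed rather than learned.

`classify_tus` applies the filter cascade in a fixed order: (1) TUs fully
containing a same-strand transcript are genic; (2) TUs whose total
same-strand overlap with the *merged* transcript cover is at least 3 kb
or at least 25 % of the TU length are genic (merging prevents isoform
double-counting; the published rule does not state per-transcript versus
aggregate accounting, and aggregate-over-merged-cover was adopted);
(3) surviving TUs within 1 kb of a TSS on the antisense strand are
PROMPTs; (4) otherwise TUs within 500 bp of an enhancer are eRNAs;
(5) otherwise `other`. Distances are edge-to-edge gaps, boundary
inclusive (≤ 500, ≤ 1000), measured from the TU edge. PROMPT precedes
eRNA when both conditions hold — the antisense-TSS condition is the more
specific positional signature — and both evidence distances are retained
in the output so a user can re-label. TUs removed by the genic filters
are labeled `genic` with the removal reason in `discard_reason`;
PROMPT/eRNA are only ever assigned to TUs that passed both filters.

# Premature termination

A termination site is assigned to a same-strand gene whose
(optionally flank-extended) span contains it; with several candidates the
gene with the nearest TSS wins, ties going to the lexicographically
smaller gene id. The premature set comprises expressed genes with at
least one pA+,− site at `0 <= d_tss <= 500` — downstream-inclusive, since
upstream antisense events are PROMPT territory handled by the TU module.
The expression predicate is caller-supplied (the CLI uses
`base_mean > 0` from the companion DE table). Site-frequency profiles
deduplicate sites at (chromosome, position, strand, status) and count
them into the same scale-regions grid as the metagene. Covariate
stratification cuts genes into length × expression quantiles and reports
Spearman correlations of per-gene TSS-proximal counts against each
covariate.

# Asymmetry and preranked GSEA

Gene length is the major-isoform genomic span (TSS to TES), not summed
exon length — the asymmetry concerns transcription across the locus. The
major isoform is the highest-expressed when isoform expression is given
(ties to the longer span, then the smaller id), else the longest. Default
exon-count bins are {1 | 2–3 | 4–10 | 11+}: the published figures bin by
exon count without printing edges, and this choice places the
biologically critical more-than-3-exons boundary on a bin edge. The
reference group for pairwise Wilcoxon tests is the first bin; the
summary also reports a Spearman trend of bin order against bin median
statistic.

GSEA follows the classical preranked formulation. The ranking is the DE
statistic, descending, ties broken by feature id so results are
platform-independent. Walking the list, set members add
`|s|^w / sum(|s_set|^w)` and non-members subtract `1/(N - n_set)`; ES is
the extreme deviation of this running sum, so `|ES| <= 1`. The null is
random same-size sets drawn without replacement — the only null available
when all that exists is a ranked list. The p-value is one-sided on the
sign of ES with the +1 floor, `NES = ES / mean |ES_null|` over same-sign
nulls, and the leading edge is the set members at or before the extremum
(at or after, for negative ES). `weight = 1` is the default of the
reference implementations. An exhaustive-enumeration null is available
for small universes and anchors the permutation machinery in tests.
Signature definition uses strict thresholds (`padj < 0.05`,
`log2FC > 5`); note that a planted fold of exactly 32 gives
`log2FC = 5` and is excluded by the strict inequality.

Benjamini–Hochberg is implemented as the textbook step-up (sort, scale by
n/rank, enforce monotonicity from the top, cap at 1) and is
property-tested against an independent direct-definition oracle and
`stats::p.adjust`.

# The synthetic-genome generator

The generator exists to make every stage falsifiable: each planted effect
is recorded and each analysis must recover it. One global seed fans out
to fixed per-stage child seeds, so stages reproduce independently and the
whole pipeline is byte-deterministic.

Structure: chromosomes of equal length; genes placed without overlap,
with at least 2 kb intergenic gaps and 2 kb chromosome margins so the
PROMPT/eRNA distance rules have unambiguous answers in fixtures; exons of
600–1000 bp and introns of 1–3 kb, so exon count and gene length are
strongly coupled (as in real genomes, where the elongation-defect and
termination analyses rely on exactly this coupling); TE copies placed
uniformly, overlaps permitted; enhancers kept 2.5 kb clear of genes so an
eRNA-adjacent TU can never sit within 1 kb of a TSS.

Coverage: an exact step function — baseline 1, a promoter rectangle of
height 10 over TSS−30..TSS+300 and a body plateau of height 2 to the TES
for RNAPII-like assays; plateaus of `baseline × fold` over planted TE
families for chromatin assays. With `noise_sd = s > 0` the track is
re-emitted as per-10-bp-bin Poisson counts divided by bin width
(`counts ~ Pois(mu·w/s²)`, density `counts·s²/w`), preserving the mean
with variance `mu·s²/w`; `s = 0` keeps the analytic track exact, so
closed-form expectations (pausing ratio 5, planted log2 enrichment
exactly log2(fold)) hold to 1e-9 in tests.

The cKO elongation defect attenuates the body plateau by
`exp(-pausing_defect × body_kb)` — and only in genes with more than 3
exons. The conditioning is a modelling choice of this package: the
phenomenon being emulated is splicing-coupled and exon-count-dependent,
and an unconditional per-kb attenuation would shift mono-exonic genes by
a small but systematic amount that any sufficiently powered rank test
detects, contradicting the exon-specific phenotype the generator is
supposed to plant. Mono- and oligo-exonic bins are therefore true nulls.

DE tables: per-gene `log2fc = −slope·log2(n_exons) + N(0, noise_sd)`
(the monotone exon-count map is `log2`), per-family
`log2fc = log2(fold) + N(0, noise_sd)`, `stat = log2fc/se` with constant
`se = 0.1`, two-sided normal p-values, BH adjustment. Termination sites:
per gene a Poisson count with mean
`premature_rate × length_kb × expression` of pA+,− sites uniform over the
first 500 bp downstream of the TSS, plus one pA+ site at the TES with a
small inward jitter. TUs: genic TUs covering each gene ± 50 bp, antisense
PROMPTs 100–500 bp upstream of sampled TSSs, eRNA TUs within 0–300 bp of
sampled enhancers, and `other` TUs in gene deserts.

What the generator does **not** emulate: mappability and multi-mapping
ambiguity (TE signal in real data is confounded by alignment choices made
upstream), copy-level sequence divergence within families, overlapping
gene models, chromatin-state autocorrelation, replicate structure, or
dispersion in the DE model (the emitted `se` is constant). Passing tests
therefore demonstrate that the estimators recover what they claim to
estimate under clean conditions — not that any particular biological
dataset will behave as cleanly.

# Problem sizes and runtime

The test-suite and acceptance-script simulations use: 200 families × 50
copies on a 6 Mb genome for null calibration; 60 families with planted
folds {2, 4, 8} for recovery; 240 genes on 18 Mb with `noise_sd = 1` and
`pausing_defect = 0.08` for the pausing contrast; 1000 genes (≈ 250 per
exon bin) for the asymmetry trend; 400 genes with `premature_rate = 0.08`
and planted slope 0.5 for the termination/GSEA chain; 1000 permutations
for GSEA p-values. These sizes give stable planted-versus-null contrasts
(planted effects many standard errors from 0; null fractions inside
binomial confidence bands) while a full run stays in the tens of seconds
on a single core.

# Known limitations

* The TU segmenter is a thresholder, not a two-state HMM; on noisy tracks
  its `threshold`/`max_gap` interact and should be tuned together.
* BigWig input is not supported; convert to bedGraph upstream.
* `family_enrichment` draws one background per copy by default
  (`n_draws` raises it); very small families (< 2 copies) are excluded
  with a warning rather than tested.
* The Wilcoxon normal approximation is inaccurate for groups of a handful
  of genes; group p-values under n = 3 are suppressed, but 3–10-gene
  groups should be read with care.
* The generator's gene models are single-chromosome, non-overlapping and
  at most two isoforms; analyses accept arbitrary `GeneModelSet`s, but
  planted-truth guarantees only hold for generated genomes.
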