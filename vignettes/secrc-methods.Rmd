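---
title: "Super-enhancer calling and core regulatory circuitry with secrc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer calling and core regulatory circuitry with secrc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secrc)
```

# Scope and model

`secrc` starts where upstream ChIP-seq processing ends: it takes per-sample
H3K27ac peak calls (MACS2-style narrowPeak or plain BED) and aligned
fragment tracks (BED3, or bedGraph coverage), a TSS annotation, an optional
set of nucleosome-free regions (NFRs), a JASPAR-style PFM motif library and
optionally a gene-expression matrix, and carries them through five analysis
layers:

1. **Enhancer definition.** Significant peaks (p < 1e-9 by default, strict
   inequality on the p-value, i.e. `-log10 p > 9`) whose midpoints lie
   strictly more than 2.5 kb from the nearest TSS are kept as enhancers and
   extended to a fixed 10 kb window (±5 kb around the peak midpoint,
   clamped at the chromosome start). The distance anchor is the peak
   midpoint: the extension is midpoint-anchored, so using the same anchor
   for the distance rule keeps the two steps consistent.
2. **Signal quantification.** Each enhancer window is cut into 100 bp bins;
   a fragment counts once in every bin it shares at least one base with
   (no length weighting), and the enhancer signal is the mean per-bin count
   scaled to fragments per million. Counting *fragments* per bin - rather
   than peak calls - is the only reading under which the quantity behaves
   as a continuous signal; a per-bin count of peak calls would be almost
   always 0 or 1. Per-million scaling is one choice of depth normalization
   among several; it is recorded in output headers and cancels out of every
   downstream rank- or correlation-based statistic.
3. **Super-enhancer calling (ROSE-style).** Enhancers within 12.5 kb of
   each other (gap ≤ 12 500 bp, inclusive; overlapping or touching windows
   always merge, transitively) are stitched into single entities whose
   signal is the *sum* of constituent signals (ROSE's cumulative-signal
   convention; the mean would penalize large clusters, which is the
   opposite of what the SE definition intends). Entities are ranked by
   signal, both axes are scaled to [0, 1], and the SE/TE cutoff is the
   point where the scaled curve's slope reaches 1. For a convex increasing
   curve that point is exactly the point maximizing
   `scaled_rank - scaled_signal`, so the cutoff is computed by that argmax
   identity rather than by finite differences, which are noise-sensitive on
   real rank curves. Entities with signal strictly greater than the cutoff
   entity's signal are super-enhancers; ties at the cutoff stay typical.
4. **Cross-sample analysis.** SE calls from cell lines of the same tumor
   type are unioned transitively wherever they share at least one base;
   merged SEs supported by fewer than 2 cell lines are dropped. Each merged
   SE is assigned to the gene with the nearest TSS (unbounded distance,
   ties broken lexicographically for determinism - the same default
   behaviour as HOMER's annotatePeaks). A gene's frequency is the number of
   *distinct tumor types* (not cell lines) in which it carries a merged SE:
   the classification scale runs 1-8 over eight tumor types, with
   frequency > 6 conservative and frequency = 1 tumor-specific. The same
   logic classifies TFs with a > 4 / = 1 rule.
5. **Motif scanning and core regulatory circuitry.** NFRs are intersected
   with SE intervals (or detected from coverage, below) and scanned on both
   strands with additive log2-odds PWM scores; a window is a hit when its
   score reaches 80% of the PWM's maximum attainable score. Motif
   enrichment of SE NFRs against background sequences is a hypergeometric
   upper tail on the per-sequence hit indicator. The CRC graph has an edge
   u → v when TF u's motif hits any NFR of TF v's SE; TFs with a self-edge
   are autoregulated, and the circuitry is reported as all maximal fully
   interconnected (mutual-edge) cliques of autoregulated TFs. A TF's score
   is the fraction of enumerated cliques containing it and a clique's score
   the mean of its members' scores - a frequency-based ranking in the
   spirit of CRCmapper's output ordering, chosen because no closed formula
   for the "TF score" is fixed by the method description this package
   follows.

Genomic coordinates are 0-based half-open (BED convention) everywhere
inside the package; GTF input is converted on read. Using one convention
throughout removes a whole class of off-by-one mistakes that arise when
ROSE-, HOMER- and bedtools-style conventions are mixed.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `p_threshold` | 1e-9 | p-value | peak significance filter (strict `<`) |
| `min_tss_distance` | 2500 | bp | midpoint-to-TSS distance, strict `>` |
| `bin_size` | 100 | bp | enhancer signal bins |
| `corr_bin_size` | 2000 | bp | genome bins for sample correlation |
| `stitch_distance` | 12500 | bp | maximum stitch gap, inclusive |
| `min_cell_lines` | 2 | count | merged-SE support filter |
| `gene_conservative_gt` | 6 | tumor types | gene frequency threshold |
| `tf_conservative_gt` | 4 | tumor types | TF frequency threshold |
| `motif_threshold` | 0.8 | fraction | of the PWM's maximum score |
| `min_clique_size` | 2 | TFs | smallest reported clique |
| `enrichment_alpha` | 0.05 | p-value | enriched-TF call per tumor type |
| `n_background_nfrs` | 200 | count | seeded background intervals |

The 0.8 motif threshold is a common log-odds scanning default; a
p-value-calibrated per-PWM threshold would be a natural refinement and the
parameter is exposed for that reason. Lowering the threshold can only add
CRC edges, never remove one (tested as a property).

# Numerical and degenerate-input choices

* **PWM pseudocount.** Count matrices are normalized with +1 per cell,
  `(c + 1) / (sum + 4)`, avoiding -Inf log-odds for unobserved bases.
  Probability matrices supplied deliberately without smoothing
  (`pseudocount = 0`) are supported for exact-match scanning.
* **Uniform PWM.** A flat PWM against a uniform background scores 0
  everywhere, which equals its maximum score, so every window is a hit at
  any threshold ≤ 1. This degenerate case is documented and returned
  as-is rather than raising an error.
* **`N` bases** never match: any window containing `N` is skipped on both
  strands.
* **Rank-curve ties.** `rank_and_cutoff` requires at least two entities
  and non-constant signals (otherwise the rank curve is degenerate and the
  call errors). Entities with signal exactly equal to the cutoff entity's
  signal are typical; `cutoff_rank` is therefore the number of typical
  entities, and the `is_super` flag equals `rank > cutoff_rank` even in
  the presence of ties.
* **Zero-depth tracks** and zero-variance correlation rows raise errors
  naming the offending sample rather than propagating NaN.
* **Book-ended intervals** (end of one equals start of the next) share no
  base and are *not* merged by `merge_ses`; stitching, by contrast, merges
  them because its gap rule is `gap ≤ stitch_distance` with gap 0.
* **Background sampling** for enrichment inside `run_pipeline` is the only
  source of randomness in the pipeline; it is seeded from the
  configuration, so reruns are byte-identical.

# The valley-mode NFR detector

When no NFR file is available, `find_nfrs(mode = "valley")` detects
coverage valleys directly: within each constituent, maximal runs of at
least 50 bp where coverage falls below 0.25 × the constituent's peak
coverage, flanked on both sides by coverage reaching at least 0.5 × the
peak. This rule is a self-contained fallback of this package's own design -
it captures the twin-peak-with-dip shape that nucleosome-free regions show
in H3K27ac data, but it is not a reimplementation of any published NFR
caller. Supplying measured NFRs (`mode = "provided"`) is the faithful path
and is what the pipeline uses.

# What the synthetic generator emulates - and what it does not

`generate_synthetic()` builds a complete toy study on one 5 Mb chromosome:
8 tumor types × 3 cell lines, 8 shared SEs, 2 type-specific SEs per type,
30 isolated typical enhancers, and a triad of TF genes whose SE NFRs carry
all three TF motifs, making the triad fully interconnected and
autoregulated. Planted SEs are clusters of four 1 kb constituent peaks
3 kb apart (well within stitching range) whose fragment rate is 8× the
typical-enhancer rate; fragments are fixed 200 bp with centers normal
around constituent centers (sd 500 bp) plus 10% uniform background. Decoy
significant peaks within 2.5 kb of every TSS exercise the TSS filter, and
sub-threshold peaks exercise the significance filter. Motifs are planted
as consensus sequences, which guarantees hits at any threshold ≤ 1. The
scale was chosen as the smallest at which 12.5 kb stitching, 10 kb
enhancer windows and dozens of loci coexist without collisions, keeping an
end-to-end run around ten seconds.

The generator reproduces the *statistical structure* the pipeline relies
on - clustered high signal vs isolated signal, shared vs specific loci,
within-type correlation exceeding between-type correlation, a planted
autoregulated clique - but none of the realism of sequencing: no read-level
errors, duplicates, GC bias, mappability gaps, input-DNA background
structure, or chromatin-state heterogeneity between cell lines of a type.
Passing the planted-recovery tests therefore demonstrates that the
algorithms are implemented correctly, not that they would achieve the same
precision on real tumor ChIP-seq, where constituent signal folds are more
variable and peak boundaries noisier.

Tests and the acceptance checks run the generator at two scales: the
default design above for study-scale checks (~10 s end to end) and a
reduced design (3 types × 2 lines, 2 Mb, 8 000 fragments per sample) for
module-level tests, chosen so the whole suite stays fast while still
exercising every stage.

# Design choices where the method description was open

* **Stitched signal = sum of constituents**, not mean (ROSE's convention;
  recorded in output headers).
* **Gene/SE frequency counts distinct tumor types**, not cell lines - the
  1-8 classification scale only makes sense over the eight tumor types.
* **Known-motif scanning + hypergeometric enrichment** stand in for
  HOMER's de-novo discovery pipeline: the downstream circuitry logic needs
  only "which TF motifs occur in which SE NFRs", and de-novo motif
  discovery is a separate research program.
* **Enriched TF per tumor type** means hypergeometric p below
  `enrichment_alpha` against seeded genomic background intervals of
  matching widths.
* **The TSS annotation build is the caller's choice**; any BED6 or GTF
  works, since no specific gene build is mandated by the method.

# Known limitations

* No input-DNA (control track) subtraction inside signal quantification;
  control is assumed to have been used upstream at peak calling.
* No bigWig output (bedGraph input is supported; binned-signal tables are
  plot-ready TSVs).
* Expression validation is a per-type mean-FPKM concordance summary, not a
  statistical test.
* The CRC analysis assumes one SE per TF gene per tumor type (the nearest
  assignment); TFs regulated by several distinct SEs are collapsed to the
  merged entity nearest their TSS.
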