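---
title: "Methods: peak calling and differential methylation with mbdscan"
author: "mbdscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling and differential methylation with mbdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdscan)
```

## The assay and the inference problem

Methyl-binding-protein capture sequencing (MBD/MBP-seq) enriches genomic DNA
fragments that carry methylated CpGs: fragmented DNA is precipitated with a
methyl-CpG-binding protein, and the captured fraction is sequenced. After
mapping, methylated regions appear as local pileups of reads over a diffuse
background of non-specifically captured fragments. The inference problem is
that of ChIP-seq peak calling without an input control: each sample must be
compared against its *own* background, estimated from the bulk of the genome
that is not enriched.

`mbdscan` implements a four-stage peak finder on this principle, followed by
feature annotation, cross-sample differential calls and gene-set enrichment:

1. estimate the null distribution of the background signal,
2. scan fixed-width windows for counts higher than expected under that null,
3. merge overlapping candidate windows into peaks,
4. refine peaks by the spatial distribution of forward and reverse reads.

## Window counts

Each chromosome is tiled with windows of `window_size` bp (default 300)
placed every `step` bp from coordinate 0; the last partial window is kept.
A read is counted in every window containing its 5'-most coordinate
(`start` for `+` reads, `end - 1` for `-` reads). Counting by the 5' point
rather than by overlap makes the counts of a non-overlapping tiling an exact
partition of the reads — a conservation property the unit tests exploit —
and gives each fragment a single, strand-meaningful anchor.

The default step is `window_size / 3` (100 bp at the default window). The
scan statistic is defined per window, so a sub-window step only improves the
localization of peak boundaries; `step = window_size` recovers plain tiling,
in which case book-ended candidate windows are treated as contiguous during
merging.

## The negative-binomial null on low-coverage windows

Sequencing background is overdispersed relative to Poisson, so the null for
window counts is a negative binomial with mean $\mu$ and dispersion $k$
(variance $\mu + \mu^2/k$). Because enriched windows would inflate the fit,
the model is fitted only on "low coverage" windows: those with a count at or
below the `low_coverage_quantile` quantile of all window counts (default
0.90, computed as an inverse-ECDF quantile so the cutoff is an observed
count value). The default assumes enriched windows are a small minority;
for landscapes where methylation covers a large fraction of the genome the
quantile should be lowered, or the null will absorb part of the signal.

The fit is by the method of moments — $\hat\mu$ the sample mean,
$\hat k = \hat\mu^2 / (s^2 - \hat\mu)$ — which is closed-form and
well-behaved on the truncated count sample. Two degenerate regimes are
handled explicitly: when $s^2 \le \hat\mu$ there is no detectable
overdispersion and the null degrades to Poisson($\hat\mu$); when every
window count is zero the model is flagged degenerate and any window with a
read is subsequently called (there is no background to test against). At
$10^5$ windows the moment estimators recover $\mu$ to within 2% and $k$ to
within 10%, which the test suite checks on counts simulated from
NB($\mu = 3$, $k = 2$).

## The empirical FDR statistic

For a read count $c$ the empirical false discovery rate compares how many
windows the null *expects* at that count level with how many are *observed*:

$$\mathrm{FDR}(c) \;=\; \frac{P_{\mathrm{null}}(C \ge c)}
{\widehat{P}_{\mathrm{obs}}(C \ge c)}$$

clipped to $[0, 1]$. Both numerator and denominator use upper-tail
fractions. A per-count form ($P(C = c)$ over the observed fraction exactly
at $c$) is available via `mode = "density"`; the tail form is the default
because single-count observed fractions are noisy at high counts where only
a handful of windows exist, while tail fractions are monotone by
construction and stable.

Raw values are then regularized to be monotone non-increasing in $c$ by a
running minimum over increasing counts,
$\mathrm{FDR}^\ast(c) = \min_{c' \le c} \mathrm{FDR}(c')$. This never
increases a value and guarantees that raising the threshold `max_fdr` can
only add called windows, never remove one. Only count values actually
observed in the track are tabulated. The scan then returns every window
with $\mathrm{FDR}^\ast(\text{count}) \le$ `max_fdr` (default 0.01); the
defaults of 300 bp windows and a 1% FDR ceiling are the package's standard
operating point.

## Merging and strand-spatial refinement

Candidate windows overlapping by $\ge$ 1 bp are merged into peaks spanning
their union (book-ended windows merge only under plain tiling, as above).
Each peak's `read_count` is the number of reads whose 5' coordinate lies in
the merged span and `min_window_fdr` the minimum over its windows.

At a genuine enrichment site, fragments are sampled from both sides of the
methylated locus: forward-strand 5' ends accumulate on the left flank and
reverse-strand 5' ends on the right. `refine_peaks()` quantifies this with
a one-sided Wilcoxon rank-sum test of the alternative "forward positions
lie left of reverse positions", using midranks for ties. For
$n + m \le 20$ the p-value is exact — the fraction of all
$\binom{n+m}{n}$ rank assignments whose forward rank sum is at or below the
observed one, computed by a subset-sum dynamic program over doubled
midranks — and otherwise a normal approximation with tie and continuity
correction is used. The exact convention includes the observed point in the
tail, so the fully separated 3-vs-3 configuration gives
$p = 1/\binom{6}{3} = 1/20$, and a peak whose two
strands are identically placed is (correctly) non-significant with
$p \ge 0.5$.

By default refinement is annotate-only: the p-value is recorded on every
peak but none is dropped, because the count-based FDR already controls the
call set and any orientation cutoff is an additional modelling choice. With
`require_orientation = TRUE`, peaks with $p >$ `wilcoxon_alpha` — including
peaks with fewer than 2 reads on either strand, which are assigned
$p = 1$ — are removed.

## Feature annotation

Each gene contributes three strand-aware intervals in genome coordinates
(all 0-based half-open): the gene body `[min(tss, tts), max(tss, tts))` —
the transcribed span, exons and introns alike; the promoter, `flank_size`
bp upstream of the TSS; and the 3'-flanking region, `flank_size` bp
downstream of the TTS. The default `flank_size` of 20,000 bp defines a
deliberately wide regulatory neighbourhood — distal elements such as
enhancers commonly sit tens of kilobases from the TSS, and capture peaks
are assigned at 300 bp resolution, so a narrow 1–2 kbp promoter window
would leave most regulatory peaks unclassified; it is configurable.

The three classes can overlap across genes (one gene's promoter may lie in
another's body), so a peak is assigned the class with the largest overlap
in bp with the peak span, with ties resolved by the fixed precedence
gene body > promoter > 3'-flank; a peak overlapping none is intergenic.
Every peak thus receives exactly one of the four classes, and the class
fractions are also reported in the 3-way grouping (gene body, regulatory =
promoter + 3'-flank, intergenic) used in summary pie charts. The nearest
gene is the gene on the same chromosome whose TSS is closest to the peak
midpoint, with the signed distance negative upstream in the gene's
orientation.

## Differential calls and the normalized difference

Peaks are called per sample, each against its own background, and then
compared by interval overlap: a treated peak overlapping any control peak
by at least `min_overlap_bp` (default 1 — presence/absence is the
criterion, so any contact counts) is `shared`, a treated-only peak is
`hyper` (methylation gained under treatment), a control-only peak `hypo`
(methylation lost). Shared peaks are reported rather than discarded;
analyses of sample-specific sites simply filter on the label. When hypo
calls outnumber hyper calls the summary flags global hypomethylation.

Each call also carries a `normalized_difference`: with $a$ and $b$ the
reads in the peak span per million mapped reads in the treated and control
libraries,

$$\mathrm{nd} = \frac{a - b}{a + b} \in [-1, 1],$$

0 for balanced coverage, $+1$/$-1$ for one-sided signal, and 0 with a
degenerate flag when both counts are zero. The statistic is computed on
peak-span counts from per-million-normalized libraries; this definition is
isolated in one function so an alternative normalization can be swapped in.

## Gene-set enrichment

Focus genes — by default the nearest genes of non-intergenic, non-shared
calls, filterable by class and label — are tested against user-supplied
GMT gene sets with a right-tailed Fisher's exact test: the upper tail of
the hypergeometric distribution, accumulated from exact point masses. The
universe defaults to all genes in the gene model, not just genes appearing
in the sets, because the natural background is the annotated genome.
Raw p-values are reported alongside Benjamini–Hochberg adjusted values
across all tested sets; results are sorted by raw p with ties broken by
set id for determinism.

## The synthetic-data generator

`simulate_landscape()` plants non-overlapping methylated intervals on a
small multi-chromosome genome (control condition) and retains a uniform
random subset of them in the treated condition — the two-condition design
in which treatment erases methylated regions genome-wide, so
control-specific calls should dominate. `simulate_reads()` drops fragments
uniformly on the genome (length uniform on 50–350 bp, truncated at
chromosome ends; strand uniform) and models capture as per-fragment
acceptance: fragments overlapping a methylated interval of the condition by
$\ge$ 1 bp are always retained, background fragments with probability
$1/\text{enrichment\_factor}$, so the expected within-region window density
exceeds background by exactly the configured factor. Fragments are drawn
until the read target is met exactly, with sub-draws in a fixed order
(position, length, strand, acceptance) under one explicitly seeded RNG
stream per call, so identical seeds give byte-identical read sets. The two
conditions share the same background process but draw independently, as
pooled independent animals would.

The generator emulates count enrichment structure only. It does not model
base-level sequence, CpG density, capture-affinity dependence on
methylation density, sequencing error, mappability, duplicate reads, or
between-animal variance (each condition is one pooled sample). Passing
tests therefore demonstrate that the statistical machinery recovers planted
structure under the stated count model — not that real-data artifacts such
as mappability bias are handled.

## Validation conditions and problem sizes

The test suite validates the pipeline at desk scale, with every expected
value computed by an independent oracle (brute-force loops, full
permutation enumeration, reference implementations):

* the FDR table equals a per-count brute-force loop exactly on random
  tracks of up to $10^4$ windows;
* under a null-only simulation (enrichment 1, 10 Mb genome, $10^5$ reads,
  300 bp windows at step 100, FDR ceiling 1%, 10 seeds) the called-window
  fraction stays at or below 5% in every run;
* with 100 planted regions of ~1 kb on 10 Mb at enrichment 8 and in-region
  coverage of $\ge$ 10 reads per window, at least 90 regions are recovered
  at $\ge$ 50% reciprocal overlap;
* the hypomethylation contrast (retained fraction 0.6, enrichment 8, 25,000
  reads per condition on 2 Mb, 50 seeds) recovers the hypo > hyper
  direction in at least 45 of 50 runs;
* exact Wilcoxon p-values match full enumeration for all $n + m \le 12$,
  and the Fisher tail matches hypergeometric enumeration to $10^{-12}$.

These genome and library sizes are scaled-down study conditions chosen so
the background density (a few reads per 300 bp window) and the
signal-to-background ratio are in the regime the method targets.

## Numerical choices and limitations

* Quantiles for the low-coverage cutoff use the inverse ECDF (type 1), so
  the cutoff is always an observed count.
* The FDR ratio is undefined at counts never observed; such counts are not
  tabulated, and windows whose count has no table entry are never called.
* Annotation ties are deterministic (fixed class precedence; nearest gene
  by first minimum in gene-table order); enrichment output order is
  deterministic under p-value ties (set id).
* Peaks are called per sample against an assumed-homogeneous background;
  there is no input-control comparison, copy-number or mappability
  correction, and no replicate-aware dispersion estimate (the design pools
  samples per condition).
* The per-sample FDR controls window-level false discovery against the
  fitted null; the cross-sample hypo/hyper labels inherit those error
  rates and carry no additional joint significance measure.
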