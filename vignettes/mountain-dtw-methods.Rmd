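---
title: "Methods: arm-wise CNV curves, DTW similarity and the bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arm-wise CNV curves, DTW similarity and the bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mountaincnv)
```

This vignette is the package's own account of what it computes and why the
numerical choices are what they are. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## From segments to gene-level CNV

The input is segmented copy-number data: per sample, disjoint genomic
intervals with a `Segment_Mean` on a log2-ratio-like scale (0 = neutral).
A gene's value in a sample is the **unweighted arithmetic mean** of the
means of every segment that intersects the gene body — any nonzero overlap
counts, so a segment covering one base of a gene contributes fully. All
interval arithmetic is 1-based and fully closed (the TCGA seg convention);
segments of one sample may abut (`end`, `end + 1`) but never overlap, and
overlap is an error rather than a silent merge. The unweighted reading is
deliberate: "the average of all mapped segments" is taken at face value,
and an overlap-length-weighted mean is available behind
`map_segments_to_genes(weighted = TRUE)` for sensitivity checks. Genes with
no intersecting segment get `NA`, which propagates and is excluded
pairwise downstream — never imputed.

Analysis is restricted to autosomes, and non-primary samples are removed
before anything else using the TCGA barcode sample-type code: `01` primary
tumor, `02`–`09` other tumor (excluded by the primary filter), `10`–`14`
nonmalignant solid-tissue/blood controls.

## Mountain curves

A Mountain curve is the ordered per-gene summary of one chromosome arm for
one sample group: genes sorted by genomic start (ties broken
alphabetically by symbol, a fixed and therefore reproducible rule), each
carrying the group **median** (default) or mean. The median is the default
because single-sample extreme amplifications — which copy-number data
produce routinely — move a mean arbitrarily but a median at most to the
next order statistic. Genes are assigned to arms by position relative to
the centromere; a gene straddling the centromere goes to the arm holding
the larger share of its body, ties to p. The p arms of the acrocentric
chromosomes 13, 14, 15, 21 and 22 carry no profiled genes and stay empty
(a flag re-enables them when an annotation provides such genes), so a
fully profiled autosomal genome has 39 non-empty arms out of 44 slots.

## DTW similarity and its normalization

Two arms' curves are intersected to their common genes in shared order and
aligned by dynamic time warping with the standard three-predecessor
recursion

$$D(i,j) = d(i,j) + \min\bigl[D(i{-}1,j),\, D(i,j{-}1),\, D(i{-}1,j{-}1)\bigr],
\qquad D(1,1) = d(1,1),$$

with local cost $d(i,j) = |x_i - y_j|$ (absolute difference; a squared
variant sits behind `cost = "squared"`). The optimal warping path is
recovered by backtracking from $(n,m)$; cost ties prefer the diagonal
predecessor, then the vertical one — an arbitrary but fixed rule, so paths
are deterministic. The accumulated distance grows with arm length, so it
is mapped to a bounded per-step similarity

$$S = \frac{1}{1 + D(n,m)/K},$$

where $K$ is the warping-path length. This form was chosen over
alternatives because it is endpoint-correct ($D=0 \Rightarrow S=1$,
$S \to 0$ as curves diverge), strictly decreasing in $D$, and path-length
scaled so arms with different gene counts are comparable;
`method = "exponential"` selects $e^{-D/K}$, which shares the endpoints.
The choice of normalization (and of the local cost) is a design decision
of this package: published score tables from platform implementations of
the same idea cannot disambiguate the formula, and no numerical agreement
with any particular published table is claimed.

A consequence worth knowing when reading scores: DTW can warp *around* a
short spike but not around a long plateau, so the **length** of an
alteration depresses the score more than its height. A one-gene +2 focal
amplicon costs a couple of distance units; a +1 shift across 25 genes
costs ~25. The signed, absolute and squared index-wise distances
(Σ(x−y), Σ|x−y|, Σ(x−y)²) are reported alongside because the signed sum
cancels symmetric gains/losses that the other two expose. The genome-wide
score is the **sum** of arm scores over non-empty arms (39 on a full
genome, so identical cohorts sum to 39), with the arm count reported — a
deliberate aggregation choice that keeps arm scores and the genome score
on interpretable scales.

## The bootstrap test

Whether two groups' curves differ beyond sampling fluctuation is tested by
pooling the two groups' sample columns and drawing, with replacement, two
pseudo-groups of the original sizes; both curves and their normalized DTW
score are rebuilt per draw. A *low* score means a *large* difference, so
the lower tail is extreme and the add-one p-value is

$$p = \frac{1 + \#\{S_{\text{null}} \le S_{\text{obs}}\}}{B + 1},$$

with attainable floor $1/(B+1)$ — at $B = 999$ the smallest reportable p
is 0.001. The resampling unit is the sample (column), never the gene, so
gene–gene correlation along an arm is preserved under the null. The test
is deterministic under a seed and restores the caller's RNG state. Type-I
behaviour is checked in the test suite on 100 null fixtures (20 + 20
samples, $B = 199$) and sits at the nominal 5% level. Note the null is
*exchangeability of samples between groups*; with an alteration present in
every tumor, pooled pseudo-groups also carry it, which costs power for
focal events — visible in the worked example, where the one-gene spike is
not significant while the broad arm event hits the floor.

## Per-gene statistics

- `gene_test()` defaults to **Welch's** unequal-variance t-test (cohort
  variances differ; the pooled form is avoided), with the Wilcoxon
  rank-sum test as `method = "rank"`. Degenerate cases are explicit: two
  constant equal groups give $p = 1$; two constant different groups have a
  zero-variance statistic and give the smallest representable positive p
  with a warning.
- `adjust_pvalues()` defaults to Benjamini–Hochberg step-up q-values
  (deterministic and testable against the literal step-up definition); a
  fixed-λ (0.5) Storey-style variant rescales BH by an estimated null
  proportion; `"bonferroni"` returns the single threshold $\alpha/n$.
- Manhattan and Deflection amplitudes are $-\log_{10}(Q)$ — q-values,
  because thousands of genes are tested at once; the volcano keeps the raw
  p-value on its y axis, the convention for that display. All logarithms
  of significance are base 10.
- Directional signs come from group medians: group 1 below group 2 plots
  below the baseline (−1), above plots above (+1), equal medians sit on
  the baseline (0). The deflection winner is the cancer type with the
  larger absolute amplitude; exact ties are reported as `"tie"`.
- Volcano fold change is $\log_2((\bar x_1 + 1)/(\bar x_2 + 1))$ on
  expression (pseudo-count 1 on normalized counts avoids division by
  zero); on CNV matrices — already log2-ratio scale — the effect is the
  difference of group means, since a ratio of log-ratios is meaningless.
  Significance is strict: `p < cutoff`.
- The bee-swarm layout is a deterministic greedy packer: points in sorted
  value order, each taking the smallest-magnitude lateral offset that
  keeps it at least one point-diameter (in the plane) from every placed
  neighbour, magnitude ties going positive first so swarms grow
  symmetrically. Both axes share the diameter's units, so callers rescale
  values to plot coordinates when aspect ratio matters.

## The synthetic generator

`sim_config()` emulates a TCGA-style cohort: chromosomes with a centromere
between two arms (13/14/15/21/22 acrocentric), arms tiled by abutting
segments whose means are baseline 0 plus Gaussian noise, broad (whole-arm)
and focal (gene-span) alterations added to a configurable fraction of
tumor samples, and expression generated as
$\max(0,\ \beta_0 + \beta_1 \cdot \text{CNV} + \varepsilon)$. Sample ids
carry `-01`/`-11` barcode suffixes so the primary/nonmalignant filters are
exercised end to end. The defaults — 22 chromosomes, 25 genes and 10
segments per arm, 30 tumors vs 30 normals, segment noise sd 0.1, unit
expression noise with slope 2 — are the cohort scale and noise regime at
which arm-level analysis of array-segmented data is meaningful: 30 + 30 is
a small but realistic cohort pair, and 0.1 is the scale of segment-mean
jitter in quiet genomes. Test scenarios shrink the genome (2–4
chromosomes, 5–12 genes per arm) where the property under test does not
need 44 arms; the end-to-end recovery checks use the full default genome.

What the generator does **not** emulate: realistic breakpoint processes,
GC/wave artifacts, subclonality, tumor purity, or heavy-tailed expression
dispersion. Passing tests therefore demonstrate that the algorithms are
implemented correctly and recover planted structure under Gaussian
segment noise — not that any biological claim about real cohorts holds.

## Numerical and degenerate-input policy

Exact-equality oracles (DTW vs exhaustive path enumeration, gene mapping
vs brute-force interval scan, BH vs the literal step-up definition) are
asserted at tolerance 1e-12. Empty sample sets, sequences, or gene sets
are errors, except where an empty *result* is a legitimate outcome
(filtering to a class with no samples, acrocentric p arms), which warns
and returns an empty object. All-missing genes are dropped with a warning
and recorded by omission so two groups' curves intersect cleanly before
scoring.

## Known limitations

- No banded/windowed DTW: arms are at most a few thousand genes, so the
  full $O(nm)$ table (in compiled code) is cheap; extremely long inputs
  would need banding.
- The bootstrap's pooled null loses power for events carried by every
  tumor sample on short spans (see above); a label-permutation variant
  would behave similarly and is not provided.
- No segmentation (CBS), no GISTIC-style broad/focal decomposition, no
  MAF/methylation/miRNA readers, no web tier: segments come in as given,
  results go out as tables and static figures.
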