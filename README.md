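# mountaincnv

Copy-number variation (CNV) in cancer is organised along chromosome arms:
broad, arm-scale gains and losses coexist with short focal amplicons, and
two tumor cohorts can be compared by asking how similar their arm-wise
copy-number *profiles* are, not just which single genes differ.
`mountaincnv` implements that comparison for segmented CNV data
(TCGA-legacy style `*.seg.txt` files) at desk scale, for cancer genomicists
and biostatisticians who want the analysis without a platform around it:

- **gene-level CNV**: each gene's value in a sample is the unweighted mean
  of `Segment_Mean` over every segment intersecting the gene body (1-based
  closed intervals; partial overlap counts), restricted to autosomes, with
  non-primary samples removed by TCGA barcode code (`-01` = primary tumor,
  `-10`…`-14` = nonmalignant controls);
- **Mountain curves**: per chromosome arm, genes sorted by genomic start,
  each carrying the group median (default; the mean is an option) — the
  ordered track whose ups and downs profile arm-level alterations;
- **curve similarity**: dynamic time warping on two arms' aligned value
  vectors,

  ```
  D(i,j) = d(i,j) + min[ D(i-1,j), D(i,j-1), D(i-1,j-1) ],   d(i,j) = |x_i - y_j|
  ```

  normalized to a similarity score `S = 1 / (1 + D(n,m)/K)` in [0, 1]
  (`K` = warping-path length; identical curves score exactly 1), plus the
  three index-wise scores Σ(x−y), Σ|x−y|, Σ(x−y)², a genome-wide score
  (sum of arm scores over the 39 profiled autosome arms), and a
  pooled-resampling bootstrap p-value for each arm;
- **per-gene statistics** behind the classic displays: Welch/Wilcoxon tests
  with Benjamini–Hochberg q-values (volcano uses raw p, Manhattan and
  Deflection use q), directional signs from group medians, CNV–expression
  Pearson/OLS regression, and a deterministic bee-swarm layout;
- **a synthetic cohort generator** (SEG + annotation + layout + expression
  + truth record) with controlled broad/focal alterations, so the whole
  pipeline is testable offline.

## Worked example

Simulate a 4-chromosome cohort (30 tumors vs 30 normals, segment noise sd
0.1) carrying a broad +1.0 amplification of 2q and a one-gene +2.0 focal
event on 3p, then score every arm:

```r
library(mountaincnv)

cfg <- sim_config(
  n_chromosomes = 4, genes_per_arm = 12,
  alterations = list(
    alteration("2", "q", "broad", 1.0),
    alteration("3", "p", "focal", 2.0, focal_span = c(5, 5))),
  seed = 42)

gen <- generate_segments(cfg)
cnv <- map_segments_to_genes(gen$segments, gen$annotation)
tumors  <- grep("-01$", matrix_samples(cnv), value = TRUE)
normals <- grep("-11$", matrix_samples(cnv), value = TRUE)

similarity_report(cnv, gen$annotation, gen$layout,
                  tumors, normals, n_boot = 999, seed = 7)
```

```
  chromosome  arm   n_genes dtw_raw dtw_score signed_distance ... boot_p n_boot
1 1           p          12   0.272     0.981         0.163        0.298    999
2 1           q          12   0.175     0.989        -0.0335       0.908    999
3 2           p          12   0.244     0.982        -0.0952       0.269    999
4 2           q          12  11.7       0.507        11.7          0.001    999
5 3           p          12   2.16      0.881         2.16         0.302    999
6 3           q          12   0.202     0.988         0.225        0.729    999
7 4           p          12   0.153     0.991         0.00255      0.946    999
8 4           q          12   0.187     0.987         0.185        0.211    999
9 genome-wide <NA>       96  NA         7.30         NA           NA        999
```

The broadly amplified arm 2q stands out exactly as designed: its curves
diverge (score 0.51 vs ≈0.99 for unaltered arms, bootstrap p = 0.001, the
add-one floor at `n_boot = 999`), while the one-gene focal spike on 3p
lowers the score only mildly (0.88) — with DTW, the *length* of an
alteration matters more than its height. The signed/absolute/squared
distances separate directional shifts from cancelling ones, and the
`genome-wide` row sums the arm scores. `plot_mountain()`,
`plot_manhattan()`, `plot_deflection()`, `plot_volcano()` and
`plot_beeswarm()` render the corresponding displays, and the same pipeline
is scriptable through the `mountaincnv` CLI (`inst/cli/mountaincnv`):
`simulate`, `map-genes`, `mountain`, `similarity`, `manhattan`,
`deflection`, `volcano`, `beeswarm`, `correlate`.

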