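---
title: "Methods: a cis co-expression screen for lncRNAs in a small two-group RNA-seq design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cis co-expression screen for lncRNAs in a small two-group RNA-seq design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreen)
```

## The scientific problem

Long non-coding RNAs (lncRNAs) frequently regulate genes in *cis*: the
coding gene they overlap, or their nearest coding neighbour. In a bulk
RNA-seq experiment on a sorted neuronal population with a small two-group
design (six exposed and five control animals, eleven libraries in total),
a practical first-pass screen for candidate cis-regulation is:

1. classify every annotated gene by biotype, and every lncRNA by its
   position relative to protein-coding genes (antisense, intergenic
   "lincRNA", sense-intronic, sense-overlapping, 3'-overlapping);
2. keep genes whose mean expression across all eleven samples exceeds
   1 count per million (CPM);
3. pair each expressed lncRNA of the antisense, lincRNA and
   sense-intronic classes with its overlapping or nearest expressed
   protein-coding gene(s);
4. call a pair co-expressed when the Pearson correlation of the two
   expression profiles across the eleven samples exceeds, in absolute
   value, the analytic critical value of the correlation coefficient at a
   two-tailed 5 % level;
5. characterize the significant pairs: sign of the correlation, span
   overlap, overlap of the lncRNA with the coding gene's promoter window,
   relative expression level, and transcription from annotated enhancer
   intervals;
6. separately, test each gene for differential expression between the two
   groups with more than one caller and take the intersection of the
   significant calls.

This package implements each of these stages as an isolated, testable
function, plus a driver (`run_screen()`) that chains them, and a seeded
synthetic-data generator that emulates the study design so every
statistical behaviour can be verified against a known ground truth.

## Coordinate and counting conventions

Internally all intervals are 0-based half-open `[start, end)`. The GTF
dialect (1-based inclusive) is converted at the `read_gtf()` /
`write_gtf()` boundary and nowhere else; BED input is already half-open.
Overlap always means at least one shared base. The transcription start
site (TSS) is the first transcribed base: `start` on the plus strand,
`end - 1` on the minus strand. The promoter window is the 10-kb interval
immediately upstream of the TSS, clipped at coordinate zero.

Reported percentages are rounded half away from zero
(`round_half_away()`), not with base R's banker's rounding: a summary
that averages to 70.45 % must print 70.5, and integer prose percentages
such as 72 % of 82 pairs are reproduced exactly by the same rule.

CPM uses the externally supplied per-library size — the number of
read-pairs mapped to the genome — as its denominator, not the exonic
column sum; `cpm_normalize(..., denominator = "column_sum")` provides the
generic alternative. The expression filter keeps genes with mean CPM
strictly above 1 across all samples.

## The correlation screen

For `n` samples the critical Pearson value at two-tailed level `alpha`
follows from the exact null distribution of the sample correlation via
the t transform `t = r * sqrt((n - 2) / (1 - r^2))`:

```{r crit}
critical_r(11, 0.05)   # the 11-sample design
critical_r(12, 0.05)
```

A pair is significant when `|r|` strictly exceeds this value. No
multiple-testing correction is applied across pairs — the fixed per-test
critical value *is* the screen's decision rule, which is why the
synthetic null calibration (below) checks the per-pair false-positive
rate, not a family-wise rate. Pairs with a zero-variance profile have an
undefined correlation; they are skipped and tallied, never silently
dropped. Correlation is computed on raw CPM by default (`scale = "log2"`
is available); the choice matters for the realized `r` values but not for
the invariances the tests pin down (affine invariance, symmetric
treatment of both genes).

## Differential expression: three callers and an intersection

`de_exact()` implements an exact conditional test on group-aggregated
counts: with `k_A` read-pairs for a gene in group A (total library size
`L_A`) and `k_B` in group B, conditional on `k = k_A + k_B` the count
`k_A` is Binomial(`k`, `L_A / (L_A + L_B)`) under a common rate. The
two-sided p-value is the minimum-likelihood sum over outcomes no more
probable than the observed one. `de_poisson()` is its asymptotic
counterpart, a Poisson deviance likelihood-ratio test with library-size
offsets. Both deliberately ignore biological replicate-to-replicate
variability, so under overdispersed counts their type-I error is
inflated; the package's simulations report this honestly rather than
hiding it, and the caller intersection exists precisely to temper it.

`de_permutation()` relabels the eleven samples exhaustively (462
relabelings for 6-vs-5) using the absolute difference of group mean CPM
as statistic. It respects biological variability but has a hard
resolution floor of 1/462 ≈ 0.0022: after Benjamini–Hochberg adjustment
across a transcriptome-scale gene set, tied null genes push every
adjusted value toward 1, so permutation q-values can reach a 0.05 cutoff
only for gene sets of a few dozen genes. It is therefore shipped as a
calibration diagnostic, and the default transcriptome-scale intersection
pairs the exact caller with the Poisson deviance caller. (For an equal
group split the floor doubles, because each relabeling and its complement
produce the same symmetric statistic.)

`intersect_calls()` takes the genes with `q <= 0.05` in *every* supplied
call set; its cardinality is monotone non-increasing in the number of
callers.

## The synthetic-data generator

`synthetic_config()` freezes the study conditions: 6 exposed vs 5 control
samples, a census of 16,014 expressed genes across thirteen biotype
leaves (84.5 % protein-coding, 10.7 % ncRNA, 4.8 % pseudogene), library
size 10^6 read-pairs (a desk-scale default; real libraries are ~30-fold
deeper), negative-binomial counts with one global dispersion
`phi = 0.1`, log-normal baseline expression (log2-CPM normal with mean 3,
SD 2, truncated below at 1 so the matrix emulates an already-filtered
expressed transcriptome), sixteen planted co-expressed lncRNA/coding
pairs at target correlation 0.9 in the 8:6:2
antisense : lincRNA : sense-intronic mix, and one planted antisense
lncRNA (three exons, 662-nt mature transcript, overlapping two coding
genes) upregulated 80-fold in the exposed group at an all-sample mean of
4.5 CPM.

Planted pairs share a per-sample standard-normal latent factor on the
log scale. The loading is calibrated in closed form (`pair_loading()`):
with baseline count mean `m`, lognormal multiplier of natural-log SD
`sigma` and NB dispersion `phi`, the count covariance of a pair with
loading product `c` is `m^2 (exp(sigma^2 c) - 1)` against a per-gene
variance `m + phi m^2 e^{sigma^2} + m^2 (e^{sigma^2} - 1)`; solving for
the target correlation and clipping the loading product to `[-1, 1]`
gives both the loading and the analytically expected realized
correlation. Sampling noise bounds the attainable `|r|` (about 0.91 at
the default dispersion), and the lognormal construction also bounds how
*negative* a planted correlation can be; the truth table stores
`expected_r` so tests compare against the attainable value, not the
naive target.

Annotation geometry is deterministic: each planted pair occupies an
isolated 200-kb block on chr1 realizing its requested geometry exactly
(antisense overlap, adjacency with promoter overlap, or plain
adjacency); background genes fill chr2 onwards in seeded shuffled order
in 40-kb slots so nothing overlaps unintentionally and the census is met
exactly. One enhancer interval covers the TSS of the first planted
antisense lncRNA; the remaining intervals are decoys in gene-free space.
`write_fixture_bundle()` emits the exact dialects the pipeline readers
consume (GTF, TSV, BED3, truth tables, config JSON) and is
byte-reproducible given the seed.

### What the generator does and does not establish

Passing the recovery suites shows the pipeline's statistics behave as
designed **under the generator's assumptions**: independent NB counts
with a single global dispersion, lognormal baselines, equal library
sizes, and planted structure that is exactly cis in geometry. It does not
validate performance on real data, where dispersion varies per gene,
libraries differ several-fold, counts correlate through shared biology,
and annotation is imperfect. In particular, the exact and Poisson callers
are anti-conservative under NB noise by construction — the synthetic DE
suite measures recovery of a planted 80-fold signal, not false-discovery
control against biological replicate variance.

One resolution limit deserves emphasis. At the desk-scale depth of 10^6
read-pairs, the planted DE gene's control baseline is ~0.1 CPM ≈ 0.1
counts per sample, so a ratio estimator is dominated by count
granularity: a control group total of 0 versus 1 moves the estimated
fold by an order of magnitude, and no pseudocount choice fixes both cases
at once. Detection (the gene surviving the caller intersection) is robust
at desk depth; fold-magnitude recovery within a factor of two of the
planted 80 is only expected — and only tested — at a realistic depth of
2 × 10^7 read-pairs.

## Metabolic helpers

The package also bundles the small, exactly checkable formulas of the
physiological side of such a study: Friedewald-style lipid derivation
(`VLDL-C = TG/5`, `LDL-C = TotChol − HDL-C − VLDL-C`, negative results
flagged rather than clipped), trapezoidal area under tolerance-test
curves (exact on piecewise-linear data, additive over partitions,
optionally baseline-subtracted), qPCR ΔΔCt fold change (`2^(−ΔΔCt)`,
invariant to a constant Ct shift), and the daily dose delivered through
drinking fluid at a given formulation concentration (200 µg/mL default;
3.85 mL/day ↦ 0.77 mg/day).

## Design decisions worth knowing

- **3'-overlap classification** is a gene-level approximation: the
  overlap must be confined to the coding gene's 3'-most exon. Same-strand
  overlaps matching none of the specific geometries fall back to
  `sense_overlapping` rather than erroring. Trusted subclass tags in the
  annotation short-circuit geometry (`use_tag = FALSE` re-derives).
- **Nearest-partner ties** return all tied coding genes, and overlap
  always beats any distance, so one lncRNA can legitimately contribute
  several pairs.
- **Enhancer transcription** defaults to TSS containment
  (`start <= tss < end`, half-open); `mode = "any"` relaxes to any span
  overlap.
- **Determinism**: every bundle and every report is a pure function of
  its inputs and parameters; the run log records the package version,
  input checksums and all parameters.
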