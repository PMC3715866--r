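---
title: "Methods: ranking cell lines as tumour models from genomic profiles"
author: "cellmodelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking cell lines as tumour models from genomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cancer cell lines are chosen as laboratory models of a tumour type mostly by
historical convention, yet their genomes can differ substantially from the
tumours they are meant to represent. For high-grade serous ovarian cancer
(HGSOC) the genomic signature is well defined: near-universal TP53 mutation,
extensive DNA copy-number alteration, and a comparatively low coding
mutation rate, while the other ovarian-cancer subtypes (endometrioid, clear
cell, mucinous, low-grade serous) instead carry mutations in a small set of
signature genes (ARID1A, BRAF, CTNNB1, ERBB2, KRAS, PIK3CA, PTEN) on flat
copy-number backgrounds. `cellmodelr` turns that contrast into a
reproducible scoring pipeline: given segmented copy-number profiles,
mutation catalogues with coverage information, and expression matrices for
a tumour cohort and a cell-line panel, it ranks the cell lines by how well
they match the cohort's genomic signature.

## Copy-number concordance

Segmented profiles are tables of `(sample, chromosome, start, end, log2
ratio)`. Coordinates are treated as 1-based, fully closed intervals — the
convention of SEG exports from the major genomics portals — so a segment's
length is `end − start + 1`, and analyses run on autosomes only (sex
chromosomes are dropped on read).

**Fraction genome altered (FGA)** summarises how much of a genome deviates
from diploid:

$$\mathrm{FGA} = \frac{\sum_i L(i)\,[\,|CN_i| > T\,]}{\sum_i L(i)}$$

with $CN_i$ the segment's log2 copy ratio and $L(i)$ its base-pair length.
Both gains and losses count as alterations, and the inequality is strict.
The threshold is platform- and purity-dependent: the default is $T = 0.2$
for tumours, whose signal is attenuated by stromal contamination and
heterogeneity, and $T = 0.3$ for the purer cell lines. We use base-pair
lengths for $L(i)$ rather than probe counts; with reasonably uniform probe
spacing the two weightings agree closely, and base pairs are
platform-independent.

**Gene-level mapping.** To compare profiles from different platforms,
segments are mapped to a common gene space. A gene's value in a sample is
the segment-length-weighted mean of the log2 ratios of all segments
overlapping the gene body; this is robust to genes straddling breakpoints.
A `largest_overlap` rule (take the single dominant segment's value) is
available as an option. Genes covered by no segment are missing, not zero.

**Three similarity measures.** For each cell line we compute Pearson
correlations of its gene-level profile with (a) every single tumour, (b)
the median of those per-tumour correlations, and (c) the cohort **mean
profile** (per-gene mean over tumours, which preserves recurrent events
while noise averages out). The maximum single-tumour correlation is also
reported. Every correlation uses pairwise-complete genes so each comparison
exploits the maximal shared information; an undefined correlation (zero
variance) propagates as missing with a warning and is excluded from the
median — it is never silently zero. High-level amplifications are called at
log2 ratio strictly above 1.0 by default.

The mean profile includes all cohort samples by default, including any
flat TP53-wild-type tumours; because these are few and flat, their effect
on the mean is a mild shrinkage toward zero that does not change the
ranking.

## Mutation burden

Mutation catalogues are validated against a fixed classification
vocabulary; dataset-specific spellings are translated by an editable YAML
map, because classification vocabularies drift across dataset versions.
The **likely-functional filter** removes intronic, UTR, flanking,
intergenic, silent and RNA records; splice-site and in-frame indels are
retained. The filter is idempotent, and burden computation refuses
unfiltered input unless explicitly acknowledged.

Burden is coverage-corrected: `frequency = functional count / bases
covered × 10^6`. Two coverage dialects are supported, mirroring how
cohorts actually distribute coverage: per-base read-depth tracks in wig
format (covered = positions with ≥ 1 read) and per-exon tables of length
and coverage fraction (covered = Σ length × fraction, summed in real
arithmetic and rounded once — per-row rounding would bias the sum). Each
mutation record counts once; multiple records in the same gene are not
collapsed, since catalogues list distinct variants. Note that some panels
include private germline variants while tumour cohorts report mostly
somatic calls; burdens therefore reflect what the input contains, and
marker flags accept an optional somatic-only switch rather than hiding the
asymmetry.

## The suitability score

A cell line is a good HGSOC model when its copy-number profile correlates
with the cohort mean, it carries a TP53 mutation, it is not hypermutated,
and it lacks mutations in the seven non-HGSOC signature genes. These are
assembled per line as

- $A$: correlation with the mean copy-number profile,
- $B$: 1 if TP53 is mutated,
- $C$: 1 if hypermutated,
- $D$: number of mutated non-HGSOC panel genes (0–7),

and combined into the score

$$S = w_A A + w_B B - w_C C - w_D D.$$

The default weights $(1, 0.5, 0.5, 0.25)$ put each term on a comparable
dynamic range ($A$ spans about one unit; $D/4$ spans at most 1.75). All
weights are configuration, must be positive (the signs are structural),
and are recorded in the output metadata so a ranking is always
reproducible from its components.

**Hypermutators** are flagged when frequency exceeds 10 per Mb *and* FGA
falls below 0.25. The frequency cut sits roughly halfway between typical
cell-line rates (~4 per Mb) and the outlier regime (≥ 13 per Mb), and the
FGA cut requires a visibly flat profile; both are configurable. The
mutation rate enters the score only through the binary $C$.

**Tiers.** Lines are sorted by $S$ descending (ties broken by $A$, then by
identifier, with a note recorded) and split into good/moderate/poor either
by counts (default: top 12, bottom 12) or by score cuts — both modes are
provided because a tier boundary is ultimately a reporting convention. The
ordering is intended to separate better from poorer models, not as a
finely graduated ranking.

## Expression analyses

Expression values are standardised per gene with **robust z-scores**,
`(x − median)/MAD`, using the *plain* MAD without the 1.4826 consistency
factor (a `consistent` switch is provided). Genes with zero MAD are
dropped with a logged count. The most variable genes are selected by
interquartile range (type-7 linear-interpolation quantiles; ties at the
boundary broken by gene symbol so the selection is reproducible — the
quantile convention matters because it shifts boundary genes). The
sample–sample distance is `1 − r` (Pearson), clustered with Ward's method
(R's `ward.D2`) for within-panel analyses or complete linkage for combined
tumour/cell-line analyses. PCA runs on the gene-centred matrix with a
fixed sign convention (largest-magnitude loading positive) so embeddings
are identical across runs and platforms.

Two datasets from different platforms are combined by z-scoring each
separately and joining on the shared genes. Cell lines are ranked by the
mean of their correlations with all tumours over the shared gene space,
and that ordering is compared with the suitability ordering via
**Kendall's tau-b** (tie-corrected, since tier-derived rankings can
contain ties) with an exact enumeration p-value for n ≤ 8 and a normal
approximation with tie-corrected variance and continuity correction
otherwise; the method used is recorded in the result.

## The synthetic cohort generator

Because the real cohorts behind this kind of analysis are external
downloads, the package ships a seeded generator whose defaults *are* the
study conditions the pipeline assumes, so every stage is testable
end-to-end:

- **Tumours** (default 316, 2,200 genes on 22 chromosomes): six broad
  recurrent events (gains on chromosomes 2/5/14, losses on 4/6/16,
  amplitude ±0.8, prevalence 0.7) plus Gaussian segment noise (sd 0.15);
  TP53 mutant with overall probability 0.95, wild-type tumours
  preferentially flat so the flat TP53-wild-type subpopulation is ~5%;
  functional mutation rate 1.6 per Mb over 30 Mb of per-exon coverage.
  Variant classes follow a fixed mixture (70% missense, 10% silent, 10%
  frameshift/nonsense, 10% non-coding), so the functional filter has real
  work to do; rates are interpreted as functional rates and totals drawn
  as Poisson(rate/0.8 × Mb). Background mutations never hit TP53 — its
  status is controlled by the explicit indicator, keeping the calibration
  exact.
- **Cell lines** (default 47 = 12 HGSOC-like + 30 non-HGSOC + 5
  hypermutators): HGSOC-like profiles equal the tumour mean profile plus
  per-gene noise (sd 0.1) with an explicit TP53 mutation and a clean
  non-HGSOC panel; non-HGSOC lines are flat (sd 0.05), TP53 wild-type,
  with 1–3 planted functional panel mutations; hypermutators are flat
  with 15 functional mutations per Mb. Coverage is per-base (wig).
- **Expression**: every sample is a noisy baseline plus *sparse positive
  activations* (probability 0.3 per gene and sample) of a gene
  programme — a tumour signature for tumours, re-expressed at attenuated
  magnitude (2 vs 6) in HGSOC-like lines, a different programme in other
  lines — and all cell lines additionally activate a dedicated platform
  gene set at magnitude 12. The sparse-activation form is deliberate: a
  constant per-gene offset would be removed exactly by per-dataset robust
  z-scoring, whereas real platform artefacts are asymmetric and survive
  it. Sparse spikes shift per-gene means without moving medians, which is
  what lets the combined analysis reproduce the observed division between
  cell lines and tumours after separate z-scoring.

The generator takes explicit seeds everywhere, restores the caller's RNG
state, and identical `(spec, seed)` pairs are bit-identical. It does **not**
emulate every feature of real data — no dosage coupling between copy
number and expression, no subclonal heterogeneity, no germline/somatic
mixture, equal-length genes — so passing tests demonstrate that the
*pipeline machinery* is correct under the assumed statistical structure,
not that the biological conclusions transfer to any particular real
cohort.

## Numerical and design choices

- SEG round-trips are bit-exact: log2 ratios are written with 17
  significant digits and re-read with a correctly-rounded parser.
- Gene mapping, FGA and burden are checked against per-base brute-force
  oracles in the test suite; the Kendall p-value is checked against
  exhaustive permutation enumeration at n = 7.
- Deterministic tie-breaks everywhere a sort appears (score ties by `A`
  then identifier; IQR ties by gene symbol; PCA signs by largest
  loading).
- Degenerate inputs fail loudly: empty profiles, non-positive thresholds,
  unknown classification labels, zero-variance vectors, missing marker
  flags and sample mismatches are all errors or explicit missing values,
  never silent defaults.
- Pipeline stages communicate through TSV files in the output directory,
  so each stage is independently re-runnable and testable; a manifest
  records the configuration hash, seed and package version.

At the synthetic scale used in the tests and the acceptance script
(2,200 genes, 316 tumours, 47 lines, 100 panel replicates for the
recovery checks), the full pipeline and suite run comfortably on a single
CPU; the gene count and replicate numbers are package choices that keep
the brute-force oracles cheap while leaving every statistical property
intact.

## Known limitations

- The suitability weights are a documented convention, not estimated from
  data; rankings under different weightings should be compared with the
  recorded metadata.
- The expression concordance on synthetic data is driven by the shared
  programme between tumours and HGSOC-like lines; its magnitude is not
  calibrated to any real cohort.
- Recurrent-event detection (peak calling) and batch-effect correction
  are out of scope: segmented input is assumed, and the batch separation
  is itself a reported observation rather than something to remove.
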