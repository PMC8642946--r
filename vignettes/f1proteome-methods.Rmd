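---
title: "Methods: genetic architecture of protein expression in a reciprocal F1 cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic architecture of protein expression in a reciprocal F1 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f1proteome)
```

# The study design

`f1proteome` analyses quantitative proteomes of two inbred mouse strains —
C57BL/6J (B6) and DBA/2J (D2) — and their reciprocal F1 hybrids (B6D2F1:
B6 mother; D2B6F1: D2 mother), profiled together in one isobaric-label
(TMT) batch with both sexes per genotype. The design supports four
questions: which proteins differ between the parental strains; how protein
abundance is inherited (additive vs dominant, and how heritable); whether
the two alleles of a heterozygous F1 are expressed unequally at the
protein level (pASE); and how protein-level regulation compares with
transcript-level allele-specific expression.

Because the raw mass-spectrometry and RNA-seq data are not required here,
a first-class synthetic-data module generates every input with the
statistical structure the analyses assume, including planted ground truth.
All downstream stages are exercised and validated against that truth.

# TMT quantification

PSM-level reporter intensities (linear scale) are processed in a fixed
order:

1. **Isotope-impurity correction.** Observed intensities are `m %*% x` for
   impurity matrix `m` (entry *i, j* = fraction of channel *j* read in
   channel *i*); correction solves the system per PSM. Negative solutions,
   which arise from noise near zero, are clipped to 0 and flagged rather
   than failing — the standard practice for impurity deconvolution.
2. **Intensity filtering.** A PSM is dropped when its cross-channel
   minimum is below 1000 or its median below 5000 (defaults), or when more
   than half its channels are missing. Removals are recorded, not silent.
3. **Loading normalisation.** Channels are scaled so trimmed medians of
   log2 intensity agree. The trim fraction (default 10% per tail) is
   configurable; note that a median after *symmetric* trimming equals the
   plain median, so the parameter matters only for documentation and for
   any asymmetric extension. Whether the reference statistic operates on
   raw or log2 intensities was an open choice; log2 is used because
   loading bias is multiplicative.
4. **Protein roll-up.** The relative profile of a protein is the mean of
   its PSMs' mean-centred log2 profiles (missing values excluded, rows
   re-centred); the absolute scalar is the grand mean of its three most
   intense PSMs (by summed cross-channel intensity, ties broken by psm_id
   for determinism).

With zero PSM noise the chain recovers planted relative profiles exactly
(float tolerance), which the test suite asserts.

# Differential expression, SPE, and the hybrid screen

The B6-vs-D2 contrast uses an empirical-Bayes moderated t-test: pooled
per-feature variances are shrunk towards a prior estimated by
moment-matching a scaled inverse chi-square distribution on the log sample
variances (`limma::squeezeVar`), and the statistic uses d0 + d degrees of
freedom. With n = 2 per group this borrowing of strength is what makes the
screen usable; `d0 = 0` recovers the ordinary pooled t-test and `d0 = Inf`
the fully-shrunk limit, both kept as testable limits. Features with zero
sample variance receive the prior variance through shrinkage and are never
dropped.

Defaults follow the study thresholds: BH-adjusted p < 0.05 and |log2FC| >
1.5. The volcano-style presets ("strict": 4-fold, 1% FDR; "lenient":
2-fold, 5% FDR) are provided as named configurations; where the figure
annotation and the stated thresholds disagree, the stated thresholds are
the default.

Single-parent expression is the extreme tail of differential expression:
per parental strain, log2 abundances are z-scored **across proteins**, and
a protein is SPE when one parent sits above its strain's 25th-percentile
cut-off while the other falls below its 5th-percentile cut-off. The
alternative reading (z-scoring per protein across strains) collapses for a
two-parent design, so the across-proteins reading is implemented; the
screen is intended to run on the differential set (a `proteins` argument
restricts it).

The reciprocal-hybrid screen contrasts B6D2F1 vs D2B6F1 with raw p < 0.01
and |log2FC| > 0.3. The fold-change threshold is interpreted on the log2
scale: a raw fold change of 0.3 would be a ~3-fold *decrease*,
inconsistent with reporting both up- and down-regulated candidates.

`simulate_power()` plants log2 shifts into null Gaussian data and reports
detection power and observed false-discovery proportion per effect size at
BH level alpha, reproducing the design's power analysis at n = 2.

# Inheritance: relatedness matrices, REML, D/A

The per-protein mixed model is

y = mu + A + D + S + e,  A ~ N(0, sigma_a^2 R1),  D ~ N(0, sigma_d^2 R2),
e ~ N(0, sigma_e^2 I),

with sex S a fixed effect. R1 and R2 are pedigree expectations for the
four genotypes (order B6, D2, B6D2F1, D2B6F1):

```{r}
build_relatedness_matrices()[c("R1_strain", "R2_strain")]
```

Sample-level expansion sets same-genotype pairs to 1 in both matrices —
inbred and F1 animals of one genotype are isogenic. That expansion is rank
deficient, so a relative ridge of 1e-8 is added to covariance diagonals
before Cholesky factorisation (with one larger-ridge retry).

Restricted maximum likelihood is maximised by Nelder-Mead search over
log-variances from three fixed starting points (balanced, additive-heavy,
residual-heavy), convergence tolerance 1e-8 on the restricted
log-likelihood. The data are variance-standardised internally so the
estimator is exactly scale-equivariant (components scale by var(y), H2
invariant). Components estimated below 1e-6 x var(y) are set to 0 and
flagged as boundary estimates.

**The sex variance Vs.** Sex enters the model as a fixed effect, yet the
heritability denominator includes a sex variance. The implemented reading
defines Vs as the population variance across samples of the fitted sex
term (beta^2/4 for a balanced 0/1-coded design) — the only reading that
makes H2 = (Va + Vd) / (Va + Vd + Vs + Ve) computable from a fixed-effect
fit. A `sex = "random"` variant adds a same-sex covariance component and
reports its REML estimate instead; neither reading is asserted to
reproduce the original per-protein table, which would require the real
data.

The dominance/additivity ratio is D/A = [mean(F1s) − mid-parent] /
[max(B6, D2) − mid-parent]; 0 is purely additive, ±1 complete dominance.
Equal parents make the ratio undefined; such proteins are flagged and
excluded from D/A distributions. The class labels (|D/A| ≤ 0.25 additive,
≤ 1.25 dominant, above that over/under-dominant) are a convention for
summarising the continuous ratio, not a claim from the source analyses.

# Proteogenomics and protein ASE

The B-allele is **defined** as the reference (GRCm38/UniProt-style)
sequence and the D-allele as the missense-substituted sequence, matching
how D2 variants are called against the mouse reference. A customised
database appends one substituted entry per (protein, variant) with a
structured header. Tryptic digestion cleaves after K/R, suppressed before
proline, with up to 2 missed cleavages and peptide lengths 6–50 (the
observable MS range; only the missed-cleavage setting is inherited from
the search parameters, the length bounds are a documented default).

Variant peptide pairs are aligned **by coordinates**: a substitution that
neither creates nor destroys a cleavage site leaves both digests aligned,
so the D-allele peptide covering a variant pairs with the reference
peptide of identical start/end. When the substitution changes the
cleavage pattern the coordinates no longer align and the peptide is
emitted as a singleton with reason `site_change`. Pairs differing only by
isoleucine/leucine are flagged MS-indistinguishable (equal mass) rather
than dropped. Modification strings in identified-peptide input are
stripped by removing bracketed groups and non-uppercase characters before
matching.

Allelic ratios are log2(B) − log2(D): parental rP from each allele in its
carrier strain, F1 rF1 within hybrid samples. Ionisation-efficiency bias
between the two peptide forms is *not* corrected — the two sequences have
different chemical properties, so absolute allele amounts are not
comparable — but the bias is shared between parents and F1s and cancels
when ratios are compared across genotypes, which is all the
classification uses.

The five-way classification at threshold tau = 1 log2 unit (the only
printed ratio threshold):

| parental change (abs rP ≥ tau) | F1 change (abs rF1 ≥ tau) | signs | category |
|---|---|---|---|
| yes | yes | equal | cis |
| yes | no | — | trans |
| no | yes | — | compensatory |
| no | no | — | conserved |
| yes | yes | opposite | unexpected bias |

The cis criterion "F1 ratio similar to the parental ratio" is
operationalised as same-sign super-threshold ratios (an axis-aligned
partition of the plane); the diagonal-band alternative (|rF1 − rP| < tau)
is available as `mode = "proximity"`. The opposite-sign rule for
"unexpected bias" is an explicit convention — such pairs may reflect
false identification or measurement error, and in real data deserve
inspection. Significance gating (requiring BH < 0.05 from the moderated
allele test before a ratio counts as changed) is available but off by
default, since the classification is ratio-based.

# Transcript ASE and the cross-level comparison

Hybrid allele counts are pooled (summed) across hybrid samples per gene —
the unit of inference is the gene, not the sample — and tested with the
exact binomial test against 0.5, using the minimum-likelihood two-sided
convention, BH-adjusted. Genes with pooled totals below 10 reads are
skipped (a documented default; no depth filter is stated in the source).
The F1 ratio for classification uses a 0.5 pseudocount, whose effect on
ratios is negligible (< 0.05 log2 units) at totals ≥ 100. The transcript
classification calls the identical `classify_regulation()` implementation
used for proteins.

The cross-level comparison tabulates ASE (non-conserved category) vs
non-ASE membership at each level over shared genes and applies the exact
two-sided Fisher test, plus a per-category co-membership table.

# The synthetic-data generator

The generator emulates the study design, not the dataset:

* **Proteome.** Genotype means follow mu + a·g + d·h with additive scores
  g = +1 (B6), −1 (D2), 0 (F1) and dominance scores h = 1 for F1s
  (the classical cross-mean parameterisation, oriented so that
  B6 − D2 = 2a matches the log2(B6/D2) convention); per-protein effects
  are drawn with SDs sigma_a, sigma_d, sex effect sigma_s, residual
  sigma_e, and a configurable fraction of null proteins. PSM intensities
  are linear lognormal draws around 2^(protein level) with per-PSM
  ionisation efficiency, channel loading-bias multipliers and optional
  isotope-impurity mixing.
* **Pedigree mode.** `additive_model = "pedigree"` draws genotype-level
  effects from N(0, sigma_a^2 R1) and N(0, sigma_d^2 R2) — the exact
  generative model of the REML estimator. Parameter recovery of an
  estimator is only well-posed under the estimator's own model, so
  recovery studies (median estimated H2 vs (sigma_a^2 + sigma_d^2) /
  (sigma_a^2 + sigma_d^2 + sigma_e^2)) use this mode; the cross-mean mode
  remains the default for the phenotypic screens.
* **Variant pairs.** Sequence pairs are tryptic-like (C-terminal K/R,
  internal residues that cannot create or destroy cleavage sites) and
  carry planted categories: cis (rP = rF1 = ±effect), trans (parental
  only), compensatory (F1 only), conserved (neither), unexpected
  (opposite signs). The B-peptide is missing (NA, not zero) in D2
  animals and vice versa — each parent carries only its own allele. A
  small synthetic reference proteome realising each B-peptide as a
  digestion product, with its variant table, links the generator to the
  enumeration code. Default per-sample log2 noise is 0.25, a typical
  replicate CV for isobaric data (~18%).
* **Allele counts.** Hybrid B-counts are Binomial(n, p) with
  p = 2^r / (1 + 2^r) at the planted F1 ratio r and Poisson(depth)
  totals; parental expression levels encode the parental ratio. Default
  depth is 100 reads per gene per sample.

The residual noise magnitude of the original TMT data is not stated
anywhere; the defaults (sigma_e = 0.5 log2, PSM CV 10%) are plausible
values for deep isobaric proteomes and are placeholders for test
sensitivity — passing recovery tests demonstrates correctness of the
machinery under these conditions, **not** equivalence to the real
dataset. Features of real data that the generator does not emulate
include peptide-level interference/ratio compression, shared peptides
across proteins, batch structure beyond a single plex, and
mapping-bias in allele counts.

# Problem sizes and runtime choices

The bundled analyses use 1000 proteins (power simulation: 1000 features x
5 replicates), 500 variant pairs, 2000 genes; recovery studies for the
variance-component estimator use 2000 proteins, where the per-protein
Nelder-Mead REML fit (3 starts, 8 samples) takes ~0.1 s. These sizes give
stable distribution-level summaries while keeping a full run on one CPU
in minutes. All generators take explicit integer seeds and are
byte-reproducible; the pipeline manifest records md5 digests of every
output so end-to-end determinism is checkable.

# Known limitations

* Per-protein variance components at n = 8 are individually very noisy
  and often sit on the boundary (a component estimated at 0); only
  distribution-level summaries (median H2, component means over thousands
  of proteins) are meaningful, and the median H2 estimator shows a mild
  downward bias (~0.05–0.09) relative to the generating value at this
  sample size.
* The moderated test assumes equal within-group variances (pooled
  model), the convention for small-n isobaric designs.
* Protein inference/parsimony, spectral search and FDR estimation are
  upstream of this package: PSM tables arrive with unique protein
  assignments, and identified-peptide tables with search-engine FDR
  already applied.
* The cross-level comparison assumes a 1:1 pair-to-gene mapping; genes
  with several variant peptide pairs contribute through their first
  mapped pair.
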