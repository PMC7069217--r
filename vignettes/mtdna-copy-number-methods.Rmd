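---
title: "Methods: mtDNA copy-number quantification and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA copy-number quantification and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocn)
```

## The measurement problem

Mitochondrial DNA copy number — the number of mitochondrial genome copies
per cell, expressed relative to the two nuclear copies — is measured here by
two routes:

1. **qPCR**: a nuclear single-copy gene (RNase P) and a mitochondrial gene
   (MT-CYB) are amplified from the same DNA dilution; since CT is linear in
   log2 of starting template, the between-gene difference of
   reference-corrected CTs (ΔΔCT) estimates log2 relative copy number.
2. **Sequencing coverage**: after removing reads that are unmapped, have an
   unmapped mate, or are secondary, QC-failed, duplicate or supplementary
   (flag mask 3852), the ratio of mean per-base depth over the mitochondrial
   genome to mean depth over an autosomal reference region is proportional
   to copy number.

Both raw measures are mapped to normal scores by a rank-based inverse normal
transform before modelling, so downstream regression coefficients are in
cohort-SD units and robust to scale and outliers.

## qPCR model and corrections

Each plate carries a constant-concentration reference sample (REF) in
triplicate per gene; samples run in duplicate. Per-plate subtraction of the
REF mean CT removes additive plate effects exactly: adding any constant to
every CT on a plate leaves all ΔΔCT unchanged (this is a tested invariant).

What per-plate referencing does **not** remove are technical effects that act
differentially between the diluted samples and the fixed-concentration
reference — threshold-setting differences interacting with amplification
curve shape, reagent batch chemistry, and dilution error correlated with the
pre-dilution DNA concentration. These survive into ΔΔCT and are removed by
OLS on plate CT threshold (continuous), batch (categorical) and DNA
concentration (continuous). Variance shares are **sequential (type-I) sums
of squares** in that fixed order, because the target study design reports
one number per term; with the generator's orthogonalized effects the order
barely matters, with collinear real data the order is part of the estimand
and is documented in the output.

QC rules (all boundaries tested): an NTC passes only above 38 cycles (an
undetermined NTC — no amplification at all — passes); a sample well must be
determined and below 30 cycles. The NTC gates a whole plate-and-gene; a bad
sample well discards only that sample's replicate set. Replicate
discordance above 1 cycle warns but never discards — no concordance rule is
prescribed for this assay, and silently dropping discordant duplicates would
bias the variance decomposition.

The subtraction orientation ΔΔCT = ΔCT(RNase P) − ΔCT(MT-CYB) is a package
decision (the assay itself fixes only the magnitude): it makes larger values
mean more mitochondrial template, so positive downstream betas read as
copy-number increases.

## Inverse normal transform

`score = qnorm((rank − 3/8) / (n + 1/4))` (Blom offset), average ranks for
ties. Properties relied on by tests: monotone in the input, idempotent,
invariant under any strictly monotone transform of the input, scores sum to
~0, ties map to equal scores. All-identical input is an error rather than a
vector of zeros: there is no ordering information to normalize.

## Haploid GRM and PCA

Mitochondrial genotypes are haploid and homoplasmic, so SNPs are standardized
by the **observed haploid variance p(1−p)** (population denominator), not
the diploid Hardy–Weinberg 2p(1−p), and every SNP gets equal weight
regardless of allele frequency. With fully observed data GRM = ZZ'/m and
trace(GRM) = n exactly (tested to 1e−6·n); missing genotypes fall back to
pairwise-complete products with per-pair variant counts. PCA takes the GRM's
eigenpairs; scores are eigenvectors scaled by √eigenvalue so that eigenvalue
sums reproduce the trace (tested to 1e−8).

A variant is *private* to a group when it has at least one carrier and all
carriers belong to that group; monomorphic variants are never private.
Haplogroup effects on copy number are one-vs-rest OLS with optional
covariates, reported in descending beta order.

## Cohort statistics

- **PCL-C**: 17 items summed; probable PTSD at total ≥ 30 (inclusive — the
  cutoff convention is not prescribed, and the inclusive reading keeps a
  "cut-off score of 30" itself positive). Item scale defaults to 0–5, the
  only scale on which the instrument's printed 0–85 range is attainable;
  1–5 is supported as an option.
- **Fisher 2×2**: two-sided p by summing hypergeometric probabilities not
  exceeding the observed table's (1e−7 relative tolerance for ties),
  verified against an independent `choose()`-based enumeration for every
  table with margins ≤ 20. The odds ratio is the sample cross-ratio (0.5
  continuity correction when a cell is zero, flagged); the CI is Woolf
  log-OR normal, with the method recorded in the result.
- **Power**: the minimal detectable Cohen's f solves
  `P(F(1, v; λ) > F_crit) = power` with v = n − k − 2 and λ = f²(v + 2).
  This convention reproduces the study design's printed 0.29 at n = 97 and
  0.48–0.49 at n = 37; no standard convention reproduces its printed 0.32
  at n = 62 (we obtain 0.37), so that value is not asserted anywhere.
- **Blood screen**: each of 20 measures inverse-normal transformed and
  regressed on age, sex, group and probable PTSD jointly; the Bonferroni
  threshold follows the stated formula α/(20·4) = 6.25e−4. The joint
  copy-number model uses raw measure units so the platelet coefficient is
  per 10⁹/L. Clustering is Euclidean/average-linkage — a package decision,
  as no distance or linkage is prescribed.
- **Inheritance**: child score on parent score (or parent exposure group),
  controlling for age and sex of both; built from all recorded parent–child
  links, optionally mothers only.

Relatedness between participants is deliberately **not** modelled in the
association models (plain OLS, matching the target design); the pedigree is
used only to build inheritance pairs and lineage flags.

## The synthetic cohort: a stated world

The generator's defaults are the conditions of the study design it emulates,
fixed once:

- 196 participants: exposed-lineage 15/60/42 and controls 22/37/20 across
  three generations; 77:119 male:female ratio; generation age ranges
  (G2 30–73, G3 15–48; G1 75+ as survivors must be).
- 17 plates in 3 batches of 96 wells; REF triplicates and one NTC per gene
  per plate; samples in duplicate for both genes; well noise SD 0.15
  cycles (typical TaqMan replicate scatter); NTC contamination and
  well-failure rates 2% to exercise the QC paths.
- Technical variance shares 0.45 (CT threshold), 0.05 (batch), 0.01
  (concentration) of total ΔΔCT variance. Effects are injected on the
  mitochondrial gene's sample wells only: if REF and samples were shifted
  equally, per-plate referencing would cancel the effects exactly and the
  reported nonzero shares could never arise. Effect vectors are empirically
  scaled and sequentially orthogonalized (batch ⊥ threshold,
  concentration ⊥ both) so sequential-SS recovery is unbiased.
- Latent copy number is log-normal: effects act additively on the log scale
  in units of the latent SD (default 0.35 natural-log units, ~35%
  between-individual CV), so configured effect sizes match what is recovered
  on the inverse-normal scale. Defaults: sex (male) +0.37, age −0.002/yr,
  group 0 (the design's null finding), maternal transmission h = 0.
- Plate assignment randomly permutes samples into near-equal plates. This is
  the one deliberate deviation from naive i.i.d. plate draws: i.i.d.
  assignment overflows a 96-well plate with ~2% probability per cohort,
  which would make seeded multi-cohort experiments flaky, while balanced
  randomization keeps assignment independent of every covariate (the
  balance checks stay calibrated, which is tested).
- Genotypes: a 3,779-SNP panel with 626 variants private to haplogroup L
  (including its defining SNPs), the rest shared across at least two
  haplogroups by construction so private counts are exact at any cohort
  size. Haplogroup frequencies default to a 1000-Genomes-like mix with
  L at 26%.
- Depths: per-base Poisson, nuclear mean 30×, mtDNA mean 30 × 20 × CN over
  the 16,569 bp rCRS length; the autosomal reference region is a 100 kb toy
  region (the real choice of chromosome is irrelevant to the ratio).
- PCL-C prevalence per group × generation defaults to 0.47/0.35/0.20
  (exposed G1–G3) vs 0.12/0.12/0.10 (controls): the exposed-G1 value is the
  observed 7/15, the remaining cells were chosen once to give enrichment
  odds ratios of the reported magnitude and are not tuned. Blood measures
  use adult reference means/SDs with the reported standardized sex effects
  (RBC 0.857, HGB 1.087, HCT 1.067, monocyte% 0.955, platelets −0.820);
  the optional platelet→copy-number coupling defaults to off.
- One global seed; each generator draws from its own fixed substream, so
  adding a generator never perturbs another's output (tested).

What the generator does **not** emulate — and hence what a green test does
not establish: amplification-efficiency differences between genes,
heteroplasmy, NUMTs and GC bias in coverage, real phylotree structure,
item-level PCL-C psychometrics, and the unexplained 235→196 recruitment
attrition (a neutral drop-out rate is exposed but its mechanism is not
modelled). Green tests establish that the estimators recover the stated
world's parameters and hold their exact invariants, not that the biological
conclusions of any particular study are correct.

## Numerical choices

- Power root-solve: `uniroot` on f ∈ (1e−8, 100), tolerance 1e−10; the
  round-trip through the power function is tested to 1e−6.
- GRM missing-data entries with no shared observed variants are NA rather
  than 0.
- Degenerate inputs error loudly: empty regions, zero nuclear depth,
  all-monomorphic panels, all-identical transform input, zero Fisher
  margins, collinear designs (naming the aliased columns).
- Determinism: all generators restore the caller's RNG state, so package
  calls never silently advance a user's random stream.

## Known limitations

- The minimal SAM reader counts a read at every position of its aligned
  reference span (CIGAR M/D/N/=/X sum); deletions inside reads are counted
  as covered. For the mean-depth ratio at the simulated depths this bias
  cancels between numerator and denominator.
- Pairwise-complete GRM entries are not guaranteed positive semi-definite
  under heavy missingness.
- `fisher_2x2` enumerates the hypergeometric support directly, which is
  exact but not suitable for margins in the thousands.
- The CLI exposes scalar `cohort_config` overrides via `--set`; structured
  fields (age distributions, prevalence matrices) are R-level only.
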