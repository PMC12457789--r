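---
title: "Methods: partitioning pollen-parent effects on seed rutin and quantifying pollen-allele expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning pollen-parent effects on seed rutin and quantifying pollen-allele expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xeniaseq)
```

## The problem

Common buckwheat is heterostylous and self-incompatible (SI): every seed
is an F1 between two genotypes, and commercial lines are heterogeneous
populations. Seed rutin content — the flavonol glycoside that motivates
much buckwheat breeding — is therefore never measured on a fixed
genotype, and the question of whether the *pollen* parent influences the
trait of the seed it sires (xenia) cannot be answered by comparing
cultivars alone. This package implements the two computations that answer
it quantitatively:

1. **Effect partitioning.** Per-seed rutin measurements of parent lines
   and F1 seed lots are reduced to group means, and the F1 mean is
   modelled as a mixture of the parental means,
   $$F_1 = m\,P_m + (1-m)\,P_p,$$
   where $P_m$ and $P_p$ are the maternal and pollen-parent mean rutin
   contents (mg/g). Solving gives the maternal effect
   $m = (F_1 - P_p)/(P_m - P_p)$ and the pollen (xenia) effect $1-m$;
   the mid-parent value is $(P_m+P_p)/2$. Group differences are tested
   with Fisher's LSD (unadjusted pairwise $t$ on the pooled one-way
   ANOVA error variance).

2. **Pollen-allele expression.** RNA-seq reads from maturing F1 seeds
   are mapped to the cDNA of a homozygous self-compatible line that is
   also used as the outcross pollen parent. At a transcriptome position
   the maternal SI line may be heterozygous reference/alternative
   (pattern I) or carry no reference allele at all (pattern II). In the
   outcross, reference-base reads at a pattern II site can only have
   come from the pollen parent, so the per-SNP *pollen-allele ratio* is
   the percentage of reads carrying the reference base. A self-type
   cross from the same maternal plant distinguishes the two patterns
   from ordinary within-line variation.

The pipeline operates downstream of mapping: its inputs are per-position
nucleotide-count tables (pileups), expression estimates (counts +
effective lengths, converted to TPM), per-seed rutin tables and locus
metadata, all as plain TSV.

## Assumptions of the mixture model

- The trait is measured per seed, and group means are compared; the
  mixture weight $m$ is defined on means, not on individual seeds.
- $m$ is deliberately **not clamped** to $[0,1]$: noise or non-additive
  inheritance can push the estimate outside, and a flag
  (`m_outside_01`) marks such crosses instead of hiding them.
- $m$ is invariant under affine rescaling of the trait (unit changes),
  which the property suite verifies, and $F_1$ equals the mid-parent
  value exactly when $m = 0.5$.
- SDs are sample SDs ($n-1$); the data layout (5 plants × 15 seeds) is
  treated as 75 i.i.d. seeds per group by default. Whether the original
  analysis used per-plant means ($n=5$) or per-seed values ($n=75$) as
  LSD replicates is not stated in the source material; per-seed is the
  default here, and `lsd_test()` accepts any grouping the analyst
  prefers. The LSD is run as the three-group (maternal, F1, pollen)
  procedure within a cross's field plot.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `trim_bases` | 6 | bases | base-call quality at locus ends is unreliable; positions $p \le 6$ or $p > L-6$ are discarded |
| `tpm_threshold` | 1.0 | TPM | a locus is expressed iff TPM is **strictly** greater |
| `min_allele_count` | 3 | reads | an allele must have this many reads to be "present" at a position |
| `min_allele_fraction` | 0.10 | fraction of column depth | suppresses sequencing-error noise at typical depths |
| `band_lo`, `band_hi` | 20, 40 | % | inclusive pollen-ratio band highlighted in reports |
| `rutin_low`, `rutin_high` | 0.1, 0.5 | mg/g | group boundaries: `< 0.1` low, `> 0.5` high, the closed interval medium |
| `rounding_decimals` | 2 | — | report rounding, half away from zero |

The presence thresholds replace the original by-eye genome-browser
calls, which are threshold-free; they are the one part of the pipeline
with no published counterpart, so they are config-exposed and the
pattern classifier is a standalone pure function
(`classify_pattern()`) that an alternative taxonomy can replace.

A caution that the test suite makes explicit: the presence fraction
**censors** alleles expressed below it. Measuring a pollen fraction of
0.10 with `min_allele_fraction = 0.10` drops roughly half the
informative sites (those whose binomial draw lands below 10%) and
biases the pooled estimate upward. The estimator-recovery tests
therefore run with `min_allele_fraction = 0.02`, which is appropriate
whenever the error rate is low; with noisy data the default 0.10 trades
a detection floor of ~10% for robustness.

## The two-pattern decision rule

With `S` and `O` the sets of present alleles in the self-cross and
outcross columns and `r` the reference base, at a variant position:

- **pattern I** iff `r ∈ S` — the maternal line is heterozygous
  reference/alternative, so outcross reference reads are confounded
  between the parents; the SNP demonstrates the pollen allele's presence
  but yields no ratio;
- **pattern II** iff `r ∉ S` and `r ∈ O` — the maternal line carries
  only non-reference alleles and the reference reads in the outcross are
  attributable to the pollen parent; the ratio is
  `100 · count(r) / Σ counts over present alleles`;
- otherwise **uninformative** (the pollen allele is not observed).

This rule reproduces every consistency signal in the published
summaries: ratios exist exactly where pattern II counts are positive,
the SE is dashed exactly where a single pattern II SNP exists, and
pattern-I-only loci still count as "pollen allele detected". Whether it
matches the original authors' (unpublished) site taxonomy in every edge
case cannot be verified; hence the pluggable classifier. Per-locus
summaries report the arithmetic mean of the per-SNP ratios and its
standard error (sample SD / √n, absent below two SNPs); replicate
maternal plants are analyzed independently, never pooled.

## What the generators emulate — and what they do not

`simulate_rutin()` draws per-seed values from per-line Normal
distributions at the published means/SDs under the 5 × 15 field design,
with F1 lots centred on the mixture formula at a chosen true $m$.
Negative draws are redrawn until non-negative (`clip_resample`), which
for a wide, near-zero distribution shifts the realized mean noticeably
upward (about +0.06 mg/g for a Normal(0.60, 0.41²) line); the shift is
logged per line, and the quadrature-oracle test pins the realized mean
to the truncated-normal expectation. A plant-level random effect is
available (`plant_sd`) but defaults to 0 because no within- vs
between-plant variance decomposition is published.

`simulate_ase()` draws, per position, a maternal genotype (heterozygous
ref/alt, homozygous-alternative, or two alternative alleles at
configurable rates), a self-cross pollen allele from the same population
frequencies, Poisson depth, a binomial split between pollen and maternal
transcripts at the true fraction $\pi$, and uniform base mis-calls at
rate $\varepsilon$. The default site-class rates (1.5% heterozygous,
0.5% homozygous-alternative) give SNP densities of the order seen in
heterozygous buckwheat cDNA, with pattern I outnumbering pattern II as
in the published per-locus counts. An optional three-compartment seed
model derives $\pi$ from tissue dosage (embryo ½, endosperm ⅓, testa 0)
under supplied tissue weights; the default single-$\pi$ model reflects
that only an aggregate ratio is measured.

Neither generator models mapping bias, positional error profiles,
indels, library-size differences between replicates, or linkage between
neighbouring sites (sites are independent). Passing recovery tests
therefore demonstrates correctness of the *estimators* under the
declared sampling model, not robustness to alignment artefacts in real
data.

## Numerical and reporting choices

- All effect computations run at full precision; rounding (half away
  from zero, 2 decimals) happens once, at report time. Recomputing the
  published per-cross table from its own printed 2-decimal means
  reproduces several cells exactly (the c1 maternal/pollen effects, the
  a1 and e mid-parent values, both group averages) and the remainder to
  within ±0.02 — the residue of the original unrounded intermediates.
- Boundary conventions: rutin 0.1 and 0.5 mg/g are *medium*; the ratio
  band is inclusive at both edges (a 20.0% ratio is inside); TPM at the
  threshold is *not* expressed.
- Absent values are written as `"-"` and parsed back to `NA`, never 0.
- Degenerate LSD inputs (zero pooled variance) yield p = 1 for equal
  means, p = 0 otherwise, with a warning.
- Pathway totals: the detected-in-reference total counts all ten enzyme
  families (62 loci including the 12 glycosyltransferases), while the
  expressed and pollen-detected totals exclude the glycosyltransferase
  family, whose single expressed gene appeared in only one plant — the
  one reading of the published summary in which every total equals its
  column sum.

## Problem sizes

The bundled analyses and tests run at desk scale by choice: effect
partitioning on 10 crosses × 75 seeds; simulation-recovery at one
524-bp locus with ~50 informative sites at mean depth 200 (three truth
fractions 0.1/0.3/0.5); maternal-effect recovery at 750 seeds/group;
the full simulated ASE experiment at 14 loci of 0.8–2.2 kb in two
replicates. At these sizes the binomial/Monte-Carlo standard errors are
small enough that every recovery check is decided at 3 SE without
being slow.

## Known limitations

- The pattern taxonomy is a reconstruction (see above).
- Whether the per-SNP ratio denominator should use all reads or only
  present-allele reads is not documented in the source material;
  present-allele reads is the default here (error-level bases are
  excluded), the alternative is one line of config away.
- The published per-locus "total number of nucleotides" may be pre- or
  post-trimming; summaries here report the post-trim retained length.
- `compute_effects()` treats seeds as exchangeable within a group; if
  plant effects are material, supply per-plant means to `lsd_test()`
  directly.
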