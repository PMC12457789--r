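# xeniaseq

Quantifying the pollen parent's influence on seeds in an obligate
outcrosser. Buckwheat (*Fagopyrum esculentum*) is heterostylous and
self-incompatible: every seed is an F1, lines are heterogeneous, and the
seed trait that breeders care most about — rutin content — is always
measured on a mixture of genotypes. `xeniaseq` implements the two
computations needed to show, and to size, a xenia effect on seed rutin:

1. **Effect partitioning** from per-seed rutin measurements of parent
   lines and F1 seed lots. The F1 group mean is modelled as a mixture of
   the parental means, `F1 = m·Pm + (1−m)·Pp`, giving the maternal
   effect `m = (F1 − Pp)/(Pm − Pp)`, the pollen (xenia) effect `1 − m`
   and the mid-parent value `(Pm + Pp)/2`, with group differences tested
   by Fisher's LSD (pairwise t on the pooled one-way ANOVA error
   variance).
2. **Pollen-allele expression** in maturing F1 seeds from per-position
   nucleotide-count pileups. Reads are mapped to the cDNA of a
   homozygous reference line that is also the outcross pollen parent; at
   sites where the heterozygous maternal line carries no reference
   allele ("pattern II" SNPs), reference-base reads in the outcross are
   attributable to the pollen parent, and their percentage is the
   pollen-allele ratio. A paired self-type cross separates these sites
   from ordinary maternal heterozygosity ("pattern I"). Per-locus
   ratios aggregate to enzyme families of the rutin biosynthesis
   pathway (PAL … FLS, GTR).

Both stages come with synthetic-data generators (`simulate_rutin()`,
`simulate_ase()`) that emit the same file formats with known ground
truth, so the whole pipeline is testable without sequencing data. The
published tables of the motivating crossing study are bundled as in-code
constructors (`ref_parent_lines()`, `ref_crosses()`,
`ref_pathway_loci()`, `ref_pollen_ratios()`).

Intended users: plant breeders and quantitative geneticists partitioning
parental effects on seed metabolites, and anyone estimating
parent-of-origin expression from paired-cross RNA-seq count tables.

## Worked example

Partition the parental effects for the cross of the high-rutin maternal
line HR8 (0.60 mg/g) to the medium-rutin pollen parent RRN (0.15 mg/g),
whose F1 seeds averaged 0.40 mg/g:

```r
library(xeniaseq)

desk <- effects_from_means(ref_parent_lines(), ref_crosses())
subset(as.data.frame(desk), cross_id == "c1")
#>   cross_id pm_mean pp_mean f1_mean    mp         m pollen_effect
#> 3       c1     0.6    0.15     0.4 0.375 0.5555556     0.4444444
round_report(desk$m[desk$cross_id == "c1"])
#> [1] 0.56
```

The F1 mean sits 56% of the way from the pollen parent to the maternal
parent: the maternal effect is 0.56 and the pollen parent contributes
the remaining 0.44 — a direct xenia effect on seed rutin. Averaged over
all six crosses with the high-rutin line as mother the pollen effect is
0.46; in the reciprocal direction it is 0.19.

On the expression side, the per-locus pollen-allele ratio summaries of
the two replicate maternal plants pool to:

```r
ratio_stats(ref_pollen_ratios()$mean_ratio)
#> # A tibble: 1 × 5
#>   n_values min_ratio max_ratio band_count band_percent
#>      <int>     <dbl>     <dbl>      <int>        <dbl>
#> 1       20       9.6      74.2          8           40
```

i.e. 40% of locus × replicate ratios fall in the 20–40% band (inclusive),
with extremes at 9.6% and 74.2% — the pollen allele is expressed at
every informative locus, at fractions broadly matching the phenotypic
pollen effect.

## The analysis workflow

The `analysis/` scripts narrate the full pipeline and write their tables
under `results/` (run them in order from the repository root):

- `01_reference_effects.R` — desk-scale effect partitioning from the
  bundled published means; rutin group classification.
- `02_simulated_effects.R` — regenerates the 5-plants × 15-seeds field
  design from the published line distributions and runs the complete
  per-seed engine including LSD star codes.
- `03_simulate_ase.R` — simulates the paired self-cross/outcross
  sequencing design over 14 synthetic cDNA loci (two replicates, true
  pollen fractions 0.30 and 0.25).
- `04_allele_expression.R` — runs SNP detection, pattern classification
  and per-locus summaries on those pileups and compares against the
  generator truth.
- `05_pathway_report.R` — pathway-family aggregation, pooled ratio
  statistics and the rendered report.

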