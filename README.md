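# bsbtools

Screening and quantification of bile salt biotransformation (BSB) genes in
the human gut microbiome.

Gut bacteria convert host primary bile acids (cholate, chenodeoxycholate
and their glyco-/tauro- conjugates) into secondary bile acids
(deoxycholate, lithocholate, ursodeoxycholate) through thirteen enzyme
categories: the *bai* operon proteins BaiA–BaiL, bile salt hydrolase (Bsh)
and hydroxysteroid dehydrogenases (HSD). The collective abundance of these
genes in a stool metagenome measures the community's biotransformation
potential, which is depleted in inflammatory bowel disease (IBD) — chiefly
through Firmicutes — with a matching shift in the fecal bile-acid pool
(primary up, secondary down). `bsbtools` is for microbiome researchers who
want that analysis as a tested, reusable pipeline.

## What it computes

* **Calibrated homolog screening.** Smith–Waterman local alignment (affine
  gaps, BLOSUM62 11/1) with Karlin–Altschul significance
  `E = K·m·n·exp(−λS)`; thresholds on identity, e-value and query/target
  coverage calibrated on labeled controls by maximizing Youden's
  `J = sensitivity + specificity − 1`; BSH/PVA discrimination by
  profile-HMM e-value comparison; exact domain-architecture and
  orthology-annotation filters; strain × category prevalence matrices.
  External search output in the 12-column tabular dialect can be swapped in.
* **Protein sequence similarity networks (PSSN).** All-vs-all alignment, an
  e-value decade sweep of connected-component counts, a plateau rule for
  the optimal cutoff, networks with the edge metric *e-value < cutoff and
  identity > 30%*, and phylum co-localization metrics.
* **Metagenomic gene abundance.** Normalization of mapped-read counts to
  total paired reads (unitless fractions, magnitude ~1e-4 for a full BSB
  gene set), taxonomic aggregation with exact conservation, two-sided
  Mann–Whitney–Wilcoxon tests (enumeration-exact for groups of ≤ 8),
  Kruskal–Wallis for three groups, star annotations, and a multivariable
  regression confounder scan (age, BMI, gender; flagged at p < 0.01).
* **Bile-acid proportions.** Per-sample proportions of total BA level,
  primary/secondary and conjugation classification, class totals, and
  group comparisons per metabolite and per class.
* **Synthetic data.** Seeded generators for protein families with decoys,
  BSH/PVA score tables, two-group cohort metagenomes with a
  phylum-restricted depletion, and bile-acid tables with class-level group
  shifts — the inputs every stage consumes in tests, so the whole pipeline
  runs with no downloads.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on synthetic
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # generate family, cohort, metabolites
Rscript analysis/02_screen.R     # calibrate + screen homologs
Rscript analysis/03_network.R    # PSSN of the retained set
Rscript analysis/04_abundance.R  # group comparisons of gene abundance
Rscript analysis/05_metabolites.R
```

The screening step calibrates on the labeled controls and composes the
filter cascade:

```
calibrated thresholds: identity >= 50%, e <= 1e-50, coverage >= 0.80
achieved sensitivity 1.000, specificity 1.000
homolog_set: 50 of 100 candidates retained across 13 categories
recall of true homologs: 1.000; decoys retained: 0
```

All 50 designed homologs pass, all 50 shuffled decoys are rejected. The
abundance step then compares total BSBG abundance between groups at the
simulated cohort's sizes (H = 14, CD = 4, UC = 21):

```
  group1 group2 n1 n2        mean1        mean2 statistic     p_value stars
1      H     CD 14  4 9.159432e-05 6.138352e-05        46 0.063100902    ns
2      H     UC 14 21 9.159432e-05 6.026876e-05       237 0.002581494    **
3     CD     UC  4 21 6.138352e-05 6.026876e-05        45 0.852984068    ns
```

The designed twofold Firmicutes depletion is detected against UC (n = 21)
but not against the 4-sample CD arm — small subtype arms genuinely lack
power, which is why such arms are excluded from subtype comparisons in
practice. Phylum-stratified comparisons flag exactly Firmicutes, and the
metabolite step recovers the designed bile-acid shift:

```
  secondary_total H vs CD: mean 0.882 vs 0.519, p = 0.0035 **
  secondary_total H vs UC: mean 0.882 vs 0.483, p = 8.1e-07 ****
```

In code, the same computations are plain function calls:

```r
library(bsbtools)
coh  <- gen_metagenome_counts(cohort_spec(n_per_group = c(H = 14, CD = 25),
                                          log2_effect = -1, seed = 1))
norm <- normalize_abundance(coh$counts, coh$depths)
total <- total_bsbg_abundance(norm, coh$gene_set)
compare_groups(total, coh$metadata)
#> mann_whitney on H vs CD : statistic = 308 , p = 0.000104799
```

See `vignettes/bsb-pipeline.Rmd` for the full methods account: models,
parameter defaults and why, numerical conventions, and what the synthetic
generators do and do not emulate.

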