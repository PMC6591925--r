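---
title: "Screening and quantifying bile salt biotransformation genes: methods"
author: "bsbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and quantifying bile salt biotransformation genes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Gut bacteria convert host-derived primary bile acids (cholate,
chenodeoxycholate and their glycine/taurine conjugates) into secondary bile
acids (deoxycholate, lithocholate, ursodeoxycholate). The enzymes involved —
the *bai* operon proteins BaiA–BaiL, bile salt hydrolase (Bsh) and
hydroxysteroid dehydrogenases (HSD), thirteen categories in all — are
scattered unevenly across gut taxa, and their collective gene abundance in a
stool metagenome is a proxy for the community's biotransformation potential.
In inflammatory bowel disease (IBD) this potential is depleted, most of the
loss being attributable to Firmicutes, and the fecal bile-acid pool shifts
accordingly: primary (and conjugated primary) bile acids up, secondary bile
acids down.

`bsbtools` implements that entire analysis as a tested pipeline: calibrated
homolog screening, protein sequence similarity networks (PSSN), normalized
metagenomic gene-abundance comparison with taxonomic stratification, and
bile-acid proportion analysis. Because the original inputs (a dated protein
database release, two cohort metagenome archives, an orthology mapping
version) cannot be reconstructed at desk scale, the package ships a
first-class synthetic-data module that generates inputs with the statistical
structure the analysis assumes, so every stage is testable end to end with
no downloads. Headline counts tied to those dated resources (total homolog
numbers, per-phylum tallies, cohort means) are therefore not reproduction
targets; the pipeline's correctness is established by property-based checks
against independent oracles and by parameter-recovery on the synthetic
cohorts.

## Homolog screening

Candidates are aligned to a per-category reference with Smith–Waterman
local alignment under affine gaps (BLOSUM62, gap open 11, gap extend 1 — a
gap of length $k$ costs $11 + k$). Significance uses the Karlin–Altschul
model $E = K m n e^{-\lambda S}$ with the published gapped-BLOSUM62
constants $K = 0.041$, $\lambda = 0.267$. The substitution matrix and gap
penalties of the original external search are not recorded anywhere we can
consult, so these de-facto defaults are a stated assumption, overridable
through `scoring_scheme()`. Percent identity is identical columns over
alignment columns (gaps included); coverage is the aligned span over the
full sequence length. When no positive-scoring local alignment exists, the
empty-alignment convention applies (score 0, length 0, identity and
coverages 0). The unknown residue `X` is accepted and scores 0 against
everything. Among equal-scoring alignments the traceback deterministically
prefers matched columns over gaps, favouring higher identity and shorter
alignments; only the score is contractual, and it is checked against a
brute-force dynamic-programming oracle in the test suite. External aligner
output in the standard 12-column tabular dialect can be swapped in via
`read_tabular_hits()` (coordinates 1-based inclusive; coverages derived
from separately supplied sequence lengths).

Thresholds (minimum identity, maximum e-value, minimum query and target
coverage) are calibrated on labeled positive/negative control hits by
exhaustive evaluation of a candidate lattice, choosing the point that
maximizes Youden's $J = \text{sensitivity} + \text{specificity} - 1$. The
original analysis says only that an accuracy analysis with user-defined
criteria chose the operating point; $J$ is the standard such criterion, and
ties are broken toward the most stringent candidate (highest identity, then
lowest e-value, then highest coverages) so that exchangeable controls yield
a conservative rule. Thresholds can be per enzyme category (a named list
with a `default` fallback) or global. Boundary values pass the hit filter
(identity exactly at the minimum is in).

Bsh candidates additionally pass a profile-HMM discrimination against
penicillin-V-acylase (PVA), which shares the CBAH domain. The package's
default calls BSH when the BSH-model e-value is *lower* (more significant)
than the PVA-model e-value; the source text's literal phrasing selects the
higher e-value, which contradicts e-value semantics, so that reading is
preserved behind `mode = "literal_paper_text"` for auditability rather than
guessed at. Ties and missing scores are ambiguous and conservatively
excluded. The remaining filters are exact: the ordered domain-accession
architecture must equal the reference's exactly (no clan merging), and the
orthology annotation must match (strict mode; a relaxed mode accepts
overlapping functional-category codes). Every record carries per-stage
provenance flags, so disabling a stage can only grow the set — an invariant
the tests assert. Strain-level presence/absence of the 13 categories feeds
`select_prevalent_strains()`, which keeps strains carrying a strict
majority (at least 7 of 13).

## Similarity networks

For divergence analysis, retained homologs are compared all-vs-all; each
unordered pair contributes one hit (the scheme is symmetric). An e-value
decade sweep (default $10^{-5}$ to $10^{-180}$ in steps of $10^{-5}$)
counts connected components among edges with e-value at or below the cutoff
and identity strictly above 30%. Component count is non-decreasing and edge
count non-increasing in stringency — asserted on every synthetic run. The
"optimal" cutoff is taken as the most stringent point of the longest
plateau of the component-count curve (ties between equal-length plateaus go
to the more stringent one): a stable cluster count over a cutoff range is
the operational meaning we give the original method's threshold
distribution, which is otherwise unspecified. The final network uses the
strict rule — e-value strictly below the cutoff and identity strictly above
30% — and labels clusters by connected components (igraph under the module
surface; tests compare against a naive transitive-closure oracle). Phylum
co-localization is summarized as the same-phylum edge fraction and
per-component majority purity. Networks are built per enzyme category;
pooling related categories (BaiCD with BaiH, BaiA with BaiL) is left to the
caller by passing the pooled sequence set.

## Abundance analysis

Mapped-read counts are normalized by each sample's declared total paired
reads, giving unitless fractions of magnitude around $10^{-4}$ for a full
BSB gene set. Whether "total paired reads" means reads or read pairs (a
factor of two) is not recorded; the divisor is simply the supplied depth
column, documented as such. No gene-length scaling is applied by default,
matching the stated normalization. Taxonomic aggregation parses 7-rank
lineage strings (`k__;p__;c__;o__;f__;g__;s__`); genes with an empty rank
land in an `unclassified` bucket so that taxon sums conserve the total
exactly (to $10^{-12}$ in tests) rather than silently dropping mass.

Two-group comparisons use the two-sided Mann–Whitney–Wilcoxon test,
computed exactly by enumeration of all group assignments when both groups
have at most 8 samples (midranks make this tie-exact; identical multisets
give $p = 1$), and by the normal approximation with tie-corrected variance
and continuity correction otherwise. Three groups dispatch to
Kruskal–Wallis. Shapiro–Wilk normality p-values are reported per group for
context but do not gate the nonparametric tests. Significance stars follow
the conventional cutpoints (ns $> 0.05$; one to four stars at $\le 0.05$,
$\le 0.01$, $\le 0.001$, $\le 0.0001$). Raw p-values are reported without
multiple-testing correction, matching the original reporting; comparisons
require at least 2 samples per group (the original excluded a 4-sample CD
arm from subtype analysis without stating a minimum; we enforce only
$n \ge 2$ and leave stricter demands to the caller). Confounding is scanned
by ordinary least squares of abundance on age, BMI and gender jointly, with
coefficients flagged at $p < 0.01$; constant covariates are excluded with a
warning. Country matching is applied as an explicit metadata filter before
comparisons.

## Metabolite analysis

Bile-acid levels are expressed as per-sample proportions of the total BA
level, which makes them invariant to per-sample scale and comparable across
samples. The shipped vocabulary classifies each BA on two axes — class
(primary/secondary) and conjugation (unconjugated/glyco/tauro) — and is
extensible via TSV. Ursodeoxycholate is grouped with the secondary bile
acids, following the source's grouping of DCA, LCA and UDCA as
secondary/tertiary microbial products. Class totals partition each sample's
proportions (primary + secondary = 1 under full coverage), and group
comparisons reuse the abundance module's tests per metabolite and per
class.

## The synthetic-data module

The generators are the package's study conditions, not tuning knobs:

* **Protein families** (`gen_protein_family`): one random reference
  (uniform residue composition), derivatives mutated to a target global
  identity drawn from the requested band (substitutions at distinct sites,
  uniform over the 19 alternatives; indel events Poisson with geometric
  length of mean 2, scaled by divergence so fully identical homologs carry
  none), and decoys that are residue shuffles of the reference — homology
  destroyed, length and composition preserved, so identity/coverage filters
  rather than composition separate the classes. Realized identity is
  checked with the package's own aligner to within $\pm 0.05$ of the band.
  The screening family defaults to 50 homologs at 60–90% identity plus 50
  decoys on a 300-residue reference.
* **HMM score tables** (`gen_hmm_scores`): matched-model e-value exponents
  `separation` decades stronger than the other model's, unit-normal noise
  on each exponent; separation 0 yields exchangeable scores and chance
  classification, separation 10 (the default used in the drivers) is
  effectively error-free.
* **Cohort metagenomes** (`gen_metagenome_counts`): negative-binomial gene
  counts (size 10) with gene-specific means proportional to log-normal
  gene weights, the sample's depth, and a per-sample log-normal community
  factor (sd 0.3 on the log scale) emulating inter-individual variation in
  BSB carriage; depths are log-normal around 5 million paired reads (CV
  0.2). The BSB set's total baseline relative abundance is $10^{-4}$ — the
  magnitude the real cohorts show. A fraction (default 0.8) of genes is
  assigned to Firmicutes, the rest to Bacteroidetes, Actinobacteria and
  Proteobacteria with realistic family/genus lineages; in non-healthy
  groups the Firmicutes genes are scaled by $2^{\text{log2\_effect}}$
  (default $-1$, i.e. a twofold depletion). Group sizes default to the
  14/4/21 (H/CD/UC) cohort; the 14-vs-25 arm used in the power checks
  mirrors the real healthy-vs-IBD comparison, and direction-recovery runs
  use 18 healthy vs 25 disease samples. Per sample, gene
  counts never exceed the declared depth. Because no effect-size estimates
  beyond group means exist for the real cohorts, the twofold depletion is a
  calibration choice — strong enough to be detectable at the real sample
  sizes — not a reproduction.
* **Bile-acid tables** (`gen_metabolite_table`): log-normal levels (CV
  0.4), secondary BAs dominating the healthy baseline, with class-level
  multiplicative group shifts (the drivers use primary ×2 and secondary
  ×0.25 in disease; `conjugated_primary` shifts stack on conjugated primary
  forms).

Every generator is deterministic given its spec's seed and restores the
caller's RNG state. What the generators do **not** emulate: real protein
domain content (architectures and annotations are synthetic side tables),
sequencing reads and mapping noise, compositionality between the BSB set
and the rest of the metagenome, correlations between genes beyond the
shared community factor, and LC-MS measurement artifacts. Passing tests
therefore demonstrate that the pipeline recovers designed structure under
its stated statistical model, not that it would be robust to every artifact
of real data.

## Numerical conventions and problem sizes

Boundary rules are explicit throughout: hit-filter boundaries pass;
network edges are strict on both e-value and identity; star cutpoints are
inclusive. The exact/approximate Mann–Whitney switch is at 8 samples per
group (the largest enumeration is $\binom{16}{8} = 12870$ assignments).
The test suite and acceptance script size their simulations to run on one
CPU in minutes: 500 alignment-oracle pairs at length $\le 10$, 1000
component-oracle graphs at $\le 12$ nodes, 100 calibration seeds with 500
controls per class, 20 screening families of 100 sequences, 400 null and
100 alternative cohort simulations, and 100 direction-recovery runs. These
sizes give binomial standard errors comfortably inside the asserted bands
(e.g. a 5% type-I rate estimated from 400 runs has standard error about
1.1%).

## Known limitations

The aligner is a dense $O(mn)$ Smith–Waterman without heuristic seeding and
is meant for reference-scale screens (hundreds of sequences), not database
search. E-value constants are fixed rather than estimated from the scoring
system. The plateau rule for the PSSN cutoff is one defensible reading of
an underspecified method; per-network optimal cutoffs from the original
supplement are not reproduced. The enzyme catalog's reference
architectures and annotations are illustrative defaults for plumbing and
tests; a real screen should supply a curated catalog. The per-category
screening drivers exercise one category (Bsh) end to end; multi-category
screens are a matter of supplying records and thresholds per category.
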