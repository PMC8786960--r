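---
title: "Strain sharing and transcriptional shifts in mother-infant dyads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain sharing and transcriptional shifts in mother-infant dyads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadshift)
```

dyadshift analyses paired mother-infant gut metagenomes and
metatranscriptomes: it detects bacterial strains shared within a dyad from
SNP-haplotype alignments and quantifies how those shared strains change
their per-gene-family expression in the infant gut. This vignette explains
the underlying models, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where the methodology left them open.

## Strain sharing from SNP haplotypes

The dominant strain of each species in each sample is represented by an
aligned SNP haplotype (the concatenated variant sites emitted by upstream
strain-profiling tools). For every within-species sample pair we compute
the observed mismatch fraction *p* over alignment columns where **both**
sequences carry a plain base — columns with a gap (`-`) or ambiguous base
(`N`) in either sequence are excluded — and correct for multiple
substitutions with the Jukes-Cantor model,
$d = -\tfrac{3}{4}\,\ln(1 - \tfrac{4}{3}p)$, defined for $p < 0.75$.
Pairs with fewer than `min_overlap = 100` compared sites are skipped with
a warning rather than treated as evidence: strain haplotypes can be very
gappy where coverage is low, and a distance over a handful of sites is
noise. Pairs at or beyond the saturation bound ($p \ge 0.75$, possible
only between essentially random sequences) are likewise skipped.

Species differ enormously in within-species diversity, so raw distances
are not comparable across species. Each pair's $d$ is therefore divided by
the **median of all pairwise distances of that species**, pooling
within-family and between-family pairs. Pooling is deliberate: the
normalization is meant to express "how close is this pair relative to a
typical pair of this species", and with ten dyads the within-family pairs
are a small minority, so pooling barely moves the median while keeping the
definition simple and symmetric. A species whose median distance is zero
(all haplotypes identical) carries no discriminating signal and is
excluded with a warning.

A within-family mother-infant pair is called a **shared strain** when its
normalized distance is at or below the threshold 0.2. The comparison is
inclusive (`<=`), exposed as a flag; the threshold is conservative — on
cohorts the dyad pairs concentrate near 0 and background pairs near 1 —
so inclusivity at the boundary is immaterial in practice but should not
silently drop a pair sitting exactly at it. Only mother-infant pairs
within one family are eligible: mother-mother or infant-infant
similarities appear in the distance table but are never called, and at
most one event is kept per (species, family) (the closest pair). The
method is symmetric and says nothing about direction: a "shared strain"
may be a mother-to-infant transmission, a common external source, or the
reverse direction.

Per-species neighbor-joining trees (negative branch lengths clamped to
zero) are provided for visual confirmation of family-specific clustering;
tree building is delegated to ape.

## Relative expression and shift calls

RNA and DNA abundances are both *relative* (copies-per-million within a
sample), so the RNA/DNA ratio of a gene family confounds the gene's
transcription with the overall transcriptional activity of its species in
that sample: one highly active species depresses the apparent RNA of every
other species. The statistic analysed is therefore the **relative
expression**: the gene's RNA/DNA ratio divided by the median RNA/DNA
ratio of its (species, sample) stratum. By construction the stratum
median of relative expression is 1, and any stratum-wide rescaling of RNA
(or DNA) cancels exactly — a property the test suite asserts.

Handling of zeros follows the definition of the ratio:

- genes with `dna_cpm = 0` have no defined ratio and are excluded from the
  stratum and from the median (no pseudocount by default; a pseudocount
  would manufacture expression evidence for genes with no detected gene
  copy);
- genes with `rna_cpm = 0` but `dna_cpm > 0` are real "present but not
  transcribed" observations: they get ratio 0 and participate in the
  median;
- a stratum with fewer than `min_genes = 10` eligible gene families, or a
  zero median ratio (less than half the genes transcribed at all), is
  excluded — too little signal to normalize against.

A shared strain is **eligible** for shift calling when both the mother and
infant stratum pass those preconditions. For eligible strains, gene
families with `dna_cpm > 0` on *both* sides are compared; genes present on
one side only are never called, since the infant/mother fold is undefined
for them. With infant and mother relative expressions $e_I$ and $e_M$:

- **activated**: $e_I > 2$ and $e_I / e_M > 2$;
- **deactivated**: $e_I < \tfrac12$ and $e_I / e_M < \tfrac12$;
- neutral otherwise.

All four inequalities are strict; a gene at exactly 2 is neutral. The two
conditions are mutually exclusive because the activation threshold exceeds
1 and the deactivation threshold lies below it. $e_M = 0$ with $e_I > 2$
gives an infinite fold and is an activation; symmetrically $e_I = 0$ gives
fold 0 and (with $e_I = 0 < \tfrac12$) a deactivation. If a family had
several infant samples the analysis stops and asks for explicit sample
selection — silent averaging would blur the per-dyad interpretation (the
intended design is one sample per subject).

Event counting distinguishes **events** (one per family-and-gene-family
occurrence) from **unique gene families** (a gene family activated in
several infants counts once per species). Overall percentages are taken
over the *universe*: all compared (species, family, gene family) tuples on
eligible shared strains. The **replication rate** of a species with
shared strains in two or more families is the fraction of its unique
infant-activated gene families activated in at least two infants; it is
`NA` for species with a single family pair.

The **annotated-rate test** computes, per shared strain, the percentage of
annotated gene families among all compared genes and among the
(de)activated genes, and compares the paired percentages across strains
with a Wilcoxon signed-rank test — exact when at most 25 informative pairs
and no ties, the normal approximation with continuity correction
otherwise; all-zero differences give p = 1. Annotation status defaults to
an id convention (ids ending `_unknown` are unannotated), can be extended
by an explicit id set or pattern, and is overridden by a two-column
annotation table when one is supplied, since annotation pipelines rarely
agree on a format.

## Community and pathway statistics

Shannon diversity is reported in nats (the convention of the vegan
ecosystem, which also backs the Bray-Curtis computation). PERMANOVA is
implemented directly from the squared-distance decomposition: with $a$
groups and $n$ samples, $F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(n-a)}$ and
$R^2 = 1 - SS_W/SS_T$, with the permutation p-value
$(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$ — ties count as
exceedances (conservative), permutations are seeded, and the default is
999 permutations. The direct implementation pins down these exact
semantics (and the error contracts: groups of one, or zero within-group
spread, are errors); the test suite cross-checks the statistic and $R^2$
against vegan's `adonis2` and the p-value against exhaustive enumeration
at small *n*. Mother-vs-infant diversity uses the equal-variance Student
t-test.

Pathway tables are filtered to pathways observed in at least 2 samples,
then each pathway is tested with the mixed model
`log10(abundance + pseudocount) ~ role + (1 | family)`. Family is the
random grouping — with one sample per subject it is the only replicated
structure, and it absorbs the dyad pairing. The pseudocount is half the
smallest nonzero value of the table, a standard choice that keeps zeros
finite without dominating the dynamic range. If the mixed fit fails the
pathway falls back to a fixed-effects linear model with a logged
downgrade (a boundary fit with zero family variance is *not* a failure —
lme4 handles it). DNA and RNA are tested separately, with
Benjamini-Hochberg q-values computed within each molecule over the
filtered set only, significant at q < 0.05.

## The synthetic cohort generator

`generate_cohort()` plants known truth behind every stage:

- **Haplotypes.** Each species has an i.i.d.-uniform ancestor sequence.
  For a transmitted (family, species) pair, mother and infant haplotypes
  are mutated independently from a common family strain at
  `transmitted_strain_divergence` (default 1e-4 substitutions/site); all
  other strains diverge independently from the ancestor at
  `background_strain_divergence` (default 1e-2). The 100-fold separation
  mirrors the empirical picture of dyad strain pairs being nearly
  identical against the species background, and makes exact recovery the
  correct expectation. Mutation is site-independent substitution to a
  uniformly chosen different base; optional gaps exercise the
  pairwise-deletion handling.
- **Expression.** Each gene's RNA equals its DNA times lognormal noise
  (`ratio_noise_sd`, default 0.1 — multiplicative noise on the ratio,
  which is the analysed statistic). On each transmitted strain, 10% of
  gene families are activated and 10% deactivated in the infant RNA by a
  factor of `activation_fold` (default 8). Per-sample totals are scaled
  to 0.9e6 CPM, leaving an unclassified remainder as real profilers do;
  the median normalization must absorb this scaling, so recovery also
  validates the normalization.
- **Taxonomy and pathways.** Mothers draw Dirichlet(1) profiles, infants
  Dirichlet(0.3) — fewer effective species, qualitatively mirroring the
  lower infant diversity. 15% of pathways get a four-fold role effect of
  random direction under lognormal noise (sd 0.2).

Defaults describe a ten-dyad pilot: 10 families, 20 species, 500 gene
families per species, alignment length 1000, transmission probability
0.25. One sample per subject; longitudinal sampling is out of scope.

What the generator does **not** emulate: within-subject temporal
variation (no day-to-day replicates exist to estimate it from),
phylogenetically realistic substitution models, compositional coupling
between species abundances and gene-family depth, read-level noise, and
incomplete strain detection (every species is observed in every sample).
Passing recovery tests therefore demonstrates correctness of the
computations and thresholds under the stated noise model — not the field
performance of strain tracking on real sequencing data.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `run_pipeline()` fans a
single global seed out to fixed per-stage child seeds so stages can be
rerun in isolation. Cohorts are byte-identical under a fixed seed.

The validation suite runs at desk scale by design: exact-oracle checks
(Jukes-Cantor closed form, Bray-Curtis brute force, BH step-up, PERMANOVA
by exhaustive permutation at n = 6, signed-rank by sign enumeration at
n ≤ 10) are instant; parameter recovery uses full-size cohorts (10
families × 20 species × 500 gene families) across five seeds; pathway
null calibration uses 200 pathways × 10 families across ten seeds,
checking the realized p < 0.05 rate against the binomial band around 0.05
and the q < 0.05 rate against the FDR target.

## Known limitations

- The printed activation totals of the motivating cohort study disagree
  internally by ten gene families (12,574 events vs 12,564 in the
  annotation comparison); the shipped counts table carries both values
  unmodified, and each summary uses the count printed for that quantity.
- Sharing calls are threshold-based, not probabilistic: no uncertainty is
  attached to an event near 0.2.
- Per-gene significance of expression shifts is intentionally out of
  scope (single samples per subject cannot support it); the
  activation/deactivation thresholds are descriptive calls.
- The mixed-model pathway test assumes log-scale additive noise; strongly
  zero-inflated pathway tables would need a different model.
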