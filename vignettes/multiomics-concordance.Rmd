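---
title: "Multi-omics concordance analysis of germfree versus conventional intestine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics concordance analysis of germfree versus conventional intestine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfconcord)
```

## The problem

Germfree (GF) mice are the standard tool for asking what the gut microbiota
does to its host. Comparing GF with conventionally raised (C) animals at a
single molecular layer — usually the transcriptome — is routine, but
transcript changes do not reliably predict protein changes: regulation can
act post-transcriptionally, co-translationally, or through targeted
degradation and secretion. `gfconcord` implements a complete analysis chain
for quantifying where the transcriptome (T), the proteome (P) and a
cross-study transcriptomic meta-analysis (M) of the intestine agree or
disagree about the host's response to the microbiota, and for attaching
defensible statistics to those statements at the gene, gene-set and pathway
levels.

Throughout, the germfree state is treated as the perturbed condition: a gene
with GF/C ratio above 1 is *upregulated*, below 1 *downregulated*. A feature
is *significantly affected by germ status* when its minimum
Benjamini-Hochberg q value across the germ-relevant contrasts (`q_min`) is
strictly below 0.1.

## The layers and their models

### Two-colour transcriptome

Raw input is a spot-level table of foreground/background median pixel
intensities, two channels per array, each array cohybridising one GF and one
C mouse of matched sex and strain (a *reference-free* paired design across
eight experimental classes: 2 germ statuses x 2 sexes x 2 strains).
Preprocessing follows a fixed order:

1. **Background capping** — per array and channel, backgrounds above four
   times the partition median are set to exactly that cap.
2. **Net-intensity flooring** — net = foreground − background; values
   strictly below 10 are replaced by a seeded uniform draw in [10, 20].
   Draws are consumed in a stable (array, channel, probe, spot) sort order,
   so the result is independent of input row order.
3. **Replicate collapsing** — arithmetic mean of nets across replicate
   spots, then log2.
4. **Intra-array LOWESS** — per array, the trend of M = log2(ch1/ch2)
   against A = mean log2 intensity is removed (classic locally weighted
   regression, degree 1, 3 robustifying iterations, span 0.4). A is left
   untouched. An inter-array LOESS against the per-probe median
   pseudo-sample (same span) is provided for the single-channel analyses.

Differential calling fits, per probe, intensity = intercept + array effect +
class effect + residual. Because each array links only the GF and C classes
of one sex/strain stratum, fixed array effects leave cross-stratum class
contrasts non-estimable; the fit therefore uses the classic split-plot
decomposition: within-array differences (GF − C) carry the four germ-matched
contrasts exactly (the array effect cancels algebraically), and
between-array channel sums carry the cross-stratum information with the
array effect treated as random. Variances are pooled within strata
separately for the difference and sum layers; contrasts mixing the two use
Satterthwaite degrees of freedom. Residual variances can be moderated by
empirical-Bayes shrinkage toward a common value across features
(`limma::squeezeVar`), an explicit stand-in for proprietary random-variance
moderation; it is on by default and none of the package's headline
statistics depend on it. All `r choose(8, 2)` class pairs receive
t-statistics, two-sided p values, and BH q values adjusted within each class
pair across features. `q_min` is the minimum over the four sex/strain-matched
GF-versus-C pairs, and the per-probe GF/C ratio is the anti-logged mean of
the per-array log2 ratios. Zero-variance features get p = 1, never `NaN`.

A separate three-way factorial ANOVA (germ, sex, strain, all interactions,
no array effect) provides per-parameter `q_min` values, e.g. `q_min(sex)` =
minimum of the q values of the four terms involving sex. Type-II sums of
squares are used because one experimental class has fewer mice than the
others; the computation is vectorised across features by comparing residual
sums of squares of nested model matrices, and is checked in the tests
against `car::Anova` per feature.

### Proteome

Input is a PSM-level table of sample/pool ratios from isobaric labelling.
Protein-group identifications are kept iff they have at least 2 peptide
groups and 4 PSMs, or else at least 10 PSMs (the filter is monotone:
additional evidence never hurts). Abundance per (group, mouse) is the median
of the PSM ratios, pooled across fractions and runs. A central-tendency
normalization divides each mouse by its median abundance — the
post-normalization per-mouse median is exactly 1 — and reports the
normalization values as "log-absolute" values (the value if above 1, else
its reciprocal): the mean abundance bias is
(geometric mean of log-absolute values − 1) x 100 percent, with subset
geometric means per experimental parameter as a diagnostic of
parameter-associated bias. Differential calling reuses the three-way ANOVA
on log2 abundances (log2 after normalization); GF/C is the ratio of GF and C
geometric means of the normalized (not log-transformed) abundances.

### Meta-analysis

The meta layer works on intrastudy *comparison group pairs*: one GF group
and one C group from the same study, each with at least three replicate
columns. Per pair, a pooled-variance two-sample t statistic per gene yields
one-sided p values in both directions (p(up) = P(T >= t)). Per direction,
the per-pair p values are combined with Fisher's method (Stouffer's method
is available as an alternative; the combiner of the original online toolset
is not published, so the choice is deliberately pluggable) and BH-adjusted
across genes, giving q(up) and q(down); `q_min` is their minimum, and GF/C
is the geometric mean of the per-pair ratios. Negating every log ratio swaps
q(up) and q(down) exactly.

## Gene states, gene sets and pathway statistics

Each gene gets a per-layer state: up, down, unaffected or unquantified. Ten
gene sets are built from the states: the three single-layer sets; the
concordant sets (significant in the named layers with all GF/C ratios on the
same side of 1); the one-sided discordant sets (significant in one layer,
quantified in the other, and either unaffected there or regulated in the
opposite direction — opposite-direction genes belong to both one-sided
sets); their union; and the invariant proteome set (germ-affected, sex- and
strain-unaffected). Each set carries up and down subsets split by the
defining layer's direction; for the union set, opposite-direction genes
follow the transcriptome (a documented tie rule — the defining layer is
otherwise unambiguous).

Every set is tested for pathway enrichment three times (up, down, up + down)
against its reference universe — the quantified gene universe of the
defining layer(s), or a supplied genome universe for the meta layer — with a
right-tailed Fisher exact (hypergeometric) test and BH adjustment across
pathways within each analysis. A pathway is then classified from its q
triple: *upregulated* if q(up) is strictly smallest and below 0.1 (mirrored
for *downregulated*), *intraset-discordant* if q(up + down) is weakly
smallest and below 0.1. The non-strict comparison means an exact three-way
tie is discordant; the tie q(up) = q(down) < q(up + down) fires no rule and
is reported not-enriched (the classification source is silent on it).

Two concordance statistics accompany the sets. The intraset concordance
P\_c is the exact two-tailed binomial p value of the up/down split at p =
0.5, defined as twice the smaller tail probability capped at 1 (at p = 0.5
this coincides with the equal-or-smaller-likelihood definition). The
interset discordance P\_MW is a two-tailed Mann-Whitney test between two
layers' log-ratio distributions, exact by enumeration when the smaller
sample has at most 8 values and no ties, otherwise the tie-corrected normal
approximation.

Enriched pathways are linked into an overlap network: an edge joins two
pathways sharing at least k (1–5) significantly affected genes, weighted by
the shared count. Raising k thins edges monotonically and refines the
component partition. "Clusters" are operationalised as connected components:
a proprietary layout cannot be reproduced, but the reported
two-cluster/three-cluster structure is exactly a statement about components,
which is testable.

For heat maps, rows are standardized per strain: `sigma` mode divides by the
strain-wise sample (n − 1) standard deviation of the log2 GF/C values,
`zscore` mode also centres on the strain-wise mean. Hierarchical clustering
is complete-linkage on Euclidean distance; missing cells are handled
pairwise-complete with the squared distance rescaled by total/observed
coordinates (the behaviour of `stats::dist`), a documented choice where the
original desktop tool's behaviour is unrecorded.

## The synthetic-data generator

Every stage is testable without downloads because the generator plants a
known truth with the structure the analysis assumes:

* a gene universe (default 2,000 genes) in which a fraction (default 0.15,
  matching the ~13% germ-affected genes a transcriptome of this design
  detects) responds to germ status;
* responders split into transcript-protein concordant / transcript-only /
  protein-only / opposite-direction categories (default mix 0.11 / 0.74 /
  0.14 / 0.01, the proportions implied by the observed tallies 88 / 578 /
  113 / 5);
* planted pathways labelled up, down, discordant or null (default 20
  pathways of 30 genes, mix 0.4 / 0.4 / 0.1 / 0.1). Up- and down-pathways
  draw members from disjoint pools of up- and down-responders, so their
  overlap network separates into two homogeneous components; discordant
  pathways deliberately bridge the pools;
* a paired two-colour design of 19 arrays (five mice per class, one GF class
  reduced to four, dye assignment alternating within class), log-normal
  multiplicative signal with additive per-array effects (log2 sd 0.3), spot
  noise (default sd 0.6 on log2, typical for two-colour arrays), and
  backgrounds uniform in [20, 50] so the cap rule is exercised;
* a stronger response in one strain, implemented as a multiplier (default 3)
  on effect sizes of the responsive strain. The default per-gene effect
  (0.6 on log2) was chosen by a-priori power analysis so that the weak
  strain's effects sit near the detection margin while the responsive
  strain's are clearly detectable — the qualitative strain asymmetry
  requires the weak strain not to be saturated;
* a PSM table with isobaric semantics (each PSM contributes one ratio per
  mouse), random peptide-group/PSM counts, per-mouse abundance biases for
  the normalization to remove, and planted identification-filter violators;
* per-study meta matrices (default 8 studies, 31 comparison group pairs,
  3 replicates per group) whose per-pair effect magnitudes come from a
  strong/weak mixture (default 0.5/0.5, weak multiplier 0.3), emulating the
  observed clustering of strongly and weakly affected comparisons.

All generators are deterministic given their configuration and seed (a
single `withr::with_seed` scope per generator), and dye effects default to
zero and are not modelled downstream, mirroring the randomization-based
mitigation of the emulated design.

What the generator does **not** emulate: probe sequence effects, spatial
array artifacts, missing-at-random dropout in the microarray (every probe is
present on every array), peptide-level interference or ratio compression in
the isobaric quantification, and inter-study platform differences beyond a
study-level offset. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
real-data pathology.

## A property of the q_min filter worth knowing

`q_min < 0.1` takes the minimum over four separately BH-adjusted contrasts,
i.e. it is the union of four FDR-0.1 discovery sets. Each set's realized
false discovery proportion concentrates near 0.1 x m0/m, but the four false
subsets are nearly disjoint (noise is independent across strata), while the
true discoveries largely coincide. The union's false discovery proportion is
therefore inflated roughly fourfold relative to a single contrast: with 15%
of genes affected and saturating power, the simulation experiments in the
test suite realize an FDP around 0.3 for the q_min call, even though every
individual contrast is properly FDR-controlled. A small additional
anti-conservatism arises because intra-array LOWESS, applied to arrays where
15% of probes carry strong planted effects, slightly perturbs null probes'
ratios. This is a property of the published filtering rule itself, faithfully
reproduced — not an implementation artifact — and it is why the single-layer
gene sets run larger than their planted counts while the concordant sets
(which require significance in two layers) do not.

## Numerical and design choices

* Strict inequalities everywhere the rules state them: `q_min < 0.1`,
  net `< 10` triggers flooring, backgrounds equal to the cap are untouched.
* BH scope for the pairwise contrasts: within each class pair across
  features. The alternative (pooling all contrasts into one family) changes
  little here because the four germ contrasts are exchangeable by design.
* Gene-level collapsing of probes: a gene's q_min is the minimum over its
  probes, its GF/C comes from the min-q probe, and conflicting significant
  directions are flagged; unmapped probes stay in the probe table only.
* Degenerate inputs: zero-variance features get p = 1; constant rows become
  missing under per-strain standardization and are flagged; a significant
  gene with GF/C exactly 1 is flagged indeterminate and treated as
  unaffected.
* Median PSM pooling is per (protein group, mouse) across fractions and
  runs; the original report does not subdivide further.
* Problem sizes in the test suite: the oracle-equivalence batteries run on
  10^4 random hypergeometric tables (N <= 500), BH vectors up to 10^4,
  exhaustive binomial enumeration to n = 20, full Mann-Whitney permutation
  to 6 + 6, and hand agglomeration to 6 points; the recovery experiments use
  2,000 genes, 19 arrays and 10 seeds. These sizes make the whole suite run
  in a couple of minutes while leaving the asymptotic regimes to the
  closed-form checks.

## Limitations

The package does not parse vendor microarray files or mass-spectrometry
raw data (inputs enter as plain tables), does not model dye effects, does
not re-annotate probes across platforms, and replaces two proprietary
components — the random-variance moderation and the commercial pathway
knowledge base — with a documented moderation option and a user-supplied GMT
catalogue. Headline counts from any particular real data set depend on those
proprietary components and on the deposited raw data, and are outside what
the synthetic experiments can or should reproduce.

## A short session

```{r example, eval = FALSE}
cfg <- truth_config(n_genes = 1000, n_pathways = 10, genes_per_pathway = 20,
                    effect_log2 = 1.2, seed = 42)
res <- run_pipeline(cfg, seed = 42)
res$tallies$tally        # up/down/discordant pathway counts per gene set
res$concordance          # n_up, n_down and exact binomial P_c per gene set
res$components           # pathway-overlap network components
```
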