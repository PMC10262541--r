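---
title: "Models and methods behind holoshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holoshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

holoshare analyses multi-site, longitudinal host microbiota data: ASV count
tables from several body sites of the same animals sampled repeatedly, with
extraction negative controls. This vignette explains the statistical
procedures the package implements, the choices made where the design was
genuinely open, and what the synthetic herd generator does and does not
emulate.

## The filtering chain

Filters run in a fixed order, each exactly once:

1. **Low abundance / low prevalence.** An ASV is removed iff it is
   low-abundance (pooled relative abundance strictly below 1e-5 in *every*
   site-by-time stratum, or strictly below 5e-5 overall) or low-prevalence
   (positive in strictly less than 5% of samples within *every* site, or in
   fewer than 3 samples overall). "Pooled" means stratum-summed reads:
   the abundance of ASV $a$ in stratum $s$ is
   $\sum_{i \in s} x_{ia} / \sum_{i \in s} x_{i\cdot}$. A
   `mean_per_sample` switch averages per-sample fractions instead, for
   sensitivity analysis; pooling is the default because it is the simpler
   reading of "the relative abundance of each ASV was computed in each
   site" and is robust to uneven depths. Controls are excluded from these
   strata — a contaminant must not rescue itself via control prevalence.
2. **Kitome decontamination.** Samples are split by site with the negative
   controls as an extra stratum. An ASV is flagged iff its prevalence among
   control samples is *strictly* greater than 50% and its pooled relative
   abundance in the controls exceeds that over all body-site samples
   combined. Both measured numbers are reported per ASV so that borderline
   calls can be audited. This is a rule-based decontamination in the
   negative-control tradition, not a model-based (frequency/prevalence
   mixture) method.
3. **Minimum reads.** Samples with strictly fewer than 1000 reads after the
   ASV-level filters are discarded. Running this last means samples pushed
   below the threshold by decontamination (negative controls above all) are
   caught — the cascade is intentional and applied once.

Every removal is logged as (entity, rule, measured values); replaying the
log on the input table reproduces the filtered table bit-exactly, which the
tests assert.

**Rarefaction** subsamples each retained sample without replacement to a
common depth (default: the minimum retained total), seeded and
reproducible. Rarefied counts feed alpha and beta diversity only; core
membership and sharing use the *unrarefied* filtered table, since presence
thresholds (count > 0) lose information under subsampling. A rarefied
variant is available for sensitivity analysis.

## Diversity and ordination

Shannon entropy uses the natural logarithm. Jaccard is binary
presence/absence, $1 - |A \cap B| / |A \cup B|$ (the quantitative
"Jaccard" of some ecology packages is not used). Bray–Curtis is
$\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on rarefied counts, which equals
the proportion-based form when depths are equal.

UniFrac is computed by propagating per-sample presence (or relative
abundance) to every branch of the rooted tree: for a branch of length $b$
subtending leaf set $L$, unweighted UniFrac accumulates $b$ into the
numerator when exactly one of the two samples has a positive count in $L$,
and into the denominator when at least one does. Weighted UniFrac uses
$\sum_b b\,|p_A(b) - p_B(b)|$, normalized by $\sum_b b\,(p_A(b) + p_B(b))$
by default (the usual "wUniFrac"); the raw variant is available. On a star
tree with unit branches these reduce analytically to Jaccard and
Bray–Curtis respectively, which the tests assert on random fixtures, and
both match an exhaustive branch-enumeration oracle to 1e-12.

PCoA is classical scaling: eigendecomposition of the double-centered
$-\tfrac12 D^2$. Axes with positive eigenvalues carry coordinates scaled by
$\sqrt{\lambda}$; negative eigenvalues (non-Euclidean dissimilarities) are
reported but not corrected — no Cailliez or Lingoes constant is added, so
the ordination stays faithful to the raw dissimilarity. Axis signs follow a
deterministic convention (largest-magnitude loading positive).

## Permutation statistics

**PERMANOVA.** With $G = -\tfrac12 C D^2 C$ (Gower centering), the
sequential sum of squares of term $k$ in an ordered model is
$\mathrm{tr}(H_k G) - \mathrm{tr}(H_{k-1} G)$, where $H_k$ is the hat
matrix of the design through term $k$ (factors dummy-coded, covariates
centered, rank handled through QR). The pseudo-F is
$(SS_k/df_k)/(SS_{res}/df_{res})$; p-values come from permuting samples,
i.e. rows and columns of $D$ jointly, with
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$. Sequential (type-I) SS with
user-controlled order is the default, matching the common adonis2 usage; a
marginal mode exists because multi-covariate models are order-sensitive and
the appropriate choice is the analyst's. Permutations are free (no
strata): animal identity enters the model as an ordinary factor rather
than as a restricted permutation block. An `exact = TRUE` mode enumerates
all $n!$ permutations for $n \le 8$, used to verify the permutation
machinery against exhaustive label enumeration. Default `n_perm` is 9999
in the exported function interface for final analyses; the orchestrated
pipeline uses 999 by default to keep full runs fast, and both are
reproducible from the seed. Under a true null the permutation p-values are
uniform, which the test suite checks by simulation (500 replicates,
Kolmogorov–Smirnov).

**Beta-dispersion.** Samples are embedded by PCoA keeping positive and
negative eigen-axes separately; the squared distance of a sample to its
group centroid is the positive-space squared distance *minus* the
negative-space one, floored at zero (the standard treatment of
non-Euclidean dissimilarities). The observed F is a one-way ANOVA on these
distances; significance comes from permuting group labels over the
distances, and pairwise comparisons use Tukey's HSD. Centroids (not
spatial medians) are used. Groups of size one are excluded with a warning.

**Clustering and stability.** Animals are clustered per site and time
point by Ward linkage on Bray–Curtis distances between their aggregated
communities. The ward.D2 convention is used (Lance–Williams update on
squared dissimilarities, heights in original units) — the variant that
optimizes the Ward objective on dissimilarity input; the test suite checks
its merge sequence against a brute-force Ward-objective minimizer on
Euclidean fixtures. The dendrogram is cut at k = 5 by default, and
partitions at consecutive time points are compared with the Hubert–Arabie
Adjusted Rand Index restricted to animals present at both times.

## Core microbiota and sharing

The analysis unit is the **animal-level community**: for milk, quarter
samples of an animal/time are summed before computing presence and
relative abundance (union semantics — an ASV present in one quarter is
present in the animal's milk community); other sites have one sample.

An ASV is **core** for (site, time) iff its animal-level relative abundance
is strictly above 0.01% in at least 50% of the animals having a community
in the stratum. The prevalence comparison is `>=` by default with a strict
mode available, since "at least" and "more than" both appear in common
usage; the abundance comparison is strict. Core output includes per-ASV
evidence, the stratum's total ASV count (present in at least one animal)
and the per-animal fraction of its own ASVs that are core.

**Pairwise sharing** reports, per animal and unordered site pair, the
intersection size, the two directional fractions (shared count divided by
each site's own community size — the denominators are the animal's
communities, not herd totals), and the summed relative abundance of shared
ASVs in each site. **Multi-way sharing** counts occurrences: tuples (ASV,
animal, time, site combination of size 3 or 4) where the ASV is present in
every site of the combination; an ASV in all four sites contributes
$\binom{4}{3} = 4$ three-way occurrences and one four-way occurrence.
These tallies are validated against an exhaustive tuple-enumeration oracle.

## The synthetic herd generator

`generate_herd()` draws, in a fixed seeded order: (1) a global ASV pool and
per-site templates with log-normal abundances, a fraction `f_core` of each
template marked core; (2) per animal-site communities = core ASVs, non-core
template ASVs kept with probability `occupancy`, and `n_private` fresh
animal-private ASVs, abundances jittered per animal; (3) within-animal
transfers: each source-community ASV moves to each other site with
probability `f_share` at `transfer_scale` times its abundance; (4) temporal
turnover replacing the lowest-abundance fraction `time_turnover` of each
community with fresh private ASVs between consecutive time points
(detection-limit churn, deterministic given abundances); (5) kit
contaminants: negative controls are pure contaminant, body samples receive
a contaminant mass fraction `kit_load * min(biomass)/biomass[site]` — the
inverse-biomass carry-over that makes milk the most contaminated site;
(6) multinomial read sampling at log-normal depths floored at 200 reads
(so the 1000-read sample filter is exercised), with an optional Dirichlet
overdispersion; (7) a random bifurcating tree with exponential branch
lengths over all ASVs.

Transfers are applied fresh at every time point to the turnover-evolved,
pre-transfer communities, so sharing reflects the current rate rather than
compounding over time, and the measured shared fraction stays monotone in
`f_share` at every time point.

Defaults are the study conditions the pipeline targets: 45 animals in
three groups (18/15/12), four sites, four time points, 66 negative
controls, biomass 10:10:3:1 (oral:nasal:vaginal:milk) with
`kit_load = 0.15` — giving expected contaminant read fractions of about
1.5%, 1.5%, 5% and 15% across the four sites — and depths log-normal
around 10^4 reads. Pool sizes (P = 600, S = 150) keep a desk-scale run in
minutes while leaving roughly a thousand ASVs after filtering. The default
design is complete (all sites at all times, one milk sample per
animal/time); quarter-level milk generation (`milk_quarters = 4`) is
supported for exercising the aggregation rule. Real-data features the
generator does **not** emulate: taxonomy, sequence-level error and
chimeras, phylogenetic signal in community assembly (the tree is random,
so UniFrac has no planted structure beyond composition), temporal
autocorrelation beyond single-step turnover, and missing-by-design cells.
Passing the recovery tests therefore demonstrates correctness of the
statistical machinery on known structure, not performance on real
sequencing artefacts.

## Numerical and reproducibility notes

Counts are stored as integers; relative abundances as doubles with row
sums checked to 1e-12. Distance matrices are validated for symmetry, zero
diagonal and non-negativity on IO. Eigenvalues within a relative 1e-9 of
zero are treated as zero in PCoA and the dispersion embedding. Ties in
turnover removal are resolved by abundance order after jitter, making the
churn deterministic. All permutation procedures and the generator are
bit-reproducible given their seed; the pipeline derives per-stage seeds by
hashing (master seed, stage name), so inserting a stage never perturbs
another stage's random stream. Problem sizes in the test suite (herds of
5–20 animals, pools of 60–400 ASVs, 199–999 permutations, 200–500
simulation replicates) were chosen so the whole suite runs in about a
minute while keeping Monte-Carlo standard errors small enough for the
calibration checks to be meaningful.

## Known limitations

The dispersion permutation test permutes distances-to-centroid rather than
recomputing centroids per permutation, the standard but approximate
approach. PERMANOVA offers no restricted permutation schemes, so repeated
measures on the same animal are modelled as a factor, not as an
exchangeability block. Rule-based decontamination cannot flag a genuine
community member that also contaminates kits. Core and sharing statistics
treat presence as binary above zero reads, so they inherit depth
sensitivity from sequencing effort; the unrarefied default favours
sensitivity over strict comparability across samples.
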