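---
title: "Methods: trans-kingdom analysis of paired 16S/ITS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-kingdom analysis of paired 16S/ITS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `transkingdom`, the
assumptions behind each stage, the generative model of the synthetic
cohorts, and the design decisions that were genuinely open.

## Data model

Every abundance table is samples-by-taxa, always. Taxa carry rank-prefixed
lineages (`k__...;p__...;...;g__...`, unassigned ranks kept with an empty
suffix), and a table is tagged with its kingdom (bacteria from 16S, fungi
from ITS) and its normalization state. Counts and relative abundances are
distinct states: richness estimators need counts (Chao1 is undefined
without singletons), whereas correlation networks and differential
screens operate on proportions. `to_relative()` is total-sum scaling;
proportions stay in [0, 1] and are only multiplied up (per-million) where a
procedure's convention demands it.

## Alpha diversity and the ITS/16S ratio

Per sample: observed richness `sobs`; the bias-corrected Chao1
`sobs + F1(F1 - 1) / (2(F2 + 1))` (F1 singletons, F2 doubletons), used
unconditionally so the estimator is continuous in its inputs; Shannon
entropy in natural log; and the Gini–Simpson index `1 - sum(p^2)`. The
Simpson variant is deliberately the *diversity*-oriented one (higher =
more diverse); packages and platforms disagree on this, so the choice is
stated here and in the function documentation.

The fungal-to-bacterial ratio is `sobs_fungal / sobs_bacterial` per sample.
It is a ratio of richnesses, not of abundances, and therefore insensitive
to sequencing depth differences between the two marker genes as long as
depth does not censor detection; it is undefined (an error) when a sample
has zero detected bacterial genera.

Group comparisons use the two-sided Wilcoxon rank-sum test with average
ranks for ties: exact enumeration of all label assignments when both
groups have at most 8 samples (the two-sided p is the fraction of
assignments whose rank sum deviates from the null mean at least as much as
observed), and the tie-corrected normal approximation without continuity
correction otherwise.

## Beta diversity

`bray_curtis()` and `unweighted_unifrac()` are implemented from first
principles and cross-checked in the test suite against independent
references. Unweighted UniFrac covers a branch by a sample when any leaf
below the branch is present; the distance is the branch length covered by
exactly one of the two samples over the branch length covered by their
union. Note a subtlety that is easy to get wrong by hand: a stem above two
leaves is *shared* as soon as each sample contains at least one of its
descendants, even if the two samples contain different descendants.

PCoA is classical metric scaling: Gower double-centering of `-D^2/2`,
eigendecomposition, axes retained above an eigenvalue tolerance of 1e-10.
Negative eigenvalues (non-Euclidean dissimilarities) are reported as-is;
no Lingoes/Cailliez correction is applied, to keep the embedding
transparent. Explained fractions are relative to the positive eigenvalue
total.

PERMANOVA follows the classical one-way formulation:
`SS_total = sum_{i<j} d^2 / N`, within-group sums analogous, pseudo-F
`(SS_between/(a-1)) / (SS_within/(N-a))`. With two groups and at most
10,000 distinct relabelings the permutation distribution is enumerated
exactly (small designs deserve exact p); otherwise seeded Monte Carlo with
the +1 correction, so p is never zero and never below
`1/(n_permutations + 1)`. Type-I error calibration (0.05 ± 0.03 over 200
null simulations) is asserted in the acceptance tests.

## Differential abundance

The Wilcoxon screen applies the rank-sum test per taxon on proportions and
controls FDR with Benjamini–Hochberg across all tested taxa. Keep in mind
that proportions are compositional: a single strongly shifted taxon
necessarily shifts others in the opposite direction, so "significant"
means "different in relative terms".

The LDA effect-size procedure mirrors the LEfSe recipe with its published
defaults (per-million scaling, Kruskal–Wallis screen at alpha = 0.05, 30
bootstrap rounds, log10 score) because the upstream tool is cited only by
its thresholds (3.5 for 16S, 3.0 for ITS); every knob is an argument. The
subclass (within-group Wilcoxon) stage is omitted — the two-group design
has no subclass structure. Each bootstrap round subsamples two thirds of
every group without replacement and fits a one-dimensional linear
discriminant per feature; for a single feature the discriminant-aligned
class separation equals the class-mean difference (which is also LEfSe's
regularization term), so the effect size is the mean separation over
rounds, reported as `sign * log10(max(|effect|, 1) + 1)`. Bootstrap
subsamples are drawn over sample ids sorted within group, shared by all
features, which makes the output invariant to sample and taxon order at a
fixed seed. Magnitudes beyond the first decimal are tool-specific across
LEfSe implementations; the tests therefore assert rank ordering and
threshold behavior, not third-decimal agreement. Multi-rank input is
concatenated into one feature table, the LEfSe convention.

## Trans-kingdom networks

No consensus defines when two genera are "connected"; the criteria are
therefore an explicit parameter object (`network_params()`), defaulting to
prevalence >= 20% of shared samples, mean relative abundance >= 1e-4,
|Spearman rho| >= 0.6, and BH-adjusted p < 0.05 across all tested pairs —
common practice for trans-kingdom co-occurrence analysis. Correlations are
computed on proportions (not counts, not CLR), and the choice is recorded
in the network object. Spearman p-values use the t-approximation, or exact
enumeration below 10 samples; below 4 shared samples network construction
refuses to run.

Summary parameters follow the conventions of trans-kingdom network tables:
node counts split by kingdom with their fungi:bacteria ratio, signed edge
counts, relative connectedness = edges/nodes (this definition is
cross-validated in the acceptance tests against two independent printed
node/edge/connectedness triples: 273/126 -> 2.17 and 86/55 -> 1.56), and
clusters = connected components, so dyads and triads detached from the
main component count separately. Isolated genera are not nodes: a genus
enters the graph only through at least one edge.

Modules are connected components at a minimum size (default 3), ordered by
decreasing size with lexical tie-break; a module's per-sample profile is
the mean of its members' z-scored abundances. Module–module and
module–metabolite associations use partial Spearman correlation: all three
vectors are rank-transformed, profile ranks are residualized on covariate
ranks by least squares, and the Pearson correlation of residuals is tested
on n - 3 degrees of freedom. With a constant covariate this reduces
exactly to plain Spearman.

## Metabolomics

Preprocessing is log transform followed by per-metabolite autoscaling
(mean 0, variance 1); non-positive intensities are an error, not silently
imputed, and the state flag makes preprocessing idempotent. PCA is the SVD
of the centered matrix.

OPLS-DA: the class code y = ±1 is centered; orthogonal signal correction
(Trygg–Wold) removes `n_ortho` components of X-variation orthogonal to y,
then one predictive NIPALS PLS component is fitted. R²Y is explained class
variance in training; Q² comes from stratified, seeded k-fold
cross-validation (default 7-fold, the chemometrics convention) in which
the orthogonal filter and the predictive component are refitted per fold
and applied to the held-out samples. With `n_ortho = 0` the model reduces
exactly to single-component PLS-DA (asserted against an independent NIPALS
oracle in the tests). VIP uses the standard weighted-loadings formula over
the predictive plus orthogonal components, with each component weighted by
the y sum of squares it explains; with unit-norm weight vectors the mean
of squared VIP is identically 1, which the tests assert. Permutation
validation refits the full pipeline under label permutations and reports
`(1 + #{permuted >= observed}) / (1 + n_perm)` for both R²Y and Q².

The univariate biomarker screen is Student's t by default (rank-sum is an
option), two-tiered: VIP > 1.5 with p < 0.05, then additionally BH
q < 0.05. Fold change is reported through the group means but is not used
as a filter, since no threshold for it is established here.

## FMT accounting and behavior

Engraftment is a set computation at the genus level: a genus is "detected"
in a group when its summed count reaches a threshold (default: any nonzero
count), and the transfer percentage divides the shared genus count by the
*donor* genus count — the denominator choice is fixed by the convention
that engraftment asks how much of the inoculum took hold.

The anxiety composite follows integrated behavioral z-scoring: each test
is standardized against the control group, multiplied by -1 where a higher
raw value means *less* anxiety (center time, open-arm time; the
orientation registry is explicit and extensible), and averaged. The
control composite mean is 0 by construction. The alcohol-preference ratio
is the alcohol share of total fluid intake over the recording window
(alcohol/(alcohol + water), in [0, 1]); the alternative alcohol/water
ratio is unbounded and was rejected for that reason.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure a paired 16S/ITS
study of an alcohol-dependence-like contrast would produce, not its
biology:

- Latent factors. Each sample draws `n_latent` (default 10) standard
  Gaussian factors; the affected group's factors are shifted by
  `group_location_shift` (default 1.5 SD). Factors are the common currency
  that couples kingdoms, metabolites, and the group contrast.
- Counts. Half of each kingdom's genera load on the factors (cycled); a
  genus's log abundance is its base level plus a 2-log-unit signal
  combining factor and idiosyncratic noise, softmax-normalized per kingdom
  and sample, scaled by a log-uniform library size spanning one order of
  magnitude (2e4–2e5 bacterial, 5e3–5e4 fungal reads), and Poisson
  sampled. This Poisson-log-normal scheme is the simplest mechanism that
  yields controllable rank correlations together with realistic zero
  inflation and unequal depth.
- Coupling asymmetry. Fungal genus pairs sharing a factor have latent
  correlation equal to the group's `coupling_strength` c (control 0.8,
  affected 0.2 by default); bacterial pairs couple at `c^(1/2)` and
  cross-kingdom pairs at `c^(3/4)`. All three are monotone in c and vanish
  at c = 0 (full independence, used by the null-calibration tests). The
  asymmetry gives the bacterial flora a more persistent backbone, so
  weakening c thins fungal and cross-kingdom edges first — the observed
  signature of an affected-group network that stays bacteria-dominated.
- Dominance control. Factored (high-amplitude) genera draw their base
  abundance from N(0, 1) while the stable unfactored flora spans N(0, 2)
  and dominates the composition. Without this, a dominant swinging genus
  drives the softmax denominator and compositional closure induces
  spurious correlations among all other genera. The first factor-anchored
  genus of each kingdom is pinned at the median base abundance so the
  planted cross-kingdom edge is observable rather than censored by the
  Poisson detection limit.
- Richness deficit. The `fungal_richness_deficit` fraction (default 0.4)
  of the *least abundant* fungal genera is structurally zeroed in affected
  samples, mimicking depletion of rare taxa; this is what lowers affected
  fungal Chao1/Sobs and the ITS/16S ratio.
- Metabolites. Two metabolites per factor track the factors at correlation
  `metabolite_loading` (default 0.7) on the log scale; the remaining
  metabolites are log-normal noise. With the default shift this yields a
  cross-validated OPLS-DA (Q² around 0.6–0.8) whose top VIP decile is
  occupied by the planted metabolites — both are tested recovery
  properties.
- Behavior. Center time, open-arm time (higher = calmer) and immobility
  time (higher = more affected) shift by `behavior_effect` control-SDs
  (default 1) in the anxious direction.
- Covariate. Daily alcohol intake is generated at roughly 9 ± 3 g/day for
  controls and 490 ± 30 g/day for the affected group, so
  covariate-adjusted analyses have a realistic confounder to work with.

Determinism: the entire cohort is generated under one seed and restoring
the caller's RNG state; identical configurations give bit-identical
cohorts.

What the generator does **not** emulate: taxonomic correlation structure
beyond the factor model (no phylogenetic signal in abundances), sequencing
error, chimeras or compositional biases of PCR, batch effects, overdispersion
beyond Poisson-log-normal, metabolite identities or pathway structure, and
covariance between behavior and the microbiome beyond the shared group
label. Passing recovery tests therefore demonstrates that the pipeline
detects the planted statistical structure at realistic sizes — not that it
would reach the same biological conclusions on any real cohort.

## Problem sizes and numerical choices

The default cohort is 30 samples per group, 90 bacterial and 40 fungal
genera, 120 metabolites — the scale of the motivating study design (dozens
of subjects, genus-level tables). Replicate-based properties use 20
cohorts; null calibrations use 200 simulations with 99 permutations, sizes
at which the whole test suite runs in well under a minute.

Tolerances: PCoA eigenvalue cutoff 1e-10; permutation-test comparisons use
a 1e-12 slack so ties at the observed statistic count as "as extreme";
relative-state row sums are enforced to 1e-9; VIP identity to 1e-6.
Degenerate inputs fail loudly and early: all-zero samples, constant
profiles, zero control SDs, empty donor sets and empty networks are
errors, not NaNs. An affected-group network with *no* surviving edges is a
legitimate analysis outcome under weak coupling; `summarize_network()`
refuses it (there is nothing to summarize) and callers that compare groups
should treat it as zero connectedness, as the acceptance checks do.

## Known limitations

- Correlation networks on proportions inherit compositional closure;
  SparCC/SPIEC-EASI-style compositionality-aware estimators are out of
  scope, and with ~60–130 genera the closure bias at |rho| >= 0.6 is
  modest but not zero.
- PERMANOVA is one-way; no covariate adjustment or strata.
- The LDA score is a faithful re-derivation of the LEfSe recipe, not a
  byte-for-byte port; agreement is at the level of feature selection and
  ranking.
- Q² uses fold-wise refitting on globally preprocessed data; fold-wise
  re-preprocessing would be stricter and slightly lowers Q² in practice.
- Rarefaction/coverage standardization is not implemented; richness
  comparisons assume comparable depth, which the generator's log-uniform
  library sizes deliberately stress.
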