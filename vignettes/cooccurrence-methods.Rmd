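---
title: "Methods: from genus counts to co-occurrence inference in small compartmentalised designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genus counts to co-occurrence inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The setting

gutcooc targets a study shape that is common in livestock microbiome
work and statistically awkward: two phenotype groups (low and high body
weight, selected beyond one standard deviation of a flock mean of
2696 ± 227 g), five birds per group, and three gut compartments sampled
per bird (jejunum chymus, jejunum mucosa, caecum chymus). Thirty samples
in total, but every within-group question rests on n = 5 and every
pooled-place question on n = 10. The methods below are chosen for that
regime: exact or permutation-based wherever a parametric approximation
would be meaningless at these sizes.

## Diversity and ordination

Counts are filtered to features with ≥ 10 reads overall, then rarefied
once per sample, without replacement, to a common depth (default
10,000); samples below the depth are dropped and named. A single
rarefaction draw (rather than an average over draws) matches what the
dominant amplicon pipelines do; `rarefaction_curve()` provides the
averaged view when the Monte Carlo mean is wanted.

Alpha diversity reports observed features, bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ — the bias-corrected form stays finite
when no doubletons exist — Shannon entropy in log base 2 by default
(diversity suites disagree between bits and nats; base 2 is the default
here and the base is configurable), Gini-Simpson $1-\sum p_i^2$, and
Faith's PD, the branch-length sum of the minimal rooted subtree spanning
the observed leaves. Chao1, Shannon and Simpson are delegated to vegan
and Faith's PD to picante; the test suite re-derives each from closed
forms and from a brute-force subtree sum on small trees, so the
delegation is verified, not assumed.

Between-sample structure uses two complementary distances: Bray-Curtis
$\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$, which weighs taxa by abundance,
and the correspondence-analysis chi-square distance
$d(i,j)=\sqrt{\sum_k (1/c_k)(p_{ik}/r_i-p_{jk}/r_j)^2}$, which
up-weights rare taxa. Bray-Curtis is a semimetric — the triangle
inequality can fail — so it is ordinated by PCoA with negative
eigenvalues reported rather than corrected away. Group separation is
tested by PERMANOVA (pseudo-F) and ANOSIM (rank-based R), both with free
label permutation and $p = (\#\{T_{perm} \ge T_{obs}\}+1)/(B+1)$, which
bounds p away from zero. One practical consequence of free label
permutation at 5+5: about 0.8% of permutations reproduce the observed
partition and tie with the observed statistic, so the attainable p floor
is ≈ 0.009, not $1/(B+1)$. The effect of body weight on composition is
additionally assessed by CCA on the chi-square-standardised table with a
permutation test of the constrained pseudo-F.

## Composition screening

Relative abundances (percent, per sample) are aggregated at phylum and
genus rank; unclassified features are pooled under one label and kept,
since genus-level classification of 16S data is typically incomplete.
Group-mean tables report cell means per place × BW group and margins
that are arithmetic means of the cells — exact under the balanced
design, and the property the acceptance worked-examples check against
published cell values. The Bacteroidetes/Firmicutes ratio is computed
per sample and averaged per group; the mean of per-sample ratios is not
the ratio of group means (Jensen gap), which is why published B/F
margins cannot be recomputed from printed B/F cells, and the per-sample
convention is used here.

Each taxon is screened by a two-way fixed-effects ANOVA (place, BW
group, interaction) on untransformed percentages — ANOVA is robust to
the non-normality of abundance data at equal cell sizes, and no
transform is applied by default; an arcsine-square-root option exists
for sensitivity analysis. Benjamini-Hochberg FDR is applied across taxa
separately per effect (one family per effect column, the layout used in
published tables); adjusted p < 0.05 is significant and 0.05–0.10 a
trend. Tukey HSD letters are derived from the pairwise results as
maximal cliques of the non-significance graph, ordered by group means.
Constant taxa are excluded from the FDR family and flagged rather than
silently dropped.

The body-weight screen correlates each genus with the birds'
individual weights (grams, both groups pooled per place, n = 10), not
with the group label — the continuous weight carries more information
and matches how such correlations are reported. Genera enter only if
their mean relative abundance exceeds 0.01% in that place and they are
non-zero in ≥ 8 of the place's samples; the 0.01% rule is read as mean
relative abundance because that is the only scale on which the
threshold is dimensionally meaningful, and the 8-sample rule is applied
per place (each place has 10). No multiplicity correction is applied in
this screen by design; the output marks raw p < 0.05, and the caveat is
documented here rather than hidden.

## Exact Spearman at n ≤ 10

At n = 5 the asymptotic Spearman test is useless, so `exact_spearman()`
enumerates the permutation null. For n ≤ 8 all n! orderings of one
vector are enumerated; ties are handled with average ranks, and the
observed values themselves are permuted, so the null conditions on the
observed tie pattern. For untied data at 8 < n ≤ 12 the exact null
distribution of $S=\sum d_i^2$ is computed by dynamic programming over
rank subsets (a bitmask DP counting permutations attaining each S), so
that, e.g., a strictly monotone series of 10 birds gets the exact
two-sided p of $2/10!$. Beyond that, or with ties at n > 8, a
t-approximation is the documented fallback. Enumeration includes the
identity permutation, so no p-value is ever zero.

## The co-occurrence procedure

Within each place × BW group (five samples): genera with non-zero
abundance in at least four of five samples are retained; all pairwise
Spearman correlations are computed on the five samples; an edge is
called at ρ ≥ 0.9 (and at ρ ≤ −0.9 — negative edges are allowed by
default and carry their sign, since nothing in the procedure restricts
association to the positive side). The 0.9 threshold is a descriptive
edge rule, not a per-edge test: at n = 5 only |ρ| = 1 attains two-sided
exact p < 0.05, so testing individual edges would empty every network.
Inference instead targets network-level statistics:

* **Connection counts.** The null model permutes each genus's abundance
  vector across the group's five samples independently — every marginal
  distribution is preserved exactly while all cross-genus association is
  destroyed — and rebuilds the thresholded network per replicate. For a
  genus with observed degree d, $p=(\#\{d_{null}\ge d\}+1)/(B+1)$; an
  isolated genus has p = 1 by construction. This is the standard
  permutation null for co-occurrence screens.
* **Components.** Each observed component is scored by its internal
  edge count and compared against the *maximum* component edge count of
  the null network per replicate. Using the null maximum makes the test
  family-wise valid across the components of one network — the price is
  conservatism for secondary components, which is the right trade-off
  when one community per network is the scientific claim.
* **Cross-compartment variant.** For one BW group, lumen and mucosa
  samples are aligned by bird, filters are applied per compartment, and
  every (lumen genus, mucosa genus) pair is correlated across the five
  matched birds. Only bipartite edges exist; the per-lumen-genus
  out-degree is tested with the same permutation null (permuting the
  lumen vectors breaks the bird alignment).

Degree discreteness is worth stating plainly: with m retained genera the
null degree is roughly Binomial(m−1, 1/12) (P(|ρ| ≥ 0.9) = 10/120 for
untied data at n = 5), so the achieved level of the degree test at
α = 0.05 depends on m through the discrete tail. At m ≈ 30 — a typical
post-filter genus count — the achieved level is ≈ 0.036, inside the
0.03–0.07 band the calibration suite checks; much smaller networks make
the test conservative.

## The synthetic generator

`simulate_counts()` emulates the data-generating assumptions the
analysis relies on, with ground truth:

* A flock of body weights N(2696 g, 227 g²); low/high groups are drawn
  from beyond ±1 SD, with bounded redraws — the selection rule of the
  emulated design.
* Log-normal genus baselines (sdlog 1) plus genus × compartment offsets
  (sdlog 1, driving the strong between-compartment separation real
  studies show) plus residual per-sample noise (sdlog 0.15).
* Planted blocks: a per-bird latent factor shared by the block's genera,
  scaled by a loading, added on the log scale; loading 2 makes
  within-block rank correlation saturate (median pairwise ρ ≥ 0.8 at
  n = 5). Blocks can span compartments (the latent is per bird), which
  is how lumen→mucosa drivers are planted, and can be restricted to one
  BW group. Block genera draw their baselines from the detectable upper
  half of the baseline distribution: a co-occurring community has to
  survive the prevalence filter to be a recovery target at all —
  planting one on a genus expected at a handful of reads per sample
  would make "recovery" ill-posed rather than merely hard.
* Planted BW effects multiply abundance by
  $2^{l2fc \cdot z_{bird}}$ with z the standardised individual weight,
  so both the group-label ANOVA and the continuous Spearman screen see
  signal from the same planting.
* Counts are Dirichlet-multinomial at a per-sample depth uniform on
  12,000–20,000 reads (so rarefaction to 10,000 is meaningful and no
  sample is lost). The default noise scales (noise sdlog 0.15,
  concentration 50,000 — close to pure multinomial counting) are chosen
  for test power, not biological fidelity: with five birds per group the
  realised spread of a block's latent factor is itself a lottery, and
  heavier residual noise would make planted structure at loading 2 a
  coin flip rather than a recoverable target. Real 16S data is far more
  overdispersed; lowering `dispersion` and raising `noise_sdlog` gives
  harder, more realistic conditions at the price of power.
* Thirty genera by default — the scale of a genus table after
  prevalence filtering — with a synthetic taxonomy over six real phylum
  names so aggregation and B/F machinery run end to end.

Determinism: one master seed; every stage (weights, baselines, offsets,
latents, counts, tree, and each analysis stage in the pipeline) derives
a child seed from the master seed and a stage tag, so stages are
reproducible in isolation and pipeline reruns are byte-identical.

One behaviour deserves emphasis because it is a property of the method,
not a bug of the generator: the procedure correlates *relative*
abundances, and a strong latent factor anywhere in the community moves
every other genus through the shared denominator. Networks built on
compositions are therefore dense around genuine structure — a planted
block typically sits inside a component larger than itself. The
marginal-preserving permutation null controls the resulting inference
(the component and degree tests stay calibrated on null communities),
but edge lists should be read as descriptive, and compositionality-aware
estimators (SparCC-type) are deliberately out of scope.

What the generator does *not* emulate: sequencing error and chimeras,
taxonomy misassignment, structural zeros, phylogenetic correlation of
abundances, and real 16S overdispersion heavier than the chosen
concentration. Passing recovery and calibration suites therefore show
that the procedures behave as designed under their own assumptions —
not that five samples suffice to reconstruct real microbial
interaction networks, which remains a severe limit of the design
itself.

## Numerical choices and degenerate inputs

Edge thresholds compare with a 1e-12 slack so ρ computed as 0.8999…9
counts as 0.9. Constant genus vectors yield undefined ρ; they are
flagged (exact test) or produce no edges (network path, where the
standardised rank vector is zeroed). Empty samples get NA diversity
indices with a warning; all-zero sample pairs get Bray-Curtis 0 with a
warning; zero-total features are dropped from the chi-square distance
with a warning. Monte Carlo and permutation p-values are never 0 and
never below 1/(B+1). Tables written by the pipeline round numerics to
six decimals purely so reruns are byte-comparable.

## Problem sizes used by the validation suites

Calibration uses 1,000 null communities for PERMANOVA/ANOSIM (199
permutations each) and 50 null tables × ~30 genera (B = 999) for the
degree test; recovery uses 100 simulations each for the planted
7-genus block (B = 999) and the cross-compartment driver. These sizes
give binomial standard errors of well under a percentage point on the
calibration rates while keeping the full suite inside a coffee break on
one CPU.
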