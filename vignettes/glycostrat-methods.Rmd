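---
title: "Methods: unsupervised glycometabolic stratification and microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised glycometabolic stratification and microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`glycostrat`, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The stratification model

Participants are described by 16 clinical variables: HbA1c (%), OGTT
glucose and insulin at 0/30/60/120/180 min (mmol/L and µU/mL), BMI
(kg/m²), waist and hip circumference (cm), fasting triglyceride and HDL
(mmol/L). The stratification matrix is built on complete cases only —
missing values are never imputed, participants with a missing
stratification variable are excluded with reason `"missing"`. Each column
is z-scored; participants with any |z| ≥ `outlier_z` (default 5) are
excluded and the retained set re-standardized. By default this is a single
exclusion pass: the re-standardized matrix may again contain marginal
outliers, which mirrors a one-shot exclusion protocol; `iterate = TRUE`
runs the cycle to a fixed point for users who want the invariant "no
retained |z| ≥ 5" to hold exactly.

Clustering is k-medoids (PAM) on Euclidean distances of the z-scores,
implemented in C++ with greedy BUILD initialisation and best-improvement
SWAP to a local optimum; all ties (BUILD, SWAP, assignment) break toward
the lowest row index so runs are bit-reproducible across platforms. The
number of clusters maximises the mean silhouette width over k = 2…20
(ties to the smallest k); a best silhouette below 0.25 is logged as weak
structure. Stability is assessed by resampling participants with
replacement `n_bootstrap` (default 100) times, reclustering, and matching
each original cluster to the bootstrap cluster with maximal Jaccard
similarity on the unique resampled points; mean Jaccard > 0.7 is flagged
(never enforced). Clusters are renumbered by ascending mean glucose AUC so
"cluster 1" is deterministically the best-glycemia cluster.

Out-of-sample assignment standardizes the new cohort with the *discovery*
means and SDs (centers live on the discovery z-scale; the alternative —
re-standardizing within the test cohort — is not equivalent and is not the
default), restricts to the 14 variables available in both cohorts (the 3-h
OGTT points are excluded), applies the same |z| ≥ 5 exclusion, and takes
the nearest per-cluster median center by Euclidean distance, ties to the
lowest cluster index.

## Derived clinical quantities

HOMA-IR = G₀·I₀/22.5 and HOMA-IS = 22.5/(G₀·I₀) (so IR·IS ≡ 1 whenever
both are defined); HOMA-β = 20·I₀/(G₀ − 3.5), undefined at G₀ ≤ 3.5
mmol/L. OGTT areas are trapezoids over 0–180 min and require all five
points; a four-point 0–120 min variant (`*_auc_0_120`) is provided for
cohorts without the 3-h sample and is labelled distinctly. ADA classes use
the thresholds 5.6/7.0 mmol/L (fasting), 7.8/11.1 mmol/L (2-h) and 6.5 %
HbA1c; the criteria themselves are config-overridable since the source
protocol cites rather than prints them. Coefficients of variation use the
sample (n−1) SD. Group comparisons are Kruskal-Wallis (tie-corrected),
pairwise Wilcoxon with BH adjustment rendered as compact letter displays
(groups share a letter iff q > 0.05), and Pearson chi-square without
continuity correction for categorical data.

## Community analysis

Counts are rarefied without replacement to `rarefaction_depth`. The
published protocol normalises to a very large pooled figure; synthetic
work here uses 10,000 (5,000 in the test suite) — behaviour is identical
up to scale, so the depth is a configuration value, not a constant.
Alpha diversity: Shannon (natural log), Simpson (1 − Σp²), observed ASVs,
and Faith's PD — the sum of branch lengths of the minimal subtree spanning
the present tips and the root, excluding the root's own edge (stated so
tests are unambiguous; `picante::pd(include.root = TRUE)` matches this
convention).

The PhILR transform adds a pseudocount of 1 to every cell (a 0.5·minimum
alternative is available), closes rows, and computes for each internal
node of the rooted binary phylogeny with left/right tip sets L, R the
balance √(rs/(r+s))·ln(g(x_L)/g(x_R)) with g the geometric mean, ordered
by preorder traversal. This is an orthonormal ILR basis, so Euclidean
distance on balances equals the Aitchison (CLR) distance — the core
correctness property, asserted to 1e-8 against a direct CLR oracle.
Multifurcations are resolved beforehand, deterministically, into
left-branching zero-length expansions in tip-lexicographic order.

PERMANOVA partitions squared distances (pseudo-F with k−1 and n−k df) and
permutes labels; p = (1 + #{F* ≥ F})/(1 + n_perm). With perfectly
separated equal-sized groups some permutations reproduce the observed
partition and tie F at its maximum, so the attainable minimum p is
(1 + #partition-preserving permutations)/(1 + n_perm), not 1/(1 + n_perm).
Mantel correlates upper triangles under joint row/column permutation;
Procrustes m² = 1 − (Σσ)²/(‖X‖²‖Y‖²) with row-shuffled permutation p. LDA
scores are computed after a PCA reduction to 95 % variance (singularity
guard) with the sign convention that each axis's first loading is
nonnegative.

Cluster-specific ASVs: per pairwise contrast, two-sided Wilcoxon rank-sum
on relative abundances (exact in small samples, normal approximation with
tie and continuity correction otherwise — `stats::wilcox.test`
behaviour), BH adjustment *within* each contrast (the design reports
per-contrast counts, so pooling across contrasts would change the
published semantics), log₂ fold change of mean relative abundances with
ε = 1e-6 (negligible at rarefied depths, prevents division by zero), and
the union over contrasts of ASVs with q < 0.05 and |log₂FC| > 1. The
relative abundances come from the rarefied table (the alternative —
unrarefied proportions — is not used). The operation accepts any number of
clusters ≥ 2; the study design yields the three contrasts 1v2, 1v3, 2v3.

## Networks and co-abundance groups

Per cluster, nodes are ASVs present in strictly more than
`prevalence_min` (default 20 %) of the cluster's samples; every node pair
gets a Pearson r on relative abundances with a two-sided t-test p, BH
across all pairs, and edges where q < 0.05 (no additional |r| threshold —
significance is the only published filter). Density is
edges/(nodes·(nodes−1)/2); degree centrality is degree/(nodes−1); network
pairs are compared by two-sample KS tests on the centrality
distributions.

CAGs are built on the union of the three networks' nodes. Networks are
per-cluster objects but the grouping needs one common correlation, so
correlations for CAGs pool *all* samples (documented resolution). The
signed correlation distance d = 1 − r (not 1 − |r|: positive and negative
co-abundance are distinct ecology) is clustered with ward.D2, and the
tree is cut top-down: each split is kept only when PERMANOVA on the
distance submatrix of the two daughter clades rejects at `cag_alpha`
(default 0.01, 9,999 permutations in the full configuration); otherwise
the clade is one CAG. Clades with fewer than 3 members, and splits with a
singleton daughter (PERMANOVA needs ≥ 2 per group), become CAGs without
testing — a conservative merge.

A known limitation, documented rather than hidden: the split test is
applied to the *selected* (Ward-optimal) split with a naive permutation
null, which is anti-conservative for large homogeneous clades — on a
single exchangeable correlation block the recursion will keep splitting
until clade sizes are small enough that the discrete permutation space
bounds p above `cag_alpha` (at α = 0.01 that is balanced clades of ≤ 4,
i.e. a universe of ~8). The planted-block recovery checks are sized
accordingly (two blocks of 6; a single block of 8); on real-scale data the
procedure behaves like the published one, including this property.

## Associations and classification

Feature–phenotype association fits, per (feature, variable) pair on
complete cases, the OLS model asin(√abundance) ~ variable + age + gender,
continuous predictors z-scored (making results scale-invariant), gender
coded 0/1, and BH across all pairs with significance at q < 0.25 — the
published screening threshold, reported as such. Clinical outcome
variables enter untransformed (the protocol is silent; z-scoring the
predictor side already fixes scale).

Classification is one-vs-rest random forests (√p features per split,
bootstrap per tree) on the cluster-specific ASV panel, scored by
leave-one-out cross-validation: each sample's positive-class probability
comes from a forest trained without it, with a per-fold seed derived from
the master seed so folds are independent but reproducible. The ROC is the
tie-aware staircase; the AUC equals the normalised Mann-Whitney U
statistic (ties counted half) and the equivalence is asserted on every
run. `n_trees` defaults to 500 (the source does not state a forest size);
the test suite and acceptance script use 50–200 trees and a scaled-down
cohort for the LOOCV loops, which changes runtime, not the construction.
For the testing cohort the default is to *retrain* the forests on the
testing samples (the published wording suggests retraining); applying the
discovery forests unchanged is available via `retrain = FALSE`.

## The synthetic cohort generator

`simulate_clinical()` draws, per cluster, OGTT glucose and insulin curves
as multivariate normals with exchangeable within-subject correlation
(default 0.6) and the remaining variables as independent normals, all
clipped below at 0.1 (clipping, not rejection sampling; at the calibrated
means and SDs the clipped mass is negligible except in the low-insulin
tails). The per-cluster means are the published Table-style cluster
profiles and the SDs are SEM·√n with the published per-cluster n
(132/96/30). Weight is derived from BMI and height so anthropometrics are
internally consistent, and HOMA/AUC are *never* drawn — they are computed
downstream, so derived quantities are consistent by construction. True
cluster labels travel as an attribute visible to tests only.

`simulate_asv_table()` draws baseline mean abundances log-normal(0, 1.5)
across ASVs; each of the `n_differential` (default 67) planted ASVs is
assigned round-robin to one cluster where its abundance is multiplied by
2^`planted_log2fc` (default 2), which makes it differential in both
contrasts involving that cluster and spreads the planted set over all
three contrasts. Per-sample, per-ASV lognormal noise (sdlog `dispersion`,
default 0.8) models biological overdispersion; compositions are closed and
counts drawn multinomially at lognormal per-sample depths (mean
`depth_mean` = 10,000, sdlog 0.3). Because each cluster receives a
comparable planted mass, closure shifts largely cancel between clusters,
keeping null ASVs inside the fold-change gate. The phylogeny is a random
rooted bifurcating tree with exponential branch lengths; taxonomy strings
cycle through a fixed lexicon of gut taxa. `simulate_scfa()` produces
butyrate/acetate with cluster means ordered 1 > 2 > 3 (12/9/6 and
45/38/30 µmol/g, SD 3 and 8 — chosen as typical fecal SCFA scales) and
floors at zero.

What the generator does *not* emulate: inter-variable correlations beyond
the OGTT blocks (none are published; plausible positive correlations would
make Euclidean cluster recovery harder, not easier), batch effects,
longitudinal sampling, read-level sequence noise, and realistic taxonomic
tree shape. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the *operations*, not that real cohorts
will yield the published cluster structure.

### A candid note on cluster recovery

With profiles calibrated exactly to the published per-cluster means and
SEM·√n dispersions, the planted three-cluster partition is recoverable in
principle — a likelihood (QDA-style) classifier under the true generative
model separates it almost perfectly, because cluster 2's insulin variance
is several-fold cluster 1's — but Euclidean k-medoids on pooled z-scores
cannot exploit covariance differences: it typically merges clusters 1 and
2 (silhouette-selected k is often 2, and forced k = 3 reaches only
moderate agreement with truth). The mean silhouette of the synthetic
cohorts (~0.25–0.33) sits near the weak value the real cohort produced,
which is evidence the calibration is faithful rather than that the
algorithm is wrong. The acceptance suite reports these recovery numbers
honestly instead of adjusting the generator to make them pass.

## Numerical choices and problem sizes

All randomness flows from one seed through derived per-stage sub-seeds
(kept below 2³¹). PAM, silhouette, BH, letter displays and ROC staircases
are deterministic given inputs. The test suite runs at reduced sizes:
999/199/99 permutations instead of 9,999, rarefaction depth 5,000,
bootstrap B = 20–50, forests of 50–200 trees, and scaled-down cohorts for
LOOCV; these sizes are stated where used and change only runtime and
Monte-Carlo resolution, not any definition.
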