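---
title: "Methods: from pose tracks to behavioral clusters and brain networks"
author: "fearfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pose tracks to behavioral clusters and brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearfish)
```

# What the package models

Adult zebrafish exposed to conspecific alarm substance (CAS) show fear
responses that persist into a memory test the next day, and individual fish
differ strikingly in *how* they express that fear: some freeze, some show
evasive bursts and erratic C-bend swimming, some do both, some neither.
`fearfish` implements the full analysis chain for this kind of experiment:

1. **Pose to behavior.** Head/trunk/tail coordinates at 60 fps are converted
   into windowed kinematic features and classified into a five-state
   ethogram (straight swimming, normal turns, freezing, burst swimming,
   erratic movements) with a random forest.
2. **Behavior to phenotype.** Per-fish summaries (% freezing, % evasion,
   % evasion of active time), stage difference scores, time profiles and
   frame-level Markov transition matrices.
3. **Phenotype to clusters.** A similarity-score k-nearest-neighbor network
   over fish, partitioned with Louvain community detection; k chosen by
   internal cluster-validity indices; new fish assigned by a 33-neighbor
   vote; strain/sex representation tested by permutation.
4. **Clusters to brains.** Regional cfos cell counts, normalized by cohort
   medians, related to behavior with behavioral partial least squares
   (PLS) — permutation tests on singular values, bootstrap ratios on
   region saliences — and compared between groups through FDR-thresholded
   Pearson correlation networks with confidence-interval-based unique-edge
   detection.

No raw videos or imaging volumes enter the package: the pipeline starts at
tracked coordinates and count tables, and a synthetic-data module generates
all four input classes with known ground truth so that every stage is
testable end to end.

# The synthetic-data generator

The generator defines the study conditions under which the package's claims
are verified. It is first-class, tested code, not a fixture.

## Behavior scripts

`markov_script()` iterates a frame-level first-order Markov chain. This
matches the downstream analysis exactly — transition matrices are computed
frame to frame, self-transitions included — so recovering the generating
matrix is a closed loop. Bout structure (multi-second freezing episodes,
brief bursts) is produced by high self-transition probabilities rather than
explicit dwell-time distributions; under a first-order chain, bout lengths
are geometric with mean $1/(1-p_{\text{self}})$, which the tests verify.
The default matrix makes freezing the stickiest state
($p_{\text{self}} = 0.99$).

## Trajectories

`simulate_track()` emits 2-D top-down coordinates in a 20 × 7 cm tank
(continuous cm, origin at a corner, reflective walls). Each behavior has a
kinematic signature (`default_kinematics()`): a speed range (cm/s), an
angular-velocity range (deg/s), a heading-reversal rate (the ≥ 3
C-bends-per-second signature of erratic movement), a positional jitter
bound, and body-bend variability. The defaults are chosen to be separable
the way hand-scored behaviors are — freezing is near-motionless
(< 0.03 cm/s), bursts are far faster (15–30 cm/s) than straight swimming
(2–8 cm/s), turns share straight-swimming speed but carry 250–600 deg/s of
heading change — while leaving the turn/straight and burst/erratic pairs
close enough that their confusions mirror the ones seen with real
classifiers. Positional jitter is applied with per-axis SD of
`jitter_sd/4`, so the typical per-frame jitter displacement stays below
`jitter_sd`; this keeps a freezing fish's total path length under
`jitter_sd × frames`. The camera geometry is assumed top-down; side-view
recordings would need a different arena box but no other change.

## Planted behavioral clusters

`simulate_cohort()` draws, for each group, (% freezing, % evasion) from a
Gaussian around the group centroid, truncated to valid percentages with
evasion capped at the non-freezing share, and *derives* % evasion of active
time as $100 \cdot e / (100 - f)$. The third behavior is a deterministic
function of the other two in real data as well, so the generator enforces
that consistency rather than sampling three free axes. `spread` is the RMS
radius of a group's scatter (per-axis SD = `spread`/√2). We chose the
radius reading over the per-axis reading because only it makes a k-means
oracle at the true k recover the default four groups at ARI > 0.9 whenever
the spread is at most a quarter of the minimum inter-centroid distance — the
regime the recovery guarantees are stated for. The default four centroids
sit at the qualitative positions of the four published fear-memory types:
non-reactive (low/low), evaders (low freezing, high evasion), evading
freezers (high/high), freezers (high freezing, low evasion). Strain, sex
and cohort are assigned independently of group unless the caller fixes
them, so stratum-by-cluster tests are null by construction.

## Region counts

`simulate_region_counts()` uses a log-normal latent + Poisson emission
model: for fish $i$ and region $r$,

$$\log \mu_{ir} = \log(\text{base}) + \sigma\,(s_r\,c_i + z_{ir}), \qquad
  n_{ir} \sim \text{Poisson}(\mu_{ir}\,b_{\text{cohort}(i)}),$$

where $z_i \sim \mathcal N(0, \Sigma)$ plants inter-regional covariance
(any symmetric PSD $\Sigma$), $c_i$ is the z-scored freezing-minus-evasion
contrast of the fish's behavior, $s_r$ is the per-region salience (in units
of latent SDs per SD of contrast, so $s_r = 1$ implies a region–contrast
correlation of $1/\sqrt2$ before count-noise attenuation), $\sigma$
(`noise_sd`, default 0.3) is the latent dispersion, and $b$ is a positive
per-cohort batch factor emulating staining/imaging brightness differences.
Keeping $\Sigma$ on the log scale keeps "PSD covariance" interpretable;
Poisson emission adds realistic mean-dependent noise that mildly attenuates
correlations (measured ≈ 0.65 at $s_r = 1$, base count 500).

# Feature extraction

`pose_primitives()` computes per-frame speed of each body point, trunk
acceleration, heading of the head–trunk axis, absolute heading change,
body-bend angle at the trunk (180° = collinear), bend-angle change, and the
two segment lengths. First-frame derivatives use the forward difference so
every frame is defined; coincident head/trunk points make heading and bend
momentarily undefined and are interpolated with a warning.

`extract_features()` applies windowed statistics over a sliding window of
45 frames (750 ms at 60 fps), centered on each frame and truncated at the
edges so that every frame remains classifiable. The default bank crosses 9
translation-invariant primitives with {mean, SD, max, min} and drops the
two near-constant segment-length minima, for 34 features. The exact feature
inventory used with real data varies between laboratories; the bank is
therefore fully configurable (any primitive/statistic table), and the
windowed-kinematics design is the invariant part. Windows are centered by
default with a trailing option (`centered = FALSE`) for on-line use; the
absolute heading is computed but excluded from the default bank because it
is not rotation-invariant and carries no behavioral information here.
A low-confidence tracking filter (interpolate points with likelihood below
0.9) is available at read time in `read_pose_csv()`.

# The classifier harness

`split_train_test()` stratifies an 80/20 split within every class;
`tune_forest()` scans a (trees × variables-per-tree) grid — one forest per
`mtry` at the largest size, smaller sizes read off the cumulative
out-of-bag (OOB) error curve — and breaks ties toward fewer variables, then
fewer trees. The published defaults (2,000 trees, 10 variables per tree)
are the `fit_forest()` defaults. Hard labels only; no probability
calibration and, by default, no temporal smoothing of predicted sequences
(`predict_sequence()` offers optional modal smoothing behind an argument,
off by default). Frames with non-finite features are labeled missing and
excluded from summaries. On the synthetic separable behaviors
(2,000 frames/class) the tuned forest reaches ≥ 94% per-class held-out
accuracy with the OOB estimate within 3 points of test error — the
desk-scale analog of the published model quality, which passing does *not*
certify for real video, where tracking noise and behavioral ambiguity are
larger.

# Behavioral summaries, transitions and tests

% evasion of active time is evasive frames over non-freezing frames; when a
fish freezes every frame the quantity is undefined and reported as 0 with an
explicit flag. Time profiles are per-bin across-fish means with t-based 95%
confidence intervals (no bootstrap is implied by a plain CI ribbon; at
n = 1 the CI is NA). Transition matrices are frame-level with
self-transitions — the diagonal is where freezing's stability lives — pooled
within stages but never across trial boundaries, and a bout-level variant
(consecutive-run compression) is available behind `bouts = TRUE`. Group
comparisons default to Welch t-tests (no equal-variance assumption) and
one-sample t-tests against zero for difference scores.

# Clustering

Fish are standardized on the three behaviors (reference means/SDs; new data
are standardized with the *reference* parameters, never their own) and
compared by the similarity score $1/(1+D)$, $D$ the Euclidean distance in
the standardized 3-D space. The k-NN graph links each fish to its k most
similar neighbors, symmetrized by union (mutual-k-NN fragments at small k
on the planted-cluster tests) with unweighted edges — the similarity score
defines neighbor ranking only, since it is a monotone transform of distance
and the original analysis does not state that Louvain used weights.
Distance ties break deterministically by row order.

`select_k()` runs Louvain across a k range, computes Calinski–Harabasz,
mean silhouette and Davies–Bouldin for each partition, rank-aggregates them
(CH and silhouette descending, DB ascending), and picks the midpoint of the
widest contiguous plateau of k values whose aggregated score is within 5%
of the optimum's range. The plateau rule is this package's codification of
"best and robust to small changes in k"; the full metric curves are always
returned so the choice can be inspected. When four clusters emerge they are
named by their centroid's quadrant on the (freezing, evasion) z-axes:
non-reactive, evader, evading freezer, freezer.

`assign_clusters()` gives each new fish the majority cluster among its 33
nearest reference fish (half the size of the smallest published cluster),
ties resolved by the single nearest neighbor; a new fish whose id matches a
reference fish is compared leave-one-out. `representation_test()` permutes
cluster labels across fish (10,000 times by default) and computes, per
(stratum × cluster) cell, a two-sided p-value on the deviation of the cell
count from its expectation, with Benjamini–Hochberg correction across
cells. Because the cell count is discrete, the plain "at least as extreme"
p-value is super-uniform; the default therefore breaks ties with a seeded
uniform draw (a randomized p-value — the rank of the observed deviation
among the B + 1 exchangeable values with uniform tie-splitting), which is
exactly uniform under the null. `tie_smoothing = FALSE` restores the
conservative step-function p-value.

# Behavioral PLS

For one group of fish, `behavioral_pls()` forms the 4 × regions matrix
$R$ of Pearson correlations between the behavior block (% normal swimming,
% freezing, % evasion, % evasion while active) and the normalized counts,
and decomposes $R = U S V^\top$. The mean-centering that behavioral PLS
requires is implicit in Pearson correlation (columnwise standardization),
which is why the correlation-matrix variant is the right reading for a
single-group design. Latent variables are ordered by singular value and
signed so that each LV's largest-magnitude behavioral salience is positive.

Inference: `pls_permutation()` permutes whole rows of the behavior block
(keeping the behavioral covariance intact) and reports
$p_k = (1 + \#\{s_k^{perm} \ge s_k\}) / (1 + B)$ per LV.
`pls_bootstrap()` resamples fish with replacement, aligns each replicate's
LVs to the original by maximal absolute inner product of brain saliences
(then sign), preventing axis-swap inflation of standard errors, and divides
each original salience by its bootstrap SE. The resulting bootstrap ratios
behave like z-scores; 2.5 is the conventional reporting threshold, applied
to the magnitude since saliences of both signs are meaningful. Replicates
that produce a constant column are redrawn and counted.

Counts are first normalized by `normalize_counts()`: each fish's counts are
scaled by (global median per-fish total) / (its cohort's median per-fish
total), which equalizes cohort medians exactly and is idempotent.

# Correlation networks

Per experimental group, `correlation_network()` computes the region ×
region Pearson matrix across fish (≥ 4 fish; constant regions dropped with
a warning). `threshold_fdr()` converts each unique pair to a two-sided
p-value via $t = r\sqrt{(n_{\rm eff}-2)/(1-r^2)}$ and applies
Benjamini–Hochberg at α = 0.001. Two deliberate choices: p-values use a
*shared, conservative* effective n (the smallest group, 16 in the published
design) so edge counts do not simply track group size, while the 95%
Fisher-z confidence intervals
($\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$) use each group's own
n, because the CI-overlap rule compares groups of different sizes and an
interval should reflect the precision actually available for that group.
BH was chosen as the FDR procedure (the original analysis does not name
one; BH is the field default). $|r| = 1$ maps to the largest representable
Fisher z with a warning rather than overflowing.

An edge of a target network is **unique** when it is suprathreshold *and*
its CI overlaps no other network's CI for that pair — an asymmetric,
per-target classification that returns the empty set when the target is
compared with itself. `relative_degree()` computes
$(d_a - d_b)/(d_a + d_b)$ per region (undefined when isolated in both),
with the published reporting filter (|score| > 0.5, degree > 12) available.
`matrix_similarity()` correlates vectorized lower triangles with a
fish-resampling bootstrap CI, and `modularity_partition()` runs Louvain on
the thresholded adjacency. Exports (edge-list CSV, GraphML) carry the
unique/shared flag for Cytoscape-style dashed/solid rendering.

# Problem sizes and what the tests show

The verification suite runs the whole chain at desk scale: 2,000 frames per
behavior for the classifier analog; 100,000 frames for transition-matrix
recovery (±0.01 elementwise); 320 fish in four planted clusters (spread a
quarter of the minimum centroid separation) for clustering, with 160
held-out fish for 33-NN assignment; 500 simulated datasets × 1,000
permutations for representation-test calibration; 200 null datasets and 50
planted-effect runs (n = 80, 30 regions) for PLS; 200 null simulations
(n = 16, 100 regions) and 40 paired split-population simulations for the
network thresholds. These sizes are the package's chosen verification
conditions; the same generators run at any scale.

Under these conditions one documented gap remains: with a planted salience
of exactly 1 latent SD per SD of behavioral contrast (region–contrast
correlation ≈ 0.65 after count-noise attenuation), the LV1 permutation test
at n = 80 with a 30-region background detects the effect in roughly 70–80%
of runs, not ≥ 90% — the planted LV1 singular value (median ≈ 1.19) sits
close to the permutation null for LV1 (median ≈ 0.96). The bootstrap-ratio
detector reaches ≥ 90% at the same effect size, and the null calibration is
exact; the corresponding power assertion in the acceptance suite is left
failing rather than met by strengthening the planted effect.

What passing does and does not show: the generator's trajectories have no
tracking dropouts, occlusions or identity swaps; its bout structure is
exactly first-order Markov; its count covariance is homogeneous-Gaussian on
the log scale with no anatomical structure. Results on real data therefore
inherit the pipeline's correctness, not its synthetic performance numbers.

# Numerical and degenerate-input conventions

Angles are degrees, speeds cm/s, coordinates cm. Seeds are explicit
integer arguments everywhere; no function mutates the caller's RNG state
(`withr::with_seed` semantics), and every stochastic default (10,000
permutations and bootstraps, FDR 0.001, 45-frame window, 33-neighbor vote,
80/20 split) equals the published parameter. Degenerate inputs are flagged
rather than silently patched: all-freezing fish (undefined active-time
proportion), single-fish time profiles (no CI), single-cluster partitions
(metrics NA), zero-variance groups in t-tests (p NA), isolated regions in
both networks (relative degree NA), |r| = 1 edges (degenerate CI). The
2-D UMAP-style embedding used for display in the original analysis is a
visualization device, not part of the method, and is intentionally absent.
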