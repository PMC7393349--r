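---
title: "Network dysregulation analysis with dysnet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network dysregulation analysis with dysnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysnet)
```

# Overview

`dysnet` compares immune gene networks between two phenotype groups —
here called *control* and *asthma* — using paired unstimulated (NS) and
antigen-stimulated (TT) expression samples from the same subjects. The
pipeline asks three nested questions:

1. **Which gene modules respond to stimulation, and how are they wired
   together?** Signed co-expression modules are detected among
   stimulation-perturbed genes, summarized by module eigengenes, and
   module-module correlation networks are compared between groups.
2. **Which regulators drive the wiring differences?** A TF-by-gene
   regulatory network is inferred per group and condition by message
   passing over a motif-derived prior, a TF-TF interaction prior, and
   gene co-expression. The *regulatory shift* of a TF on a module is the
   median difference (case minus control) of its edge weights over its
   targets in that module; TFs are clustered by their shift patterns.
3. **Do co-shifted TFs bind near each other?** Within differentially
   methylated regions (DMRs), each bound TF gets a smoothed binding
   profile; a silhouette statistic on the profile distances, evaluated
   under the TF shift-cluster labels, is tested against a label
   permutation null. Proximal binding of co-shifted TFs is the signature
   expected if shared accessibility changes drive the dysregulation.

A synthetic-data generator produces every input with known ground truth,
so each stage is benchmarked against planted structure.

# Stage models and parameters

## Normalization and the paired stimulation test

Counts are normalized by median-of-ratios size factors (geometric-mean
reference over genes with no zero count; size factors rescaled to
geometric mean 1) followed by `log2(x / sf + 1)`. This is a deliberately
simple, pluggable stand-in for a variance-stabilizing transform: only the
set of stimulation-perturbed genes feeds the downstream analysis, not the
transform itself. One consequence worth knowing: scaling one of *n*
samples by *c* moves the geometric-mean reference by *c^(1/n)*, so the
other columns drift by that factor rather than staying exactly fixed.

The stimulation test is a per-gene paired t-test on the per-subject
TT − NS differences, run separately per group (each subject contributes
both conditions, so pairing is the natural design), with
Benjamini–Hochberg correction within each group's test family. A gene is
*perturbed* if q < 0.05 in either group; the union feeds module
detection.

Median-of-ratios assumes most genes are unchanged and approximately
exchangeable. With the default four-block simulation the reference rests
on four correlated factor draws, so the DE-stage benchmarks use a
finer-grained configuration (20–50 small modules; the null-calibration
config additionally sets `module_factor_sd = 0.05` and no stimulation
shift) where gene-level exchangeability holds. This is a property of the
benchmark geometry, not a tuning of the test.

## Module detection

- **Adjacency** `a_ij = ((1 + r_ij)/2)^beta` with `beta = 12` (signed:
  anti-correlated genes get adjacency near 0).
- **Topological overlap**
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  `l_ij = Σ_{u≠i,j} a_iu a_uj`: genes sharing strong neighbourhoods get
  high overlap even when their direct edge is moderate.
- **Cut**: average-linkage clustering of `1 − TOM`. Candidate cut heights
  are the midpoints of the widest gaps between consecutive merge heights
  (distinct partitions live between merges); the chosen height maximizes
  the number of branches with at least `min_module_size = 30` genes that
  are also *cohesive* — mean within-branch overlap above twice the mean
  overlap between branch members and all other genes (absolute floor 0.1
  when one branch spans every gene). Without the cohesion rule any
  dendrogram has a root "branch" containing everything, and structureless
  data would yield one spurious module; with it, uniform-overlap data
  comes back fully unassigned. Small or incohesive branches are labelled
  `"unassigned"`.
- **Merge**: modules whose eigengenes correlate above
  `1 − merge_height = 0.85` are merged iteratively until stable.
- **Eigengene**: first right singular vector of the gene-standardized
  module submatrix (computed from the samples-by-samples crossproduct for
  speed), sign-fixed to correlate positively with the module's mean
  profile, so "higher eigengene" reads as "higher module expression".

Stimulation and group-by-stimulation effects on each eigengene use the
standard two-way mixed ANOVA, `aov(value ~ group * condition +
Error(subject))`, taking the within-subject stratum's F tests. With
unbalanced groups the stimulation main-effect F is not exactly invariant
to relabeling groups (the stratum residual depends on the interaction
term); the tests therefore check power against planted shifts and
uniformity of the interaction p-value under the null rather than any
permutation identity.

## What module networks can recover

Module connectivity is Pearson correlation of eigengenes with BH
correction within each group, restricted to one condition: pooling NS and
TT lets the shared stimulation response dominate every correlation.

A structural caveat established during development and encoded in the
tests: global normalization removes the component of expression shared
across modules, so the recoverable inter-module correlation matrix is the
mean-centred projection `cov2cor(P Σ P′)` with `P = I − 11′/M`, not the
planted `Σ` itself. The tests assert (i) significant edges carry the
projected planted signs and (ii) for pairs whose projected sign differs
between groups, the observed between-group correlation difference has the
planted direction. Edge-level detection of sign discordance at n = 19
subjects is noise-dominated (SE(r) ≈ 0.23) and is not claimed.

## Motif scanning and the regulatory prior

PFM counts become log-odds PWMs with a total pseudocount of 0.8
distributed by the (uniform) background. A window is a hit when its
min-max-normalized score `(s − s_min)/(s_max − s_min)` reaches 0.8 — the
"80% of maximum accuracy" convention; `score / s_max` is available behind
the `mode` flag since the convention is not uniquely determined by that
phrase. Both strands are scanned; minus-strand hits are found with the
reverse-complemented PWM so all coordinates stay on the forward strand,
0-based. Overlapping hits all count, because the prior is a raw hit
count: `prior[t, g]` = number of hits of motif *t* in the promoter of
gene *g* (window −1000/+200 around the TSS, strand-aware, truncated at
contig ends with a warning).

## Message-passing network inference

With z-score-normalized motif prior `W0` (TF×gene), interaction prior
`P0` (TF×TF) and co-expression `C0` (gene×gene), each iteration computes
the continuous Tanimoto similarity
`T(x, y) = ⟨x,y⟩ / sqrt(‖x‖² + ‖y‖² − |⟨x,y⟩|)` to form a
responsibility `R = T(P, W)` and availability `A = T(W, C)`, then moves
`W ← (1−α) W + α (R + A)/2`. `P` and `C` are in turn moved toward
`T(W, Wᵀ)` and `T(Wᵀ, W)` with the same step and a diagonal damping
(diagonal replaced by the off-diagonal column SD times the dimension
times `exp(2αt)`) that keeps self-similarity from dominating.
Convergence is declared when the mean absolute change of `W` drops below
`tol`. Defaults `α = 0.1`, `tol = 1e-3`, `max_iter = 200` are the
algorithm's conventional settings, surfaced in the configuration rather
than asserted as anyone's choices; a non-converged fit is returned with
an explicit flag. Output weights are on the z-score scale throughout.

Four networks are fitted — (control, asthma) × (NS, TT) — sharing `W0`
and `P0`, with `C0` computed from the samples of that group and
condition only.

## Regulatory shift and TF communities

Edge shift is `z_case − z_control` elementwise on the TT-condition
networks (the stimulated networks are where the groups are compared). A
TF's *targets* are the genes with a nonzero motif-prior count — the
network itself is dense, and the discrete prior is what "its targets"
can mean operationally. The per-TF, per-module summary is the median
shift over targets in the module; a TF is eligible only if it has at
least one target in every module, and ineligible TFs are reported
separately, not imputed.

Eligible TFs are clustered on their shift-pattern rows by k-means
(Euclidean), k scanned over 2..10 with 20 restarts per k under a fixed
seed; the mean silhouette (own implementation, singleton clusters scored
0) selects k, smallest k on ties. Ward hierarchical clustering is
available behind `method = "hclust"` since descriptive text and figure
legends in this analysis tradition disagree on the algorithm; both must
and do select k = 2 on the planted fixture. A separate per-TF Wilcoxon
signed-rank test of edge shifts against zero (BH-corrected) summarizes
how many TFs show any altered regulation; it is a declared stand-in for
an unspecified published test and is reported apart from the shift
pipeline.

## DMR binding proximity

For each DMR and each TF with at least one motif hit (hit location =
motif start; midpoint behind a flag), a Gaussian kernel (SD 5 bp)
truncated to a 21-bp window is placed at every hit and the summed vector
is renormalized to total mass 1 — renormalization, not per-kernel
truncation correction, is what guarantees edge-clipped hits still give a
proper density. Distances are L1, bounded by 2 for disjoint support.

TFs closer than 0.1 are then thinned: repeatedly pick a random pair
below threshold, drop a random member. This guards against TFs that
share a motif (identical hit sets) dominating the silhouette. The
retained TFs' mean silhouette under their shift-cluster labels is
compared against `n_perm = 10000` label permutations;
`p = #(SS_perm > SS_obs) / n_perm` with strict inequality, so p = 0 is
possible and is reported as stored (displayed as `< 1/n_perm` in
human-readable output). A DMR with fewer than two bound TFs, or with a
single cluster represented after elimination, is flagged untestable
rather than erroring the panel. The permutation evaluation is vectorized
(cluster sizes are permutation-invariant, so per-cluster distance sums
reduce to one matrix product per cluster) and agrees exactly with the
per-permutation silhouette; permutations are drawn fresh per DMR.

# The synthetic-data generator

The generator defines the study conditions the tests exercise:

- **Design**: 30 control and 19 case subjects, each with one NS and one
  TT sample; genes in `n_modules = 4` equally sized modules (5000 genes
  by default).
- **Counts**: per-gene log-normal baselines (floored at mean 1) times a
  module latent factor with `module_factor_sd = 1` (natural-log scale),
  through a negative binomial with dispersion 0.1. Half of the factor
  variance is a subject effect shared between a subject's two samples.
- **Group difference**: inter-module factor correlations have magnitude
  0.3 and random signs; a fraction `flip_fraction = 0.3` of the pairwise
  signs is flipped in the case group. Marginal means carry no group
  signal, and the TT shift (±0.8 on the log scale, alternating by
  module) is identical in both groups — the planted difference lives
  only in the correlation structure and the binding geometry, mirroring
  a setting where single-gene differential expression is null.
- **Motifs**: two TF communities of 8 TFs each. Every TF's consensus is
  its community's 8-bp core with one private substitution at a
  community-unique position; PFM columns have uniform strength (17 vs 1
  counts), making the 0.8 relative-score threshold equal to "at most one
  mismatch". Promoters of a TF's ~12 intended targets (drawn from its
  community's modules) carry two exact consensus plants at
  non-overlapping positions.
- **DMRs**: each community plants two pure-core *anchor* occurrences
  near its zone centre — every community member matches them at one
  mismatch, giving shared binding mass — plus one private
  exact-consensus slot per TF (jitter SD 25 bp), which keeps every pair
  of profiles at L1 ≥ ~0.1 so communities survive the elimination step.
  Zone centres are `cluster_separation = 50` bp apart; at separation 0
  the zones coincide.
- **Seeding**: one root seed; per-stage seeds are drawn from it once, so
  the three generators are individually and jointly reproducible.

What the generator does *not* emulate: read-level noise, GC and length
biases, cell-type mixtures, batch effects, motif families with unrelated
consensi binding the same region, and methylation levels themselves.
Passing tests show the algorithms recover the planted structure under
the stated noise model — not that real cohorts behave this way.

# Numerical and procedural choices

- Problem sizes in the test-suite benchmarks: module recovery runs ten
  seeds at the full 5000-gene default; the end-to-end pipeline
  determinism checks run at 200–250 genes; proximity-test calibration
  uses 500 null DMRs at 1000 permutations and the power analysis 100
  DMRs at 10000 permutations; these sizes give the binomial bands quoted
  in the tests while keeping the suite comfortably re-runnable.
- Ties in the height scan go to the largest height (coarsest partition
  that achieves the maximum count of cohesive branches); k-selection
  ties go to the smallest k; centrality ties break by summed edge
  weight, then gene id.
- The elimination step's randomness is seeded per DMR and logged
  (pair considered, member dropped), so a published-style analysis is
  reproducible end to end; `run_dmr_panel` derives per-DMR seeds from
  the panel seed.
- Degenerate inputs error early and by name: all-zero samples, zero-
  variance genes (adjacency) or eigengenes (ANOVA), unpaired subjects,
  mismatched TF/gene universes, constant matrices in z-scoring.
- Degree centrality is the module-centrality measure; it is the simplest
  defensible choice and deliberately replaceable (the ranking interface
  does not depend on it).

# Known limitations

- The simplified static-height cut with cohesion validation approximates
  dynamic branch cutting; very unequal module sizes or nested module
  structure may be split or merged differently than a full dynamic-cut
  implementation would.
- The message-passing fit is O(genes² × TFs) per iteration in the
  co-expression update; at the 5000-gene scale a four-network fit is a
  batch job, which is why the end-to-end benchmarks run at a few hundred
  genes.
- Eligibility ("a target in every module") can exclude many TFs when
  modules are small or priors sparse; the ineligible list should be
  inspected rather than ignored.
- Permutation p-values at n_perm = 10000 saturate at 1e-4; claims below
  that resolution are not made.
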