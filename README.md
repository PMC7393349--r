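# dysnet

Network dysregulation analysis for paired-stimulation transcriptomics.

## The problem

Some disease predispositions leave no trace in single-gene differential
expression yet reshape how genes *interact*. `dysnet` targets exactly
that setting: two groups of subjects (here `control` and `asthma`),
each providing an unstimulated (NS) and an antigen-stimulated (TT)
blood-cell expression sample. Instead of asking which genes change, the
pipeline asks which **co-expression modules** respond to stimulation,
how module-module **connectivity** differs between groups, which
**transcription-factor (TF) regulatory edges** shift, whether TFs fall
into **communities with shared shift patterns**, and whether those
communities **bind near each other** inside differentially methylated
regions (DMRs) — the signature expected when accessibility changes
drive the rewiring.

It is written for computational biologists who want each stage as a
plain R function over plain-text formats (TSV / FASTA / BED / JASPAR /
JSON), with a synthetic ground-truth generator to validate every step.

## The statistics at the core

- **Signed modules**: adjacency `a_ij = ((1 + cor(x_i, x_j))/2)^12`,
  topological overlap
  `TOM_ij = (l_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij)`, average-linkage
  clustering with cohesive-branch validation, eigengene merge at
  correlation 0.85, minimum module size 30.
- **Regulatory networks**: message passing integrating a motif-hit prior
  (PWM relative score ≥ 0.8 in promoter windows −1000/+200 of the TSS),
  a TF-TF interaction prior, and per-(group × condition) co-expression,
  via the continuous Tanimoto similarity
  `T(x,y) = ⟨x,y⟩ / sqrt(‖x‖² + ‖y‖² − |⟨x,y⟩|)`; edge weights on a
  z-score scale; four networks: (control, asthma) × (NS, TT).
- **Regulatory shift**: per TF t and module m,
  `shift(t, m) = median_{g ∈ targets(t) ∩ m} [z_asthma(t,g) − z_control(t,g)]`
  on the TT networks; TFs with a target in every module are clustered by
  k-means with the mean silhouette selecting k ∈ 2..10.
- **Binding proximity**: per DMR, each bound TF's hit positions are
  smoothed with a 21-bp, SD-5 Gaussian kernel into a sum-to-1 profile;
  pairwise L1 distances (near-duplicates below 0.1 eliminated); the mean
  silhouette under TF-cluster labels is compared with 10,000 label
  permutations, `p = #(SS_perm > SS_obs)/10000`.

## Worked example

```r
library(dysnet)

cfg <- sim_config(n_genes = 400, n_tfs = 16, n_modules = 4, seed = 3)
sim  <- simulate_counts(cfg)
expr <- normalize_counts(sim$counts)

de_c <- paired_de(expr, "control")
de_a <- paired_de(expr, "asthma")
perturbed <- select_perturbed_union(de_c, de_a, 0.05)
length(perturbed)
#> [1] 398

v   <- expr$values[perturbed, ]
tom <- topological_overlap(signed_adjacency(v, beta = 12))
assignment <- cut_modules(tom, v, min_module_size = 30)
table(assignment)
#> assignment
#>         M1         M2         M3         M4 unassigned
#>        100        100         97         96          5

mclust::adjustedRandIndex(assignment,
                          sim$truth$gene_module_labels[perturbed])
#> [1] 0.9832749

E <- eigengene_matrix(v, assignment)
eigengene_interaction_test(E["M1", ], sim$counts$samples)$stim_p
#> [1] 2.800981e-11
```

398 of 400 genes respond to stimulation (every module carries a planted
TT shift), the four planted modules are recovered almost exactly
(adjusted Rand index 0.98), and module M1's eigengene shows the planted
stimulation effect at p ≈ 3e-11 with the mixed two-way ANOVA.

Downstream, on the same simulation:

```r
seqs  <- simulate_motifs_and_sequences(cfg, sim$truth)
ppi   <- simulate_ppi(cfg, seqs$truth)
prior <- build_prior(seqs$pfms, seqs$promoters, threshold = 0.8)
nets  <- panda_four_networks(prior, ppi, expr)
S  <- module_median_shift(edge_shift(nets$asthma_TT, nets$control_TT),
                          sim$truth$gene_module_labels, prior)
cl <- cluster_tfs(S, seed = 1)
cl$k
#> [1] 2

panel <- run_dmr_panel(seqs$dmrs, seqs$pfms, cl$labels,
                       n_perm = 10000, seed = 5)
head(panel[, c("dmr", "n_retained", "observed_ss", "p", "stars")], 3)
```

The silhouette-selected number of TF communities is 2 (the planted
value); with the default 50-bp separation between community binding
zones, DMR silhouette scores sit near 0.6 against permutation nulls
centred near 0, and the panel reports `p = 0` (`< 1/n_perm`) rows with
`***` stars.

The whole pipeline, file-to-file with a manifest of md5 hashes, is
`run_all(pipeline_config(outdir, sim = cfg, seed = 1))`; a thin CLI
wrapper lives at `inst/scripts/dysnet-pipeline.R`.

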