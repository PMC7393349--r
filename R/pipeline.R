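#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline with the
#' analysis defaults: q threshold 0.05, soft power 12, minimum module size
#' 30, merge height 0.15, motif threshold 0.8, promoter window -1000/+200,
#' message-passing alpha 0.1 / tol 1e-3 / 200 iterations, k range 2..10,
#' smoothing kernel 21 bp wide with SD 5, duplicate-elimination threshold
#' 0.1, and 10000 permutations.
#'
#' @param outdir output directory for all stage artifacts.
#' @param sim a [sim_config()] to generate inputs, or NULL to read
#'   previously written inputs from `outdir`.
#' @param q_threshold,beta,min_module_size,merge_height,motif_threshold
#'   stage parameters (see the stage functions).
#' @param promoter_upstream,promoter_downstream promoter window in bp.
#' @param panda_alpha,panda_tol,panda_max_iter message-passing parameters.
#' @param k_range candidate TF cluster numbers.
#' @param gaussian_window,gaussian_sd binding-profile kernel.
#' @param dup_threshold,n_perm DMR-test parameters.
#' @param seed root seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, sim = sim_config(),
                            q_threshold = 0.05, beta = 12,
                            min_module_size = 30, merge_height = 0.15,
                            motif_threshold = 0.8,
                            promoter_upstream = 1000,
                            promoter_downstream = 200,
                            panda_alpha = 0.1, panda_tol = 1e-3,
                            panda_max_iter = 200, k_range = 2:10,
                            gaussian_window = 21, gaussian_sd = 5,
                            dup_threshold = 0.1, n_perm = 10000,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_files <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  list(
    simulate = c(o("counts.tsv"), o("samples.tsv"), o("motifs.jaspar"),
                 o("promoters.fa"), o("dmrs.fa"), o("dmrs.bed"),
                 o("ppi.tsv"), o("truth.json")),
    expression = c(o("normalized.tsv"), o("de_control.tsv"),
                   o("de_asthma.tsv"), o("perturbed_genes.txt")),
    modules = c(o("modules.tsv"), o("eigengenes.tsv"),
                o("module_anova.tsv"), o("module_network_control.tsv"),
                o("module_network_asthma.tsv")),
    prior = c(o("prior.tsv")),
    panda = c(o("network_control_NS.tsv"), o("network_control_TT.tsv"),
              o("network_asthma_NS.tsv"), o("network_asthma_TT.tsv"),
              o("panda_meta.json")),
    shift = c(o("shift_matrix.tsv"), o("tf_clusters.tsv"),
              o("silhouette_by_k.tsv"), o("shift_long.tsv"),
              o("tf_altered.tsv")),
    dmr = c(o("dmr_proximity.tsv")),
    manifest = c(o("manifest.json"))
  )
}

#' Run the full pipeline
#'
#' Executes, in order: simulate (optional) -> expression (normalize +
#' paired DE per group + perturbed-gene union) -> modules (signed
#' adjacency, TOM, module cut, eigengenes, stimulation/interaction ANOVA,
#' per-group module networks) -> motif prior -> four message-passing
#' regulatory networks -> TF regulatory shift and clustering -> DMR
#' binding-proximity panel -> manifest. Every artifact is a plain-text
#' file under `cfg$outdir`; the manifest records parameters and md5 hashes
#' of all outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param resume skip stages whose output files already exist.
#' @param quiet suppress stage messages.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(cfg, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- stage_files(cfg)
  say <- function(...) if (!quiet) message("[dysnet] ", ...)
  done <- function(stage) all(file.exists(files[[stage]]))
  stages_run <- character(0)
  o <- function(...) file.path(cfg$outdir, ...)

  ## stage 1: simulate ------------------------------------------------------
  if (!is.null(cfg$sim) && (!resume || !done("simulate"))) {
    say("stage simulate")
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed  # the pipeline seed governs everything
    sim_cfg <- do.call(sim_config, sim_cfg[setdiff(names(sim_cfg), NULL)])
    cnt <- simulate_counts(sim_cfg)
    seqs <- simulate_motifs_and_sequences(sim_cfg, cnt$truth)
    ppi <- simulate_ppi(sim_cfg, seqs$truth)
    write_counts_tsv(cnt$counts, o("counts.tsv"))
    write_samples_tsv(cnt$counts$samples, o("samples.tsv"))
    write_jaspar(seqs$pfms, o("motifs.jaspar"))
    write_fasta(seqs$promoters, o("promoters.fa"))
    write_fasta(seqs$dmrs, o("dmrs.fa"))
    write_bed(seqs$dmr_bed, o("dmrs.bed"))
    write_edge_list(matrix_to_edges(ppi), o("ppi.tsv"))
    truth <- seqs$truth
    write_manifest(list(
      gene_module_labels = as.list(truth$gene_module_labels),
      tf_cluster_labels = as.list(truth$tf_cluster_labels),
      tf_targets = truth$tf_targets,
      motif_consensus = as.list(truth$motif_consensus),
      dmr_zone_centres = as.list(truth$dmr_zone_centres)
    ), o("truth.json"))
    stages_run <- c(stages_run, "simulate")
  } else if (!is.null(cfg$sim)) say("stage simulate: cached")

  ## stage 2: expression ----------------------------------------------------
  if (!resume || !done("expression")) {
    say("stage expression")
    cm <- read_counts_tsv(o("counts.tsv"), o("samples.tsv"))
    expr <- normalize_counts(cm)
    de_c <- paired_de(expr, "control")
    de_a <- paired_de(expr, "asthma")
    perturbed <- select_perturbed_union(de_c, de_a, cfg$q_threshold)
    write_matrix_tsv(round(expr$values, 6), o("normalized.tsv"), "gene")
    utils::write.table(de_c, o("de_control.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(de_a, o("de_asthma.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(perturbed, o("perturbed_genes.txt"))
    stages_run <- c(stages_run, "expression")
  } else say("stage expression: cached")

  ## stage 3: modules -------------------------------------------------------
  if (!resume || !done("modules")) {
    say("stage modules")
    values <- read_matrix_tsv(o("normalized.tsv"))
    samples <- utils::read.delim(o("samples.tsv"),
                                 stringsAsFactors = FALSE)
    perturbed <- readLines(o("perturbed_genes.txt"))
    vp <- values[perturbed, , drop = FALSE]
    adj <- signed_adjacency(vp, beta = cfg$beta)
    tom <- topological_overlap(adj)
    assignment <- cut_modules(tom, vp, cfg$min_module_size,
                              cfg$merge_height)
    utils::write.table(
      data.frame(gene = names(assignment), module = assignment),
      o("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    E <- eigengene_matrix(vp, assignment)
    write_matrix_tsv(round(E, 8), o("eigengenes.tsv"), "module")
    anova_rows <- lapply(rownames(E), function(m) {
      tst <- eigengene_interaction_test(E[m, ], samples)
      data.frame(module = m, stim_F = tst$stim_F, stim_p = tst$stim_p,
                 interaction_F = tst$interaction_F,
                 interaction_p = tst$interaction_p,
                 stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, anova_rows), o("module_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in c("control", "asthma")) {
      net <- module_network(E, samples, g, cfg$q_threshold,
                            condition = "TT")
      utils::write.table(net, o(paste0("module_network_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stages_run <- c(stages_run, "modules")
  } else say("stage modules: cached")

  ## stage 4: motif prior ---------------------------------------------------
  if (!resume || !done("prior")) {
    say("stage prior")
    pfms <- read_jaspar(o("motifs.jaspar"))
    promoters <- read_fasta(o("promoters.fa"))
    perturbed <- readLines(o("perturbed_genes.txt"))
    prior <- build_prior(pfms, promoters[intersect(names(promoters),
                                                   perturbed)],
                         threshold = cfg$motif_threshold)
    write_matrix_tsv(prior, o("prior.tsv"), "tf")
    stages_run <- c(stages_run, "prior")
  } else say("stage prior: cached")

  ## stage 5: regulatory networks -------------------------------------------
  if (!resume || !done("panda")) {
    say("stage panda (4 networks)")
    prior <- read_matrix_tsv(o("prior.tsv"))
    ppi <- edges_to_matrix(read_edge_list(o("ppi.tsv")),
                           nodes = rownames(prior))
    values <- read_matrix_tsv(o("normalized.tsv"))
    samples <- utils::read.delim(o("samples.tsv"),
                                 stringsAsFactors = FALSE)
    expr <- structure(list(values = values, samples = samples),
                      class = "expression_matrix")
    nets <- panda_four_networks(prior, ppi, expr, alpha = cfg$panda_alpha,
                                tol = cfg$panda_tol,
                                max_iter = cfg$panda_max_iter)
    meta <- list(alpha = cfg$panda_alpha, tol = cfg$panda_tol,
                 max_iter = cfg$panda_max_iter)
    for (nm in names(nets)) {
      write_matrix_tsv(round(nets[[nm]]$W, 8),
                       o(paste0("network_", nm, ".tsv")), "tf")
      meta[[nm]] <- list(iterations = nets[[nm]]$iterations,
                         converged = nets[[nm]]$converged,
                         convergence = nets[[nm]]$convergence)
    }
    write_manifest(meta, o("panda_meta.json"))
    stages_run <- c(stages_run, "panda")
  } else say("stage panda: cached")

  ## stage 6: regulatory shift ----------------------------------------------
  if (!resume || !done("shift")) {
    say("stage shift")
    prior <- read_matrix_tsv(o("prior.tsv"))
    net_case <- read_matrix_tsv(o("network_asthma_TT.tsv"))
    net_ctrl <- read_matrix_tsv(o("network_control_TT.tsv"))
    mods <- utils::read.delim(o("modules.tsv"), stringsAsFactors = FALSE)
    assignment <- stats::setNames(mods$module, mods$gene)
    shifts <- edge_shift(net_case, net_ctrl)
    S <- module_median_shift(shifts, assignment, prior)
    write_matrix_tsv(round(S, 8), o("shift_matrix.tsv"), "tf")
    cl <- cluster_tfs(S, k_range = cfg$k_range, seed = cfg$seed)
    utils::write.table(
      data.frame(tf = names(cl$labels), cluster = cl$labels),
      o("tf_clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cl$silhouette_by_k, o("silhouette_by_k.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    long <- data.frame(tf = rep(rownames(S), ncol(S)),
                       module = rep(colnames(S), each = nrow(S)),
                       median_shift = as.vector(S),
                       stringsAsFactors = FALSE)
    utils::write.table(long, o("shift_long.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tf_altered_regulation(shifts), o("tf_altered.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_run <- c(stages_run, "shift")
  } else say("stage shift: cached")

  ## stage 7: DMR proximity -------------------------------------------------
  if (!resume || !done("dmr")) {
    say("stage dmr")
    pfms <- read_jaspar(o("motifs.jaspar"))
    dmrs <- read_fasta(o("dmrs.fa"))
    tfc <- utils::read.delim(o("tf_clusters.tsv"),
                             stringsAsFactors = FALSE)
    labels <- stats::setNames(tfc$cluster, tfc$tf)
    panel <- run_dmr_panel(dmrs, pfms, labels,
                           threshold = cfg$motif_threshold,
                           window = cfg$gaussian_window,
                           sd = cfg$gaussian_sd,
                           dup_threshold = cfg$dup_threshold,
                           n_perm = cfg$n_perm, seed = cfg$seed)
    utils::write.table(panel, o("dmr_proximity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stages_run <- c(stages_run, "dmr")
  } else say("stage dmr: cached")

  ## stage 8: manifest ------------------------------------------------------
  say("stage manifest")
  outputs <- setdiff(unlist(files), files$manifest)
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    pipeline = "dysnet",
    stages = names(files),
    stages_run = stages_run,
    parameters = cfg[setdiff(names(cfg), c("outdir", "sim"))],
    sim = if (!is.null(cfg$sim)) unclass(cfg$sim),
    seed = cfg$seed,
    files = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                    basename(outputs)))
  )
  write_manifest(manifest, o("manifest.json"))
  invisible(manifest)
}
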