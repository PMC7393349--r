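#' Simulation configuration
#'
#' Builds and validates the configuration driving all three synthetic-data
#' generators ([simulate_counts()], [simulate_motifs_and_sequences()],
#' [simulate_ppi()]). Defaults emulate the study design the pipeline targets:
#' paired unstimulated (NS) / stimulated (TT) PBMC samples from 30 control
#' and 19 case subjects, latent-factor-driven gene modules whose inter-module
#' correlations differ in sign between groups, and two TF communities that
#' occupy spatially distinct binding zones inside DMRs.
#'
#' @param n_genes number of simulated genes.
#' @param n_tfs number of transcription factors; must be even and at most
#'   `2 * motif_length` (substitution positions are unique per community).
#' @param n_modules number of planted co-expression modules.
#' @param n_subjects_control,n_subjects_case subjects per group; each subject
#'   contributes one NS and one TT sample.
#' @param nb_dispersion negative-binomial dispersion (1/size) common to all
#'   genes.
#' @param module_factor_sd standard deviation (natural-log scale) of the
#'   module latent-factor effect on gene means.
#' @param flip_fraction fraction of inter-module correlation signs that
#'   differ between the two groups.
#' @param motif_length motif width in bp; 5..9 so that the 80% relative-score
#'   threshold equals "at most one mismatch" for the planted uniform-strength
#'   motifs.
#' @param promoter_length promoter length in bp.
#' @param n_dmrs number of DMR sequences.
#' @param dmr_length DMR length in bp.
#' @param cluster_separation bp offset between the binding-zone centres of
#'   the two planted TF communities.
#' @param seed integer root seed; every stochastic draw in the generators
#'   derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, n_tfs = 16, n_modules = 4,
                       n_subjects_control = 30, n_subjects_case = 19,
                       nb_dispersion = 0.1, module_factor_sd = 1,
                       flip_fraction = 0.3, motif_length = 8,
                       promoter_length = 1200, n_dmrs = 10, dmr_length = 500,
                       cluster_separation = 50, seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_tfs = n_tfs, n_modules = n_modules,
    n_subjects_control = n_subjects_control,
    n_subjects_case = n_subjects_case,
    nb_dispersion = nb_dispersion, module_factor_sd = module_factor_sd,
    flip_fraction = flip_fraction, motif_length = motif_length,
    promoter_length = promoter_length, n_dmrs = n_dmrs,
    dmr_length = dmr_length, cluster_separation = cluster_separation,
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_tfs", "n_modules", "n_subjects_control",
              "n_subjects_case", "motif_length", "promoter_length",
              "n_dmrs", "dmr_length")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop("invalid configuration field '", f, "': must be an integer >= 1",
           call. = FALSE)
    }
  }
  for (f in c("nb_dispersion", "module_factor_sd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("invalid configuration field '", f, "': must be a positive real",
           call. = FALSE)
  }
  if (!is.numeric(cfg$flip_fraction) || cfg$flip_fraction < 0 ||
      cfg$flip_fraction > 1)
    stop("invalid configuration field 'flip_fraction': must lie in [0, 1]",
         call. = FALSE)
  if (cfg$cluster_separation < 0)
    stop("invalid configuration field 'cluster_separation': must be >= 0",
         call. = FALSE)
  if (cfg$promoter_length < cfg$motif_length)
    stop("invalid configuration field 'promoter_length': must be >= motif_length",
         call. = FALSE)
  if (cfg$motif_length < 5 || cfg$motif_length > 9)
    stop("invalid configuration field 'motif_length': must be in 5..9 ",
         "(so that the 0.8 relative-score threshold = one mismatch)",
         call. = FALSE)
  if (cfg$n_tfs %% 2 != 0 || cfg$n_tfs < 4)
    stop("invalid configuration field 'n_tfs': must be even and >= 4",
         call. = FALSE)
  if (cfg$n_tfs / 2 > cfg$motif_length)
    stop("invalid configuration field 'n_tfs': at most 2 * motif_length ",
         "TFs supported (unique substitution positions per community)",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Derive per-stage seeds from the single root seed so the three generators
# are independently reproducible.
stage_seeds <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("counts", "sequences", "ppi", "spare")
  s
}

# Nearest correlation-matrix repair: clip eigenvalues, rescale to unit diag.
fix_correlation <- function(S, eps = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S2))
  S2 / tcrossprod(d)
}

#' Simulate paired two-group RNA-seq counts with planted modules
#'
#' Genes belong to `n_modules` latent modules. Each sample draws a module
#' factor vector from a multivariate normal whose correlation matrix has
#' entries `+/- rho`; a `flip_fraction` of the inter-module correlation signs
#' differ between the two groups (the planted group difference). Stimulation
#' (TT) adds a per-module mean shift identical in both groups, so marginal
#' means carry no group signal. Counts are negative binomial around
#' log-normal means.
#'
#' @param cfg a [sim_config()].
#' @param rho magnitude of inter-module factor correlations.
#' @param subject_share fraction of factor variance shared between a
#'   subject's NS and TT samples (pairing).
#' @param tt_shift magnitude (natural-log scale) of the per-module
#'   stimulation shift.
#' @return list with `counts` (a `count_matrix`: integer matrix genes x
#'   samples plus `samples` metadata) and `truth` (ground-truth labels, sign
#'   matrices, per-stage seeds).
#' @export
simulate_counts <- function(cfg, rho = 0.3, subject_share = 0.5,
                            tt_shift = 0.8) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- stage_seeds(cfg$seed)
  set.seed(seeds[["counts"]])

  M <- cfg$n_modules
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  module_labels <- sprintf("M%d", rep_len(seq_len(M), cfg$n_genes))
  names(module_labels) <- genes

  ## subjects and samples (paired NS/TT)
  subjects <- c(sprintf("C%02d", seq_len(cfg$n_subjects_control)),
                sprintf("A%02d", seq_len(cfg$n_subjects_case)))
  group_of <- c(rep("control", cfg$n_subjects_control),
                rep("asthma", cfg$n_subjects_case))
  samples <- data.frame(
    sample = paste(rep(subjects, each = 2), c("NS", "TT"), sep = "_"),
    subject = rep(subjects, each = 2),
    group = rep(group_of, each = 2),
    condition = rep(c("NS", "TT"), length(subjects)),
    stringsAsFactors = FALSE
  )

  ## per-group module-factor correlation matrices with flipped signs
  base_sign <- matrix(1, M, M)
  if (M > 1) {
    up <- which(upper.tri(base_sign))
    s <- sample(c(-1, 1), length(up), replace = TRUE)
    base_sign[up] <- s
    base_sign <- base_sign * t(base_sign)  # symmetrize keeping diag 1
    diag(base_sign) <- 1
    n_flip <- round(cfg$flip_fraction * length(up))
    flip_idx <- if (n_flip > 0) sample(up, n_flip) else integer(0)
  } else {
    up <- integer(0); flip_idx <- integer(0)
  }
  case_sign <- base_sign
  if (length(flip_idx)) {
    tmp <- case_sign
    tmp[flip_idx] <- -tmp[flip_idx]
    # mirror into the lower triangle
    tmp[lower.tri(tmp)] <- t(tmp)[lower.tri(tmp)]
    case_sign <- tmp
  }
  sigma_control <- fix_correlation(diag(M) * (1 - rho) + rho * base_sign)
  sigma_case <- fix_correlation(diag(M) * (1 - rho) + rho * case_sign)

  ## latent factors: subject-level component shared across conditions plus a
  ## condition-specific component; marginal covariance equals the group Sigma
  draw_mvn <- function(n, Sigma) {
    L <- chol(Sigma)
    matrix(stats::rnorm(n * M), n, M) %*% L
  }
  n_sub <- length(subjects)
  f_subject <- matrix(0, n_sub, M)
  f_subject[group_of == "control", ] <-
    draw_mvn(sum(group_of == "control"), sigma_control)
  f_subject[group_of == "asthma", ] <-
    draw_mvn(sum(group_of == "asthma"), sigma_case)
  n_samp <- nrow(samples)
  f_cond <- matrix(0, n_samp, M)
  ctrl_rows <- samples$group == "control"
  f_cond[ctrl_rows, ] <- draw_mvn(sum(ctrl_rows), sigma_control)
  f_cond[!ctrl_rows, ] <- draw_mvn(sum(!ctrl_rows), sigma_case)
  sub_idx <- match(samples$subject, subjects)
  factors <- sqrt(subject_share) * f_subject[sub_idx, , drop = FALSE] +
    sqrt(1 - subject_share) * f_cond

  ## gene-level parameters
  log_base <- stats::rnorm(cfg$n_genes, mean = log(100), sd = 1)
  base <- pmax(exp(log_base), 1)  # baseline floor: mean >= 1
  loading <- stats::runif(cfg$n_genes, 0.7, 1.3)
  delta <- tt_shift * rep_len(c(1, -1), M)  # per-module stimulation shift
  names(delta) <- sprintf("M%d", seq_len(M))

  mod_idx <- rep_len(seq_len(M), cfg$n_genes)
  is_tt <- as.numeric(samples$condition == "TT")
  ## log mu: genes x samples
  log_mu <- log(base) +
    (cfg$module_factor_sd * loading) * t(factors)[mod_idx, , drop = FALSE] +
    outer(delta[mod_idx], is_tt)
  log_mu <- pmin(log_mu, log(1e7))
  counts <- matrix(
    stats::rnbinom(length(log_mu), mu = exp(log_mu),
                   size = 1 / cfg$nb_dispersion),
    nrow = cfg$n_genes,
    dimnames = list(genes, samples$sample)
  )
  storage.mode(counts) <- "integer"

  ## TF community structure: A targets the first half of the modules, B the
  ## rest; target genes drawn from those modules.
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  tf_community <- rep(c("A", "B"), each = cfg$n_tfs / 2)
  names(tf_community) <- tfs
  mods_A <- seq_len(ceiling(M / 2))
  mods_B <- setdiff(seq_len(M), mods_A)
  if (!length(mods_B)) mods_B <- mods_A
  tf_targets <- lapply(seq_len(cfg$n_tfs), function(i) {
    mods <- if (tf_community[i] == "A") mods_A else mods_B
    pool <- genes[mod_idx %in% mods]
    sort(sample(pool, min(12L, length(pool))))
  })
  names(tf_targets) <- tfs

  truth <- list(
    gene_module_labels = module_labels,
    tf_cluster_labels = tf_community,
    tf_targets = tf_targets,
    sign_control = base_sign,
    sign_case = case_sign,
    flipped_pairs = which(base_sign != case_sign, arr.ind = TRUE),
    sigma_control = sigma_control,
    sigma_case = sigma_case,
    tt_shift = delta,
    stage_seeds = seeds,
    config = unclass(cfg)
  )
  class(truth) <- "sim_truth"

  cm <- count_matrix(counts, samples)
  list(counts = cm, truth = truth)
}

## -- sequence-level generator ------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

mutate_base <- function(base) sample(setdiff(DNA_BASES, base), 1)

# Choose k plant positions in [0, L_seq - L_mot] with pairwise separation >=
# L_mot, greedily.
choose_positions <- function(k, L_seq, L_mot, taken = integer(0)) {
  pos <- integer(0)
  cand <- 0:(L_seq - L_mot)
  for (i in seq_len(k)) {
    ok <- cand[vapply(cand, function(p)
      all(abs(p - c(pos, taken)) >= L_mot), logical(1))]
    if (!length(ok)) break
    pos <- c(pos, sample(ok, 1))
  }
  sort(pos)
}

plant_at <- function(seq, motif, pos) {
  # pos 0-based
  substr(seq, pos + 1, pos + nchar(motif)) <- motif
  seq
}

# Nearest free slot to `want` keeping >= L separation from `taken`.
nearest_free_slot <- function(want, taken, L, L_seq) {
  lim <- L_seq - L
  for (d in 0:lim) {
    for (p in unique(c(want - d, want + d))) {
      if (p >= 0 && p <= lim && all(abs(p - taken) >= L)) return(p)
    }
  }
  NA_integer_
}

#' Simulate motifs, promoter sequences and DMR sequences
#'
#' Each TF community is built around a core consensus; a TF's own consensus
#' is the core with one private substitution (position unique within the
#' community). PFMs are information-rich with uniform column strength, so a
#' relative score of at least 0.8 on the default 8-bp motifs corresponds to
#' at most one mismatch from the consensus. Promoters of a TF's intended
#' targets carry exact consensus occurrences. Each DMR carries, per
#' community, two pure-core "anchor" occurrences near the community's zone
#' centre (shared binding mass) and one private consensus occurrence per TF
#' (distinguishing mass); community B's zone centre is offset from A's by
#' `cluster_separation` bp.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @param n_promoter_plants occurrences of a TF's consensus planted in each
#'   target promoter.
#' @param zone_sd SD (bp) of private-slot placement around the zone centre.
#' @return list with `pfms` (a `pfm_set`), `promoters` (named character),
#'   `dmrs` (named character), `dmr_bed` (data.frame), and `truth` updated
#'   with planted positions (`promoter_plants`, `dmr_plants`) and motif
#'   metadata.
#' @export
simulate_motifs_and_sequences <- function(cfg, truth,
                                          n_promoter_plants = 2,
                                          zone_sd = 25) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  if (cfg$motif_length > cfg$dmr_length)
    stop("invalid configuration: motif_length exceeds dmr_length",
         call. = FALSE)
  set.seed(truth$stage_seeds[["sequences"]])
  L <- cfg$motif_length
  tfs <- names(truth$tf_cluster_labels)
  comm <- truth$tf_cluster_labels

  ## community cores, Hamming distance >= 4 apart
  core_A <- strsplit(random_dna(L), "")[[1]]
  repeat {
    core_B <- strsplit(random_dna(L), "")[[1]]
    if (sum(core_A != core_B) >= min(4, L)) break
  }
  cores <- list(A = core_A, B = core_B)

  ## per-TF consensus: core with one substitution at a community-unique pos
  consensus <- character(length(tfs))
  sub_pos <- integer(length(tfs))
  names(consensus) <- names(sub_pos) <- tfs
  for (cm in c("A", "B")) {
    members <- tfs[comm == cm]
    pos <- sample(seq_len(L), length(members))
    for (i in seq_along(members)) {
      cons <- cores[[cm]]
      cons[pos[i]] <- mutate_base(cons[pos[i]])
      consensus[members[i]] <- paste(cons, collapse = "")
      sub_pos[members[i]] <- pos[i]
    }
  }

  ## PFMs: 17 counts for the consensus base, 1 elsewhere (uniform strength)
  pfms <- lapply(seq_along(tfs), function(i) {
    cons <- strsplit(consensus[i], "")[[1]]
    m <- matrix(1L, 4, L, dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(L)) m[cons[j], j] <- 17L
    m
  })
  names(pfms) <- tfs
  attr(pfms, "ids") <- sprintf("MA%04d.1", seq_along(tfs))
  class(pfms) <- "pfm_set"

  ## promoters: random background + exact consensus plants for targets
  genes <- names(truth$gene_module_labels)
  promoters <- vapply(genes, function(g) random_dna(cfg$promoter_length),
                      character(1))
  plants_by_gene <- list()
  for (tf in tfs) {
    for (g in truth$tf_targets[[tf]]) {
      taken <- if (is.null(plants_by_gene[[g]])) integer(0) else
        vapply(plants_by_gene[[g]], `[[`, 0L, "pos")
      pos <- choose_positions(n_promoter_plants, cfg$promoter_length, L,
                              taken = taken)
      for (p in pos) {
        promoters[[g]] <- plant_at(promoters[[g]], consensus[tf], p)
        plants_by_gene[[g]] <- c(plants_by_gene[[g]],
                                 list(list(tf = tf, pos = p)))
      }
    }
  }

  ## DMRs: anchors (pure core) near zone centres + one private slot per TF
  centre_A <- max(0L, round((cfg$dmr_length - cfg$cluster_separation) / 2))
  centre_B <- min(cfg$dmr_length - L, centre_A + cfg$cluster_separation)
  dmr_ids <- sprintf("DMR%02d", seq_len(cfg$n_dmrs))
  dmrs <- vapply(dmr_ids, function(d) random_dna(cfg$dmr_length),
                 character(1))
  dmr_plants <- list()
  dmr_tf_positions <- list()
  for (d in dmr_ids) {
    taken <- integer(0)
    plants <- list()
    anchors <- list(A = integer(0), B = integer(0))
    private <- stats::setNames(vector("list", length(tfs)), tfs)
    for (cm in c("A", "B")) {
      centre <- if (cm == "A") centre_A else centre_B
      ## two anchor slots straddling the centre; every community member
      ## matches them (one mismatch from its own consensus)
      for (want in c(centre - L, centre + 1)) {
        p <- nearest_free_slot(max(0, min(want, cfg$dmr_length - L)), taken,
                               L, cfg$dmr_length)
        if (is.na(p)) next
        dmrs[[d]] <- plant_at(dmrs[[d]], paste(cores[[cm]], collapse = ""), p)
        taken <- c(taken, p)
        anchors[[cm]] <- c(anchors[[cm]], p)
        plants <- c(plants, list(list(tf = paste0("core_", cm), pos = p,
                                      community = cm)))
      }
      ## one private exact-consensus slot per community member
      for (tf in tfs[comm == cm]) {
        want <- round(stats::rnorm(1, centre, zone_sd))
        p <- nearest_free_slot(max(0, min(want, cfg$dmr_length - L)), taken,
                               L, cfg$dmr_length)
        if (is.na(p)) next
        dmrs[[d]] <- plant_at(dmrs[[d]], consensus[tf], p)
        taken <- c(taken, p)
        private[[tf]] <- p
        plants <- c(plants, list(list(tf = tf, pos = p, community = cm)))
      }
    }
    dmr_plants[[d]] <- plants
    ## intended binding positions per TF: community anchors + private slot
    dmr_tf_positions[[d]] <- lapply(stats::setNames(tfs, tfs), function(tf)
      sort(c(anchors[[comm[[tf]]]], private[[tf]])))
  }
  dmr_bed <- data.frame(
    chrom = dmr_ids,
    start = 0L,
    end = cfg$dmr_length,
    name = dmr_ids,
    stringsAsFactors = FALSE
  )

  truth$motif_consensus <- consensus
  truth$motif_sub_pos <- sub_pos
  truth$community_cores <- lapply(cores, paste, collapse = "")
  truth$promoter_plants <- plants_by_gene
  truth$dmr_plants <- dmr_plants
  truth$dmr_tf_positions <- dmr_tf_positions
  truth$dmr_zone_centres <- c(A = centre_A, B = centre_B)

  list(pfms = pfms, promoters = promoters, dmrs = dmrs, dmr_bed = dmr_bed,
       truth = truth)
}

#' Simulate a TF-TF interaction prior
#'
#' Symmetric non-negative TF x TF weights with unit diagonal;
#' within-community weights are drawn higher than between-community weights.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @return symmetric numeric matrix with TF dimnames.
#' @export
simulate_ppi <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(truth$stage_seeds[["ppi"]])
  tfs <- names(truth$tf_cluster_labels)
  n <- length(tfs)
  same <- outer(truth$tf_cluster_labels, truth$tf_cluster_labels, "==")
  W <- matrix(0, n, n, dimnames = list(tfs, tfs))
  up <- upper.tri(W)
  W[up] <- ifelse(same[up], stats::runif(sum(up), 0.6, 1),
                  stats::runif(sum(up), 0, 0.4))
  W <- W + t(W)
  diag(W) <- 1
  W
}
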