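#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta`, preserving correlation sign
#' (anti-correlated genes get adjacency near 0). The soft-thresholding power
#' defaults to 12.
#'
#' @param values numeric matrix, genes x samples (e.g. `expr$values`
#'   restricted to the perturbed genes).
#' @param beta soft-thresholding power.
#' @return genes x genes adjacency in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(values, beta = 12) {
  if (ncol(values) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(values, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(values)[v == 0], 10), collapse = ", "),
         call. = FALSE)
  r <- stats::cor(t(values))
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Genes sharing many strong neighbours get high overlap even
#' if their direct adjacency is moderate.
#'
#' @param adjacency symmetric adjacency with unit diagonal from
#'   [signed_adjacency()].
#' @return symmetric TOM in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- adjacency
  ## l_ij excludes u = i and u = j; with unit diagonal each contributes a_ij
  l <- a %*% a - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix over
#' samples, sign-fixed so that its correlation with the module's mean
#' standardized profile is positive.
#'
#' @param values genes x samples matrix.
#' @param genes gene ids of the module (length >= 2).
#' @return list with `eigengene` (unit-norm vector over samples) and
#'   `explained` (fraction of variance captured, in (0, 1]).
#' @export
module_eigengene <- function(values, genes) {
  if (length(genes) < 2)
    stop("module must contain at least 2 genes", call. = FALSE)
  X <- values[genes, , drop = FALSE]
  Xs <- t(scale(t(X)))  # standardize each gene across samples
  if (any(!is.finite(Xs)))
    stop("zero-variance gene in module", call. = FALSE)
  ## right singular vectors via the small samples x samples crossproduct
  cp <- crossprod(Xs)
  e <- eigen(cp, symmetric = TRUE)
  v <- e$vectors[, 1]
  expl <- e$values[1] / sum(pmax(e$values, 0))
  profile <- colMeans(Xs)
  if (stats::cor(v, profile) < 0) v <- -v
  list(eigengene = stats::setNames(v, colnames(values)), explained = expl)
}

#' Eigengene matrix for all named modules
#'
#' Stacks [module_eigengene()] over every module of an assignment
#' (modules x samples); "unassigned" genes are skipped.
#'
#' @param values genes x samples matrix.
#' @param assignment named gene -> module labels.
#' @return modules x samples matrix.
#' @export
eigengene_matrix <- function(values, assignment) {
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  E <- t(vapply(mods, function(m) {
    module_eigengene(values, names(assignment)[assignment == m])$eigengene
  }, numeric(ncol(values))))
  rownames(E) <- mods
  E
}

#' Detect modules by clustering topological overlap
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at the static
#' height that maximizes the number of branches of at least
#' `min_module_size` genes (largest such height on ties), followed by
#' iterative merging of modules whose eigengenes correlate above
#' `1 - merge_height`. Genes in branches smaller than `min_module_size` are
#' labelled "unassigned". Modules are renamed "M1", "M2", ... by decreasing
#' size.
#'
#' @param tom TOM from [topological_overlap()].
#' @param values genes x samples expression matrix (for eigengene merging).
#' @param min_module_size smallest module size retained.
#' @param merge_height modules with eigengene correlation `> 1 -
#'   merge_height` are merged.
#' @param n_heights number of candidate cut heights scanned.
#' @param cohesion a branch only counts as a module when its mean within-
#'   branch overlap exceeds `cohesion` times the mean overlap between its
#'   members and all other genes (guards against partitioning structureless
#'   overlap into spurious modules).
#' @param min_tom absolute mean-overlap floor applied when a branch spans
#'   every gene (no outside genes to compare against).
#' @return named character vector: gene id -> module label ("M1", ...,
#'   or "unassigned").
#' @export
cut_modules <- function(tom, values, min_module_size = 30,
                        merge_height = 0.15, n_heights = 100,
                        cohesion = 2, min_tom = 0.1) {
  genes <- rownames(tom)
  if (is.null(genes)) stop("tom must have gene rownames", call. = FALSE)
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all unassigned")
    return(stats::setNames(rep("unassigned", nrow(tom)), genes))
  }
  n <- nrow(tom)
  ## cohesive branches at one cut: per-branch within / outside mean overlap
  ## in a single O(n^2) pass
  qualified_branches <- function(ct) {
    sz <- tabulate(ct)
    big <- which(sz >= min_module_size)
    if (!length(big)) return(integer(0))
    B <- rowsum(tom, ct)                 # branches x genes
    S <- rowsum(t(B), ct)                # pairwise branch overlap sums
    keep <- integer(0)
    for (b in big) {
      bs <- sz[b]
      mw <- (S[b, b] - bs) / (bs * (bs - 1))  # exclude unit diagonal
      ok <- if (bs == n) mw > min_tom else {
        mo <- (sum(S[b, ]) - S[b, b]) / (bs * (n - bs))
        mw > cohesion * mo
      }
      if (ok) keep <- c(keep, b)
    }
    keep
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  ## candidate cut heights: midpoints of the widest gaps between
  ## consecutive merge heights (distinct partitions live between merges),
  ## plus the single-branch cut above the root
  sh <- sort(unique(h$height))
  mids <- if (length(sh) > 1) {
    gaps <- diff(sh)
    top <- order(gaps, decreasing = TRUE)[seq_len(min(n_heights,
                                                      length(gaps)))]
    (sh[top] + sh[top + 1]) / 2
  } else numeric(0)
  hts <- sort(unique(c(mids, max(sh) + 1e-9)))
  cuts <- lapply(hts, function(ht) stats::cutree(h, h = ht))
  n_big <- vapply(cuts, function(ct)
    sum(tabulate(ct) >= min_module_size), 0L)
  ## branch-and-bound: qualified count is bounded by the big-branch count,
  ## so visit cuts in decreasing bound order (largest height first on ties)
  ord <- order(-n_big, -hts)
  best_n <- 0L; best_ok <- NULL; best_cut <- NULL
  for (i in ord) {
    if (n_big[i] <= best_n) break
    ok <- qualified_branches(cuts[[i]])
    if (length(ok) > best_n) {
      best_n <- length(ok); best_ok <- ok; best_cut <- cuts[[i]]
    }
  }
  if (best_n < 1) {
    warning("no cohesive branch reached min_module_size; all unassigned")
    return(stats::setNames(rep("unassigned", length(genes)), genes))
  }
  lab <- ifelse(best_cut %in% best_ok, paste0("b", best_cut), "unassigned")
  names(lab) <- genes

  ## iterative eigengene merge
  repeat {
    mods <- setdiff(unique(lab), "unassigned")
    if (length(mods) < 2) break
    E <- eigengene_matrix(values, lab)
    rc <- stats::cor(t(E))
    diag(rc) <- -Inf
    mx <- which(rc == max(rc), arr.ind = TRUE)[1, ]
    if (rc[mx[1], mx[2]] <= 1 - merge_height) break
    from <- rownames(rc)[mx[2]]; to <- rownames(rc)[mx[1]]
    lab[lab == from] <- to
  }

  ## relabel by decreasing size (ties: by first gene id for determinism)
  mods <- setdiff(unique(lab), "unassigned")
  sz <- vapply(mods, function(m) sum(lab == m), 0L)
  first_gene <- vapply(mods, function(m) min(names(lab)[lab == m]), "")
  ord <- order(-sz, first_gene)
  map <- stats::setNames(paste0("M", seq_along(mods)), mods[ord])
  out <- ifelse(lab == "unassigned", "unassigned", map[lab])
  stats::setNames(out, genes)
}

#' Stimulation and group-by-stimulation ANOVA on a module eigengene
#'
#' Two-way mixed ANOVA with stimulation (NS/TT) as the within-subject
#' factor and group as the between-subject factor, fitted with
#' `aov(value ~ group * condition + Error(subject))`. Returns the
#' within-stratum F and p for the stimulation main effect and the group x
#' stimulation interaction.
#'
#' @param eigengene named numeric vector over samples (names = sample ids).
#' @param samples sample metadata (`sample`, `subject`, `group`,
#'   `condition`).
#' @return list with `stim_F`, `stim_p`, `interaction_F`, `interaction_p`.
#' @export
eigengene_interaction_test <- function(eigengene, samples) {
  stopifnot(all(names(eigengene) %in% samples$sample))
  df <- samples[match(names(eigengene), samples$sample), ]
  df$value <- as.numeric(eigengene)
  tab <- table(df$subject, df$condition)
  bad <- rownames(tab)[rowSums(tab == 1) != 2]
  if (length(bad))
    stop("unpaired subject(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (stats::var(df$value) == 0)
    stop("eigengene has zero variance; test undefined", call. = FALSE)
  df$group <- factor(df$group); df$condition <- factor(df$condition)
  df$subject <- factor(df$subject)
  fit <- stats::aov(value ~ group * condition + Error(subject), data = df)
  within <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  list(stim_F = within[rn == "condition", "F value"],
       stim_p = within[rn == "condition", "Pr(>F)"],
       interaction_F = within[rn == "group:condition", "F value"],
       interaction_p = within[rn == "group:condition", "Pr(>F)"])
}

#' Module connectivity network within one group
#'
#' Pairwise Pearson correlation of module eigengenes over the samples of
#' one group, two-sided p-values, and Benjamini-Hochberg correction within
#' the group.
#'
#' @param E modules x samples eigengene matrix.
#' @param samples sample metadata.
#' @param group group whose samples are used.
#' @param q_threshold significance threshold on q for the edge flag.
#' @param condition optionally restrict to one condition ("NS"/"TT");
#'   pooling both conditions lets a shared stimulation response dominate
#'   the correlations.
#' @return data.frame with one row per module pair: `m1`, `m2`, `r`, `p`,
#'   `q`, `sign`, `significant`.
#' @export
module_network <- function(E, samples, group, q_threshold = 0.05,
                           condition = NULL) {
  if (!is.null(condition)) samples <- samples[samples$condition ==
                                                condition, , drop = FALSE]
  cols <- samples$sample[samples$group == group]
  cols <- intersect(colnames(E), cols)
  if (length(cols) < 4)
    stop("need at least 4 samples in group '", group, "'", call. = FALSE)
  Eg <- E[, cols, drop = FALSE]
  mods <- rownames(E)
  pairs <- utils::combn(mods, 2)
  res <- vapply(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    ct <- stats::cor.test(Eg[pr[1], ], Eg[pr[2], ])
    c(r = unname(ct$estimate), p = ct$p.value)
  }, numeric(2))
  out <- data.frame(m1 = pairs[1, ], m2 = pairs[2, ],
                    r = res["r", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$sign <- ifelse(out$r >= 0, "positive", "negative")
  out$significant <- out$q < q_threshold
  out
}

#' Degree centrality of genes within a module subgraph
#'
#' Restricts an undirected weighted edge list to the module's genes and
#' ranks genes by degree; ties are broken by summed edge weight, then
#' lexicographically by gene id.
#'
#' @param genes module gene ids.
#' @param edges data.frame with columns `a`, `b` and optionally `weight`.
#' @return data.frame `gene`, `degree`, `strength`, `rank` sorted by rank.
#' @export
module_centrality <- function(genes, edges) {
  if (is.null(edges$weight)) edges$weight <- 1
  sub <- edges[edges$a %in% genes & edges$b %in% genes, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("empty module subgraph; all centralities zero")
    out <- data.frame(gene = sort(genes), degree = 0, strength = 0,
                      stringsAsFactors = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                       vertices = data.frame(name = genes))
    out <- data.frame(gene = igraph::V(g)$name,
                      degree = igraph::degree(g),
                      strength = igraph::strength(g, weights =
                                                    igraph::E(g)$weight),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$degree, -out$strength, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
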