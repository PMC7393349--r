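## Per-edge regulatory shift between case and control networks, per-TF
## per-module median summaries, and TF community discovery.

#' Edge-level regulatory shift
#'
#' Elementwise difference of edge weights, case minus control, on identical
#' TF and gene universes.
#'
#' @param net_case,net_control `panda_network` objects or plain TF x gene
#'   matrices.
#' @return TF x gene shift matrix.
#' @export
edge_shift <- function(net_case, net_control) {
  Wc <- if (inherits(net_case, "panda_network")) net_case$W else net_case
  W0 <- if (inherits(net_control, "panda_network")) net_control$W else
    net_control
  if (!identical(dimnames(Wc), dimnames(W0))) {
    d1 <- c(setdiff(rownames(Wc), rownames(W0)),
            setdiff(rownames(W0), rownames(Wc)),
            setdiff(colnames(Wc), colnames(W0)),
            setdiff(colnames(W0), colnames(Wc)))
    stop("TF/gene universes differ: ",
         paste(utils::head(unique(d1), 10), collapse = ", "), call. = FALSE)
  }
  Wc - W0
}

#' Per-TF per-module median regulatory shift
#'
#' For each TF and module, the median shift over that TF's targets (genes
#' with a nonzero motif-prior hit count) inside the module. Only TFs with
#' at least one target in every module are eligible; others are dropped
#' from the result.
#'
#' @param shifts TF x gene shift matrix from [edge_shift()].
#' @param assignment named gene -> module labels (from [cut_modules()]);
#'   "unassigned" genes are ignored.
#' @param prior TF x gene hit-count matrix defining targets.
#' @return TF x module matrix of median shifts (eligible TFs only), with
#'   attribute `ineligible` listing the masked TFs.
#' @export
module_median_shift <- function(shifts, assignment, prior) {
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  if (!length(mods)) stop("no named modules in assignment", call. = FALSE)
  for (m in mods)
    if (!any(assignment == m)) stop("module ", m, " has zero genes",
                                    call. = FALSE)
  genes <- intersect(colnames(shifts), names(assignment))
  S <- matrix(NA_real_, nrow(shifts), length(mods),
              dimnames = list(rownames(shifts), mods))
  for (m in mods) {
    gm <- genes[assignment[genes] == m]
    for (tf in rownames(shifts)) {
      targets <- gm[prior[tf, gm] > 0]
      if (length(targets))
        S[tf, m] <- stats::median(shifts[tf, targets])
    }
  }
  eligible <- rowSums(is.na(S)) == 0
  out <- S[eligible, , drop = FALSE]
  attr(out, "ineligible") <- rownames(S)[!eligible]
  out
}

#' Silhouette scores on a distance matrix
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean distance to
#' the other members of i's cluster and `b` the smallest mean distance to
#' another cluster. Points in singleton clusters score 0.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @param labels cluster labels, one per point.
#' @return list with `scores` (per point) and `mean`.
#' @export
silhouette_score <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  sizes <- table(labels)
  ## per-point summed distance to each cluster
  sums <- rowsum(t(D), labels)          # clusters x points
  means <- sums / as.vector(sizes[rownames(sums)])
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[li]] == 1) { s[i] <- 0; next }
    a <- sums[li, i] / (sizes[[li]] - 1)
    b <- min(means[rownames(means) != li, i])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  list(scores = stats::setNames(s, rownames(D)), mean = mean(s))
}

#' Cluster TFs by their module shift patterns
#'
#' Runs k-means (or Ward hierarchical clustering) on the TF x module shift
#' matrix for each k in `k_range`, scores each clustering by mean
#' silhouette (Euclidean distances), and returns the labels at the
#' silhouette-maximizing k (smallest k on ties).
#'
#' @param shift TF x module matrix from [module_median_shift()].
#' @param k_range candidate cluster numbers; truncated with a warning if
#'   its upper end reaches the number of TFs.
#' @param n_init random restarts per k for k-means.
#' @param seed RNG seed for reproducible restarts.
#' @param method "kmeans" (default) or "hclust" (Ward on Euclidean).
#' @return list with `labels` (named TF -> cluster), `k`, `silhouette_by_k`
#'   (data.frame `k`, `mean_silhouette`), `method`.
#' @export
cluster_tfs <- function(shift, k_range = 2:10, n_init = 20, seed = 1,
                        method = c("kmeans", "hclust")) {
  method <- match.arg(method)
  m <- nrow(shift)
  if (m < 3) stop("need at least 3 eligible TFs", call. = FALSE)
  if (max(k_range) >= m) {
    warning("k_range truncated to 2..", m - 1)
    k_range <- k_range[k_range < m]
  }
  D <- as.matrix(stats::dist(shift))
  hc <- if (method == "hclust")
    stats::hclust(stats::as.dist(D), method = "ward.D2")
  set.seed(seed)
  sil <- numeric(length(k_range))
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- if (method == "kmeans")
      stats::kmeans(shift, centers = k, nstart = n_init)$cluster
    else stats::cutree(hc, k = k)
    labs[[i]] <- cl
    sil[i] <- silhouette_score(D, cl)$mean
  }
  best <- which.max(sil)  # which.max returns the first (smallest k) on ties
  list(labels = stats::setNames(labs[[best]], rownames(shift)),
       k = k_range[best],
       silhouette_by_k = data.frame(k = k_range, mean_silhouette = sil),
       method = method)
}

#' Per-TF test for altered regulation
#'
#' Declared stand-in summary of how many TFs show overall altered
#' regulation: for each TF, a Wilcoxon signed-rank test of its edge shifts
#' against zero, BH-corrected across TFs.
#'
#' @param shifts TF x gene shift matrix.
#' @param q_threshold FDR threshold.
#' @return data.frame `tf`, `median_shift`, `p`, `q`, `altered`,
#'   `direction`.
#' @export
tf_altered_regulation <- function(shifts, q_threshold = 0.05) {
  p <- apply(shifts, 1, function(x)
    stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value)
  med <- apply(shifts, 1, stats::median)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(tf = rownames(shifts), median_shift = med, p = p, q = q,
             altered = q < q_threshold,
             direction = ifelse(med > 0, "strengthened", "weakened"),
             row.names = NULL, stringsAsFactors = FALSE)
}
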