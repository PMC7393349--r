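## Binding-location proximity analysis in differentially methylated
## regions: Gaussian-smoothed binding profiles, L1 distances, near-duplicate
## elimination, and the silhouette permutation test.

#' Smoothed binding profile over a DMR
#'
#' For each hit position a Gaussian kernel (SD `sd` bp) truncated to a
#' `window`-bp support centred on the hit is added to a vector of length
#' `n_dmr`; the vector is then renormalized to sum to 1, so kernel mass
#' clipped at the DMR edges is redistributed globally.
#'
#' @param hits integer vector of 0-based hit positions within the DMR.
#' @param n_dmr DMR length in bp.
#' @param window kernel support width in bp (odd; default 21).
#' @param sd kernel standard deviation in bp (default 5).
#' @return numeric density vector of length `n_dmr` summing to 1.
#' @export
binding_vector <- function(hits, n_dmr, window = 21, sd = 5) {
  if (!length(hits)) stop("no hits: caller must exclude this TF",
                          call. = FALSE)
  if (any(hits < 0 | hits >= n_dmr))
    stop("hit positions must lie in [0, n_dmr)", call. = FALSE)
  half <- (window - 1) %/% 2
  v <- numeric(n_dmr)
  for (p in hits) {
    lo <- max(0L, p - half); hi <- min(n_dmr - 1L, p + half)
    idx <- lo:hi
    v[idx + 1L] <- v[idx + 1L] + stats::dnorm(idx, mean = p, sd = sd)
  }
  v / sum(v)
}

#' L1 distance matrix between binding profiles
#'
#' `D_ij = sum_bp |v_i - v_j|`; for sum-to-one profiles the distances lie
#' in `[0, 2]`, attaining 2 for disjoint support.
#'
#' @param profiles matrix with one profile per row (TFs x bp), or list of
#'   equal-length vectors.
#' @return symmetric distance matrix with zero diagonal.
#' @export
binding_distance_matrix <- function(profiles) {
  if (is.list(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1)
      stop("profiles have unequal lengths", call. = FALSE)
    profiles <- do.call(rbind, profiles)
  }
  m <- nrow(profiles)
  D <- matrix(0, m, m, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- sum(abs(profiles[i, ] - profiles[j, ]))
    }
  }
  D
}

#' Eliminate near-duplicate binding profiles
#'
#' While any off-diagonal pair of profiles is closer than `threshold`, one
#' such pair is chosen uniformly at random and one member of it (uniformly)
#' is removed. Guards the silhouette test against TFs with shared motifs or
#' identical binding locations.
#'
#' @param D distance matrix.
#' @param threshold minimum allowed pairwise distance.
#' @param seed RNG seed making the elimination reproducible.
#' @return list with `kept` (names or indices retained) and `log`
#'   (data.frame of eliminations: `pair_a`, `pair_b`, `dropped`).
#' @export
eliminate_near_duplicates <- function(D, threshold = 0.1, seed = 1) {
  D <- as.matrix(D)
  nm <- rownames(D)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(D)))
  set.seed(seed)
  keep <- seq_len(nrow(D))
  log <- list()
  repeat {
    Dk <- D[keep, keep, drop = FALSE]
    close <- which(upper.tri(Dk) & Dk < threshold, arr.ind = TRUE)
    if (!nrow(close)) break
    if (length(keep) == 2 && nrow(close)) {
      # dropping one more leaves a single TF; still proceed per the rule
    }
    pick <- close[sample.int(nrow(close), 1), ]
    drop_local <- pick[[sample(c("row", "col"), 1)]]
    dropped <- keep[drop_local]
    log[[length(log) + 1]] <- data.frame(
      pair_a = nm[keep[pick[["row"]]]], pair_b = nm[keep[pick[["col"]]]],
      dropped = nm[dropped], stringsAsFactors = FALSE)
    keep <- setdiff(keep, dropped)
    if (length(keep) < 2) break
  }
  if (length(keep) < 1)
    stop("all TFs eliminated: degenerate DMR", call. = FALSE)
  list(kept = nm[keep],
       log = if (length(log)) do.call(rbind, log) else
         data.frame(pair_a = character(0), pair_b = character(0),
                    dropped = character(0)))
}

# Mean silhouette for many label permutations at once. Cluster sizes are
# invariant under permutation, so per-cluster distance sums for all
# permutations reduce to one matrix product per cluster; agrees with
# silhouette_score() applied per permutation.
perm_silhouettes <- function(D, labels, n_perm, seed) {
  set.seed(seed)
  labs <- as.character(labels)
  m <- length(labs)
  Lm <- vapply(seq_len(n_perm), function(i) sample(labs), character(m))
  cls <- sort(unique(labs))
  sizes <- table(labs)[cls]
  SC <- lapply(cls, function(cl) D %*% (Lm == cl))  # m x n_perm each
  names(SC) <- cls
  A <- matrix(0, m, n_perm)
  B <- matrix(Inf, m, n_perm)
  for (cl in cls) {
    own <- Lm == cl
    nc <- sizes[[cl]]
    if (nc > 1) A[own] <- SC[[cl]][own] / (nc - 1)
    B[!own] <- pmin(B[!own], SC[[cl]][!own] / nc)
  }
  s <- (B - A) / pmax(A, B)
  s[pmax(A, B) == 0] <- 0
  for (cl in cls) if (sizes[[cl]] == 1) s[Lm == cl] <- 0
  colMeans(s)
}

#' Silhouette permutation test of binding-location proximity
#'
#' Computes the mean silhouette of the retained TFs' binding-profile
#' distance matrix under their regulatory-cluster labels, then permutes the
#' labels `n_perm` times; the p-value is the fraction of permutations whose
#' mean silhouette strictly exceeds the observed one.
#'
#' @param D distance matrix of retained TFs (after elimination).
#' @param labels named cluster labels for the retained TFs.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `observed_ss`, `null` (permutation sample), `p`,
#'   `testable` (FALSE when fewer than 2 clusters remain, in which case the
#'   other fields are NA).
#' @export
proximity_test <- function(D, labels, n_perm = 10000, seed = 1) {
  D <- as.matrix(D)
  if (!is.null(names(labels))) labels <- labels[rownames(D)]
  if (length(unique(labels)) < 2) {
    return(list(observed_ss = NA_real_, null = numeric(0), p = NA_real_,
                testable = FALSE))
  }
  obs <- silhouette_score(D, labels)$mean
  null <- perm_silhouettes(D, labels, n_perm, seed)
  list(observed_ss = obs, null = null, p = sum(null > obs) / n_perm,
       testable = TRUE)
}

signif_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Run the binding-proximity test over a panel of DMRs
#'
#' For each DMR: scans every motif at the relative-score threshold, builds
#' smoothed binding profiles for TFs with at least one hit, eliminates
#' near-duplicate profiles, and runs the silhouette permutation test with
#' the TF regulatory-cluster labels. DMRs with fewer than two bound TFs or
#' a single represented cluster are flagged untestable.
#'
#' @param dmrs named character vector of DMR sequences.
#' @param pfms named list of PFMs.
#' @param tf_clusters named TF -> cluster labels (from [cluster_tfs()]).
#' @param threshold motif relative-score threshold.
#' @param window,sd smoothing kernel parameters.
#' @param dup_threshold elimination distance threshold.
#' @param n_perm permutations per DMR.
#' @param seed root seed; per-DMR scan/elimination/permutation seeds derive
#'   from it.
#' @param hit_position "start" (default) or "midpoint" of the motif match.
#' @return data.frame with one row per DMR: `dmr`, `n_tfs_bound`,
#'   `n_retained`, `observed_ss`, `null_mean`, `null_q95`, `p`, `stars`,
#'   `testable`; the per-DMR null samples are in `attr(, "nulls")`, the
#'   elimination logs in `attr(, "elimination")`.
#' @export
run_dmr_panel <- function(dmrs, pfms, tf_clusters, threshold = 0.8,
                          window = 21, sd = 5, dup_threshold = 0.1,
                          n_perm = 10000, seed = 1,
                          hit_position = c("start", "midpoint")) {
  hit_position <- match.arg(hit_position)
  rows <- list(); nulls <- list(); elim_logs <- list()
  half_motif <- function(pfm) ncol(pfm) %/% 2
  for (i in seq_along(dmrs)) {
    d <- names(dmrs)[i]
    n_dmr <- nchar(dmrs[[i]])
    hits_by_tf <- list()
    for (tf in names(pfms)) {
      h <- scan_pfm(pfms[[tf]], dmrs[[i]], threshold)
      if (nrow(h)) {
        pos <- h$start
        if (hit_position == "midpoint") pos <- pos + half_motif(pfms[[tf]])
        hits_by_tf[[tf]] <- pmin(pos, n_dmr - 1L)
      }
    }
    n_bound <- length(hits_by_tf)
    if (n_bound < 2) {
      rows[[d]] <- data.frame(dmr = d, n_tfs_bound = n_bound,
                              n_retained = n_bound, observed_ss = NA_real_,
                              null_mean = NA_real_, null_q95 = NA_real_,
                              p = NA_real_, stars = "", testable = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    profiles <- do.call(rbind, lapply(hits_by_tf, binding_vector,
                                      n_dmr = n_dmr, window = window,
                                      sd = sd))
    D <- binding_distance_matrix(profiles)
    el <- eliminate_near_duplicates(D, dup_threshold, seed = seed + i)
    elim_logs[[d]] <- el$log
    kept <- el$kept
    res <- if (length(kept) >= 2) {
      proximity_test(D[kept, kept, drop = FALSE],
                     tf_clusters[kept], n_perm = n_perm, seed = seed + i)
    } else list(observed_ss = NA_real_, null = numeric(0), p = NA_real_,
                testable = FALSE)
    nulls[[d]] <- res$null
    rows[[d]] <- data.frame(
      dmr = d, n_tfs_bound = n_bound, n_retained = length(kept),
      observed_ss = res$observed_ss,
      null_mean = if (length(res$null)) mean(res$null) else NA_real_,
      null_q95 = if (length(res$null))
        unname(stats::quantile(res$null, 0.95)) else NA_real_,
      p = res$p, stars = signif_stars(res$p), testable = res$testable,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dmr = character(0), n_tfs_bound = integer(0),
               n_retained = integer(0), observed_ss = numeric(0),
               null_mean = numeric(0), null_q95 = numeric(0),
               p = numeric(0), stars = character(0), testable = logical(0))
  rownames(out) <- NULL
  attr(out, "nulls") <- nulls
  attr(out, "elimination") <- elim_logs
  out
}
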