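test_that("edge shift is an elementwise difference with universe checks", {
  A <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("t1", "t2"),
                                                c("g1", "g2")))
  B <- matrix(c(0, 4, 2, 4), 2, dimnames = dimnames(A))
  expect_equal(edge_shift(A, B), A - B)
  expect_equal(edge_shift(A, A), A * 0)
  expect_equal(edge_shift(B, A), -edge_shift(A, B))
  C <- B; colnames(C) <- c("g1", "g3")
  expect_error(edge_shift(A, C), "g2")
})

test_that("median shift per module follows the eligibility rule", {
  shifts <- rbind(
    t1 = c(1, 1, -5, 2, 2, 0.5),
    t2 = c(3, 3, 3, -1, -1, -1))
  colnames(shifts) <- sprintf("g%d", 1:6)
  assignment <- setNames(rep(c("M1", "M2"), each = 3), colnames(shifts))
  prior <- rbind(t1 = c(1, 2, 1, 1, 1, 1),
                 t2 = c(0, 0, 0, 1, 1, 1))  # t2 has no target in M1
  colnames(prior) <- colnames(shifts)
  S <- module_median_shift(shifts, assignment, prior)
  expect_identical(rownames(S), "t1")
  expect_equal(S["t1", "M1"], 1)   # median(1, 1, -5)
  expect_equal(S["t1", "M2"], 2)
  expect_identical(attr(S, "ineligible"), "t2")
  # robust to a single outlier: replacing one value beyond the median
  shifts2 <- shifts; shifts2["t1", "g3"] <- -500
  expect_equal(module_median_shift(shifts2, assignment, prior)["t1", "M1"],
               1)
  # target-order invariance
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(module_median_shift(shifts[, perm], assignment[perm],
                                   prior[, perm]),
               S, ignore_attr = TRUE)
})

test_that("silhouette matches the textbook formula and the cluster package", {
  # hand-evaluated 5-point toy
  D <- matrix(0, 5, 5)
  D[1, 2] <- D[2, 1] <- 1
  D[1, 3] <- D[3, 1] <- 8; D[1, 4] <- D[4, 1] <- 9; D[1, 5] <- D[5, 1] <- 9
  D[2, 3] <- D[3, 2] <- 8; D[2, 4] <- D[4, 2] <- 9; D[2, 5] <- D[5, 2] <- 9
  D[3, 4] <- D[4, 3] <- 2; D[3, 5] <- D[5, 3] <- 2.5
  D[4, 5] <- D[5, 4] <- 1.5
  lab <- c(1, 1, 2, 2, 2)
  s <- silhouette_score(D, lab)
  # point 1: a = 1, b = mean(8, 9, 9) = 26/3
  expect_equal(unname(s$scores[1]), (26 / 3 - 1) / (26 / 3),
               tolerance = 1e-12)
  # point 3: a = mean(2, 2.5) = 2.25, b = mean(8, 8) = 8
  expect_equal(unname(s$scores[3]), (8 - 2.25) / 8, tolerance = 1e-12)
  # independent implementation: cluster::silhouette
  cs <- cluster::silhouette(lab, stats::as.dist(D))
  expect_equal(unname(s$scores), unname(cs[, 3]), tolerance = 1e-12)
  # closed forms
  D2 <- matrix(2, 4, 4) - 2 * diag(4)
  D2[1, 2] <- D2[2, 1] <- 0; D2[3, 4] <- D2[4, 3] <- 0
  expect_equal(silhouette_score(D2, c(1, 1, 2, 2))$mean, 1)
  Deq <- matrix(1, 4, 4) - diag(4)
  expect_equal(silhouette_score(Deq, c(1, 2, 1, 2))$mean, 0)
  expect_error(silhouette_score(Deq, rep(1, 4)), "2 clusters")
})

test_that("silhouette agrees with cluster::silhouette on random instances", {
  set.seed(12)
  for (r in 1:10) {
    X <- matrix(rnorm(20 * 3), 20)
    lab <- sample(1:3, 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    D <- as.matrix(dist(X))
    mine <- silhouette_score(D, lab)
    cs <- cluster::silhouette(lab, dist(X))
    expect_equal(unname(mine$scores), unname(cs[, "sil_width"]),
                 tolerance = 1e-12)
  }
})

test_that("k-means selects two blobs with perfect recovery; three for three", {
  px <- planted_shift_matrix(seed = 4)
  cl <- cluster_tfs(px$shift, seed = 1)
  expect_identical(cl$k, 2L)
  expect_equal(ari(cl$labels, px$community), 1)
  # three far-separated blobs
  set.seed(5)
  X <- rbind(matrix(rnorm(15, 0, 0.1), 5, 3),
             matrix(rnorm(15, 30, 0.1), 5, 3),
             matrix(rnorm(15, -30, 0.1), 5, 3))
  rownames(X) <- sprintf("t%02d", 1:15)
  cl3 <- cluster_tfs(X, seed = 1)
  expect_identical(cl3$k, 3L)
  expect_equal(ari(cl3$labels, rep(1:3, each = 5)), 1)
})

test_that("row duplication leaves the chosen k unchanged", {
  px <- planted_shift_matrix(seed = 6)
  X2 <- rbind(px$shift, px$shift)
  rownames(X2) <- sprintf("t%02d", seq_len(nrow(X2)))
  cl <- cluster_tfs(X2, seed = 1)
  expect_identical(cl$k, 2L)
})

test_that("k range truncates with a warning when it reaches the TF count", {
  px <- planted_shift_matrix(n_tfs = 6, seed = 7)
  expect_warning(cl <- cluster_tfs(px$shift, k_range = 2:10, seed = 1),
                 "truncated")
  expect_lt(cl$k, 6)
  expect_error(cluster_tfs(px$shift[1:2, ]), "at least 3")
})

test_that("hierarchical clustering also selects k = 2 on the planted fixture", {
  px <- planted_shift_matrix(seed = 8)
  cl <- cluster_tfs(px$shift, seed = 1, method = "hclust")
  expect_identical(cl$k, 2L)
  expect_equal(ari(cl$labels, px$community), 1)
})

test_that("chosen k is reproducible and correct across seeds", {
  hits <- 0
  for (sd in 1:10) {
    px <- planted_shift_matrix(seed = 100 + sd)
    cl <- cluster_tfs(px$shift, seed = sd)
    if (cl$k == 2L && isTRUE(all.equal(ari(cl$labels, px$community), 1)))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("per-TF altered-regulation summary flags planted shifts", {
  set.seed(13)
  shifts <- rbind(
    matrix(rnorm(8 * 200, mean = 0.4, sd = 0.5), 8),   # shifted TFs
    matrix(rnorm(8 * 200, mean = 0, sd = 0.5), 8))     # null TFs
  rownames(shifts) <- sprintf("TF%02d", 1:16)
  res <- tf_altered_regulation(shifts)
  expect_true(all(res$altered[1:8]))
  expect_identical(res$direction[1], "strengthened")
  expect_lt(mean(res$altered[9:16]), 0.3)
})
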