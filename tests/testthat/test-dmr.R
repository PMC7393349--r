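test_that("binding vectors are unimodal, normalized, and clip-safe", {
  v <- binding_vector(50, 101)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_identical(which.max(v), 51L)  # argmax at the hit (0-based 50)
  expect_equal(v[51 - 1:10], v[51 + 1:10], tolerance = 1e-12)  # symmetric
  expect_true(all(v[c(1:39, 63:101)] == 0))  # support is the 21-bp window
  # clipped at the edge: renormalization still sums to 1
  v0 <- binding_vector(0, 101)
  expect_equal(sum(v0), 1, tolerance = 1e-9)
  expect_true(all(v0[13:101] == 0))
  expect_error(binding_vector(integer(0), 101), "no hits")
  expect_error(binding_vector(200, 101), "0, n_dmr")
})

test_that("L1 distances: identical vectors 0, disjoint support 2, oracle match", {
  p1 <- binding_vector(c(10, 20), 200)
  p2 <- binding_vector(c(10, 20), 200)
  p3 <- binding_vector(c(150, 170), 200)
  D <- binding_distance_matrix(rbind(a = p1, b = p2, c = p3))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 2, tolerance = 1e-12)
  expect_identical(diag(D), c(a = 0, b = 0, c = 0))
  # two single-hit profiles 3 bp apart: direct grid-evaluation oracle
  q1 <- binding_vector(100, 300); q2 <- binding_vector(103, 300)
  grid <- 0:299
  g <- function(p) {
    x <- ifelse(abs(grid - p) <= 10, dnorm(grid, p, 5), 0)
    x / sum(x)
  }
  expect_equal(binding_distance_matrix(rbind(q1, q2))[1, 2],
               sum(abs(g(100) - g(103))), tolerance = 1e-12)
  expect_error(binding_distance_matrix(list(p1, c(p1, 0))), "unequal")
})

test_that("L1 distances stay in [0,2] and satisfy the triangle inequality", {
  set.seed(14)
  for (r in 1:20) {
    prof <- do.call(rbind, lapply(1:6, function(i)
      binding_vector(sample(0:199, sample(1:4, 1)), 200)))
    D <- binding_distance_matrix(prof)
    expect_true(all(D >= 0 & D <= 2 + 1e-12))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("near-duplicate elimination leaves no close pairs and logs drops", {
  set.seed(15)
  prof <- do.call(rbind, lapply(c(10, 10, 100, 150), function(p)
    binding_vector(p, 300)))
  rownames(prof) <- paste0("t", 1:4)
  D <- binding_distance_matrix(prof)
  expect_lt(D["t1", "t2"], 0.1)
  el <- eliminate_near_duplicates(D, 0.1, seed = 1)
  expect_length(el$kept, 3)
  expect_identical(nrow(el$log), 1L)
  expect_true(el$log$dropped %in% c("t1", "t2"))
  Dk <- D[el$kept, el$kept]
  expect_gte(min(Dk[upper.tri(Dk)]), 0.1)
  # no close pair: everything retained, empty log
  el2 <- eliminate_near_duplicates(D[2:4, 2:4], 0.1, seed = 1)
  expect_length(el2$kept, 3)
  expect_identical(nrow(el2$log), 0L)
})

test_that("a clique of near-duplicates collapses to one survivor for any seed", {
  prof <- do.call(rbind, lapply(c(50, 50, 50, 50, 200, 260), function(p)
    binding_vector(p, 400)))
  rownames(prof) <- paste0("t", 1:6)
  D <- binding_distance_matrix(prof)
  for (sd in 1:100) {
    el <- eliminate_near_duplicates(D, 0.1, seed = sd)
    expect_length(intersect(el$kept, paste0("t", 1:4)), 1)
    expect_true(all(c("t5", "t6") %in% el$kept))
  }
})

test_that("proximity test: planted disjoint halves give SS near 1 and p = 0", {
  prof <- do.call(rbind, c(
    lapply(c(48, 50, 52, 54), function(p) binding_vector(p, 400)),
    lapply(c(348, 350, 352, 354), function(p) binding_vector(p, 400))))
  rownames(prof) <- paste0("t", 1:8)
  labels <- setNames(rep(c("A", "B"), each = 4), rownames(prof))
  D <- binding_distance_matrix(prof)
  res <- proximity_test(D, labels, n_perm = 2000, seed = 2)
  expect_true(res$testable)
  expect_gt(res$observed_ss, 0.6)
  expect_identical(res$p, 0)
  # constant labels: untestable flag, not an error
  res2 <- proximity_test(D, setNames(rep("A", 8), rownames(prof)),
                         n_perm = 100, seed = 2)
  expect_false(res2$testable)
  expect_true(is.na(res2$p))
})

test_that("proximity p is invariant to label renaming and joint permutation", {
  set.seed(16)
  prof <- do.call(rbind, lapply(1:8, function(i)
    binding_vector(sample(0:390, 2), 400)))
  rownames(prof) <- paste0("t", 1:8)
  D <- binding_distance_matrix(prof)
  labels <- setNames(rep(c("A", "B"), 4), rownames(prof))
  r1 <- proximity_test(D, labels, n_perm = 500, seed = 3)
  relabeled <- setNames(c(A = "X", B = "Y")[labels], names(labels))
  r2 <- proximity_test(D, relabeled, n_perm = 500, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$observed_ss, r2$observed_ss)
  perm <- sample(8)
  r3 <- proximity_test(D[perm, perm], labels[perm], n_perm = 500, seed = 3)
  expect_equal(r3$observed_ss, r1$observed_ss, tolerance = 1e-12)
})

test_that("the DMR panel is reproducible and flags untestable DMRs", {
  seqs <- small_seqs()
  labels <- seqs$truth$tf_cluster_labels
  p1 <- run_dmr_panel(seqs$dmrs[1:3], seqs$pfms, labels, n_perm = 200,
                      seed = 4)
  p2 <- run_dmr_panel(seqs$dmrs[1:3], seqs$pfms, labels, n_perm = 200,
                      seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$testable))
  expect_true(all(p1$n_retained >= 2))
  # empty panel
  p0 <- run_dmr_panel(character(0), seqs$pfms, labels, n_perm = 10,
                      seed = 1)
  expect_identical(nrow(p0), 0L)
  # a DMR with no motif content is untestable
  p3 <- run_dmr_panel(c(empty = strrep("AT", 250)), seqs$pfms, labels,
                      n_perm = 10, seed = 1)
  expect_false(p3$testable[1])
})

test_that("wide community separation gives strong significance per DMR", {
  cfg <- sim_config(n_genes = 40, n_tfs = 16, n_dmrs = 6,
                    cluster_separation = 100, seed = 17)
  sim <- simulate_counts(cfg)
  seqs <- simulate_motifs_and_sequences(cfg, sim$truth)
  panel <- run_dmr_panel(seqs$dmrs, seqs$pfms,
                         seqs$truth$tf_cluster_labels, n_perm = 1000,
                         seed = 5)
  expect_true(all(panel$p < 0.01))
  expect_true(all(panel$observed_ss > 0.3))
  expect_identical(unique(panel$stars[panel$p < 0.001]), "***")
})
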