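test_that("signed adjacency follows the closed form", {
  # cor 1 -> 1, cor -1 -> 0, cor 0 -> 2^-12
  s <- seq(0, 3, length.out = 8)
  x <- rbind(a = s, b = s * 2 + 1, c = rev(s))
  a <- signed_adjacency(x, beta = 12)
  expect_equal(unname(a["a", "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(a["a", "c"]), 0, tolerance = 1e-12)
  expect_equal(diag(a), c(a = 1, b = 1, c = 1))
  set.seed(2)
  y <- matrix(rnorm(4 * 10), 4, dimnames = list(letters[1:4], NULL))
  r <- cor(t(y))
  expect_equal(signed_adjacency(y, 12), ((1 + r) / 2)^12 + diag(4) -
                 diag(diag(((1 + r) / 2)^12)), tolerance = 1e-12)
  y[1, ] <- 3
  expect_error(signed_adjacency(y), "zero-variance")
})

test_that("topological overlap matches the brute-force oracle", {
  # closed-form corners
  a1 <- matrix(1, 4, 4)
  expect_true(all(abs(topological_overlap(a1) - 1) < 1e-12))
  a0 <- diag(2)  # isolated pair: no direct edge, no shared neighbours
  expect_equal(topological_overlap(a0)[1, 2], 0)
  # 3x3 worked example against the independent triple loop
  a3 <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  expect_equal(topological_overlap(a3), tom_oracle(a3), tolerance = 1e-14)
  expect_error(topological_overlap(matrix(c(1, .2, .5, 1), 2)),
               "symmetric")
})

test_that("module eigengene matches an SVD oracle and fixes its sign", {
  set.seed(5)
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  eg <- module_eigengene(X, rownames(X))
  sv <- svd(t(scale(t(X))))
  v <- sv$v[, 1]
  if (cor(v, colMeans(t(scale(t(X))))) < 0) v <- -v
  expect_equal(unname(eg$eigengene), v, tolerance = 1e-10)
  expect_equal(eg$explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  # k identical genes: explained variance 1
  Xi <- X[rep(1, 3), ]; rownames(Xi) <- c("a", "b", "c")
  egi <- module_eigengene(Xi, rownames(Xi))
  expect_equal(egi$explained, 1, tolerance = 1e-12)
  expect_gt(cor(egi$eigengene, Xi[1, ]), 0.999)
  expect_error(module_eigengene(X, "g1"), "at least 2")
})

test_that("explained variance does not increase when noise genes are added", {
  sim <- small_sim()
  v <- normalize_counts(sim$counts)$values
  labs <- sim$truth$gene_module_labels
  core <- names(labs)[labs == "M1"][1:40]
  noise <- names(labs)[labs == "M3"][1:20]  # unrelated module as noise
  e1 <- module_eigengene(v, core)$explained
  e2 <- module_eigengene(v, c(core, noise))$explained
  expect_lte(e2, e1 + 1e-10)
})

test_that("two planted blocks are cut into exactly two modules", {
  set.seed(7)
  n_per <- 50; n_samp <- 40
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  X <- rbind(
    t(replicate(n_per, f1 * 2 + rnorm(n_samp, sd = 0.2))),
    t(replicate(n_per, f2 * 2 + rnorm(n_samp, sd = 0.2))))
  rownames(X) <- sprintf("g%03d", seq_len(2 * n_per))
  tom <- topological_overlap(signed_adjacency(X))
  asg <- cut_modules(tom, X, min_module_size = 30)
  truth <- rep(c("A", "B"), each = n_per)
  expect_length(setdiff(unique(asg), "unassigned"), 2)
  expect_equal(ari(asg, truth), 1)
})

test_that("structureless overlap leaves genes unassigned", {
  set.seed(8)
  ok <- 0; runs <- 20
  for (r in seq_len(runs)) {
    n <- 100
    tom <- matrix(runif(n * n, 0, 0.05), n)
    tom <- (tom + t(tom)) / 2; diag(tom) <- 1
    rownames(tom) <- colnames(tom) <- sprintf("g%03d", 1:n)
    X <- matrix(rnorm(n * 10), n, dimnames = list(rownames(tom), NULL))
    asg <- suppressWarnings(cut_modules(tom, X, min_module_size = 30))
    if (all(asg == "unassigned")) ok <- ok + 1
  }
  expect_gte(ok / runs, 0.95)
})

test_that("modules whose factors nearly coincide are merged", {
  set.seed(9)
  n_samp <- 60
  f <- rnorm(n_samp)
  f2 <- 0.97 * f + sqrt(1 - 0.97^2) * rnorm(n_samp)  # cor ~ 0.97 > 0.85
  X <- rbind(
    t(replicate(40, f * 2 + rnorm(n_samp, sd = 0.2))),
    t(replicate(40, f2 * 2 + rnorm(n_samp, sd = 0.2))))
  rownames(X) <- sprintf("g%03d", 1:80)
  tom <- topological_overlap(signed_adjacency(X))
  asg <- cut_modules(tom, X, min_module_size = 30, merge_height = 0.15)
  expect_length(setdiff(unique(asg), "unassigned"), 1)
})

test_that("module cut is invariant to gene input order", {
  sim <- small_sim()
  v <- normalize_counts(sim$counts)$values
  tom <- topological_overlap(signed_adjacency(v))
  asg <- cut_modules(tom, v)
  set.seed(10)
  perm <- sample(nrow(v))
  tomp <- tom[perm, perm]
  asgp <- cut_modules(tomp, v[perm, ])
  expect_equal(ari(asg[names(asgp)], asgp), 1)
})

test_that("stimulation ANOVA finds planted shifts and a null interaction", {
  sim <- small_sim()
  cm <- sim$counts
  v <- normalize_counts(cm)$values
  labs <- sim$truth$gene_module_labels
  E <- eigengene_matrix(v, labs)
  for (m in rownames(E)) {
    tst <- eigengene_interaction_test(E[m, ], cm$samples)
    expect_lt(tst$stim_p, 0.01)       # every module is TT-shifted by design
  }
  # interaction p approximately uniform across null replicates
  set.seed(11)
  n_sub <- 24
  subjects <- sprintf("S%02d", 1:n_sub)
  samples <- data.frame(
    sample = paste(rep(subjects, each = 2), c("NS", "TT"), sep = "_"),
    subject = rep(subjects, each = 2),
    group = rep(rep(c("control", "asthma"), c(14, 10)), each = 2),
    condition = rep(c("NS", "TT"), n_sub), stringsAsFactors = FALSE)
  ps <- replicate(200, {
    y <- setNames(rnorm(nrow(samples)), samples$sample)
    eigengene_interaction_test(y, samples)$interaction_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # degenerate input errors
  y0 <- setNames(rep(1, nrow(samples)), samples$sample)
  expect_error(eigengene_interaction_test(y0, samples), "zero variance")
})

test_that("module connectivity network flags planted sign structure", {
  sim <- small_sim()
  v <- normalize_counts(sim$counts)$values
  E <- eigengene_matrix(v, sim$truth$gene_module_labels)
  net <- module_network(E, sim$counts$samples, "control",
                        condition = "TT")
  expect_true(all(net$q >= net$p))
  # self-correlation sanity via a duplicated module row
  E2 <- rbind(E, dup = -E[1, ])
  net2 <- module_network(E2, sim$counts$samples, "control",
                         condition = "TT")
  row <- net2[net2$m1 == "M1" & net2$m2 == "dup", ]
  expect_equal(row$r, -1, tolerance = 1e-12)
  expect_identical(row$sign, "negative")
  expect_true(row$significant)
})

# Global normalization removes the shared module-factor component, so the
# recoverable inter-module correlation structure is the mean-centred
# projection of the planted one: cov2cor(P Sigma P') with P = I - 11'/M.
proj_sigma <- function(S) {
  M <- nrow(S)
  P <- diag(M) - 1 / M
  cov2cor(P %*% S %*% P + 1e-9 * diag(M))
}

test_that("significant module edges carry the projected planted signs", {
  agree <- 0L; total <- 0L
  for (sd in c(3, 21, 22)) {
    cfg <- sim_config(n_genes = 400, n_tfs = 16, n_modules = 4, seed = sd)
    sim <- simulate_counts(cfg)
    v <- normalize_counts(sim$counts)$values
    E <- eigengene_matrix(v, sim$truth$gene_module_labels)
    for (g in c("control", "asthma")) {
      St <- proj_sigma(if (g == "control") sim$truth$sigma_control else
        sim$truth$sigma_case)
      net <- module_network(E, sim$counts$samples, g, condition = "TT")
      idx <- cbind(as.integer(sub("M", "", net$m1)),
                   as.integer(sub("M", "", net$m2)))
      strong <- net$significant & abs(St[idx]) > 0.15
      agree <- agree + sum(sign(net$r[strong]) == sign(St[idx][strong]))
      total <- total + sum(strong)
    }
  }
  expect_gt(total, 3)
  expect_gt(agree / total, 0.9)
})

test_that("planted correlation flips shift group networks in the right direction", {
  tot <- 0L; good <- 0L
  for (sd in 31:36) {
    cfg <- sim_config(n_genes = 600, n_tfs = 16, n_modules = 8,
                      flip_fraction = 0.3, n_subjects_control = 60,
                      n_subjects_case = 60, seed = sd)
    sim <- simulate_counts(cfg, rho = 0.45)
    v <- normalize_counts(sim$counts)$values
    E <- eigengene_matrix(v, sim$truth$gene_module_labels)
    nets <- lapply(c(control = "control", asthma = "asthma"),
                   function(g) module_network(E, sim$counts$samples, g,
                                              condition = "TT"))
    Sc <- proj_sigma(sim$truth$sigma_control)
    Sa <- proj_sigma(sim$truth$sigma_case)
    idx <- cbind(as.integer(sub("M", "", nets$control$m1)),
                 as.integer(sub("M", "", nets$control$m2)))
    disc <- sign(Sc[idx]) != sign(Sa[idx]) &
      pmin(abs(Sc[idx]), abs(Sa[idx])) > 0.25
    if (any(disc)) {
      hit <- sign(nets$control$r - nets$asthma$r)[disc] ==
        sign(Sc[idx] - Sa[idx])[disc]
      tot <- tot + length(hit); good <- good + sum(hit)
    }
  }
  expect_gt(tot, 0)
  expect_gte(good / tot, 0.8)
})

test_that("degree centrality ranks a star hub first with declared tie-breaks", {
  edges <- data.frame(a = c("h", "h", "h", "h"),
                      b = c("l1", "l2", "l3", "l4"), weight = 1)
  cen <- module_centrality(c("h", paste0("l", 1:4)), edges)
  expect_identical(cen$gene[1], "h")
  expect_equal(cen$degree[1], 4)
  expect_true(all(cen$degree[-1] == 1))
  # complete graph: lexicographic order
  cg <- t(combn(c("a", "b", "c"), 2))
  cen2 <- module_centrality(c("a", "b", "c"),
                            data.frame(a = cg[, 1], b = cg[, 2]))
  expect_identical(cen2$gene, c("a", "b", "c"))
  # hand-enumerated 6-node graph
  e6 <- data.frame(
    a = c("u", "u", "u", "v", "v", "w"),
    b = c("v", "w", "x", "w", "y", "z"), weight = c(1, 1, 1, 1, 1, 1))
  cen6 <- module_centrality(c("u", "v", "w", "x", "y", "z"), e6)
  deg <- setNames(cen6$degree, cen6$gene)
  expect_equal(deg[c("u", "v", "w", "x", "y", "z")],
               c(u = 3, v = 3, w = 3, x = 1, y = 1, z = 1))
  expect_warning(module_centrality(c("q1", "q2"), e6), "empty")
})
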