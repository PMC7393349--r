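# Shared fixtures, generated once per test run.

# small paired two-group simulation with planted modules
small_sim <- local({
  cache <- NULL
  function(seed = 3, n_genes = 300, ...) {
    key <- paste(seed, n_genes)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    cfg <- sim_config(n_genes = n_genes, n_tfs = 16, n_modules = 4,
                      seed = seed, ...)
    value <- c(simulate_counts(cfg), list(cfg = cfg))
    cache <<- list(key = key, value = value)
    value
  }
})

# sequence-level fixture (motifs, promoters, dmrs) on top of small_sim
small_seqs <- local({
  cache <- NULL
  function(seed = 3, n_genes = 60, ...) {
    key <- paste(seed, n_genes)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    cfg <- sim_config(n_genes = n_genes, n_tfs = 16, n_modules = 4,
                      seed = seed, ...)
    sim <- simulate_counts(cfg)
    seqs <- simulate_motifs_and_sequences(cfg, sim$truth)
    value <- c(seqs, list(cfg = cfg, counts = sim$counts))
    cache <<- list(key = key, value = value)
    value
  }
})

# adjusted Rand index between two labelings (chance-corrected agreement)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force topological overlap oracle (triple loop, independent of the
# matrix-algebra implementation)
tom_oracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# planted shift-pattern fixture: two TF communities with opposite
# module-shift sign patterns plus noise
planted_shift_matrix <- function(n_tfs = 16, n_modules = 4, delta = 1,
                                 noise_sd = 0.25, seed = 1) {
  set.seed(seed)
  pattern <- rep(c(delta, -delta), each = n_modules / 2)
  comm <- rep(c("A", "B"), each = n_tfs / 2)
  S <- t(vapply(seq_len(n_tfs), function(i) {
    sgn <- if (comm[i] == "A") 1 else -1
    sgn * pattern + rnorm(n_modules, sd = noise_sd)
  }, numeric(n_modules)))
  dimnames(S) <- list(sprintf("TF%02d", seq_len(n_tfs)),
                      sprintf("M%d", seq_len(n_modules)))
  list(shift = S, community = setNames(comm, rownames(S)))
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}
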