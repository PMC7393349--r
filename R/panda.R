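## Message-passing regulatory network inference integrating a motif prior,
## a TF-TF interaction prior, and gene-gene co-expression.

#' Z-score normalize a network matrix
#'
#' Standardizes every entry by the overall mean and SD of the matrix.
#'
#' @param M finite numeric matrix.
#' @return matrix of the same shape with overall mean 0 and SD 1.
#' @export
zscore_network <- function(M) {
  if (!all(is.finite(M))) stop("matrix has non-finite entries", call. = FALSE)
  s <- stats::sd(M)
  if (s == 0) stop("constant matrix cannot be z-score normalized",
                   call. = FALSE)
  (M - mean(M)) / s
}

#' Continuous Tanimoto similarity
#'
#' `S_ij = <x_i, y_j> / sqrt(||x_i||^2 + ||y_j||^2 - |<x_i, y_j>|)` between
#' the rows of `X` and the columns of `Y`. Pairs where the denominator is
#' zero (both vectors zero) are defined as 0.
#'
#' @param X,Y numeric matrices with `ncol(X) == nrow(Y)`.
#' @return `nrow(X)` x `ncol(Y)` similarity matrix.
#' @export
tanimoto <- function(X, Y) {
  if (ncol(X) != nrow(Y)) stop("inner dimensions disagree", call. = FALSE)
  ip <- X %*% Y
  nx <- rowSums(X^2)
  ny <- colSums(Y^2)
  den2 <- outer(nx, ny, "+") - abs(ip)
  den <- sqrt(pmax(den2, 0))
  out <- ip / den
  out[den == 0] <- 0
  out
}

# Reference diagonal damping: set the diagonal to (off-diagonal column SD) *
# dim * exp(2 * alpha * step), preventing self-similarity from dominating
# the P / C self-updates.
update_diagonal <- function(M, alpha, step) {
  n <- nrow(M)
  idx <- seq(1, n * n, by = n + 1)
  M[idx] <- NA
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0  # n = 1 edge case
  M[idx] <- sds * n * exp(2 * alpha * step)
  M
}

#' Assemble PANDA-style inputs
#'
#' Z-score normalizes the motif prior, the TF-TF interaction prior and the
#' gene-gene co-expression (Pearson correlation of the supplied expression
#' submatrix), checking shape consistency.
#'
#' @param prior TF x gene motif hit-count matrix.
#' @param ppi symmetric TF x TF interaction matrix.
#' @param values genes x samples expression matrix for the samples of one
#'   group x condition; co-expression is computed from it.
#' @return list with normalized `W0`, `P0`, `C0`.
#' @export
panda_inputs <- function(prior, ppi, values) {
  if (!identical(rownames(prior), rownames(ppi)))
    stop("prior and ppi TF universes differ", call. = FALSE)
  if (!isSymmetric(unname(ppi), tol = 1e-8))
    stop("ppi must be symmetric", call. = FALSE)
  genes <- colnames(prior)
  if (!all(genes %in% rownames(values)))
    stop("expression matrix lacks prior genes", call. = FALSE)
  C0 <- stats::cor(t(values[genes, , drop = FALSE]))
  list(W0 = zscore_network(prior), P0 = zscore_network(ppi),
       C0 = zscore_network(C0))
}

#' Fit a regulatory network by message passing
#'
#' Iterates the message-passing updates: responsibility
#' `R = tanimoto(P, W)`, availability `A = tanimoto(W, C)`,
#' `W <- (1 - alpha) W + alpha (R + A) / 2`; then the TF-cooperativity
#' matrix `P` and the co-expression matrix `C` are moved toward
#' `tanimoto(W, t(W))` and `tanimoto(t(W), W)` respectively, with the
#' reference diagonal damping. Stops when `mean(|dW|) < tol` or after
#' `max_iter` iterations.
#'
#' @param inputs list from [panda_inputs()] (normalized `W0`, `P0`, `C0`).
#' @param alpha update step size in (0, 1].
#' @param tol convergence threshold on the mean absolute change of `W`.
#' @param max_iter iteration cap.
#' @return a `panda_network`: list with `W` (TF x gene edge weights,
#'   z-score scale), `iterations`, `convergence` (final mean |dW|),
#'   `converged`.
#' @export
panda_fit <- function(inputs, alpha = 0.1, tol = 1e-3, max_iter = 200) {
  stopifnot(alpha >= 0, alpha <= 1)  # alpha = 0 degenerates to W0
  W <- inputs$W0; P <- inputs$P0; C <- inputs$C0
  conv <- NA_real_; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    R <- tanimoto(P, W)
    A <- tanimoto(W, C)
    Wnew <- (1 - alpha) * W + alpha * (R + A) / 2
    conv <- mean(abs(Wnew - W))
    W <- Wnew
    if (conv < tol) { converged <- TRUE; break }
    Pnew <- update_diagonal(tanimoto(W, t(W)), alpha, it)
    P <- (1 - alpha) * P + alpha * Pnew
    Cnew <- update_diagonal(tanimoto(t(W), W), alpha, it)
    C <- (1 - alpha) * C + alpha * Cnew
  }
  if (!converged)
    warning("message passing did not converge in ", max_iter,
            " iterations (final mean |dW| = ", signif(conv, 3), ")")
  structure(list(W = W, iterations = it, convergence = conv,
                 converged = converged, alpha = alpha, tol = tol),
            class = "panda_network")
}

#' @export
print.panda_network <- function(x, ...) {
  cat("panda_network:", nrow(x$W), "TFs x", ncol(x$W), "genes;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(mean |dW| = %.2g)\n", x$convergence))
  invisible(x)
}

#' Fit the four group x condition networks
#'
#' Fits one network per (group, condition) with shared motif and
#' interaction priors but condition- and group-specific co-expression,
#' mirroring the four-network experimental design.
#'
#' @param prior TF x gene motif hit-count matrix.
#' @param ppi TF x TF interaction matrix.
#' @param expr an `expression_matrix` from [normalize_counts()].
#' @param genes genes to include (default: all prior columns).
#' @param ... passed to [panda_fit()].
#' @return named list of `panda_network` objects
#'   (`control_NS`, `control_TT`, `asthma_NS`, `asthma_TT`).
#' @export
panda_four_networks <- function(prior, ppi, expr, genes = colnames(prior),
                                ...) {
  prior <- prior[, genes, drop = FALSE]
  nets <- list()
  for (g in c("control", "asthma")) {
    for (cond in c("NS", "TT")) {
      cols <- expr$samples$sample[expr$samples$group == g &
                                    expr$samples$condition == cond]
      ins <- panda_inputs(prior, ppi, expr$values[, cols, drop = FALSE])
      nets[[paste(g, cond, sep = "_")]] <- panda_fit(ins, ...)
    }
  }
  nets
}
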