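#' Count matrix with paired-sample metadata
#'
#' Container for a genes x samples integer count matrix plus per-sample
#' metadata. Validates the paired design the pipeline assumes: each subject
#' has exactly one unstimulated (NS) and one stimulated (TT) sample, and the
#' two groups are disjoint sets of subjects.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample`, `subject`, `group`
#'   (control/asthma), `condition` (NS/TT), one row per column of `counts`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene ids as rownames", call. = FALSE)
  need <- c("sample", "subject", "group", "condition")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!identical(colnames(counts), samples$sample))
    stop("colnames(counts) must equal samples$sample in order",
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!all(samples$condition %in% c("NS", "TT")))
    stop("condition must be NS or TT", call. = FALSE)
  tab <- table(samples$subject, samples$condition)
  if (!all(tab == 1))
    stop("every subject needs exactly one NS and one TT sample",
         call. = FALSE)
  grp <- unique(samples[, c("subject", "group")])
  if (anyDuplicated(grp$subject))
    stop("groups must be disjoint: a subject appears in both groups",
         call. = FALSE)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  groups:", paste(names(table(x$samples$group)),
                         table(x$samples$group) / 2, collapse = ", "),
      "subjects\n")
  invisible(x)
}

#' Median-of-ratios normalization with log2 transform
#'
#' Computes size factors by the median-of-ratios method (each sample's
#' median ratio to the per-gene geometric-mean reference, computed over
#' genes with no zero count) and returns `log2(count / size_factor + 1)`.
#' This is the pipeline's declared stand-in for a variance-stabilizing
#' transform; it is pluggable (any matrix of the same shape can feed the
#' downstream stages).
#'
#' @param cm a [count_matrix()].
#' @return list with `values` (normalized matrix, same dimnames),
#'   `size_factors`, `samples` metadata, and a `transform` provenance note.
#' @export
normalize_counts <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "), call. = FALSE)
  nz <- rowSums(counts == 0) == 0
  if (!any(nz))
    stop("no gene with nonzero counts in every sample; cannot form the ",
         "median-of-ratios reference", call. = FALSE)
  log_ref <- rowMeans(log(counts[nz, , drop = FALSE]))
  sf <- apply(counts[nz, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_ref)))
  sf <- sf / exp(mean(log(sf)))  # geometric mean 1 (scale equivariance)
  values <- log2(sweep(counts, 2, sf, "/") + 1)
  structure(list(values = values, size_factors = sf, samples = cm$samples,
                 transform = "median-of-ratios size factors; log2(x/sf + 1)"),
            class = "expression_matrix")
}

#' Paired differential expression within one group
#'
#' For each gene, tests the per-subject normalized TT - NS difference
#' against zero with a paired (one-sample) t-test; the log2 fold change is
#' the mean paired difference. Benjamini-Hochberg correction is applied
#' across the genes tested within this group.
#'
#' @param expr an `expression_matrix` from [normalize_counts()].
#' @param group group label to test ("control" or "asthma").
#' @return data.frame with `gene`, `lfc`, `p`, `q`, `direction`.
#' @export
paired_de <- function(expr, group) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$samples
  if (!group %in% meta$group)
    stop("group '", group, "' not present in sample metadata",
         call. = FALSE)
  meta <- meta[meta$group == group, ]
  subjects <- unique(meta$subject)
  if (length(subjects) < 3)
    stop("need at least 3 subjects in group '", group, "'", call. = FALSE)
  tt <- meta$sample[meta$condition == "TT"][match(subjects,
          meta$subject[meta$condition == "TT"])]
  ns <- meta$sample[meta$condition == "NS"][match(subjects,
          meta$subject[meta$condition == "NS"])]
  d <- expr$values[, tt, drop = FALSE] - expr$values[, ns, drop = FALSE]
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  # degenerate: all differences identical
  p[s == 0 & m == 0] <- 1
  p[s == 0 & m != 0] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr$values), lfc = m, p = p, q = q,
             direction = ifelse(m > 0, "up", ifelse(m < 0, "down", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Union of perturbed genes across two groups
#'
#' @param de_control,de_case results of [paired_de()] on the same gene
#'   universe.
#' @param q_threshold FDR threshold; a gene is selected if `q <
#'   q_threshold` in either group.
#' @return character vector of selected gene ids (sorted).
#' @export
select_perturbed_union <- function(de_control, de_case, q_threshold = 0.05) {
  if (!setequal(de_control$gene, de_case$gene))
    stop("mismatched gene universes between the two DE results",
         call. = FALSE)
  sel <- union(de_control$gene[de_control$q < q_threshold],
               de_case$gene[de_case$q < q_threshold])
  sort(sel)
}
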