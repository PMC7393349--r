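## Motif scanning: PFM -> PWM conversion, promoter extraction, relative-score
## scanning of both strands, and the TF x gene hit-count prior.

#' Convert a position frequency matrix to a log-odds PWM
#'
#' `PWM[b, j] = log2(((count[b, j] + pseudo * bg[b]) / (colsum_j + pseudo))
#' / bg[b])` with a total pseudocount distributed by the background
#' composition.
#'
#' @param pfm 4 x L non-negative count matrix with rownames A, C, G, T.
#' @param pseudocount total pseudocount added per column.
#' @param background base composition (must sum to 1).
#' @return 4 x L numeric PWM.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25,
                                      T = 0.25)) {
  stopifnot(nrow(pfm) == 4, all(rownames(pfm) == c("A", "C", "G", "T")),
            all(pfm >= 0), abs(sum(background) - 1) < 1e-8)
  cs <- colSums(pfm)
  if (any(cs == 0)) stop("PFM column with zero total count", call. = FALSE)
  freq <- sweep(pfm + pseudocount * background, 2, cs + pseudocount, "/")
  pwm <- log2(freq / background)
  dimnames(pwm) <- dimnames(pfm)
  pwm
}

#' Consensus sequence of a PFM
#' @param pfm 4 x L count matrix.
#' @return character consensus (ties resolved toward the first base in
#'   A,C,G,T order).
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

# reverse complement of a character sequence (non-ACGT preserved as N)
revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

#' Extract a strand-aware promoter window
#'
#' For a + strand TSS at position `tss` (0-based) the window is
#' `[tss - upstream, tss + downstream)`; for a - strand TSS it is the
#' reverse complement of `[tss - downstream, tss + upstream)`. Windows are
#' truncated at the sequence ends with a warning.
#'
#' @param sequence character scalar (the chromosome / scaffold sequence).
#' @param tss 0-based TSS position within `sequence`.
#' @param strand "+" or "-".
#' @param upstream,downstream window extent in bp (defaults 1000 and 200).
#' @return character promoter sequence, 5' to 3' relative to the gene.
#' @export
extract_promoter <- function(sequence, tss, strand = "+", upstream = 1000,
                             downstream = 200) {
  n <- nchar(sequence)
  if (tss < 0 || tss >= n)
    stop("TSS position ", tss, " outside sequence of length ", n,
         call. = FALSE)
  if (strand == "+") {
    from <- tss - upstream; to <- tss + downstream  # [from, to)
  } else if (strand == "-") {
    from <- tss - downstream; to <- tss + upstream
  } else stop("strand must be '+' or '-'", call. = FALSE)
  cf <- max(0, from); ct <- min(n, to)
  if (cf != from || ct != to)
    warning("promoter window truncated at sequence boundary")
  win <- substr(sequence, cf + 1, ct)
  if (strand == "-") win <- revcomp(win)
  win
}

# map sequence to integer codes 1..4 (A,C,G,T), NA otherwise
seq_codes <- function(sequence) {
  lookup <- rep(NA_integer_, 256)
  lookup[utf8ToInt("A")] <- 1L; lookup[utf8ToInt("a")] <- 1L
  lookup[utf8ToInt("C")] <- 2L; lookup[utf8ToInt("c")] <- 2L
  lookup[utf8ToInt("G")] <- 3L; lookup[utf8ToInt("g")] <- 3L
  lookup[utf8ToInt("T")] <- 4L; lookup[utf8ToInt("t")] <- 4L
  lookup[utf8ToInt(sequence)]
}

# raw window scores of a PWM along integer-coded sequence; NA where the
# window contains a non-ACGT base
pwm_window_scores <- function(pwm, codes) {
  L <- ncol(pwm)
  nw <- length(codes) - L + 1
  if (nw < 1) return(numeric(0))
  s <- numeric(nw)
  for (j in seq_len(L)) s <- s + pwm[, j][codes[j:(j + nw - 1)]]
  s
}

#' Scan a sequence with a PFM at a relative-score threshold
#'
#' Scores every window on both strands with the log-odds PWM and reports
#' windows whose min-max-normalized score `(score - min) / (max - min)`
#' reaches `threshold` ("80% maximum accuracy" by default). `max`/`min` are
#' the sums of the per-position column extrema. Positions are 0-based starts
#' on the forward strand; minus-strand hits are found by scanning with the
#' reverse-complemented PWM so no coordinate flipping is needed. Windows
#' containing non-ACGT characters are skipped and tallied.
#'
#' @param pfm 4 x L count matrix (rownames A,C,G,T).
#' @param sequence character scalar.
#' @param threshold relative-score threshold in `[0, 1]`.
#' @param mode "relative" (min-max normalized, default) or "max_fraction"
#'   (score / max score).
#' @param pseudocount,background passed to [pfm_to_pwm()].
#' @return data.frame `start` (0-based), `strand`, `score`,
#'   `relative_score`; attribute `skipped` counts windows skipped for
#'   non-ACGT content.
#' @export
scan_pfm <- function(pfm, sequence, threshold = 0.8,
                     mode = c("relative", "max_fraction"),
                     pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25,
                                    T = 0.25)) {
  mode <- match.arg(mode)
  pwm <- pfm_to_pwm(pfm, pseudocount, background)
  L <- ncol(pwm)
  if (nchar(sequence) < L)
    stop("sequence shorter than motif", call. = FALSE)
  codes <- seq_codes(sequence)
  pwm_rc <- pwm[4:1, L:1, drop = FALSE]  # minus-strand scan on fwd coords
  rownames(pwm_rc) <- rownames(pwm)
  smax <- sum(apply(pwm, 2, max)); smin <- sum(apply(pwm, 2, min))
  rel <- function(s) {
    if (mode == "relative") (s - smin) / (smax - smin) else s / smax
  }
  rows <- list(); skipped <- 0L
  for (str in c("+", "-")) {
    s <- pwm_window_scores(if (str == "+") pwm else pwm_rc, codes)
    skipped <- skipped + sum(is.na(s))
    rs <- rel(s)
    keep <- which(!is.na(rs) & rs >= threshold)
    if (length(keep))
      rows[[str]] <- data.frame(start = keep - 1L, strand = str,
                                score = s[keep], relative_score = rs[keep],
                                stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), strand = character(0),
               score = numeric(0), relative_score = numeric(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Build the TF x gene motif hit-count prior
#'
#' `prior[t, g]` = number of windows in gene g's promoter scoring at or
#' above the relative-score threshold for TF t's motif (both strands;
#' overlapping hits all count).
#'
#' @param pfms named list of PFMs (a `pfm_set` or plain list).
#' @param promoters named character vector of promoter sequences (names =
#'   gene ids).
#' @param threshold relative-score threshold.
#' @param ... passed to [scan_pfm()].
#' @return integer matrix TFs x genes. Genes with missing (NA/empty)
#'   promoters are excluded with a message.
#' @export
build_prior <- function(pfms, promoters, threshold = 0.8, ...) {
  bad <- is.na(promoters) | nchar(promoters) == 0
  if (any(bad)) {
    message("excluding ", sum(bad), " gene(s) with missing promoters")
    promoters <- promoters[!bad]
  }
  genes <- names(promoters)
  prior <- matrix(0L, length(pfms), length(genes),
                  dimnames = list(names(pfms), genes))
  for (t in names(pfms)) {
    for (g in genes) {
      prior[t, g] <- nrow(scan_pfm(pfms[[t]], promoters[[g]], threshold,
                                   ...))
    }
  }
  prior
}
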