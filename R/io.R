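## Plain-text interchange: counts/samples TSV, JASPAR flat PFMs, FASTA,
## BED, edge lists, matrix TSV, JSON manifests. Every writer/reader pair
## round-trips content exactly for well-formed inputs.

#' @export
#' @rdname dysnet_io
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_counts_tsv <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene")
    stop(counts_path, ": first column must be 'gene'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)))
    stop(counts_path, ": missing cell at line ",
         which(rowSums(is.na(m)) > 0)[1] + 1, call. = FALSE)
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  count_matrix(m, samples)
}

#' @export
#' @rdname dysnet_io
write_samples_tsv <- function(samples, path) {
  utils::write.table(samples[, c("sample", "subject", "group", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write interchange formats
#'
#' Readers and writers for the pipeline's plain-text formats: counts and
#' sample-metadata TSV, JASPAR flat-format PFMs (`>ID NAME` header plus
#' four `A [ ... ]` count rows), FASTA, BED (0-based half-open), weighted
#' edge lists, numeric matrix TSV, and JSON manifests.
#'
#' @param path,counts_path,samples_path file paths.
#' @param cm,samples,pfms,seqs,bed,edges,M,x objects to write.
#' @name dysnet_io
NULL

#' @export
#' @rdname dysnet_io
write_jaspar <- function(pfms, path) {
  ids <- attr(pfms, "ids")
  if (is.null(ids)) ids <- sprintf("MA%04d.1", seq_along(pfms))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(pfms)) {
    cat(">", ids[i], " ", names(pfms)[i], "\n", sep = "", file = con)
    m <- pfms[[i]]
    for (b in c("A", "C", "G", "T"))
      cat(b, " [", paste(sprintf("%6d", m[b, ]), collapse = " "), " ]\n",
          sep = "", file = con)
  }
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_jaspar <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop(path, ": no JASPAR records found", call. = FALSE)
  pfms <- list(); ids <- character(0)
  for (i in seq_along(hdr)) {
    h <- lines[hdr[i]]
    parts <- strsplit(sub("^>", "", h), "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) parts[2] else parts[1]
    rows <- lines[hdr[i] + 1:4]
    parsed <- lapply(rows, function(r) {
      cleaned <- sub("^[ACGTacgt]", "", r)
      nums <- regmatches(cleaned, gregexpr("[0-9.]+", cleaned))[[1]]
      if (!length(nums))
        stop(path, ": malformed count row after header '", h, "': ", r,
             call. = FALSE)
      as.numeric(nums)
    })
    if (length(unique(lengths(parsed))) != 1)
      stop(path, ": ragged count rows after header '", h, "'",
           call. = FALSE)
    m <- do.call(rbind, parsed)
    rownames(m) <- c("A", "C", "G", "T")
    pfms[[name]] <- m
    ids <- c(ids, id)
  }
  attr(pfms, "ids") <- ids
  class(pfms) <- "pfm_set"
  pfms
}

#' @export
#' @rdname dysnet_io
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80)
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @export
#' @rdname dysnet_io
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(ncol(df))]
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(path, ": malformed BED line ",
         which(is.na(df$start) | is.na(df$end))[1], call. = FALSE)
  df
}

#' @export
#' @rdname dysnet_io
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @export
#' @rdname dysnet_io
write_matrix_tsv <- function(M, path, id_col = "id") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)))
    stop(path, ": missing cell at line ",
         which(rowSums(is.na(m)) > 0)[1] + 1, call. = FALSE)
  rownames(m) <- df[[1]]
  m
}

# symmetric matrix from a tf_a/tf_b/weight edge list
edges_to_matrix <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  M <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    M[edges[[1]][r], edges[[2]][r]] <- edges[[3]][r]
    M[edges[[2]][r], edges[[1]][r]] <- edges[[3]][r]
  }
  diag(M) <- 1
  M
}

matrix_to_edges <- function(M, names = c("tf_a", "tf_b", "weight")) {
  idx <- which(upper.tri(M), arr.ind = TRUE)
  out <- data.frame(rownames(M)[idx[, 1]], colnames(M)[idx[, 2]],
                    M[idx], stringsAsFactors = FALSE)
  stats::setNames(out, names)
}

#' @export
#' @rdname dysnet_io
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
#' @rdname dysnet_io
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
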