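#' Canonical form of a DNA word
#'
#' The canonical k-mer is the lexicographic minimum of a word and its reverse
#' complement, so counting is strand-independent.
#'
#' @param word Character vector of DNA words (A/C/G/T only).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize("GAT")  # "ATC"
#' @export
canonicalize <- function(word) {
  if (any(grepl("[^ACGT]", word))) {
    stop("canonicalize: word contains non-ACGT characters")
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(word)))
  ifelse(word <= rc, word, rc)
}

#' Count canonical k-mers on one chromosome
#'
#' Slides a width-k window with step 1; windows containing N are skipped;
#' counts accumulate on canonical forms. For an N-free sequence the counts
#' sum to L - k + 1.
#'
#' @param seq A single sequence: character scalar or `DNAString`/length-1
#'   `DNAStringSet`.
#' @param k Word length (default 13).
#' @return Named integer vector of counts, names in lexicographic order.
#' @export
count_kmers <- function(seq, k = 13L) {
  seq <- .as_seq_char(seq)
  cpp_count_kmers(seq, as.integer(k))
}

.as_seq_char <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  if (is(seq, "DNAString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq
}

#' High-copy canonical k-mers of a genome
#'
#' Single streaming pass over all chromosomes; returns the canonical k-mers
#' whose genome-wide total count is at least `N_min`. This is the pruning
#' pass that keeps the density matrix small: at k = 13 a random word is
#' expected well under once per 10 Mb, so almost only repetitive words
#' survive a floor of 100.
#'
#' @param genome A `DNAStringSet` (see [load_genome]).
#' @param k Word length.
#' @param N_min Genome-wide minimum total count (default 100).
#' @return Character vector of canonical k-mers, lexicographic order.
#' @export
high_copy_kmers <- function(genome, k = 13L, N_min = 100L) {
  stopifnot(N_min >= 1)
  cpp_high_copy_kmers(as.character(genome), as.integer(k), as.numeric(N_min))
}

#' Build the k-mer density matrix
#'
#' Assembles counts into a canonical k-mer x chromosome matrix with
#' normalized views: `densities = (count + pseudocount) / length` in
#' copies/bp, and `log_densities = log10(densities)`. The pseudocount
#' (default 1) keeps log densities finite for subgenome-absent markers;
#' effect sizes elsewhere stay on the raw count scale.
#'
#' @param genome A `DNAStringSet`.
#' @param k Word length.
#' @param restrict_to Optional character vector of canonical k-mers: only
#'   these rows are built (zero rows are retained for absent k-mers). Without
#'   it every observed k-mer becomes a row — only sensible for small genomes.
#' @param pseudocount Non-negative integer added to counts before
#'   normalization (default 1).
#' @return A `kmer_matrix` object: list with `k`, `kmers`, `counts`
#'   (integer matrix), `lengths`, `pseudocount`, `densities`,
#'   `log_densities`. Rows are in lexicographic k-mer order; columns follow
#'   the genome's chromosome order.
#' @export
build_kmer_matrix <- function(genome, k = 13L, restrict_to = NULL,
                              pseudocount = 1L) {
  stopifnot(length(genome) >= 1L, pseudocount >= 0)
  k <- as.integer(k)
  ids <- names(genome)
  lens <- Biostrings::width(genome)
  names(lens) <- ids
  if (is.null(restrict_to)) {
    percol <- lapply(as.character(genome), cpp_count_kmers, k = k)
    kmers <- sort(unique(unlist(lapply(percol, names), use.names = FALSE)))
    counts <- matrix(0L, nrow = length(kmers), ncol = length(ids),
                     dimnames = list(kmers, ids))
    for (j in seq_along(percol)) {
      counts[names(percol[[j]]), j] <- percol[[j]]
    }
  } else {
    kmers <- sort(unique(as.character(restrict_to)))
    if (length(kmers) && any(kmers != canonicalize(kmers))) {
      stop("restrict_to contains non-canonical k-mers")
    }
    counts <- vapply(as.character(genome), cpp_count_restricted,
                     integer(length(kmers)), k = k, kmers = kmers)
    if (length(kmers) == 1L) counts <- matrix(counts, nrow = 1L)
    dimnames(counts) <- list(kmers, ids)
  }
  dens <- sweep(counts + pseudocount, 2L, lens, "/")
  structure(
    list(k = k, kmers = kmers, counts = counts, lengths = lens,
         pseudocount = as.integer(pseudocount),
         densities = dens, log_densities = log10(dens)),
    class = "kmer_matrix"
  )
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("kmer_matrix: k =", x$k, "|", nrow(x$counts), "canonical k-mers x",
      ncol(x$counts), "chromosomes (pseudocount", x$pseudocount, ")\n")
  invisible(x)
}

#' Subset a k-mer matrix to a set of k-mers
#' @param matrix A `kmer_matrix`.
#' @param kmers Canonical k-mers to keep (order ignored; rows stay sorted).
#' @return A `kmer_matrix` with the selected rows.
#' @export
subset_kmer_matrix <- function(matrix, kmers) {
  keep <- sort(intersect(matrix$kmers, kmers))
  out <- matrix
  out$kmers <- keep
  for (f in c("counts", "densities", "log_densities")) {
    out[[f]] <- matrix[[f]][keep, , drop = FALSE]
  }
  out
}

#' Export / import the count matrix as TSV
#'
#' Rows are canonical k-mers, columns chromosome ids, integer cells. A
#' sidecar header (comment lines) records k, pseudocount and chromosome
#' lengths so densities can be rebuilt on import.
#'
#' @param matrix A `kmer_matrix`.
#' @param path Output TSV path.
#' @return `path` invisibly (`write`), or a rebuilt `kmer_matrix` (`read`).
#' @export
write_kmer_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# k=", matrix$k),
    paste0("# pseudocount=", matrix$pseudocount),
    paste0("# lengths=", paste(names(matrix$lengths), matrix$lengths,
                               sep = ":", collapse = ","))
  ), con)
  df <- data.frame(kmer = matrix$kmers, matrix$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_matrix
#' @export
read_kmer_matrix <- function(path) {
  hdr <- readLines(path, n = 3L)
  if (!all(startsWith(hdr, "# "))) stop("missing k-mer matrix header")
  val <- function(key) sub(paste0("# ", key, "="), "", hdr[startsWith(hdr, paste0("# ", key))])
  k <- as.integer(val("k"))
  pseudocount <- as.integer(val("pseudocount"))
  lf <- strsplit(strsplit(val("lengths"), ",")[[1]], ":")
  lens <- setNames(as.numeric(vapply(lf, `[`, "", 2L)),
                   vapply(lf, `[`, "", 1L))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 3L,
                          check.names = FALSE, colClasses = "character")
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$kmer
  counts <- counts[order(rownames(counts)), names(lens), drop = FALSE]
  dens <- sweep(counts + pseudocount, 2L, lens, "/")
  structure(
    list(k = k, kmers = rownames(counts), counts = counts, lengths = lens,
         pseudocount = pseudocount, densities = dens,
         log_densities = log10(dens)),
    class = "kmer_matrix"
  )
}
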