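#' Marker-discovery parameters
#'
#' @param N_min Genome-wide minimum total copy number (default 100).
#' @param F Fold-enrichment factor within a homoeologous group (default 2).
#' @param quorum Minimum number of homoeologous groups in which a k-mer must
#'   show enrichment; default NULL means "all considered groups". Relaxing to
#'   x - 1 tolerates a single outlier chromosome (e.g. a poorly assembled
#'   homoeolog).
#' @return A `marker_params` list.
#' @export
marker_params <- function(N_min = 100L, F = 2, quorum = NULL) {
  stopifnot(N_min >= 1, F > 1, is.null(quorum) || quorum >= 1)
  structure(list(N_min = as.integer(N_min), F = F,
                 quorum = if (is.null(quorum)) NULL else as.integer(quorum)),
            class = "marker_params")
}

#' High-copy filter on a built matrix
#'
#' Keeps k-mers whose summed raw counts over all chromosomes are at least
#' `N_min`. (For genome-scale inputs prefer [high_copy_kmers], which prunes
#' before the matrix is built.)
#'
#' @param matrix A `kmer_matrix` built over the full genome.
#' @param N_min Minimum total count.
#' @return Character vector of retained canonical k-mers.
#' @export
high_copy_filter <- function(matrix, N_min = 100L) {
  matrix$kmers[rowSums(matrix$counts) >= N_min]
}

#' Within-group fold enrichment
#'
#' A k-mer has a winner in a homoeologous group iff some member's
#' pseudocounted density is at least `F` times the density of at least one
#' other member (equivalently: max >= F * min). The winner is the member of
#' maximal density; ties break to the first-listed member and are flagged.
#' Densities (not raw counts) are compared because homoeologs differ in
#' length.
#'
#' @param matrix A `kmer_matrix`.
#' @param group Character vector of p chromosome ids (matrix columns).
#' @param F Fold factor.
#' @return data.frame with columns `kmer`, `winner` (chromosome id or NA),
#'   `tied` (logical).
#' @export
group_enrichment <- function(matrix, group, F = 2) {
  stopifnot(all(group %in% colnames(matrix$densities)))
  d <- matrix$densities[, group, drop = FALSE]
  hi <- apply(d, 1L, max)
  lo <- apply(d, 1L, min)
  has <- hi >= F * lo
  widx <- apply(d, 1L, which.max)  # first-listed on ties
  tied <- apply(d, 1L, function(r) sum(r == max(r)) > 1L)
  data.frame(
    kmer = matrix$kmers,
    winner = ifelse(has, group[widx], NA_character_),
    tied = has & tied,
    stringsAsFactors = FALSE
  )
}

#' Select candidate subgenome-enriched k-mers
#'
#' Applies the three discovery conditions: (1) high copy number genome-wide
#' (enforced upstream via `N_min`), (2) >= F-fold enrichment of one homoeolog
#' over at least one other member within a group, (3) such enrichment in at
#' least `quorum` of the considered groups. Condition (3) with quorum >= 2
#' discards chromosome-private expansions (e.g. pericentromeric blooms on a
#' single chromosome), which cannot unite chromosomes into a subgenome.
#'
#' @param matrix A `kmer_matrix`, normally already restricted to high-copy
#'   k-mers. Rows failing `params$N_min` on their raw counts are dropped.
#' @param design A [polyploid_design]; `bootstrap_groups` restricts which
#'   groups are considered.
#' @param params A [marker_params].
#' @return A `candidate_set`: list with `kmers` (character),
#'   `per_group_winners` (data.frame kmer/group/winner/tied),
#'   `n_groups_enriched` (named integer), `params`.
#' @export
select_candidates <- function(matrix, design, params = marker_params()) {
  groups <- design$groups[design$bootstrap_groups]
  n_considered <- length(groups)
  quorum <- if (is.null(params$quorum)) n_considered else params$quorum
  if (quorum > n_considered) {
    stop("quorum (", quorum, ") exceeds the number of considered groups (",
         n_considered, ")")
  }
  keep <- rowSums(matrix$counts) >= params$N_min
  m <- subset_kmer_matrix(matrix, matrix$kmers[keep])
  per_group <- lapply(seq_along(groups), function(i) {
    ge <- group_enrichment(m, groups[[i]], params$F)
    ge$group <- design$bootstrap_groups[i]
    ge
  })
  winners <- do.call(rbind, per_group)
  winners <- winners[!is.na(winners$winner), , drop = FALSE]
  n_enr <- table(factor(winners$kmer, levels = m$kmers))
  sel <- names(n_enr)[n_enr >= quorum]
  structure(
    list(
      kmers = sel,
      per_group_winners = winners[winners$kmer %in% sel,
                                  c("kmer", "group", "winner", "tied")],
      n_groups_enriched = setNames(as.integer(n_enr[sel]), sel),
      params = params
    ),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", length(x$kmers), "candidate marker k-mers\n")
  invisible(x)
}

#' Export candidates as TSV
#'
#' Columns: kmer, n_groups_enriched, winners (comma-joined group:chromosome).
#'
#' @param candidates A `candidate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  w <- candidates$per_group_winners
  joined <- vapply(candidates$kmers, function(km) {
    sub <- w[w$kmer == km, , drop = FALSE]
    sub <- sub[order(sub$group), , drop = FALSE]
    paste(sub$group, sub$winner, sep = ":", collapse = ",")
  }, "")
  df <- data.frame(kmer = candidates$kmers,
                   n_groups_enriched = candidates$n_groups_enriched[candidates$kmers],
                   winners = joined)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
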