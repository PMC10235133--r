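#' Correlation distance between two profiles
#'
#' `1 - r` with r the Pearson correlation; the distance used for both
#' chromosome and k-mer dendrograms. Ranges over [0, 2].
#'
#' @param a,b Numeric vectors of equal length >= 2, non-constant.
#' @return `1 - cor(a, b)`.
#' @export
correlation_distance <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("correlation distance undefined for a constant profile")
  }
  1 - cor(a, b)
}

#' Cluster chromosomes on marker log-densities and extract the partition
#'
#' Agglomerative clustering of chromosome columns of the candidate-restricted
#' log-density matrix, using 1 - Pearson r as distance. The tree is cut into
#' p clusters and cluster labels become subgenome labels. This is a
#' similarity clustering, not a phylogeny.
#'
#' Where the cut violates the one-member-per-group rule, members of the
#' offending group are re-assigned by nearest cluster centroid (1 - r),
#' choosing the label permutation of minimum total distance within the
#' group; a chromosome whose best correlation to any centroid is below
#' `min_assign_r` is declared unassigned. This is an automated stand-in for
#' completing marginal assignments by expert inspection.
#'
#' @param matrix A `kmer_matrix` restricted to candidate k-mers.
#' @param design A [polyploid_design].
#' @param p Number of subgenomes (default `design$p`).
#' @param linkage "complete" (default) or "average".
#' @param min_assign_r Minimum centroid correlation to accept a rescued
#'   assignment (default 0.2).
#' @return A `clustering_result`: `chromosome_tree`, `kmer_tree` (hclust),
#'   `partition` ([subgenome_partition]), `cophenetic_heights`,
#'   `heatmap_matrix` (filled by [export_heatmap]).
#' @export
cluster_chromosomes <- function(matrix, design, p = design$p,
                                linkage = c("complete", "average"),
                                min_assign_r = 0.2) {
  linkage <- match.arg(linkage)
  X <- matrix$log_densities
  if (nrow(X) < 2L) stop("insufficient markers: need at least 2 candidate k-mers")
  if (ncol(X) < p) stop("need at least p chromosomes to cut into p clusters")
  keep_rows <- apply(X, 1L, sd) > 0
  Xc <- X[keep_rows, , drop = FALSE]
  if (nrow(Xc) < 2L) stop("insufficient markers: need at least 2 candidate k-mers")
  dchrom <- as.dist(1 - cor(Xc))
  chrom_tree <- hclust(dchrom, method = linkage)
  kmer_tree <- hclust(as.dist(1 - cor(t(Xc))), method = linkage)
  cl <- cutree(chrom_tree, k = p)

  centroid <- function(lab) rowMeans(Xc[, cl == lab, drop = FALSE])
  cents <- vapply(seq_len(p), centroid, numeric(nrow(Xc)))

  assignment <- cl
  flags <- character()
  unassigned <- character()
  perms <- .permutations(p)
  for (g in design$groups) {
    g_in <- intersect(g, colnames(Xc))
    lab <- assignment[g_in]
    if (length(g_in) == length(g) && !anyDuplicated(lab)) next
    # violation: choose the distinct-label permutation minimizing total 1-r
    rmat <- cor(Xc[, g_in, drop = FALSE], cents)  # members x p
    best <- NULL; best_cost <- Inf
    for (pi in seq_len(nrow(perms))) {
      idx <- perms[pi, seq_along(g_in)]
      cost <- sum(1 - rmat[cbind(seq_along(g_in), idx)])
      if (cost < best_cost) { best_cost <- cost; best <- idx }
    }
    for (i in seq_along(g_in)) {
      id <- g_in[i]
      if (rmat[i, best[i]] < min_assign_r) {
        unassigned <- c(unassigned, id)
        assignment <- assignment[names(assignment) != id]
        flags[id] <- "unassigned_low_correlation"
      } else {
        if (assignment[id] != best[i]) flags[id] <- "reassigned_nearest_centroid"
        assignment[id] <- best[i]
      }
    }
  }

  part <- subgenome_partition(assignment, p, unassigned = unassigned,
                              flags = flags)
  structure(
    list(chromosome_tree = chrom_tree, kmer_tree = kmer_tree,
         partition = part, cophenetic_heights = chrom_tree$height,
         log_densities = Xc),
    class = "clustering_result"
  )
}

.permutations <- function(p) {
  if (p == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(p - 1L)
  out <- NULL
  for (i in seq_len(p)) {
    rest <- setdiff(seq_len(p), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), p - 1L)))
  }
  unname(out)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("clustering_result (similarity clustering, 1 - Pearson r):\n")
  print(x$partition)
  invisible(x)
}

#' Row-scaled heatmap matrix with dendrogram ordering
#'
#' Each k-mer row of the log-density matrix is standardized to mean 0, sd 1
#' (rows with sd below `eps` become zero rows); rows are ordered by the
#' k-mer dendrogram, columns by the chromosome dendrogram — the layout of a
#' row-scaled clustered heatmap.
#'
#' @param result A `clustering_result`.
#' @param eps Standard-deviation guard (default 1e-12).
#' @return List with `matrix` (scaled, reordered), `row_order`, `col_order`.
#' @export
export_heatmap <- function(result, eps = 1e-12) {
  X <- result$log_densities
  mu <- rowMeans(X)
  s <- apply(X, 1L, sd)
  Z <- (X - mu) / ifelse(s < eps, Inf, s)
  ro <- result$kmer_tree$order
  co <- result$chromosome_tree$order
  list(matrix = Z[ro, co, drop = FALSE],
       row_order = rownames(X)[ro],
       col_order = colnames(X)[co])
}

#' Export a dendrogram as Newick
#' @param tree An `hclust` (heights = merge distances).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}

#' Write the partition table as TSV (chromosome, subgenome, flag)
#' @param partition A [subgenome_partition].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  ids <- c(names(partition$assignment), partition$unassigned)
  df <- data.frame(
    chromosome = ids,
    subgenome = c(paste0("SG", partition$assignment),
                  rep(NA_character_, length(partition$unassigned))),
    flag = ifelse(ids %in% names(partition$flags),
                  partition$flags[ids], "")
  )
  df <- df[order(df$chromosome), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1.0 means identical up to
#' label permutation. Used to score recovered partitions against simulation
#' truth.
#'
#' @param a,b Label vectors over the same items (names matched when present).
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
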