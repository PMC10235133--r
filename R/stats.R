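#' Per-k-mer one-way ANOVA and Tukey HSD across subgenomes
#'
#' For each k-mer, log10 pseudocounted densities of the assigned chromosomes
#' are grouped by subgenome; a one-way ANOVA F statistic is computed and
#' every pair of subgenomes is compared with the Tukey–Kramer statistic
#' \deqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}
#' with the p-value taken from the studentized-range distribution with `p`
#' groups and `df = N - p` error degrees of freedom (the standard
#' studentized-range tail; by definition a one-sided test — no extra
#' halving/doubling). Confidence intervals are at the 95% family level.
#' Unassigned chromosomes are excluded.
#'
#' Effect sizes are reported on two scales: the tested log10-density scale
#' (`mean_diff`) and the raw mean count/chromosome scale
#' (`mean_diff_count`) used for volcano plots.
#'
#' @param matrix A `kmer_matrix` (rows = the k-mers to test).
#' @param partition A [subgenome_partition]; every subgenome needs >= 2
#'   assigned chromosomes.
#' @param conf_level Family confidence level for the intervals (default 0.95).
#' @return A `tukey_table`: list with `kmers`, `anova_F`, `df_error`,
#'   `n_groups`, `labels`, `degenerate` (logical: zero MSE), and `contrasts`
#'   — a long data.frame (kmer, pair, mean_diff, mean_diff_count, ci_low,
#'   ci_high, p_raw, p_bonferroni = NA until [bonferroni]).
#' @export
anova_tukey <- function(matrix, partition, conf_level = 0.95) {
  asn <- partition$assignment
  labs <- sort(unique(asn))
  p <- length(labs)
  if (p < 2L) stop("need at least 2 subgenomes")
  groups <- lapply(labs, function(s) names(asn)[asn == s])
  n_g <- lengths(groups)
  if (any(n_g < 2L)) {
    stop("every subgenome needs >= 2 chromosomes; SG",
         paste(labs[n_g < 2L], collapse = ", SG"), " has fewer")
  }
  chroms <- unlist(groups)
  N <- length(chroms)
  df_error <- N - p

  Y <- matrix$log_densities[, chroms, drop = FALSE]
  Cn <- matrix$counts[, chroms, drop = FALSE]
  gm <- vapply(groups, function(g) rowMeans(Y[, g, drop = FALSE]),
               numeric(nrow(Y)))
  gm_cnt <- vapply(groups, function(g) rowMeans(Cn[, g, drop = FALSE]),
                   numeric(nrow(Y)))
  if (nrow(Y) == 1L) { gm <- matrix(gm, 1L); gm_cnt <- matrix(gm_cnt, 1L) }
  grand <- rowSums(gm %*% diag(n_g, p)) / N
  fitted <- gm[, rep(seq_len(p), n_g), drop = FALSE]
  ssw <- rowSums((Y - fitted)^2)
  ssb <- rowSums(sweep((gm - grand)^2, 2L, n_g, "*"))
  mse <- ssw / df_error
  degen <- mse <= 0
  anova_F <- ifelse(degen, ifelse(ssb > 0, Inf, NaN),
                    (ssb / (p - 1)) / mse)

  qcrit <- qtukey(conf_level, p, df_error)
  rows <- list()
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    diff <- gm[, i] - gm[, j]
    se <- sqrt((mse / 2) * (1 / n_g[i] + 1 / n_g[j]))
    q <- abs(diff) / se
    p_raw <- ptukey(q, p, df_error, lower.tail = FALSE)
    p_raw[degen] <- ifelse(diff[degen] != 0, 0, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      kmer = matrix$kmers,
      pair = paste0("SG", labs[i], "-SG", labs[j]),
      mean_diff = diff,
      mean_diff_count = gm_cnt[, i] - gm_cnt[, j],
      ci_low = diff - qcrit * se,
      ci_high = diff + qcrit * se,
      p_raw = p_raw,
      p_bonferroni = NA_real_,
      row.names = NULL
    )
  }
  structure(
    list(kmers = matrix$kmers,
         anova_F = setNames(anova_F, matrix$kmers),
         df_error = df_error, n_groups = p, labels = labs,
         degenerate = setNames(degen, matrix$kmers),
         contrasts = do.call(rbind, rows)),
    class = "tukey_table"
  )
}

#' @export
print.tukey_table <- function(x, ...) {
  cat("tukey_table:", length(x$kmers), "k-mers,", x$n_groups,
      "subgenomes, df =", x$df_error, "\n")
  invisible(x)
}

#' Bonferroni correction over the tested k-mer family
#'
#' `p_bonferroni = min(1, m * p_raw)`. The family size `m` is the number of
#' k-mers tested genome-wide (all k-mers passing the N_min floor), not just
#' the quorum candidates.
#'
#' @param tab A `tukey_table`.
#' @param m Family size (>= 1). Defaults to the number of k-mers in `tab`.
#' @return The table with `p_bonferroni` filled in and `m` recorded.
#' @export
bonferroni <- function(tab, m = length(tab$kmers)) {
  stopifnot(m >= 1)
  tab$contrasts$p_bonferroni <- pmin(1, tab$contrasts$p_raw * m)
  tab$m <- m
  tab
}

#' Assign each k-mer to a marker class
#'
#' The class of a marker is the subset S of subgenomes it is enriched on:
#' the unique non-empty proper subset such that every contrast between a
#' member of S and a non-member is significant with the S side higher, and
#' no contrast between two members of S is significant. Combination classes
#' (e.g. SG1+SG2) record repetitive activity shared through an intermediate
#' polyploid ancestor. "none" when no subset qualifies.
#'
#' @param tab A `tukey_table` after [bonferroni].
#' @param alpha Significance threshold on corrected p (default 0.05).
#' @return Named character vector, k-mer -> class label
#'   ("SG1", "SG1+SG2", ..., or "none").
#' @export
assign_class <- function(tab, alpha = 0.05) {
  if (all(is.na(tab$contrasts$p_bonferroni))) {
    stop("run bonferroni() before assign_class()")
  }
  labs <- tab$labels
  p <- length(labs)
  cts <- tab$contrasts
  # per-kmer significance and direction, pair-indexed
  pairs <- unique(cts$pair)
  sig <- matrix(cts$p_bonferroni < alpha, ncol = length(pairs))
  dir <- matrix(sign(cts$mean_diff), ncol = length(pairs))
  # pair "SGi-SGj" -> (i, j) positions in labs
  pij <- do.call(rbind, lapply(strsplit(sub("^SG", "", pairs), "-SG"),
                               as.integer))
  pij <- cbind(match(pij[, 1L], labs), match(pij[, 2L], labs))

  subsets <- unlist(lapply(seq_len(p - 1L), function(sz)
    utils::combn(seq_len(p), sz, simplify = FALSE)), recursive = FALSE)

  classify_one <- function(krow) {
    s_sig <- sig[krow, ]; s_dir <- dir[krow, ]
    ok_sets <- Filter(function(S) {
      for (q in seq_along(pairs)) {
        i <- pij[q, 1L]; j <- pij[q, 2L]
        ii <- i %in% S; jj <- j %in% S
        if (ii && jj) { if (s_sig[q]) return(FALSE) }
        else if (ii && !jj) { if (!s_sig[q] || s_dir[q] <= 0) return(FALSE) }
        else if (!ii && jj) { if (!s_sig[q] || s_dir[q] >= 0) return(FALSE) }
      }
      TRUE
    }, subsets)
    if (length(ok_sets) == 0L) return("none")
    # deterministic: smallest qualifying subset, then lexicographic
    sizes <- lengths(ok_sets)
    ok_sets <- ok_sets[sizes == min(sizes)]
    keys <- vapply(ok_sets, paste, "", collapse = "+")
    S <- ok_sets[[order(keys)[1L]]]
    paste0("SG", labs[S], collapse = "+")
  }
  setNames(vapply(seq_along(tab$kmers), classify_one, ""), tab$kmers)
}

#' Merged-hit density of markers on their enriched subgenome
#'
#' For each k-mer, the merged coverage (bp) of its exact hits on the
#' chromosomes of a subgenome set, per Mb of that set's total length.
#'
#' @param kmers Canonical k-mers.
#' @param genome A `DNAStringSet`.
#' @param partition A [subgenome_partition].
#' @param subgenomes Subgenome label set (integer vector) defining the
#'   target chromosomes.
#' @return Named numeric vector, bp per Mb.
#' @export
marker_density_per_mb <- function(kmers, genome, partition, subgenomes) {
  chroms <- names(partition$assignment)[partition$assignment %in% subgenomes]
  sub <- genome[chroms]
  total_mb <- sum(Biostrings::width(sub)) / 1e6
  vapply(kmers, function(km) {
    h <- locate_markers(sub, km)
    sum(vapply(h$hits, function(ir) sum(IRanges::width(ir)), numeric(1))) / total_mb
  }, numeric(1))
}

#' Filter classified markers by merged-hit density
#'
#' Keeps markers whose merged hit coverage on their enriched subgenome(s) is
#' at least `density_floor` bp per Mb of those subgenomes' total length.
#' A floor of 0 is a no-op. Used to discard statistically significant but
#' physically negligible markers (e.g. a 1 kb/Mb floor).
#'
#' @param classes Named character vector from [assign_class].
#' @param genome A `DNAStringSet`.
#' @param partition A [subgenome_partition].
#' @param density_floor bp per Mb (default 0).
#' @return The subset of `classes` passing the floor ("none" entries drop).
#' @export
density_filter <- function(classes, genome, partition, density_floor = 0) {
  classes <- classes[classes != "none"]
  if (density_floor <= 0 || length(classes) == 0L) return(classes)
  keep <- vapply(seq_along(classes), function(i) {
    sgs <- as.integer(sub("^SG", "", strsplit(classes[i], "+", fixed = TRUE)[[1]]))
    d <- marker_density_per_mb(names(classes)[i], genome, partition, sgs)
    d >= density_floor
  }, logical(1))
  classes[keep]
}

#' Volcano table for one subgenome pair
#'
#' One row per k-mer: effect size = difference of mean raw counts per
#' chromosome between the two subgenomes, and -log10 Bonferroni-corrected
#' Tukey p.
#'
#' @param tab A `tukey_table` after [bonferroni].
#' @param pair Pair label, e.g. "SG1-SG2".
#' @return data.frame (kmer, effect_size, neg_log10_p).
#' @export
volcano_table <- function(tab, pair) {
  cts <- tab$contrasts[tab$contrasts$pair == pair, , drop = FALSE]
  if (nrow(cts) == 0L) {
    stop("unknown subgenome pair '", pair, "'; available: ",
         paste(unique(tab$contrasts$pair), collapse = ", "))
  }
  data.frame(kmer = cts$kmer,
             effect_size = cts$mean_diff_count,
             neg_log10_p = -log10(cts$p_bonferroni),
             row.names = NULL)
}

#' Write the full statistics table as TSV
#'
#' Long format: kmer, pair, mean_diff (log10 density), mean_diff_count,
#' ci_low, ci_high, p_raw, p_bonferroni, anova_F, class_label.
#'
#' @param tab A `tukey_table` after [bonferroni].
#' @param path Output path.
#' @param classes Optional result of [assign_class].
#' @return `path`, invisibly.
#' @export
write_stats <- function(tab, path, classes = NULL) {
  df <- tab$contrasts
  df$anova_F <- tab$anova_F[df$kmer]
  df$class_label <- if (is.null(classes)) NA_character_ else classes[df$kmer]
  df <- df[order(df$kmer, df$pair), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
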