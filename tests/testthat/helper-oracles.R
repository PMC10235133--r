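# Independent oracles used to freeze expected values. Each is a deliberately
# naive implementation, kept free of the code paths it checks.

# random DNA of length n, optionally salted with Ns
random_dna <- function(n, n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (n_prob > 0) {
    idx <- which(runif(n) < n_prob)
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# brute-force canonical k-mer counting by explicit window enumeration
naive_count_kmers <- function(seq, k) {
  L <- nchar(seq)
  counts <- new.env(parent = emptyenv())
  if (k >= 1 && k <= L) {
    for (i in seq_len(L - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      rc <- revcomp_chr(w)
      canon <- if (w <= rc) w else rc
      prev <- counts[[canon]]
      counts[[canon]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  keys <- sort(ls(counts))
  stats::setNames(vapply(keys, function(k2) counts[[k2]], integer(1)), keys)
}

# P(Q <= q) for the studentized range by direct numeric quadrature:
# outer integral over the scaled chi variable s (S^2 ~ chi^2_df / df),
# inner integral = CDF of the range of k standard normals at q*s.
ptukey_quadrature <- function(q, k, df) {
  range_cdf <- function(w) {
    f <- function(z) stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-11,
                         subdivisions = 400L)$value
  }
  s_density <- function(s) {
    exp((df / 2) * log(df) + (df - 1) * log(s) - df * s^2 / 2 -
          lgamma(df / 2) - (df / 2 - 1) * log(2))
  }
  f_outer <- function(s) vapply(s, function(si) s_density(si) *
                                  range_cdf(q * si), numeric(1))
  stats::integrate(f_outer, 0, Inf, rel.tol = 1e-9,
                   subdivisions = 400L)$value
}

# exhaustive maximum-probability path over all |states|^T assignments
enumerate_viterbi <- function(spec, symbols) {
  p <- length(spec$states)
  Tn <- length(symbols)
  grid <- do.call(expand.grid, rep(list(seq_len(p)), Tn))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    path <- spec$states[as.integer(grid[r, ])]
    lp <- path_logprob(spec, path, symbols)
    if (lp > best) { best <- lp; best_path <- path }
  }
  list(path = best_path, logprob = best)
}

# tiny FASTA writer for fixtures built in code
write_fasta_lines <- function(named_seqs, path) {
  lines <- unlist(lapply(names(named_seqs), function(id)
    c(paste0(">", id), named_seqs[[id]])))
  writeLines(lines, path)
  path
}

# map clustered labels onto true subgenome names by majority vote
label_map <- function(assignment, truth_df) {
  truth <- stats::setNames(truth_df$subgenome, truth_df$chromosome)
  tapply(truth[names(assignment)], assignment,
         function(x) names(sort(table(x), decreasing = TRUE))[1])
}
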