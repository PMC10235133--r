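# build a kmer_matrix directly from a named list of per-chromosome log10
# densities (one k-mer row per list entry not needed: rows given as matrix)
stats_matrix <- function(logdens, counts = NULL) {
  cols <- colnames(logdens)
  if (is.null(counts)) {
    counts <- matrix(0L, nrow(logdens), ncol(logdens),
                     dimnames = dimnames(logdens))
  }
  structure(list(k = 13L, kmers = rownames(logdens), counts = counts,
                 lengths = stats::setNames(rep(1e6, length(cols)), cols),
                 pseudocount = 1L, densities = 10^logdens,
                 log_densities = logdens),
            class = "kmer_matrix")
}

even_partition <- function(n_chrom, p) {
  ids <- sprintf("c%02d", seq_len(n_chrom))
  subgenome_partition(stats::setNames(rep(seq_len(p), each = n_chrom / p),
                                      ids), p)
}

random_logdens <- function(n_kmer, part, group_means, sd = 0.2) {
  ids <- names(part$assignment)
  X <- t(vapply(seq_len(n_kmer), function(i)
    rnorm(length(ids), group_means[part$assignment], sd),
    numeric(length(ids))))
  kmers <- sort(unique(canonicalize(vapply(seq_len(n_kmer), function(i)
    random_dna(13), ""))))[seq_len(n_kmer)]
  dimnames(X) <- list(kmers, ids)
  X
}

test_that("df follows the N - p rule of the case-study designs", {
  # cotton 26 chromosomes / 2 subgenomes; Camelina 20/3; strawberry 28/4;
  # tobacco 24/2
  cases <- list(c(26, 2, 24), c(20, 3, 17), c(28, 4, 24), c(24, 2, 22))
  set.seed(701)
  for (cs in cases) {
    part <- even_partition(cs[1] - (cs[1] %% cs[2]), cs[2])
    # pad uneven designs (Camelina 20 = 3 groups of 6/7/7)
    if (cs[1] %% cs[2] != 0) {
      extra <- sprintf("x%02d", seq_len(cs[1] %% cs[2]))
      part$assignment <- c(part$assignment,
                           stats::setNames(seq_along(extra), extra))
    }
    X <- random_logdens(3, part, group_means = seq_len(cs[2]) * 0)
    tab <- anova_tukey(stats_matrix(X), part)
    expect_equal(tab$df_error, cs[3])
  }
})

test_that("with two groups Tukey p equals the pooled two-sided t-test p", {
  set.seed(702)
  part <- even_partition(12, 2)
  X <- random_logdens(20, part, group_means = c(-6, -5.6), sd = 0.3)
  tab <- anova_tukey(stats_matrix(X), part)
  for (km in tab$kmers) {
    g1 <- X[km, part$assignment == 1]
    g2 <- X[km, part$assignment == 2]
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_lt(abs(tab$contrasts$p_raw[tab$contrasts$kmer == km] -
                    tt$p.value), 1e-9)
  }
})

test_that("Tukey p matches quadrature of the studentized-range CDF", {
  # spot checks here; the full (groups, df, q) grid runs in acceptance
  for (cfg in list(c(3, 15, 3.2), c(4, 24, 5))) {
    k <- cfg[1]; df <- cfg[2]; q <- cfg[3]
    expect_equal(ptukey(q, k, df, lower.tail = FALSE),
                 1 - ptukey_quadrature(q, k, df), tolerance = 1e-6)
  }
})

test_that("anova_tukey agrees with aov/TukeyHSD as an independent route", {
  set.seed(703)
  part <- even_partition(18, 3)
  X <- random_logdens(5, part, group_means = c(-6, -5.5, -4.8), sd = 0.25)
  tab <- anova_tukey(stats_matrix(X), part)
  for (km in tab$kmers) {
    df <- data.frame(y = X[km, ], g = factor(part$assignment))
    th <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
    cts <- tab$contrasts[tab$contrasts$kmer == km, ]
    # TukeyHSD reports "2-1" etc. as group2 - group1
    expect_equal(cts$mean_diff[cts$pair == "SG1-SG2"], -th["2-1", "diff"])
    expect_equal(cts$p_raw[cts$pair == "SG1-SG2"], th["2-1", "p adj"],
                 tolerance = 1e-8)
    expect_equal(cts$p_raw[cts$pair == "SG2-SG3"], th["3-2", "p adj"],
                 tolerance = 1e-8)
    expect_equal(sort(c(cts$ci_low[cts$pair == "SG1-SG2"],
                        cts$ci_high[cts$pair == "SG1-SG2"])),
                 sort(-c(th["2-1", "lwr"], th["2-1", "upr"])),
                 tolerance = 1e-8)
  }
})

test_that("identical values across chromosomes give the degenerate result", {
  part <- even_partition(8, 2)
  X <- matrix(-6, nrow = 1, ncol = 8,
              dimnames = list("AACCGGTTAACCG", names(part$assignment)))
  tab <- anova_tukey(stats_matrix(X), part)
  expect_true(tab$degenerate[[1]])
  expect_equal(tab$contrasts$mean_diff, 0)
  expect_equal(tab$contrasts$p_raw, 1)
  # zero MSE with different means: p = 0
  X2 <- X
  X2[1, part$assignment == 2] <- -5
  tab2 <- anova_tukey(stats_matrix(X2), part)
  expect_true(tab2$degenerate[[1]])
  expect_equal(tab2$contrasts$p_raw, 0)
})

test_that("anova_tukey rejects undersized subgenomes", {
  part <- subgenome_partition(c(a = 1, b = 1, c = 2), p = 2)
  X <- matrix(rnorm(3), 1, 3, dimnames = list("AACCGGTTAACCG",
                                              c("a", "b", "c")))
  expect_error(anova_tukey(stats_matrix(X), part), ">= 2 chromosomes")
})

test_that("bonferroni multiplies and caps", {
  part <- even_partition(8, 2)
  set.seed(704)
  X <- random_logdens(3, part, c(-6, -5), sd = 0.1)
  tab <- anova_tukey(stats_matrix(X), part)
  tab$contrasts$p_raw <- c(1e-8, 0.5, 0.07)
  expect_equal(bonferroni(tab, m = 838357)$contrasts$p_bonferroni,
               c(0.00838357, 1, 1))
  expect_equal(bonferroni(tab, m = 1)$contrasts$p_bonferroni,
               tab$contrasts$p_raw)
})

test_that("assign_class finds the enriched subgenome subset", {
  part <- even_partition(16, 4)  # SG1..SG4 ~ T1, I, T2, V roles
  build_tab <- function(means, sd = 0.05, seed = 705) {
    set.seed(seed)
    X <- random_logdens(1, part, means, sd = sd)
    bonferroni(anova_tukey(stats_matrix(X), part), m = 1)
  }
  # SG1 and SG2 high, SG3 and SG4 low -> combination class SG1+SG2
  expect_equal(unname(assign_class(build_tab(c(-4, -4, -6, -6)))), "SG1+SG2")
  # only SG1 high -> singleton class
  expect_equal(unname(assign_class(build_tab(c(-4, -6, -6, -6)))), "SG1")
  # no significant contrasts -> none
  part2 <- even_partition(8, 2)
  set.seed(706)
  X <- random_logdens(1, part2, c(-6, -6), sd = 0.3)
  tab <- bonferroni(anova_tukey(stats_matrix(X), part2), m = 1)
  expect_equal(unname(assign_class(tab, alpha = 0.05)), "none")
  expect_error(assign_class(anova_tukey(stats_matrix(X), part2)),
               "bonferroni")
})

test_that("volcano_table reports count-scale effects and -log10 p", {
  part <- even_partition(8, 2)
  ids <- names(part$assignment)
  X <- matrix(rep(c(-4, -6), each = 4), nrow = 1,
              dimnames = list("AACCGGTTAACCG", ids))
  counts <- matrix(rep(c(150L, 30L), each = 4), nrow = 1,
                   dimnames = list("AACCGGTTAACCG", ids))
  tab <- bonferroni(anova_tukey(stats_matrix(X, counts), part), m = 10)
  vt <- volcano_table(tab, "SG1-SG2")
  expect_equal(nrow(vt), length(tab$kmers))
  expect_equal(vt$effect_size, 120)  # 150 - 30
  expect_error(volcano_table(tab, "SG1-SG9"), "unknown")
  # p_bonferroni = 1 maps to y = 0
  tab$contrasts$p_bonferroni <- 1
  expect_equal(volcano_table(tab, "SG1-SG2")$neg_log10_p, 0)
})

test_that("p_raw decreases as |mean difference| grows, variance fixed", {
  part <- even_partition(10, 2)
  ids <- names(part$assignment)
  base <- c(rnorm(5, 0, 0) + c(-0.2, -0.1, 0, 0.1, 0.2))
  p_at <- function(delta) {
    X <- matrix(c(base, base + delta), nrow = 1,
                dimnames = list("AACCGGTTAACCG", ids))
    anova_tukey(stats_matrix(X), part)$contrasts$p_raw
  }
  ps <- vapply(c(0.1, 0.3, 0.6, 1, 2), p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("density floor drops markers with thin merged coverage", {
  # marker A tiles chromosome a1/a2 densely; marker B occurs once
  ka <- "ACGTTGCAACGTT"; kb <- "TGCAACGTACGAT"
  mk <- function(n_a, n_b, L) {
    body <- paste0(strrep(paste0(ka, "N"), n_a), strrep(paste0(kb, "N"), n_b))
    paste0(body, strrep("N", L - nchar(body)))
  }
  g <- Biostrings::DNAStringSet(c(a1 = mk(80, 1, 1e5), a2 = mk(80, 1, 1e5),
                                  b1 = mk(0, 1, 1e5), b2 = mk(0, 1, 1e5)))
  part <- subgenome_partition(c(a1 = 1, a2 = 1, b1 = 2, b2 = 2), p = 2)
  classes <- c(stats::setNames("SG1", canonicalize(ka)),
               stats::setNames("SG1", canonicalize(kb)))
  # marker A: 80*13 bp on each of two 0.1-Mb chromosomes -> 5200 bp/Mb
  dens <- marker_density_per_mb(canonicalize(ka), g, part, 1)
  expect_equal(unname(dens), 80 * 13 * 2 / 0.2)
  kept <- density_filter(classes, g, part, density_floor = 1000)
  expect_true(canonicalize(ka) %in% names(kept))
  expect_false(canonicalize(kb) %in% names(kept))
  expect_equal(density_filter(classes, g, part, 0), classes)
})

test_that("power: a 10x density ratio across 2x7 chromosomes survives m = 1e6", {
  set.seed(707)
  part <- even_partition(14, 2)
  hits <- 0L
  n_rep <- 60L  # scaled down from 200 to keep the default run fast
  for (r in seq_len(n_rep)) {
    X <- random_logdens(1, part, group_means = c(-5, -6),
                        sd = 0.2 / log(10))  # ~20% CV on the count scale
    tab <- bonferroni(anova_tukey(stats_matrix(X), part), m = 1e6)
    hits <- hits + (tab$contrasts$p_bonferroni < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("stats TSV export mirrors the long supplementary layout", {
  set.seed(708)
  part <- even_partition(12, 3)
  X <- random_logdens(4, part, c(-6, -5, -4), sd = 0.1)
  tab <- bonferroni(anova_tukey(stats_matrix(X), part), m = 100)
  classes <- assign_class(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats(tab, path, classes)
  got <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_setequal(names(got),
                  c("kmer", "pair", "mean_diff", "mean_diff_count", "ci_low",
                    "ci_high", "p_raw", "p_bonferroni", "anova_F",
                    "class_label"))
  expect_equal(nrow(got), 4 * 3)  # 4 k-mers x 3 pairs
})
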