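# small helper: a kmer_matrix with counts dictated by N-separated marker
# copies, so discovery arithmetic is exact by construction
matrix_from_counts <- function(counts, lengths = NULL) {
  kmers <- rownames(counts)
  stopifnot(all(kmers == canonicalize(kmers)))
  if (is.null(lengths)) lengths <- rep(1e5, ncol(counts))
  k <- nchar(kmers[1])
  seqs <- vapply(seq_len(ncol(counts)), function(j) {
    body <- paste(unlist(lapply(seq_along(kmers), function(i)
      rep(paste0(kmers[i], "N"), counts[i, j]))), collapse = "")
    paste0(body, strrep("N", lengths[j] - nchar(body)))
  }, "")
  g <- Biostrings::DNAStringSet(stats::setNames(seqs, colnames(counts)))
  build_kmer_matrix(g, k = k, restrict_to = kmers)
}

test_that("high_copy_filter applies the >= N_min boundary", {
  counts <- matrix(c(60L, 41L,
                     99L, 0L,
                     1L,  0L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("AACCGGTTAACCG", "ACACACACACACA",
                                     "AAAAAAAAAAAAC"), c("c1", "c2")))
  m <- matrix_from_counts(counts)
  expect_identical(m$counts, counts[order(rownames(counts)), ])
  expect_setequal(high_copy_filter(m, 100), "AACCGGTTAACCG")  # 101 >= 100
  expect_false("ACACACACACACA" %in% high_copy_filter(m, 100)) # 99 dropped
  expect_setequal(high_copy_filter(m, 1), rownames(counts))
})

test_that("group_enrichment finds winners at the F-fold density boundary", {
  # densities (2.0e-4, 0.9e-4): ratio 2.22 -> winner; (1.5e-4, 1.0e-4): none
  counts <- matrix(c(199L, 89L,
                     149L, 99L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("AACCGGTTAACCG", "ACACACACACACA"),
                                   c("h1", "h2")))
  m <- matrix_from_counts(counts, lengths = c(1e6, 1e6))
  ge <- group_enrichment(m, c("h1", "h2"), F = 2)
  ge <- ge[order(ge$kmer), ]
  expect_equal(ge$winner[ge$kmer == "AACCGGTTAACCG"], "h1")
  expect_true(is.na(ge$winner[ge$kmer == "ACACACACACACA"]))
})

test_that("trio ties break to the first-listed member and are flagged", {
  counts <- matrix(c(499L, 499L, 99L), nrow = 1,
                   dimnames = list("AACCGGTTAACCG", c("t1", "t2", "t3")))
  m <- matrix_from_counts(counts, lengths = c(1e6, 1e6, 1e6))
  ge <- group_enrichment(m, c("t1", "t2", "t3"), F = 2)
  expect_equal(ge$winner, "t1")
  expect_true(ge$tied)
  # listed order decides the tie
  ge2 <- group_enrichment(m, c("t2", "t1", "t3"), F = 2)
  expect_equal(ge2$winner, "t2")
})

test_that("select_candidates enforces the group quorum", {
  # k-mer enriched in groups 1 and 2 only, out of 3
  counts <- matrix(c(400L, 10L, 400L, 10L, 100L, 100L), nrow = 1,
                   dimnames = list("AACCGGTTAACCG",
                                   c("a1", "b1", "a2", "b2", "a3", "b3")))
  filler <- matrix(c(300L, 300L, 300L, 300L, 300L, 300L), nrow = 1,
                   dimnames = list("ACACACACACACA", NULL))
  counts <- rbind(counts, filler)
  m <- matrix_from_counts(counts)
  design <- polyploid_design(p = 2, groups = list(c("a1", "b1"),
                                                  c("a2", "b2"),
                                                  c("a3", "b3")))
  at_quorum <- function(q) select_candidates(
    m, design, marker_params(N_min = 100, F = 2, quorum = q))$kmers
  expect_false("AACCGGTTAACCG" %in% at_quorum(3))
  expect_true("AACCGGTTAACCG" %in% at_quorum(2))
  expect_error(select_candidates(m, design, marker_params(quorum = 4)),
               "quorum")
})

test_that("bootstrap groups alone decide candidacy", {
  # enriched only in groups 1 and 2; group 3 flat
  counts <- matrix(c(400L, 10L, 400L, 10L, 100L, 100L), nrow = 1,
                   dimnames = list("AACCGGTTAACCG",
                                   c("a1", "b1", "a2", "b2", "a3", "b3")))
  m <- matrix_from_counts(counts)
  d_all <- polyploid_design(p = 2, groups = list(c("a1", "b1"), c("a2", "b2"),
                                                 c("a3", "b3")))
  d_boot <- polyploid_design(p = 2, groups = d_all$groups,
                             bootstrap_groups = c(1, 2))
  expect_length(select_candidates(m, d_all,
                                  marker_params(N_min = 100))$kmers, 0)
  got <- select_candidates(m, d_boot, marker_params(N_min = 100))
  expect_equal(got$kmers, "AACCGGTTAACCG")
  expect_equal(sort(got$per_group_winners$group), c(1L, 2L))
  expect_equal(unique(got$per_group_winners$winner), c("a1", "a2"))
})

test_that("raising F, N_min or quorum never enlarges the candidate set", {
  set.seed(501)
  n <- 12
  ids <- paste0(rep(c("a", "b"), each = 3), rep(1:3, 2))
  kmers <- sort(canonicalize(vapply(seq_len(n), function(i)
    random_dna(13), "")))
  kmers <- unique(kmers)
  counts <- matrix(sample(0:300, length(kmers) * 6, replace = TRUE),
                   nrow = length(kmers),
                   dimnames = list(kmers, c("a1", "b1", "a2", "b2", "a3", "b3")))
  m <- matrix_from_counts(counts, lengths = rep(2e5, 6))
  design <- polyploid_design(p = 2, groups = list(c("a1", "b1"),
                                                  c("a2", "b2"),
                                                  c("a3", "b3")))
  base <- select_candidates(m, design,
                            marker_params(N_min = 50, F = 1.5, quorum = 2))
  for (par in list(marker_params(N_min = 200, F = 1.5, quorum = 2),
                   marker_params(N_min = 50, F = 3, quorum = 2),
                   marker_params(N_min = 50, F = 1.5, quorum = 3))) {
    expect_true(all(select_candidates(m, design, par)$kmers %in% base$kmers))
  }
  # determinism: identical inputs, identical output
  again <- select_candidates(m, design,
                             marker_params(N_min = 50, F = 1.5, quorum = 2))
  expect_identical(base, again)
})

test_that("burst-derived k-mers are recovered from a clean simulation", {
  res <- simulate_polyploid(sim_config(
    tree = sim_node(list(
      sim_leaf("A", sim_branch(0.01, sim_burst(copies = 120L,
                                               copy_mut_rate = 0))),
      sim_leaf("B", sim_branch(0.01)))),
    x = 2L, chromosome_length = 100000L, seed = 77L))
  hk <- high_copy_kmers(res$genome, N_min = 100L)
  m <- build_kmer_matrix(res$genome, restrict_to = hk)
  cand <- select_candidates(m, res$design, marker_params(N_min = 100))
  truth_kmers <- burst_kmers(res, "A.b1")
  present <- truth_kmers[truth_kmers %in% m$kmers]
  expect_gt(length(present), 900)
  expect_true(all(present %in% cand$kmers))
  # winner consistency: every per-group winner lies in subgenome A
  w <- cand$per_group_winners
  expect_true(all(startsWith(w$winner[w$kmer %in% present], "A")))
})

test_that("candidate TSV export has the documented layout", {
  counts <- matrix(c(400L, 10L, 400L, 10L), nrow = 1,
                   dimnames = list("AACCGGTTAACCG", c("a1", "b1", "a2", "b2")))
  m <- matrix_from_counts(counts)
  design <- polyploid_design(p = 2, groups = list(c("a1", "b1"),
                                                  c("a2", "b2")))
  cand <- select_candidates(m, design, marker_params(N_min = 100))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, path)
  got <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(got$kmer, "AACCGGTTAACCG")
  expect_equal(got$n_groups_enriched, 2L)
  expect_equal(got$winners, "1:a1,2:a2")
})
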