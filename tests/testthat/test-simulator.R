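test_that("the same seed reproduces byte-identical output", {
  cfg <- sim_config(
    tree = sim_node(list(
      sim_leaf("A", sim_branch(0.01, sim_burst(copies = 30L))),
      sim_leaf("B", sim_branch(0.01)))),
    x = 2L, chromosome_length = 50000L, seed = 42L)
  r1 <- simulate_polyploid(cfg)
  r2 <- simulate_polyploid(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$insertions, r2$insertions)
})

test_that("a null simulation yields identical homoeologs and no candidates", {
  cfg <- sim_config(
    tree = sim_node(list(sim_leaf("A"), sim_leaf("B"))),
    x = 2L, chromosome_length = 30000L, seed = 7L)
  res <- simulate_polyploid(cfg)
  expect_identical(as.character(res$genome[["A1"]]),
                   as.character(res$genome[["B1"]]))
  m <- build_kmer_matrix(res$genome,
                         restrict_to = high_copy_kmers(res$genome, N_min = 4))
  cand <- select_candidates(m, res$design, marker_params(N_min = 4))
  expect_length(cand$kmers, 0)
})

test_that("insertion-log coordinates address the burst sequence exactly", {
  # no substitutions, no per-copy mutation: every logged interval must spell
  # the consensus
  cfg <- sim_config(
    tree = sim_node(list(
      sim_leaf("A", sim_branch(0, sim_burst(copies = 40L, copy_mut_rate = 0,
                                            consensus_length = 500L))),
      sim_leaf("B", sim_branch(0)))),
    x = 2L, chromosome_length = 60000L, seed = 13L)
  res <- simulate_polyploid(cfg)
  cons <- res$burst_consensus[["A.b1"]]
  ins <- res$insertions
  expect_equal(nrow(ins), 40L)
  for (i in which(!ins$nested)) {
    got <- as.character(Biostrings::subseq(res$genome[[ins$chromosome[i]]],
                                           ins$start[i], ins$end[i]))
    expect_identical(got, cons)
  }
  # nested entries contain the consensus length plus the nested insert
  expect_true(all(ins$end - ins$start + 1L >= 500L))
})

test_that("burst k-mer counts are explained by the insertion log", {
  cfg <- sim_config(
    tree = sim_node(list(
      sim_leaf("A", sim_branch(0, sim_burst(copies = 120L, copy_mut_rate = 0,
                                            consensus_length = 300L))),
      sim_leaf("B", sim_branch(0)))),
    x = 2L, chromosome_length = 100000L, seed = 99L)
  res <- simulate_polyploid(cfg)
  km <- burst_kmers(res, "A.b1")
  m <- build_kmer_matrix(res$genome, restrict_to = km)
  a_cols <- c("A1", "A2"); b_cols <- c("B1", "B2")
  # every consensus-internal 13-mer occurs at least once per intact copy
  n_intact <- sum(!res$insertions$nested)
  per_copy <- rowSums(m$counts[, a_cols, drop = FALSE])
  expect_true(all(per_copy >= n_intact - 2))  # nested copies may split words
  # and is absent from the unburst progenitor (up to background chance)
  expect_true(mean(rowSums(m$counts[, b_cols, drop = FALSE]) == 0) > 0.99)
})

test_that("reciprocal and replacement exchanges move sequence and log", {
  base_tree <- sim_node(list(
    sim_leaf("A", sim_branch(0, sim_burst(copies = 40L, copy_mut_rate = 0))),
    sim_leaf("B", sim_branch(0))))
  cfg <- sim_config(base_tree, x = 1L, chromosome_length = 300000L,
                    seed = 55L,
                    exchanges = list(list(donor = "A", acceptor = "B",
                                          group = 1L, start = 100001L,
                                          length = 100000L)))
  res <- simulate_polyploid(cfg)
  expect_identical(as.character(Biostrings::subseq(res$genome[["B1"]],
                                                   100001, 200000)),
                   as.character(Biostrings::subseq(res$genome[["A1"]],
                                                   100001, 200000)))
  moved <- res$insertions[res$insertions$chromosome == "B1", ]
  expect_true(all(moved$start >= 100001 & moved$end <= 200000))
  # out-of-bounds segment errors
  bad <- sim_config(base_tree, x = 1L, chromosome_length = 300000L,
                    seed = 55L,
                    exchanges = list(list(donor = "A", acceptor = "B",
                                          group = 1L, start = 290000L,
                                          length = 100000L)))
  expect_error(simulate_polyploid(bad), "out of bounds")
})

test_that("presets are fully specified and inspectable", {
  cfg <- sim_preset("tetraploid_exchange")
  expect_equal(cfg$exchanges[[1]]$length, 500000L)
  expect_equal(cfg$exchanges[[1]]$group, 3L)
  expect_error(sim_preset("dodecaploid"), "available")
  oct <- sim_preset("octoploid_staged")
  # LTR-bearing burst sits on the shared (T1,T2),I branch
  shared <- oct$tree$children[[1]]$branch$bursts[[1]]
  expect_true(shared$with_ltr)
})

test_that("truth tables and files land on disk with the documented names", {
  cfg <- sim_config(
    tree = sim_node(list(
      sim_leaf("A", sim_branch(0.005, sim_burst(copies = 10L))),
      sim_leaf("B", sim_branch(0.005)))),
    x = 2L, chromosome_length = 20000L, seed = 3L)
  dir <- withr::local_tempdir()
  res <- simulate_polyploid(cfg, out_dir = dir)
  for (f in c("genome.fa", "truth.tsv", "design.json", "insertions.gff",
              "exchanges.bed", "ltr.tsv")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  g <- load_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(res$genome))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t")
  expect_equal(truth$subgenome, rep(c("A", "B"), each = 2))
})

test_that("hexaploid shared bursts produce a combination-class asymmetry", {
  # strictly more SG1+SG2 shared markers than SG2-only markers (reduced
  # scale; the full preset runs in acceptance)
  cfg <- sim_config(
    tree = sim_node(list(
      sim_node(list(
        sim_leaf("SG1", sim_branch(0.01, sim_burst(copies = 60L))),
        sim_leaf("SG2", sim_branch(0.01, sim_burst(copies = 60L,
                                                   consensus_length = 150L)))
      ), branch = sim_branch(0.01, sim_burst(copies = 120L))),
      sim_leaf("SG3", sim_branch(0.02, sim_burst(copies = 120L)))
    )),
    x = 3L, chromosome_length = 200000L, seed = 1729L)
  res <- simulate_polyploid(cfg)
  pl <- run_pipeline(res$genome, res$design, N_min = 50)
  map <- label_map(pl$partition$assignment, res$truth)
  lab_of <- function(nm) paste0("SG", names(map)[map == nm])
  shared <- paste(sort(c(lab_of("SG1"), lab_of("SG2"))), collapse = "+")
  n_shared <- sum(pl$classes == shared)
  n_sg2 <- sum(pl$classes == lab_of("SG2"))
  expect_gt(n_shared, n_sg2)
  expect_gt(n_sg2, 0)
})
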