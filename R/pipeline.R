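#' Run the full subgenome-partitioning workflow
#'
#' Chains the stages: genome-wide high-copy k-mer pruning, density-matrix
#' construction, fold-enrichment candidate discovery across homoeologous
#' groups, 1 - r hierarchical clustering into p subgenomes, ANOVA/Tukey
#' refinement with Bonferroni correction over the full high-copy family,
#' marker-class assignment, per-class density tracks, and Viterbi ancestry
#' segmentation with exchange calls.
#'
#' @param genome A `DNAStringSet` or a FASTA path.
#' @param design A [polyploid_design] or a design-config JSON path.
#' @param k Word length (default 13).
#' @param N_min Genome-wide minimum total count (default 100).
#' @param F Fold-enrichment factor (default 2).
#' @param quorum Group quorum (default: all considered groups).
#' @param alpha Bonferroni-corrected significance threshold (default 0.05).
#' @param bin_width HMM bin width in bp (default 100 kb).
#' @param symbol_floor Covered-bp floor below which a bin emits null.
#' @param tau HMM switch probability (default 1e-3).
#' @param min_run Minimum run length in bins for exchange calls.
#' @param density_floor Marker bp/Mb floor (default 0 = off).
#' @param linkage Clustering linkage ("complete" or "average").
#' @param out_dir Optional output directory.
#' @return A list: `matrix` (high-copy restricted `kmer_matrix`),
#'   `candidates`, `clustering`, `partition`, `stats` (`tukey_table`),
#'   `classes`, `tracks`, `segmentation`, `m_family`, `params`.
#' @export
run_pipeline <- function(genome, design, k = 13L, N_min = 100L, F = 2,
                         quorum = NULL, alpha = 0.05, bin_width = 100000L,
                         symbol_floor = 0, tau = 1e-3, min_run = 1L,
                         density_floor = 0, linkage = "complete",
                         out_dir = NULL) {
  genome_path <- NULL
  if (is.character(genome)) {
    genome_path <- genome
    genome <- load_genome(genome)
  }
  if (is.character(design)) design <- load_design(design, genome)$design
  params <- list(k = k, N_min = N_min, F = F, quorum = quorum, alpha = alpha,
                 bin_width = bin_width, symbol_floor = symbol_floor,
                 tau = tau, min_run = min_run, density_floor = density_floor,
                 linkage = linkage)

  hk <- high_copy_kmers(genome, k = k, N_min = N_min)
  if (length(hk) < 2L) stop("fewer than 2 high-copy k-mers at N_min = ", N_min)
  m_family <- length(hk)
  mat <- build_kmer_matrix(genome, k = k, restrict_to = hk)
  cand <- select_candidates(mat, design,
                            marker_params(N_min = N_min, F = F, quorum = quorum))
  if (length(cand$kmers) < 2L) stop("fewer than 2 candidate marker k-mers")
  cmat <- subset_kmer_matrix(mat, cand$kmers)
  clus <- cluster_chromosomes(cmat, design, linkage = linkage)
  part <- clus$partition
  tab <- bonferroni(anova_tukey(cmat, part), m = m_family)
  classes <- assign_class(tab, alpha = alpha)
  classes <- density_filter(classes, genome, part, density_floor)

  # single-subgenome classes drive the ancestry HMM
  states <- paste0("SG", sort(unique(part$assignment)))
  lens <- setNames(Biostrings::width(genome), names(genome))
  tracks <- class_tracks(genome, classes, bin_width = bin_width)
  zero_track <- function() {
    structure(list(bin_width = as.integer(bin_width), mode = "covered_bp",
                   bins = lapply(lens, function(L)
                     numeric(ceiling(L / bin_width)))),
              class = "bin_track")
  }
  state_tracks <- lapply(setNames(states, states), function(s)
    if (s %in% names(tracks)) tracks[[s]] else zero_track())
  spec <- hmm_spec(states, tau = tau)
  symbolized <- symbolize(state_tracks, states, floor = symbol_floor)
  segmentation <- segment_genome(spec, symbolized, min_run = min_run)

  res <- list(matrix = mat, candidates = cand, clustering = clus,
              partition = part, stats = tab, classes = classes,
              tracks = tracks, state_tracks = state_tracks,
              segmentation = segmentation, m_family = m_family,
              params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_candidates(cand, file.path(out_dir, "candidates.tsv"))
    write_partition(part, file.path(out_dir, "partition.tsv"))
    write_stats(tab, file.path(out_dir, "stats.tsv"), classes = classes)
    write_newick(clus$chromosome_tree,
                 file.path(out_dir, "chromosome_tree.nwk"))
    write_newick(clus$kmer_tree, file.path(out_dir, "kmer_tree.nwk"))
    for (cl in names(tracks)) {
      write_bedgraph(tracks[[cl]],
                     file.path(out_dir, paste0("track_", gsub("[+]", "_", cl),
                                               ".bedgraph")),
                     chrom_lengths = lens)
    }
    write_segmentation(segmentation, bin_width, lens,
                       bed_path = file.path(out_dir, "segmentation.bed"),
                       calls_path = file.path(out_dir, "exchange_calls.tsv"))
    manifest <- list(
      tool = "polykmer",
      version = as.character(utils::packageVersion("polykmer")),
      params = params,
      genome = if (!is.null(genome_path))
        list(path = genome_path,
             md5 = unname(tools::md5sum(genome_path))) else "in-memory",
      n_chromosomes = length(genome),
      n_high_copy_kmers = m_family,
      n_candidates = length(cand$kmers),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
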