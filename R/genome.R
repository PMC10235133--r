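#' Load a genome assembly from FASTA
#'
#' Reads a chromosome-scale assembly. Sequences are uppercased and every
#' character outside A/C/G/T is mapped to N; N never participates in a k-mer
#' window, so IUPAC ambiguity codes are effectively masked rather than
#' guessed at.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtRn"), fa)
#' g <- load_genome(fa)
#' as.character(g$chr1)  # "ACGTNN"
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("malformed FASTA: entry without an id")
  }
  ids <- sub("\\s.*$", "", ids)  # id = first token of header
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGT]", "N", chr)
  if (any(nchar(chr) < 1)) stop("empty sequence for: ",
                                paste(ids[nchar(chr) < 1], collapse = ", "))
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Define the polyploid experimental design
#'
#' A design declares the homoeologous structure of the assembly: `p`
#' chromosomes per homoeologous group (one per subgenome) and `x` groups.
#' Rearranged genomes are handled by declaring chromosome *segments* as
#' first-class pseudo-chromosomes. An optional subset of groups
#' (`bootstrap_groups`) restricts initial marker discovery to groups whose
#' homoeology is unambiguous, mirroring restricted-trio/pair bootstraps used
#' for rearranged hexaploids and tetraploids.
#'
#' @param p Integer, number of subgenomes (= members per group).
#' @param groups List of character vectors, each of length `p`.
#' @param bootstrap_groups Optional integer indices into `groups`.
#' @param chromosomes Optional character vector of known chromosome ids; when
#'   given, every group member must be present in it.
#' @return A `polyploid_design` object with fields `p`, `x`, `groups`,
#'   `bootstrap_groups`.
#' @export
polyploid_design <- function(p, groups, bootstrap_groups = NULL,
                             chromosomes = NULL) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 2L) stop("p must be an integer >= 2")
  if (!is.list(groups) || length(groups) < 1L) {
    stop("groups must be a non-empty list of chromosome-id vectors")
  }
  groups <- lapply(groups, as.character)
  sizes <- lengths(groups)
  if (any(sizes != p)) {
    stop("every homoeologous group must have exactly p = ", p,
         " members; group(s) ", paste(which(sizes != p), collapse = ", "),
         " do not")
  }
  ids <- unlist(groups)
  if (anyDuplicated(ids)) {
    stop("chromosome id(s) referenced in more than one group: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(chromosomes)) {
    missing <- setdiff(ids, chromosomes)
    if (length(missing)) {
      stop("unknown chromosome id(s) in design: ",
           paste(missing, collapse = ", "))
    }
  }
  x <- length(groups)
  if (is.null(bootstrap_groups)) bootstrap_groups <- seq_len(x)
  bootstrap_groups <- as.integer(bootstrap_groups)
  if (length(bootstrap_groups) < 1L || anyDuplicated(bootstrap_groups) ||
      any(bootstrap_groups < 1L | bootstrap_groups > x)) {
    stop("bootstrap_groups must be distinct indices in 1..", x)
  }
  structure(
    list(p = p, x = x, groups = groups, bootstrap_groups = bootstrap_groups),
    class = "polyploid_design"
  )
}

#' @export
print.polyploid_design <- function(x, ...) {
  cat("Polyploid design: p =", x$p, "subgenomes, x =", x$x,
      "homoeologous groups\n")
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d: %s%s\n", i, paste(x$groups[[i]], collapse = ", "),
                if (i %in% x$bootstrap_groups &&
                    length(x$bootstrap_groups) < x$x) "  [bootstrap]" else ""))
  }
  invisible(x)
}

#' Load a design (and discovery parameters) from a JSON config
#'
#' The config is a JSON object with keys `p`, `groups` (list of lists of
#' chromosome ids), and optionally `bootstrap_groups` (1-based group
#' indices), `k`, `N_min`, `F`, `quorum`.
#'
#' @param config_path Path to the JSON file.
#' @param genome Optional genome (`DNAStringSet`) to validate ids against.
#' @return A list with `design` (a [polyploid_design]) and `params` (named
#'   list of any of k, N_min, F, quorum present in the file).
#' @export
load_design <- function(config_path, genome = NULL) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (key in c("p", "groups")) {
    if (is.null(cfg[[key]])) stop("design config missing key '", key, "'")
  }
  groups <- cfg$groups
  if (is.matrix(groups)) groups <- split(groups, row(groups))
  if (!is.list(groups)) groups <- as.list(groups)
  groups <- unname(groups)
  design <- polyploid_design(
    p = cfg$p, groups = groups,
    bootstrap_groups = cfg$bootstrap_groups,
    chromosomes = if (!is.null(genome)) names(genome) else NULL
  )
  params <- cfg[intersect(c("k", "N_min", "F", "quorum"), names(cfg))]
  list(design = design, params = params)
}

#' Write a design config to JSON
#' @param design A [polyploid_design].
#' @param path Output path.
#' @param params Optional named list of discovery parameters (k, N_min, F,
#'   quorum) stored alongside the group structure.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, params = list()) {
  cfg <- c(list(p = design$p, groups = design$groups,
                bootstrap_groups = design$bootstrap_groups), params)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' A subgenome partition of chromosomes
#'
#' @param assignment Named integer (or label) vector mapping chromosome id to
#'   a subgenome label in `1..p`.
#' @param p Number of subgenomes.
#' @param unassigned Character vector of outlier chromosome ids.
#' @param flags Optional named character vector of per-chromosome flags.
#' @return A `subgenome_partition` object.
#' @export
subgenome_partition <- function(assignment, p, unassigned = character(),
                                flags = character()) {
  structure(
    list(assignment = assignment, p = as.integer(p),
         unassigned = unassigned, flags = flags),
    class = "subgenome_partition"
  )
}

#' @export
print.subgenome_partition <- function(x, ...) {
  cat("Subgenome partition over", length(x$assignment), "chromosomes,",
      x$p, "subgenomes\n")
  for (s in sort(unique(x$assignment))) {
    cat(sprintf("  SG%s: %s\n", s,
                paste(names(x$assignment)[x$assignment == s], collapse = ", ")))
  }
  if (length(x$unassigned)) {
    cat("  unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check a partition against a design's one-per-group structure
#'
#' @param partition A [subgenome_partition].
#' @param design A [polyploid_design].
#' @return TRUE when, within every group, all assigned labels are distinct.
#' @export
validate_partition <- function(partition, design) {
  for (g in design$groups) {
    lab <- partition$assignment[intersect(g, names(partition$assignment))]
    if (anyDuplicated(lab)) return(FALSE)
  }
  TRUE
}
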