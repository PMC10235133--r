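#' Jukes-Cantor distance from a mismatch proportion
#'
#' `d = -(3/4) ln(1 - (4/3) pi)`: the expected substitutions/site given an
#' observed mismatch fraction, correcting for multiple hits. Saturates at
#' pi = 0.75.
#'
#' @param p_mismatch Mismatch proportion over aligned non-gap columns,
#'   in [0, 0.75).
#' @return Jukes-Cantor distance (substitutions/site).
#' @examples
#' jc_distance(0.0344)  # ~0.035215
#' @export
jc_distance <- function(p_mismatch) {
  if (any(p_mismatch < 0 | p_mismatch >= 0.75)) {
    stop("mismatch proportion must be in [0, 0.75): Jukes-Cantor saturates")
  }
  -0.75 * log(1 - (4 / 3) * p_mismatch)
}

#' Default substitution-rate calibration
#'
#' Chosen so an LTR-pair distance of 0.035 corresponds to an insertion age
#' of exactly 3 My under age = d / (2 mu): mu = 0.035 / (2 x 3e6)
#' substitutions/site/year. Override per clade.
#' @export
default_mu <- function() 0.035 / (2 * 3e6)

#' Date an insertion from LTR-pair divergence
#'
#' The two LTRs are identical at insertion and diverge independently, so the
#' insertion age is `d / (2 mu)`, reported in million years.
#'
#' @param d Jukes-Cantor distance between the 5' and 3' LTRs.
#' @param mu Substitution rate per site per year (default [default_mu]).
#' @return Age in My.
#' @export
date_insertion <- function(d, mu = default_mu()) {
  stopifnot(mu > 0)
  d / (2 * mu) / 1e6
}

#' Construct intact LTR retrotransposon elements from a coordinate table
#'
#' The table is 1-based closed (GFF convention): columns `chromosome`,
#' `start`, `end`, `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`.
#' Elements are named by genomic location ("chr:start-end"). The inner
#' sequence spans between the LTRs and may contain Ns.
#'
#' @param genome A `DNAStringSet`.
#' @param table data.frame with the columns above, or a path to such a TSV.
#' @return List of `ltr_element`: id, chromosome, start, end, ltr5, ltr3,
#'   inner (character sequences), subgenome (NA until joined).
#' @export
ltr_elements <- function(genome, table) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  need <- c("chromosome", "start", "end", "ltr5_start", "ltr5_end",
            "ltr3_start", "ltr3_end")
  if (!all(need %in% names(table))) {
    stop("LTR table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (!r$chromosome %in% names(genome)) {
      stop("unknown chromosome in LTR table: ", r$chromosome)
    }
    L <- Biostrings::width(genome[r$chromosome])
    if (r$start < 1 || r$end > L || r$ltr5_start < r$start ||
        r$ltr3_end > r$end || r$ltr5_end >= r$ltr3_start) {
      stop("inconsistent LTR coordinates at row ", i)
    }
    seq <- genome[[r$chromosome]]
    el <- list(
      id = sprintf("%s:%d-%d", r$chromosome, r$start, r$end),
      chromosome = r$chromosome, start = r$start, end = r$end,
      ltr5 = as.character(Biostrings::subseq(seq, r$ltr5_start, r$ltr5_end)),
      ltr3 = as.character(Biostrings::subseq(seq, r$ltr3_start, r$ltr3_end)),
      inner = as.character(Biostrings::subseq(seq, r$ltr5_end + 1L,
                                              r$ltr3_start - 1L)),
      subgenome = NA_integer_
    )
    class(el) <- "ltr_element"
    el
  })
}

#' Join subgenome labels onto elements from a partition
#' @param elements List of `ltr_element`.
#' @param partition A [subgenome_partition].
#' @return Elements with `subgenome` filled (NA for unassigned hosts).
#' @export
join_partition <- function(elements, partition) {
  lapply(elements, function(el) {
    sg <- partition$assignment[el$chromosome]
    el$subgenome <- if (is.na(sg)) NA_integer_ else as.integer(sg)
    el
  })
}

.ltr_align <- function(a, b, type = "global") {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1
  )
}

#' 5'/3' LTR divergence, distance and age of one element
#'
#' Globally aligns the two LTRs (affine gaps, match 1 / mismatch -2 / gap
#' open -4 / extend -1); the mismatch proportion is computed over aligned
#' non-gap columns only (Jukes-Cantor is a substitution model), then
#' corrected to a distance and an age.
#'
#' @param element An `ltr_element`.
#' @param mu Substitution rate (default [default_mu]).
#' @param min_ltr_length Minimum LTR length in bp (default 50).
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns); below it the element is flagged unalignable (default 0.6).
#' @return A one-row data.frame: id, subgenome, pi, d, age_my, identity,
#'   alignable.
#' @export
ltr_pair_divergence <- function(element, mu = default_mu(),
                                min_ltr_length = 50L, min_identity = 0.6) {
  if (nchar(element$ltr5) < min_ltr_length ||
      nchar(element$ltr3) < min_ltr_length) {
    stop("LTR shorter than ", min_ltr_length, " bp for ", element$id)
  }
  aln <- .ltr_align(element$ltr5, element$ltr3)
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  ncols <- Biostrings::nchar(aln)  # alignment length incl. gap columns
  identity <- nmat / ncols
  alignable <- identity >= min_identity
  pi_hat <- if (nmat + nmis > 0) nmis / (nmat + nmis) else NA_real_
  d <- if (alignable && !is.na(pi_hat) && pi_hat < 0.75) jc_distance(pi_hat)
       else NA_real_
  data.frame(
    id = element$id,
    subgenome = element$subgenome,
    pi = pi_hat,
    d = d,
    age_my = if (!is.na(d)) date_insertion(d, mu) else NA_real_,
    identity = identity,
    alignable = alignable,
    stringsAsFactors = FALSE
  )
}

#' Divergence records for a set of elements
#' @param elements List of `ltr_element`.
#' @param ... Passed to [ltr_pair_divergence].
#' @return data.frame, one row per element.
#' @export
ltr_divergence_table <- function(elements, ...) {
  do.call(rbind, lapply(elements, ltr_pair_divergence, ...))
}

#' Build LTR families by reciprocal-coverage single linkage
#'
#' All-vs-all local alignment of 5' LTRs; an edge joins two elements when a
#' significant alignment spans at least `coverage` of BOTH sequences'
#' lengths. Significance is a minimum-identity plus minimum-length criterion
#' (an internal stand-in for a BLAST E-value cutoff; the reciprocal 90%
#' coverage rule is preserved exactly). Families are the connected
#' components of the edge graph (single linkage).
#'
#' @param elements List of `ltr_element`.
#' @param coverage Reciprocal coverage fraction (default 0.9).
#' @param min_identity Minimum identity within the aligned region
#'   (default 0.8).
#' @param min_length Minimum alignment length in bp (default 50).
#' @return A `ltr_families`: list with `membership` (named integer: element
#'   id -> family id), `families` (list of id vectors), `edges` (data.frame
#'   a, b, coverage_a, coverage_b, identity).
#' @export
build_families <- function(elements, coverage = 0.9, min_identity = 0.8,
                           min_length = 50L) {
  ids <- vapply(elements, `[[`, "", "id")
  n <- length(elements)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      a <- elements[[i]]$ltr5; b <- elements[[j]]$ltr5
      aln <- .ltr_align(a, b, type = "local")
      wa <- Biostrings::width(Biostrings::pattern(aln))
      wb <- Biostrings::width(Biostrings::subject(aln))
      alen <- Biostrings::nchar(aln)
      nmat <- Biostrings::nmatch(aln)
      ident <- if (alen > 0) nmat / alen else 0
      cov_a <- wa / nchar(a); cov_b <- wb / nchar(b)
      if (alen >= min_length && ident >= min_identity &&
          cov_a >= coverage && cov_b >= coverage) {
        edges[[length(edges) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], coverage_a = cov_a, coverage_b = cov_b,
          identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), coverage_a = numeric(),
               coverage_b = numeric(), identity = numeric())
  g <- igraph::graph_from_data_frame(edf[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  membership <- setNames(as.integer(comp[ids]), ids)
  structure(
    list(membership = membership,
         families = split(names(membership), membership),
         edges = edf),
    class = "ltr_families"
  )
}

#' @export
print.ltr_families <- function(x, ...) {
  cat("ltr_families:", length(x$families), "family(ies) over",
      length(x$membership), "elements\n")
  invisible(x)
}

#' Histogram of LTR-pair divergence by host-subgenome group
#'
#' Restricted to elements in large families (minimum family size), the
#' distribution of Jukes-Cantor LTR-pair distances per host subgenome; a
#' shared mode across subgenomes records transposon activity in a common
#' (intermediate-polyploid) ancestor.
#'
#' @param div data.frame from [ltr_divergence_table] (alignable rows used).
#' @param families Optional `ltr_families`; with `min_family_size` filters
#'   to large families.
#' @param min_family_size Minimum family size (default 10).
#' @param bin_width Histogram bin width on d (default 0.01).
#' @return data.frame: group (subgenome label or NA), bin_low, bin_high,
#'   count.
#' @export
divergence_histogram <- function(div, families = NULL, min_family_size = 10L,
                                 bin_width = 0.01) {
  keep <- div[!is.na(div$d) & div$alignable, , drop = FALSE]
  if (!is.null(families)) {
    sizes <- lengths(families$families)
    big <- names(families$membership)[
      sizes[as.character(families$membership)] >= min_family_size]
    keep <- keep[keep$id %in% big, , drop = FALSE]
  }
  if (nrow(keep) == 0L) {
    return(data.frame(group = character(), bin_low = numeric(),
                      bin_high = numeric(), count = integer()))
  }
  keep$bin <- floor(keep$d / bin_width)
  agg <- aggregate(list(count = keep$d),
                   by = list(group = ifelse(is.na(keep$subgenome), "NA",
                                            paste0("SG", keep$subgenome)),
                             bin = keep$bin),
                   FUN = length)
  out <- data.frame(group = agg$group,
                    bin_low = agg$bin * bin_width,
                    bin_high = (agg$bin + 1) * bin_width,
                    count = agg$count)
  out[order(out$group, out$bin_low), ]
}
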