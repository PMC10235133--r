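#' Locate exact marker occurrences on the genome
#'
#' Every exact occurrence of each marker or its reverse complement is
#' recorded (0-based half-open internally via IRanges 1-based closed), then
#' overlapping or adjacent hits are merged. Exact both-strand string
#' matching of canonical k-mers coincides with word-exact alignment.
#'
#' @param genome A `DNAStringSet`.
#' @param markers Character vector of canonical k-mers (all same length).
#' @return A `marker_hits` object: list with `hits` (per-chromosome merged
#'   [IRanges::IRanges]), `hit_counts` (pre-merge occurrence count per
#'   marker, summed over chromosomes), `k`.
#' @export
locate_markers <- function(genome, markers) {
  k <- unique(nchar(markers))
  if (length(k) != 1L) stop("markers must share one length")
  if (any(markers != canonicalize(markers))) stop("markers must be canonical")
  mset <- Biostrings::DNAStringSet(markers)
  rcset <- Biostrings::reverseComplement(mset)
  notpal <- as.character(rcset) != markers
  query <- c(mset, rcset[notpal])
  qmarker <- c(markers, markers[notpal])
  pd <- Biostrings::PDict(query)
  per_chrom <- vector("list", length(genome))
  names(per_chrom) <- names(genome)
  hit_counts <- setNames(numeric(length(markers)), markers)
  for (i in seq_along(genome)) {
    m <- Biostrings::matchPDict(pd, genome[[i]])
    cnt <- S4Vectors::elementNROWS(m)
    hc <- tapply(cnt, qmarker, sum)
    hit_counts[names(hc)] <- hit_counts[names(hc)] + hc
    per_chrom[[i]] <- IRanges::reduce(unlist(m))
  }
  structure(list(hits = per_chrom, hit_counts = hit_counts, k = k),
            class = "marker_hits")
}

#' Bin marker coverage into fixed-width windows
#'
#' @param hits A `marker_hits` (or a named list of merged `IRanges`).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param bin_width Bin size in bp (default 100000).
#' @param mode "covered_bp": bp of merged intervals in each bin, split at bin
#'   boundaries (total coverage is conserved across bins); "hit_count":
#'   intervals assigned to the bin of their start coordinate.
#' @return A `bin_track`: list with `bin_width`, `mode`, `bins` — per
#'   chromosome a numeric vector of length `ceiling(L / bin_width)`.
#' @export
bin_density <- function(hits, chrom_lengths, bin_width = 100000L,
                        mode = c("covered_bp", "hit_count")) {
  mode <- match.arg(mode)
  if (inherits(hits, "marker_hits")) hits <- hits$hits
  bins <- lapply(names(chrom_lengths), function(id) {
    L <- chrom_lengths[[id]]
    nb <- ceiling(L / bin_width)
    v <- numeric(nb)
    ir <- hits[[id]]
    if (is.null(ir) || length(ir) == 0L) return(v)
    if (mode == "hit_count") {
      b <- (IRanges::start(ir) - 1L) %/% bin_width + 1L
      t <- table(b)
      v[as.integer(names(t))] <- as.numeric(t)
    } else {
      win <- IRanges::IRanges(start = seq(1L, by = bin_width, length.out = nb),
                              width = pmin(bin_width, L - bin_width * (seq_len(nb) - 1L)))
      cov <- IRanges::coverage(ir, width = L)
      v <- as.numeric(sum(IRanges::Views(cov, win)))
    }
    v
  })
  names(bins) <- names(chrom_lengths)
  structure(list(bin_width = as.integer(bin_width), mode = mode, bins = bins),
            class = "bin_track")
}

#' Per-class bin tracks
#'
#' Builds one [bin_density] track per marker class — the input of the
#' ancestry HMM.
#'
#' @param genome A `DNAStringSet`.
#' @param classes Named character vector (k-mer -> class label), e.g. from
#'   [assign_class]; "none" entries are ignored.
#' @param bin_width Bin size in bp.
#' @param mode Passed to [bin_density].
#' @return Named list of `bin_track`, one per class label.
#' @export
class_tracks <- function(genome, classes, bin_width = 100000L,
                         mode = "covered_bp") {
  classes <- classes[classes != "none"]
  lens <- setNames(Biostrings::width(genome), names(genome))
  out <- lapply(split(names(classes), classes), function(kms) {
    bin_density(locate_markers(genome, kms), lens, bin_width, mode)
  })
  out
}

#' Export a bin track as bedGraph
#'
#' One record per non-zero bin: chrom, 0-based start, half-open end, value.
#'
#' @param track A `bin_track`.
#' @param path Output path.
#' @param chrom_lengths Named lengths (bins of the last partial window are
#'   clipped to the chromosome end when given).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom_lengths = NULL) {
  rows <- list()
  for (id in names(track$bins)) {
    v <- track$bins[[id]]
    nz <- which(v != 0)
    if (!length(nz)) next
    start0 <- (nz - 1L) * track$bin_width
    end0 <- nz * track$bin_width
    if (!is.null(chrom_lengths)) end0 <- pmin(end0, chrom_lengths[[id]])
    rows[[id]] <- data.frame(chrom = id, start = start0, end = end0,
                             value = v[nz])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export / import merged marker hits as BED (0-based half-open)
#'
#' @param hits A `marker_hits` (or named list of `IRanges`).
#' @param path BED path.
#' @return `path` invisibly (`write`); a named list of merged `IRanges`
#'   (`read`).
#' @export
write_bed <- function(hits, path) {
  if (inherits(hits, "marker_hits")) hits <- hits$hits
  rows <- lapply(names(hits), function(id) {
    ir <- hits[[id]]
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = id, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer())
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  lapply(split(df, df$chrom), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
}

#' Apply a display-bias filter to classified markers
#'
#' Drops markers whose between-subgenome density ratio is below
#' `display_bias` from the *display* set only; statistics are unaffected.
#' Used to keep karyogram tracks from being dominated by weakly enriched but
#' statistically significant markers (e.g. a 100x floor).
#'
#' @param matrix A `kmer_matrix`.
#' @param classes Named character vector (k-mer -> class).
#' @param partition A [subgenome_partition].
#' @param display_bias Minimum fold-ratio of mean density on the enriched
#'   subgenome set vs the rest (default 1 = no filter).
#' @return Filtered `classes`.
#' @export
display_filter <- function(matrix, classes, partition, display_bias = 1) {
  classes <- classes[classes != "none"]
  if (display_bias <= 1 || !length(classes)) return(classes)
  asn <- partition$assignment
  keep <- vapply(seq_along(classes), function(i) {
    km <- names(classes)[i]
    sgs <- as.integer(sub("^SG", "", strsplit(classes[i], "+", fixed = TRUE)[[1]]))
    inset <- names(asn)[asn %in% sgs]
    outset <- names(asn)[!asn %in% sgs]
    mean(matrix$densities[km, inset]) >=
      display_bias * mean(matrix$densities[km, outset])
  }, logical(1))
  classes[keep]
}
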