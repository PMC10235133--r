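#' Specify the ancestry HMM
#'
#' Hidden states are subgenome identities; emitted symbols are marker
#' classes (one per state) plus a null symbol for bins without signal.
#' Transitions have stay probability `1 - tau` and switch probability
#' `tau / (p - 1)` to each other state. Default emissions: P(own symbol |
#' state) = `p_own`, P(null | state) = `p_null`, remainder uniform over the
#' other symbols.
#'
#' @param states Character vector of subgenome labels (length p >= 2).
#' @param tau Switch probability mass (default 1e-3).
#' @param p_own P(own class symbol | state) (default 0.9).
#' @param p_null P(null symbol | state) (default 0.05).
#' @param emission Optional custom emission matrix (states x symbols,
#'   symbols = `c(states, "null")`); rows must sum to 1.
#' @param initial Initial state distribution (default uniform).
#' @return An `hmm_spec`: list with `states`, `symbols`, `emission`,
#'   `transition`, `initial`.
#' @export
hmm_spec <- function(states, tau = 1e-3, p_own = 0.9, p_null = 0.05,
                     emission = NULL, initial = NULL) {
  p <- length(states)
  stopifnot(p >= 2L, tau > 0, tau < 1)
  symbols <- c(states, "null")
  if (is.null(emission)) {
    stopifnot(p_own + p_null < 1)
    other <- (1 - p_own - p_null) / (p - 1)
    emission <- matrix(other, nrow = p, ncol = p + 1L,
                       dimnames = list(states, symbols))
    diag(emission[, seq_len(p)]) <- p_own
    emission[, "null"] <- p_null
  } else {
    stopifnot(identical(dim(emission), c(p, p + 1L)) ||
                identical(dim(emission), as.integer(c(p, p + 1L))))
    dimnames(emission) <- list(states, symbols)
  }
  if (any(abs(rowSums(emission) - 1) > 1e-8)) {
    stop("emission rows must sum to 1")
  }
  transition <- matrix(tau / (p - 1), p, p, dimnames = list(states, states))
  diag(transition) <- 1 - tau
  if (is.null(initial)) initial <- rep(1 / p, p)
  stopifnot(abs(sum(initial) - 1) < 1e-8)
  structure(list(states = states, symbols = symbols, emission = emission,
                 transition = transition, initial = setNames(initial, states)),
            class = "hmm_spec")
}

#' Discretize per-class bin tracks into a symbol sequence
#'
#' Per bin: the symbol is the class of maximal density; the null symbol when
#' the total density across classes is below `floor`. Ties break to the
#' lower state index and are flagged.
#'
#' @param tracks Named list of `bin_track` (one per class; names must match
#'   the HMM states).
#' @param states Character vector of state labels, in state order.
#' @param floor Covered-bp (or hit-count) threshold below which a bin emits
#'   null (default 0: any signal wins).
#' @return List per chromosome: list with `symbols` (character vector) and
#'   `ties` (logical vector).
#' @export
symbolize <- function(tracks, states, floor = 0) {
  if (!all(states %in% names(tracks))) {
    stop("tracks are missing classes for state(s): ",
         paste(setdiff(states, names(tracks)), collapse = ", "))
  }
  tracks <- tracks[states]
  chroms <- names(tracks[[1L]]$bins)
  out <- lapply(chroms, function(id) {
    M <- vapply(tracks, function(tr) tr$bins[[id]],
                numeric(length(tracks[[1L]]$bins[[id]])))
    if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
    tot <- rowSums(M)
    widx <- apply(M, 1L, which.max)
    ties <- apply(M, 1L, function(r) max(r) > 0 && sum(r == max(r)) > 1L)
    sym <- ifelse(tot > floor, states[widx], "null")
    ties[sym == "null"] <- FALSE
    list(symbols = sym, ties = ties)
  })
  names(out) <- chroms
  out
}

#' Viterbi decoding
#'
#' Maximum a posteriori state path in log space. Ties break toward staying
#' in the current state (predecessor equal to the current state wins), then
#' to the lower state index; the final state ties break to the lower index.
#'
#' @param spec An [hmm_spec].
#' @param symbols Character vector of emitted symbols.
#' @return Character vector of states (empty for empty input).
#' @export
viterbi <- function(spec, symbols) {
  if (length(symbols) == 0L) return(character())
  if (!all(symbols %in% spec$symbols)) {
    stop("symbol(s) outside the HMM alphabet: ",
         paste(setdiff(symbols, spec$symbols), collapse = ", "))
  }
  p <- length(spec$states)
  Tn <- length(symbols)
  logE <- log(spec$emission)
  logA <- log(spec$transition)
  V <- matrix(-Inf, p, Tn)
  back <- matrix(0L, p, Tn)
  V[, 1L] <- log(spec$initial) + logE[, symbols[1L]]
  eps <- 1e-12
  for (t in seq_len(Tn)[-1L]) {
    for (s in seq_len(p)) {
      cand <- V[, t - 1L] + logA[, s]
      best <- max(cand)
      amax <- which(cand >= best - eps)
      prev <- if (s %in% amax) s else amax[1L]  # stay-bias tie-break
      back[s, t] <- prev
      V[s, t] <- cand[prev] + logE[s, symbols[t]]
    }
  }
  path <- integer(Tn)
  fin <- max(V[, Tn])
  path[Tn] <- which(V[, Tn] >= fin - eps)[1L]
  for (t in rev(seq_len(Tn - 1L))) path[t] <- back[path[t + 1L], t + 1L]
  spec$states[path]
}

#' Log joint probability of a state path and symbol sequence
#' @param spec An [hmm_spec].
#' @param path Character vector of states.
#' @param symbols Character vector of symbols (same length).
#' @return Log probability.
#' @export
path_logprob <- function(spec, path, symbols) {
  stopifnot(length(path) == length(symbols))
  if (length(path) == 0L) return(0)
  si <- match(path, spec$states)
  lp <- log(spec$initial[si[1L]]) + log(spec$emission[si[1L], symbols[1L]])
  for (t in seq_along(path)[-1L]) {
    lp <- lp + log(spec$transition[si[t - 1L], si[t]]) +
      log(spec$emission[si[t], symbols[t]])
  }
  unname(lp)
}

#' Segment a state path into ancestry runs and exchange calls
#'
#' Runs shorter than `min_run` bins are absorbed into the flanking majority
#' state (longer flank wins; left flank on ties), iterated to stability.
#' Each remaining within-chromosome transition becomes an exchange call,
#' annotated `terminal` when the breakpoint lies within `terminal_frac` of
#' either chromosome end (homoeologous exchanges often sit at or near
#' chromosome ends), otherwise `internal`.
#'
#' @param path Character vector of states for one chromosome.
#' @param min_run Minimum run length in bins (default 1 = off).
#' @param terminal_frac Fraction of the chromosome length defining the
#'   terminal zone at each end (default 0.1).
#' @return An `ancestry_segmentation`: list with `runs` (data.frame
#'   start_bin, end_bin (1-based closed), state) and `exchange_calls`
#'   (data.frame breakpoint_bin — 0-based index of the first bin in the new
#'   state — left_state, right_state, left_run, right_run, location).
#' @export
segment_path <- function(path, min_run = 1L, terminal_frac = 0.1) {
  stopifnot(min_run >= 1L)
  if (length(path) == 0L) {
    return(structure(list(runs = data.frame(), exchange_calls = data.frame()),
                     class = "ancestry_segmentation"))
  }
  r <- rle(path)
  if (min_run > 1L) {
    repeat {
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < min_run)
      if (!length(short)) break
      i <- short[1L]
      if (i == 1L) tgt <- 2L
      else if (i == length(r$lengths)) tgt <- i - 1L
      else tgt <- if (r$lengths[i + 1L] > r$lengths[i - 1L]) i + 1L else i - 1L
      r$values[i] <- r$values[tgt]
      # re-run rle to merge equal neighbours
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- data.frame(start_bin = starts, end_bin = ends, state = r$values,
                     row.names = NULL)
  n <- nrow(runs)
  if (n > 1L) {
    idx <- seq_len(n - 1L)
    left_run <- runs$end_bin[idx] - runs$start_bin[idx] + 1L
    right_run <- runs$end_bin[idx + 1L] - runs$start_bin[idx + 1L] + 1L
    bp0 <- runs$start_bin[idx + 1L] - 1L  # 0-based bin index
    near_end <- pmin(bp0, length(path) - bp0) <= terminal_frac * length(path)
    calls <- data.frame(
      breakpoint_bin = bp0,
      left_state = runs$state[idx],
      right_state = runs$state[idx + 1L],
      left_run = left_run, right_run = right_run,
      location = ifelse(near_end, "terminal", "internal"),
      row.names = NULL
    )
  } else {
    calls <- data.frame(breakpoint_bin = integer(), left_state = character(),
                        right_state = character(), left_run = integer(),
                        right_run = integer(), location = character())
  }
  structure(list(runs = runs, exchange_calls = calls),
            class = "ancestry_segmentation")
}

#' @export
print.ancestry_segmentation <- function(x, ...) {
  cat("ancestry_segmentation:", nrow(x$runs), "run(s),",
      nrow(x$exchange_calls), "exchange call(s)\n")
  invisible(x)
}

#' Segment every chromosome of a symbolized genome
#'
#' @param spec An [hmm_spec].
#' @param symbolized Output of [symbolize].
#' @param min_run Passed to [segment_path].
#' @return Named list of `ancestry_segmentation` per chromosome.
#' @export
segment_genome <- function(spec, symbolized, min_run = 1L) {
  lapply(symbolized, function(sy) segment_path(viterbi(spec, sy$symbols),
                                               min_run = min_run))
}

#' Export ancestry runs as BED and exchange calls as TSV
#'
#' BED rows: chromosome, bp start (= (start_bin-1) x bin width, 0-based),
#' bp end (clipped to chromosome length), state.
#'
#' @param segmentation Named list of `ancestry_segmentation`.
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Named chromosome lengths.
#' @param bed_path,calls_path Output paths (NULL to skip either).
#' @return Invisible list of the two data.frames written.
#' @export
write_segmentation <- function(segmentation, bin_width, chrom_lengths,
                               bed_path = NULL, calls_path = NULL) {
  beds <- list(); calls <- list()
  for (id in names(segmentation)) {
    seg <- segmentation[[id]]
    if (nrow(seg$runs)) {
      beds[[id]] <- data.frame(
        chrom = id,
        start = (seg$runs$start_bin - 1L) * bin_width,
        end = pmin(seg$runs$end_bin * bin_width, chrom_lengths[[id]]),
        state = seg$runs$state
      )
    }
    if (nrow(seg$exchange_calls)) {
      calls[[id]] <- cbind(chrom = id, seg$exchange_calls)
    }
  }
  bed <- if (length(beds)) do.call(rbind, beds) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               state = character())
  cl <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), breakpoint_bin = integer(),
               left_state = character(), right_state = character(),
               left_run = integer(), right_run = integer(),
               location = character())
  if (!is.null(bed_path)) {
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(calls_path)) {
    utils::write.table(cl, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(runs = bed, exchange_calls = cl))
}
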