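#' Synthetic allopolyploid simulation
#'
#' The simulator emulates the evolutionary scenario the partitioning method
#' exploits: independent progenitor lineages accumulate point substitutions
#' and lineage-specific transposable-element insertion bursts; staged
#' hybridizations merge lineages (bursts on internal branches become
#' activity shared by all descendant subgenomes — the signature of an
#' intermediate polyploid); optional homoeologous exchanges move segments
#' between subgenomes after the final merger. Full ground truth (subgenome
#' table, insertion log, exchange log, LTR annotation) is emitted for
#' testing.
#'
#' @name simulator
NULL

#' Describe a TE insertion burst on a branch
#'
#' A burst generates a fresh random consensus element and inserts mutated
#' copies at uniform random positions across the branch's chromosome set.
#' LTR-bearing elements are inserted as LTR-inner-LTR with the two LTRs
#' identical at insertion (per-copy mutation is applied to one LTR and then
#' duplicated), so they diverge only through subsequent branch
#' substitutions.
#'
#' @param copies Number of inserted copies.
#' @param consensus_length Total element length in bp.
#' @param with_ltr Logical; build an LTR-inner-LTR element.
#' @param ltr_length LTR length in bp (when `with_ltr`).
#' @param copy_mut_rate Per-site mutation probability applied independently
#'   to each copy at insertion (subfamily variation).
#' @return A `sim_burst` list.
#' @export
sim_burst <- function(copies = 300L, consensus_length = 1000L,
                      with_ltr = FALSE, ltr_length = 150L,
                      copy_mut_rate = 0.02) {
  stopifnot(copies >= 0, consensus_length >= 1,
            !with_ltr || consensus_length > 2L * ltr_length)
  structure(list(copies = as.integer(copies),
                 consensus_length = as.integer(consensus_length),
                 with_ltr = with_ltr, ltr_length = as.integer(ltr_length),
                 copy_mut_rate = copy_mut_rate),
            class = "sim_burst")
}

#' Branch parameters of the hybridization tree
#' @param substitution_rate Per-site substitution probability over the
#'   branch (each site flips at most once per branch, Jukes-Cantor uniform
#'   alternative base; no indels outside TE insertion).
#' @param bursts List of [sim_burst].
#' @return A `sim_branch` list.
#' @export
sim_branch <- function(substitution_rate = 0, bursts = list()) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1)
  if (inherits(bursts, "sim_burst")) bursts <- list(bursts)
  structure(list(substitution_rate = substitution_rate, bursts = bursts),
            class = "sim_branch")
}

#' Leaf (progenitor lineage) of the hybridization tree
#' @param name Subgenome name (used as chromosome-id prefix).
#' @param branch A [sim_branch] leading to this leaf.
#' @return A tree node.
#' @export
sim_leaf <- function(name, branch = sim_branch()) {
  structure(list(name = name, branch = branch, children = NULL),
            class = "sim_node")
}

#' Internal node (hybridization stage) of the tree
#' @param children List of child nodes.
#' @param branch A [sim_branch] leading to this node; its bursts are shared
#'   by every descendant subgenome.
#' @param name Optional branch label (default derived from descendants).
#' @return A tree node.
#' @export
sim_node <- function(children, branch = sim_branch(), name = NULL) {
  stopifnot(length(children) >= 2L)
  structure(list(name = name, branch = branch, children = children),
            class = "sim_node")
}

#' Assemble a simulation configuration
#'
#' @param tree A [sim_node]/[sim_leaf] tree whose leaves are the subgenomes.
#' @param x Chromosomes per subgenome (homoeologous groups).
#' @param chromosome_length Ancestral chromosome length in bp.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param exchanges List of homoeologous exchanges applied after the final
#'   merge, each `list(donor =, acceptor =, group =, start =, length =,
#'   reciprocal = FALSE)` — donor/acceptor are subgenome names, `start` is
#'   1-based bp on the current chromosomes. With `reciprocal = FALSE` the
#'   donor segment replaces the acceptor segment (typical homoeologous
#'   exchange); with TRUE the two segments are swapped.
#' @param root_branch A [sim_branch] applied to the ancestral chromosomes
#'   before the first split (shared by all subgenomes).
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, x = 5L, chromosome_length = 500000L,
                       seed = 1729L, exchanges = list(),
                       root_branch = sim_branch()) {
  structure(list(tree = tree, x = as.integer(x),
                 chromosome_length = as.integer(chromosome_length),
                 seed = as.integer(seed), exchanges = exchanges,
                 root_branch = root_branch),
            class = "sim_config")
}

.random_seq <- function(L) sample(c("A", "C", "G", "T"), L, replace = TRUE)

# mutate a character vector of bases in place (JC uniform alternative base)
.mutate_seq <- function(v, rate) {
  if (rate <= 0 || length(v) == 0L) return(v)
  n <- rbinom(1L, length(v), rate)
  if (n == 0L) return(v)
  pos <- sample.int(length(v), n)
  bases <- c("A", "C", "G", "T")
  idx <- match(v[pos], bases)
  v[pos] <- bases[(idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  v
}

# Insert `pieces` (list of char vectors) after positions `pos` (0..L) of `v`.
# Returns list(seq, starts, ends) with 1-based closed coordinates of the
# inserted pieces in the new sequence, in the order of `pos` as given.
.insert_many <- function(v, pos, pieces) {
  ord <- order(pos)
  pos_s <- pos[ord]
  pieces_s <- pieces[ord]
  n <- length(pos_s)
  parts <- vector("list", 2L * n + 1L)
  prev <- 0L
  for (i in seq_len(n)) {
    parts[[2L * i - 1L]] <- if (pos_s[i] > prev) v[(prev + 1L):pos_s[i]] else character()
    parts[[2L * i]] <- pieces_s[[i]]
    prev <- pos_s[i]
  }
  parts[[2L * n + 1L]] <- if (prev < length(v)) v[(prev + 1L):length(v)] else character()
  lens <- vapply(pieces_s, length, integer(1))
  cum <- cumsum(lens)
  starts_s <- pos_s + (cum - lens) + 1L
  ends_s <- pos_s + cum
  starts <- integer(n); ends <- integer(n)
  starts[ord] <- starts_s; ends[ord] <- ends_s
  list(seq = unlist(parts, use.names = FALSE), starts = starts, ends = ends,
       ins_pos = pos_s, ins_len = lens)
}

# Shift logged 1-based coordinates for insertions at original positions
# `ins_pos` (sorted, 0..L) with lengths `ins_len`; flags entries that now
# contain a nested insertion.
.shift_log <- function(log_df, chrom_idx, ins_pos, ins_len) {
  if (nrow(log_df) == 0L) return(log_df)
  sel <- log_df$chrom_idx == chrom_idx
  if (!any(sel)) return(log_df)
  cum <- cumsum(ins_len)
  shift_at <- function(coord_minus1) {
    k <- findInterval(coord_minus1, ins_pos)
    ifelse(k > 0L, cum[pmax(k, 1L)], 0L) * (k > 0L)
  }
  s <- log_df$start[sel]; e <- log_df$end[sel]
  ns <- s + shift_at(s - 1L)
  ne <- e + shift_at(e - 1L)
  nested <- (ne - ns) != (e - s)
  log_df$start[sel] <- ns
  log_df$end[sel] <- ne
  log_df$nested[sel] <- log_df$nested[sel] | nested
  log_df
}

.empty_log <- function() {
  data.frame(chrom_idx = integer(), start = integer(), end = integer(),
             burst = character(), branch = character(), with_ltr = logical(),
             ltr_length = integer(), nested = logical(),
             stringsAsFactors = FALSE)
}

# Apply one branch (substitutions then bursts) to a lineage state.
# state: list(chroms = list of char vectors, log = insertion log data.frame)
.apply_branch <- function(state, branch, branch_name, registry) {
  rate <- branch$substitution_rate
  if (rate > 0) {
    state$chroms <- lapply(state$chroms, .mutate_seq, rate = rate)
  }
  for (bi in seq_along(branch$bursts)) {
    b <- branch$bursts[[bi]]
    if (b$copies == 0L) next
    burst_id <- sprintf("%s.b%d", branch_name, bi)
    if (b$with_ltr) {
      ltr <- .random_seq(b$ltr_length)
      inner <- .random_seq(b$consensus_length - 2L * b$ltr_length)
      consensus <- c(ltr, inner, ltr)
    } else {
      consensus <- .random_seq(b$consensus_length)
    }
    registry[[burst_id]] <- paste(consensus, collapse = "")
    target <- sample.int(length(state$chroms), b$copies, replace = TRUE)
    for (ci in sort(unique(target))) {
      ncopy <- sum(target == ci)
      v <- state$chroms[[ci]]
      pieces <- lapply(seq_len(ncopy), function(i) {
        if (b$with_ltr) {
          ml <- .mutate_seq(ltr, b$copy_mut_rate)
          mi <- .mutate_seq(inner, b$copy_mut_rate)
          c(ml, mi, ml)  # LTR pair identical at insertion
        } else {
          .mutate_seq(consensus, b$copy_mut_rate)
        }
      })
      pos <- sample.int(length(v) + 1L, ncopy, replace = TRUE) - 1L
      ins <- .insert_many(v, pos, pieces)
      state$chroms[[ci]] <- ins$seq
      state$log <- .shift_log(state$log, ci, ins$ins_pos, ins$ins_len)
      state$log <- rbind(state$log, data.frame(
        chrom_idx = ci, start = ins$starts, end = ins$ends,
        burst = burst_id, branch = branch_name, with_ltr = b$with_ltr,
        ltr_length = if (b$with_ltr) b$ltr_length else NA_integer_,
        nested = FALSE, stringsAsFactors = FALSE))
    }
  }
  state
}

.node_name <- function(node) {
  if (!is.null(node$name)) return(node$name)
  leaves <- function(n) {
    if (is.null(n$children)) n$name
    else unlist(lapply(n$children, leaves))
  }
  paste0("(", paste(leaves(node), collapse = ","), ")")
}

# Depth-first simulation; returns list of leaf states.
.simulate_tree <- function(state, node, registry, acc_rate = 0) {
  nm <- .node_name(node)
  state <- .apply_branch(state, node$branch, nm, registry)
  acc_rate <- acc_rate + node$branch$substitution_rate
  if (is.null(node$children)) {
    return(list(list(name = node$name, state = state, total_rate = acc_rate)))
  }
  out <- list()
  for (child in node$children) {
    out <- c(out, .simulate_tree(state, child, registry, acc_rate))
  }
  out
}

#' Simulate an allopolyploid genome with ground truth
#'
#' Ancestral chromosomes are i.i.d. uniform ACGT. Each tree branch applies
#' substitutions, then TE bursts; hybridizations concatenate the descendant
#' chromosome sets with subgenome-labeled ids; exchanges then move segments
#' between homoeologs. Chromosome ids are `<leaf name><group index>`
#' (e.g. A1..A5, B1..B5); homoeologous group g holds chromosome g of every
#' subgenome.
#'
#' @param config A [sim_config].
#' @param out_dir Optional directory: writes genome.fa, truth.tsv,
#'   design.json, insertions.gff, exchanges.bed, ltr.tsv.
#' @return A `sim_result` list: `genome` (DNAStringSet), `truth`
#'   (data.frame chromosome/subgenome), `design` ([polyploid_design]),
#'   `insertions` (data.frame with final 1-based closed coordinates),
#'   `exchanges`, `ltr_table` (input for [ltr_elements]; non-nested intact
#'   LTR elements), `burst_consensus` (named character), `subgenomes`,
#'   `branch_rates` (named total root-to-leaf substitution rates).
#' @export
simulate_polyploid <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  registry <- new.env(parent = emptyenv())
  ancestral <- lapply(seq_len(config$x), function(i)
    .random_seq(config$chromosome_length))
  root_state <- list(chroms = ancestral, log = .empty_log())
  root <- config$tree
  # treat the configured root branch as the branch into the root node
  root_state <- .apply_branch(root_state, config$root_branch, "root", registry)
  leaves <- .simulate_tree(root_state, root, registry)
  subgenomes <- vapply(leaves, `[[`, "", "name")
  if (anyDuplicated(subgenomes)) stop("duplicate leaf names in tree")

  chrom_ids <- character(); seqs <- list(); logs <- list()
  for (lf in leaves) {
    ids <- paste0(lf$name, seq_len(config$x))
    chrom_ids <- c(chrom_ids, ids)
    seqs <- c(seqs, lf$state$chroms)
    lg <- lf$state$log
    if (nrow(lg)) lg$chromosome <- ids[lg$chrom_idx]
    logs[[lf$name]] <- lg
  }
  names(seqs) <- chrom_ids
  log_df <- do.call(rbind, logs)
  if (is.null(log_df) || nrow(log_df) == 0L) {
    log_df <- cbind(.empty_log(), data.frame(chromosome = character()))
  }
  rownames(log_df) <- NULL

  # homoeologous exchanges on the merged genome
  ex_rows <- list()
  for (e in config$exchanges) {
    don <- paste0(e$donor, e$group)
    acc <- paste0(e$acceptor, e$group)
    if (!don %in% chrom_ids || !acc %in% chrom_ids) {
      stop("exchange references unknown chromosome: ", don, " or ", acc)
    }
    s <- e$start; en <- e$start + e$length - 1L
    if (s < 1L || en > length(seqs[[don]]) || en > length(seqs[[acc]])) {
      stop("exchange segment out of bounds on group ", e$group)
    }
    reciprocal <- isTRUE(e$reciprocal)
    seg_d <- seqs[[don]][s:en]
    if (reciprocal) {
      seg_a <- seqs[[acc]][s:en]
      seqs[[don]][s:en] <- seg_a
    }
    seqs[[acc]][s:en] <- seg_d
    # move insertion-log entries with the segment
    inside <- function(chrom) log_df$chromosome == chrom &
      log_df$start >= s & log_df$end <= en
    overlaps <- function(chrom) log_df$chromosome == chrom &
      log_df$start <= en & log_df$end >= s
    don_in <- inside(don); acc_in <- inside(acc)
    drop <- (overlaps(acc) & !acc_in)
    if (!reciprocal) drop <- drop | acc_in
    moved_d <- log_df[don_in, , drop = FALSE]
    if (nrow(moved_d)) moved_d$chromosome <- acc
    if (reciprocal) {
      moved_a <- log_df[acc_in, , drop = FALSE]
      if (nrow(moved_a)) moved_a$chromosome <- don
      drop <- drop | (overlaps(don) & !don_in) | don_in | acc_in
      log_df <- rbind(log_df[!drop, , drop = FALSE], moved_d, moved_a)
    } else {
      drop <- drop | don_in  # donor keeps its copy too
      log_df <- rbind(log_df[!drop, , drop = FALSE], moved_d,
                      log_df[don_in, , drop = FALSE])
    }
    ex_rows[[length(ex_rows) + 1L]] <- data.frame(
      group = e$group, donor = don, acceptor = acc,
      start = s, end = en, reciprocal = reciprocal)
  }
  exchanges <- if (length(ex_rows)) do.call(rbind, ex_rows) else
    data.frame(group = integer(), donor = character(), acceptor = character(),
               start = integer(), end = integer(), reciprocal = logical())

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chrom_ids
  truth <- data.frame(chromosome = chrom_ids,
                      subgenome = rep(subgenomes, each = config$x))
  groups <- lapply(seq_len(config$x), function(g) paste0(subgenomes, g))
  design <- polyploid_design(p = length(subgenomes), groups = groups,
                             chromosomes = chrom_ids)
  log_df <- log_df[order(log_df$chromosome, log_df$start),
                   c("chromosome", "start", "end", "burst", "branch",
                     "with_ltr", "ltr_length", "nested")]
  rownames(log_df) <- NULL

  lt <- log_df[log_df$with_ltr & !log_df$nested, , drop = FALSE]
  ltr_table <- data.frame(
    chromosome = lt$chromosome, start = lt$start, end = lt$end,
    ltr5_start = lt$start, ltr5_end = lt$start + lt$ltr_length - 1L,
    ltr3_start = lt$end - lt$ltr_length + 1L, ltr3_end = lt$end)

  res <- structure(
    list(genome = genome, truth = truth, design = design,
         insertions = log_df, exchanges = exchanges, ltr_table = ltr_table,
         burst_consensus = as.list(registry), subgenomes = subgenomes,
         branch_rates = setNames(vapply(leaves, `[[`, 0, "total_rate"),
                                 subgenomes),
         config = config),
    class = "sim_result")
  if (!is.null(out_dir)) write_sim_result(res, out_dir)
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", length(x$genome), "chromosomes,",
      length(x$subgenomes), "subgenomes (",
      paste(x$subgenomes, collapse = ", "), "),",
      nrow(x$insertions), "TE insertions,",
      nrow(x$exchanges), "exchange(s)\n")
  invisible(x)
}

#' Write simulation outputs to a directory
#' @param res A `sim_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(res$genome, file.path(out_dir, "genome.fa"))
  utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_design(res$design, file.path(out_dir, "design.json"))
  ins <- res$insertions
  gff <- data.frame(
    seqid = ins$chromosome, source = "polykmer_sim",
    type = "transposable_element", start = ins$start, end = ins$end,
    score = ".", strand = "+", phase = ".",
    attributes = sprintf("ID=%s:%d-%d;burst=%s;branch=%s;nested=%s",
                         ins$chromosome, ins$start, ins$end, ins$burst,
                         ins$branch, tolower(as.character(ins$nested))))
  utils::write.table(gff, file.path(out_dir, "insertions.gff"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ex <- res$exchanges
  bed <- if (nrow(ex)) {
    data.frame(chrom = ex$acceptor, start = ex$start - 1L, end = ex$end,
               name = paste0("from_", ex$donor))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  }
  utils::write.table(bed, file.path(out_dir, "exchanges.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(res$ltr_table, file.path(out_dir, "ltr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Canonical k-mers internal to a burst consensus
#'
#' Ground-truth marker set for a simulated burst: all canonical k-mers of
#' the stored consensus sequence.
#'
#' @param res A `sim_result`.
#' @param burst Burst id (see `res$insertions$burst`); default all bursts.
#' @param k Word length.
#' @return Character vector of canonical k-mers (unique, sorted).
#' @export
burst_kmers <- function(res, burst = NULL, k = 13L) {
  cons <- res$burst_consensus
  if (!is.null(burst)) cons <- cons[burst]
  sort(unique(unlist(lapply(cons, function(s) names(count_kmers(s, k))))))
}

#' Named simulation presets
#'
#' \describe{
#'   \item{tetraploid_clean}{Two progenitors (A, B), each with one private
#'     burst — the cotton/cyprinid pattern. x = 5 chromosomes of 0.5 Mb.}
#'   \item{tetraploid_exchange}{As above at x = 8 chromosomes of 1.5 Mb, plus
#'     one 500-kb homoeologous exchange (A donates into B) on group 3.}
#'   \item{hexaploid_staged}{(SG1,SG2),SG3 with a burst on the shared
#'     (SG1,SG2) branch — an allotetraploid intermediate — plus leaf bursts;
#'     SG2's private burst is small, so shared SG1+SG2 markers outnumber
#'     SG2-only markers.}
#'   \item{octoploid_staged}{((T1,T2),I),V with bursts on the (T1,T2) and
#'     ((T1,T2),I) internal branches (the latter LTR-bearing, for dating),
#'     and leaf bursts on T1 and V. Post-burst substitution on each lineage
#'     is tuned so shared-branch LTR pairs diverge by d ~ 0.035.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed override (default 1729).
#' @return A [sim_config].
#' @export
sim_preset <- function(name = c("tetraploid_clean", "tetraploid_exchange",
                                "hexaploid_staged", "octoploid_staged"),
                       seed = 1729L) {
  if (!is.character(name) || !name[1L] %in%
      c("tetraploid_clean", "tetraploid_exchange", "hexaploid_staged",
        "octoploid_staged")) {
    stop("unknown preset '", name[1L], "'; available: tetraploid_clean, ",
         "tetraploid_exchange, hexaploid_staged, octoploid_staged")
  }
  name <- match.arg(name)
  switch(
    name,
    tetraploid_clean = sim_config(
      tree = sim_node(list(
        sim_leaf("A", sim_branch(0.02, sim_burst(copies = 300L))),
        sim_leaf("B", sim_branch(0.02, sim_burst(copies = 300L)))
      )),
      x = 5L, chromosome_length = 500000L, seed = seed),
    tetraploid_exchange = sim_config(
      tree = sim_node(list(
        sim_leaf("A", sim_branch(0.02, sim_burst(copies = 300L))),
        sim_leaf("B", sim_branch(0.02, sim_burst(copies = 300L)))
      )),
      x = 8L, chromosome_length = 1500000L, seed = seed,
      exchanges = list(list(donor = "A", acceptor = "B", group = 3L,
                            start = 600001L, length = 500000L))),
    hexaploid_staged = sim_config(
      tree = sim_node(list(
        sim_node(list(
          sim_leaf("SG1", sim_branch(0.01, sim_burst(copies = 150L))),
          sim_leaf("SG2", sim_branch(0.01, sim_burst(copies = 150L,
                                                     consensus_length = 150L)))
        ), branch = sim_branch(0.01, sim_burst(copies = 300L))),
        sim_leaf("SG3", sim_branch(0.02, sim_burst(copies = 300L)))
      )),
      x = 5L, chromosome_length = 500000L, seed = seed),
    octoploid_staged = sim_config(
      tree = sim_node(list(
        sim_node(list(
          sim_node(list(
            sim_leaf("T1", sim_branch(0.01, sim_burst(copies = 200L))),
            sim_leaf("T2", sim_branch(0.01))
          ), branch = sim_branch(0.0075, sim_burst(copies = 250L))),
          sim_leaf("I", sim_branch(0.0175, sim_burst(copies = 200L)))
        ), branch = sim_branch(
          0.005,
          sim_burst(copies = 120L, consensus_length = 1400L,
                    with_ltr = TRUE, ltr_length = 200L))),
        sim_leaf("V", sim_branch(0.035, sim_burst(copies = 300L)))
      )),
      x = 5L, chromosome_length = 500000L, seed = seed)
  )
}
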