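#' Randomly subsample reads to a target coverage
#'
#' Uniform sampling without replacement of `min(coverage, n)` reads,
#' deterministic under a fixed seed; the caller's RNG stream is untouched.
#'
#' @param records a `seq_records` tibble.
#' @param coverage target number of reads (>= 1).
#' @param seed optional integer seed.
#' @return a `seq_records` tibble with at most `coverage` rows.
#' @export
subsample_reads <- function(records, coverage, seed = NULL) {
  if (coverage < 1) stop("coverage must be >= 1")
  n <- nrow(records)
  if (n <= coverage) return(records)
  keep <- with_seed(seed, sample.int(n, coverage))
  records[sort(keep), , drop = FALSE]
}

# Orient each read to the reference strand by shared 8-mer counting
# (long reads arrive in random orientation; at Nanopore error rates the
# correct strand shares orders of magnitude more 8-mers than the reverse
# complement).  Sequences shorter than the k-mer fall back to comparing
# edit distances on both strands.
orient_to_ref <- function(ref, seqs, k = 8L) {
  n <- nchar(ref)
  if (n < k) {
    return(vapply(seqs, function(s) {
      if (cpp_edit_distance(ref, reverse_complement(s))[1] <
          cpp_edit_distance(ref, s)[1]) reverse_complement(s) else s
    }, character(1), USE.NAMES = FALSE))
  }
  ref_kmers <- unique(substring(ref, 1:(n - k + 1L), k:n))
  vapply(seqs, function(s) {
    m <- nchar(s)
    if (m < k) return(s)
    fwd <- sum(substring(s, 1:(m - k + 1L), k:m) %in% ref_kmers)
    rc <- reverse_complement(s)
    rev <- sum(substring(rc, 1:(m - k + 1L), k:m) %in% ref_kmers)
    if (rev > fwd) rc else s
  }, character(1), USE.NAMES = FALSE)
}

# One majority-vote round: align every read to `ref` (ends-free, unit
# costs) and re-call each reference column from the aligned bases; gap is a
# votable state (a gap majority deletes the column) and an insertion after
# a column is emitted when strictly more than half of the covering reads
# support one there.  Returns the new sequence and its per-column support.
vote_round <- function(ref, reads) {
  n <- nchar(ref)
  pos_all <- integer(0); base_all <- character(0); who_all <- integer(0)
  ins_pos <- integer(0); ins_str <- character(0); ins_who <- integer(0)
  cover_lo <- integer(length(reads)); cover_hi <- integer(length(reads))
  for (k in seq_along(reads)) {
    al <- cpp_align_overlap(ref, reads[k], free_ref_ends = TRUE)
    ra <- strsplit(al$ref_aln, "")[[1]]
    ba <- strsplit(al$read_aln, "")[[1]]
    is_ref <- ra != "-"
    refpos <- cumsum(is_ref) + al$ref_start        # 1-based ref coordinate
    pos_all <- c(pos_all, refpos[is_ref])
    base_all <- c(base_all, ba[is_ref])
    who_all <- c(who_all, rep.int(k, sum(is_ref)))
    cover_lo[k] <- al$ref_start + 1L
    cover_hi[k] <- al$ref_end
    if (any(!is_ref)) {
      r <- rle(is_ref)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gaps <- which(!r$values)
      for (g in gaps) {
        junction <- refpos[starts[g]]             # insert sits after this ref pos
        ins_pos <- c(ins_pos, junction)
        ins_str <- c(ins_str,
                     paste(ba[starts[g]:ends[g]], collapse = ""))
        ins_who <- c(ins_who, k)
      }
    }
  }
  # per-column vote
  new_base <- strsplit(ref, "")[[1]]
  support <- rep(NA_real_, n)
  if (length(pos_all)) {
    tab <- table(pos_all, base_all)
    cols <- colnames(tab)
    positions <- as.integer(rownames(tab))
    cover <- rowSums(tab)
    for (r in seq_along(positions)) {
      p <- positions[r]
      cnt <- tab[r, ]
      mx <- max(cnt)
      winners <- cols[cnt == mx]
      # tie-break: keep the current consensus base if tied, else first
      # alphabetically ('-' sorts first, i.e. ties lean to deletion only
      # when the reference base is not among the winners)
      b <- if (new_base[p] %in% winners) new_base[p] else sort(winners)[1]
      new_base[p] <- b
      support[p] <- mx / cover[r]
    }
  }
  # insertions: support = reads with an insert at the junction / reads
  # whose aligned span covers the junction (both flanking columns)
  inserts <- rep("", n + 1L)                     # after position 0..n
  if (length(ins_pos)) {
    for (p in unique(ins_pos)) {
      covering <- sum(cover_lo <= p & cover_hi >= min(p + 1L, n))
      sel <- ins_pos == p
      supp <- length(unique(ins_who[sel])) / max(covering, 1L)
      if (supp > 0.5) {
        s <- sort(table(ins_str[sel]), decreasing = TRUE)
        inserts[p + 1L] <- names(s)[1]
      }
    }
  }
  keep <- new_base != "-"
  pieces <- character(0)
  supp_out <- numeric(0)
  if (nzchar(inserts[1])) {
    pieces <- c(pieces, inserts[1])
    supp_out <- c(supp_out, rep(NA_real_, nchar(inserts[1])))
  }
  for (p in seq_len(n)) {
    if (keep[p]) {
      pieces <- c(pieces, new_base[p])
      supp_out <- c(supp_out, support[p])
    }
    if (nzchar(inserts[p + 1L])) {
      pieces <- c(pieces, inserts[p + 1L])
      supp_out <- c(supp_out, rep(NA_real_, nchar(inserts[p + 1L])))
    }
  }
  list(sequence = paste(pieces, collapse = ""), support = supp_out)
}

#' Draft consensus from a seed read
#'
#' The read of median length is taken as the seed (ties break to the
#' earlier read); all other reads are oriented to the seed strand, aligned
#' to it ends-free, and each seed column is re-called by majority vote,
#' with gap as a votable state and insertions included when supported by
#' strictly more than half of the reads.
#'
#' @param records a `seq_records` tibble with at least one read.
#' @return the draft consensus DNA string.
#' @export
draft_consensus <- function(records) {
  n <- nrow(records)
  if (n == 0) stop("no reads")
  lens <- nchar(records$seq)
  seed_i <- which.min(abs(lens - median(lens)))   # earliest on ties
  if (n == 1) return(records$seq[1])
  seed <- records$seq[seed_i]
  vote_round(seed, orient_to_ref(seed, records$seq))$sequence
}

#' Iterative majority-vote polishing
#'
#' Reads are first oriented to the draft strand (shared k-mer test); each
#' round then re-aligns all reads to the current consensus and re-votes
#' every column (the contract of the minimap+RACON cycles).  The support
#' vector of the final round is reported; `rounds = 0` returns the draft
#' unchanged.
#'
#' @param draft draft consensus string.
#' @param records a `seq_records` tibble.
#' @param rounds number of polishing rounds (default 2).
#' @return a `consensus_result`: `sequence`, `n_reads_used`, `rounds`,
#'   `support` (fraction of covering reads agreeing with each called base;
#'   NA at uncovered or freshly inserted positions).
#' @export
polish <- function(draft, records, rounds = 2L) {
  stopifnot(rounds >= 0)
  seqs <- if (rounds > 0) orient_to_ref(draft, records$seq) else records$seq
  cur <- draft
  support <- rep(NA_real_, nchar(draft))
  for (r in seq_len(rounds)) {
    v <- vote_round(cur, seqs)
    cur <- v$sequence
    support <- v$support
  }
  structure(list(sequence = cur, n_reads_used = length(seqs),
                 rounds = as.integer(rounds), support = support),
            class = "consensus_result")
}

#' Per-sample consensus pipeline
#'
#' Subsample to `coverage_cap` reads, build the draft, and polish.  Refuses
#' to run below `min_coverage` reads (the published minimum is 30); the
#' default cap of 300 reflects the observed accuracy plateau at high
#' coverage.
#'
#' @param records a `seq_records` tibble (one demultiplexed sample).
#' @param min_coverage minimum acceptable number of reads.
#' @param coverage_cap subsample to this many reads (NULL for no cap).
#' @param rounds polishing rounds.
#' @param seed RNG seed for the subsampling.
#' @return a `consensus_result` (see [polish()]).
#' @export
consensus_pipeline <- function(records, min_coverage = 30L,
                               coverage_cap = 300L, rounds = 2L,
                               seed = NULL) {
  n <- nrow(records)
  if (n < min_coverage)
    stop("insufficient coverage: ", n, " reads < minimum ", min_coverage)
  if (!is.null(coverage_cap))
    records <- subsample_reads(records, coverage_cap, seed = seed)
  res <- polish(draft_consensus(records), records, rounds = rounds)
  res$n_reads_used <- nrow(records)
  res
}

#' Percent identity between two sequences by global alignment
#'
#' Global unit-cost (Needleman-Wunsch) alignment; identity =
#' 100 * (1 - edits / aligned columns).  Used to score consensus sequences
#' against a known truth.
#'
#' @param a,b DNA strings.
#' @return percent identity in `[0, 100]`.
#' @export
alignment_identity <- function(a, b) {
  al <- cpp_align_overlap(toupper(a), toupper(b), free_ref_ends = FALSE)
  cols <- nchar(al$ref_aln)
  100 * (1 - al$dist / cols)
}

#' Write a consensus and its per-column support
#'
#' Emits `<sample>.consensus.fasta` plus a `<sample>.support.tsv` sidecar
#' (`position`, `base`, `support`) so mixed columns remain inspectable even
#' though the consensus itself collapses them to the majority base.
#'
#' @param result a `consensus_result`.
#' @param sample sample name (used for the FASTA id and file names).
#' @param dir output directory.
#' @return paths of the two files, invisibly.
#' @export
write_consensus <- function(result, sample, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(sample, ".consensus.fasta"))
  tsv <- file.path(dir, paste0(sample, ".support.tsv"))
  write_sequences(seq_records(sample, result$sequence,
                              desc = sprintf("n_reads=%d rounds=%d",
                                             result$n_reads_used,
                                             result$rounds)),
                  fa, format = "fasta")
  write.table(
    data.frame(position = seq_len(nchar(result$sequence)),
               base = strsplit(result$sequence, "")[[1]],
               support = round(result$support, 4)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %d bp from %d reads (%d polish rounds); mean support %.3f\n",
    nchar(x$sequence), x$n_reads_used, x$rounds,
    mean(x$support, na.rm = TRUE)))
  invisible(x)
}
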