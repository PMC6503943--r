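#' Demultiplexing configuration
#'
#' Collects the thresholds of the dual-index demultiplexer.  Defaults follow
#' the published long-amplicon run: index edit distance 2, primer edit
#' distance 11, quality > 13 and length > 3000 filters.
#'
#' @param index_max_edits maximum edit distance for an index hit.
#' @param primer_max_edits maximum edit distance for the primer confirmation.
#' @param percent_mode optional fraction in (0,1); when set, each pattern's
#'   allowance is `floor(percent_mode * nchar(pattern))` instead of the two
#'   absolute maxima.
#' @param search_window bases examined at each read end.
#' @param require_primer require the primer to be found interior to each
#'   index hit for the hit to count.
#' @param trim_mode `"trim"` (cut to the insert), `"mark"` (lowercase the tag
#'   regions; FASTA output only) or `"none"`.
#' @param output_mode `"per_sample"` or `"single_file"`.
#' @param min_quality reads must have probability-domain mean quality
#'   strictly greater than this (NA disables, e.g. for FASTA input).
#' @param min_length reads must be strictly longer than this.
#' @return a list of class `demux_config`.
#' @export
demux_config <- function(index_max_edits = 2L, primer_max_edits = 11L,
                         percent_mode = NULL, search_window = 100L,
                         require_primer = TRUE,
                         trim_mode = c("trim", "mark", "none"),
                         output_mode = c("per_sample", "single_file"),
                         min_quality = 13, min_length = 3000L) {
  trim_mode <- match.arg(trim_mode)
  output_mode <- match.arg(output_mode)
  stopifnot(index_max_edits >= 0, primer_max_edits >= 0, search_window >= 1,
            min_length >= 0)
  if (!is.null(percent_mode))
    stopifnot(percent_mode > 0, percent_mode < 1)
  structure(list(index_max_edits = as.integer(index_max_edits),
                 primer_max_edits = as.integer(primer_max_edits),
                 percent_mode = percent_mode,
                 search_window = as.integer(search_window),
                 require_primer = isTRUE(require_primer),
                 trim_mode = trim_mode, output_mode = output_mode,
                 min_quality = min_quality,
                 min_length = as.integer(min_length)),
            class = "demux_config")
}

allowance <- function(pattern, config, kind = c("index", "primer")) {
  kind <- match.arg(kind)
  if (!is.null(config$percent_mode))
    return(as.integer(floor(config$percent_mode * nchar(pattern))))
  if (kind == "index") config$index_max_edits else config$primer_max_edits
}

#' Mean read quality in the probability domain
#'
#' Per-base Phred scores are converted to error probabilities, averaged, and
#' converted back: `-10 * log10(mean(10^(-Q/10)))`.  This is the standard
#' long-read "mean quality" (NanoFilt convention), not the arithmetic mean
#' of the scores, which would understate the error rate.
#'
#' @param records a `seq_records` tibble; every record must carry qualities.
#' @return numeric vector of mean qualities, one per record.
#' @examples
#' r <- seq_records("r1", "AA", qual = list(c(10L, 20L)))
#' mean_quality(r)  # 12.596
#' @export
mean_quality <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    q <- records$qual[[i]]
    if (is.null(q)) stop("record '", records$id[i], "' has no quality scores")
    if (length(q) == 0) stop("record '", records$id[i], "' has empty sequence")
    -10 * log10(mean(10^(-q / 10)))
  }, numeric(1))
}

#' Filter reads on mean quality and length
#'
#' A read is kept iff its probability-domain mean quality is strictly
#' greater than `min_quality` and its length strictly greater than
#' `min_length` (both strict, following the published "> 13" / "> 3 kb"
#' filters).  Reads failing the length test are counted as length removals
#' even if they would also fail on quality.
#'
#' @param records a `seq_records` tibble.
#' @param config a [demux_config()]; only `min_quality` / `min_length` used.
#' @return `list(records = kept records, report = one-row tibble with
#'   n_input, n_kept, removed_quality, removed_length)`.
#' @export
filter_reads <- function(records, config = demux_config()) {
  n <- nrow(records)
  len_ok <- nchar(records$seq) > config$min_length
  if (!is.na(config$min_quality)) {
    qual_ok <- rep(TRUE, n)
    if (n > 0) qual_ok <- mean_quality(records) > config$min_quality
  } else qual_ok <- rep(TRUE, n)
  keep <- len_ok & qual_ok
  report <- tibble(n_input = n, n_kept = sum(keep),
                   removed_length = sum(!len_ok),
                   removed_quality = sum(len_ok & !qual_ok))
  list(records = records[keep, , drop = FALSE], report = report)
}

# Search one read end for the best index (+ optional primer confirmation).
# `window_seq` is the windowed text; `offset` maps window to read
# coordinates; `side` is "head" (tags at window start, primer interior to
# the right) or "tail" (tags at window end, primer interior to the left).
# `indexes`/`primers_of` give the candidate patterns already oriented as
# they appear on this strand of the read.
search_end <- function(window_seq, offset, side, indexes, primers_of, config,
                       strand) {
  hits <- list()
  for (idx in names(indexes)) {
    pat <- indexes[[idx]]
    h <- infix_search(pat, window_seq, allowance(pat, config, "index"),
                      iupac = TRUE, pattern_id = idx, strand = strand,
                      window = side)
    if (is.null(h)) next
    primer_hit <- NULL
    if (config$require_primer) {
      ok <- FALSE
      for (pr in primers_of[[idx]]) {
        k <- allowance(pr, config, "primer")
        if (side == "head") {
          sub_start <- h$end
          sub_end <- min(nchar(window_seq), h$end + nchar(pr) + k)
        } else {
          sub_start <- max(0L, h$start - nchar(pr) - k)
          sub_end <- h$start
        }
        if (sub_end <= sub_start) next
        ph <- infix_search(pr, substr(window_seq, sub_start + 1L, sub_end), k,
                           iupac = TRUE, pattern_id = pr, strand = strand,
                           window = side)
        if (!is.null(ph)) {
          ph$start <- ph$start + sub_start
          ph$end <- ph$end + sub_start
          ok <- TRUE
          primer_hit <- ph
          break
        }
      }
      if (!ok) next
    }
    h$start <- h$start + offset
    h$end <- h$end + offset
    if (!is.null(primer_hit)) {
      primer_hit$start <- primer_hit$start + offset
      primer_hit$end <- primer_hit$end + offset
    }
    hits[[length(hits) + 1L]] <- list(index = idx, hit = h,
                                      primer_hit = primer_hit)
  }
  if (length(hits) == 0) return(list(status = "none"))
  d <- vapply(hits, function(x) x$hit$edit_distance, integer(1))
  best <- which(d == min(d))
  if (length(best) > 1) return(list(status = "tie"))
  c(list(status = "hit"), hits[[best]])
}

# Evaluate one orientation hypothesis for one read.
orient_candidate <- function(seq, specs, config, strand, tags) {
  L <- nchar(seq)
  w <- min(config$search_window, L %/% 2L)
  if (w < 1L) return(list(status = "none"))
  head_seq <- substr(seq, 1L, w)
  tail_seq <- substr(seq, L - w + 1L, L)
  head_res <- search_end(head_seq, 0L, "head", tags$head_idx,
                         tags$head_primers, config, strand)
  if (head_res$status == "tie") return(list(status = "tie"))
  tail_res <- search_end(tail_seq, L - w, "tail", tags$tail_idx,
                         tags$tail_primers, config, strand)
  if (tail_res$status == "tie") return(list(status = "tie"))
  if (head_res$status != "hit" || tail_res$status != "hit")
    return(list(status = "none"))
  if (strand == "+") { fwd <- head_res; rev <- tail_res }
  else               { fwd <- tail_res; rev <- head_res }
  row <- which(specs$fwd_index == fwd$index & specs$rev_index == rev$index)
  if (length(row) != 1) return(list(status = "none"))
  list(status = "valid", sample = specs$sample_name[row],
       fwd_hit = fwd$hit, rev_hit = rev$hit,
       head = head_res, tail = tail_res,
       total = fwd$hit$edit_distance + rev$hit$edit_distance)
}

# Precompute the oriented tag patterns for both orientation hypotheses.
build_tag_sets <- function(specs) {
  uf <- unique(specs$fwd_index)
  ur <- unique(specs$rev_index)
  fwd_primers <- lapply(setNames(uf, uf), function(i)
    unique(specs$fwd_primer[specs$fwd_index == i]))
  rev_primers <- lapply(setNames(ur, ur), function(i)
    unique(specs$rev_primer[specs$rev_index == i]))
  list(
    # "+" read: fwd tags at head as-is; rev tags at tail reverse-complemented
    plus = list(head_idx = setNames(as.list(uf), uf),
                head_primers = fwd_primers,
                tail_idx = setNames(as.list(reverse_complement(ur)), ur),
                tail_primers = lapply(rev_primers, reverse_complement)),
    # "-" read: rev tags at head as-is; fwd tags at tail reverse-complemented
    minus = list(head_idx = setNames(as.list(ur), ur),
                 head_primers = rev_primers,
                 tail_idx = setNames(as.list(reverse_complement(uf)), uf),
                 tail_primers = lapply(fwd_primers, reverse_complement)))
}

#' Assign one read to a sample
#'
#' Implements the dual-index search: the first and last `search_window`
#' bases of the read are scanned for the forward and reverse index (each
#' within its edit-distance allowance, IUPAC-aware) under both orientation
#' hypotheses; when `require_primer` is on an index hit only counts if its
#' primer is found within its own allowance immediately interior to the
#' index.  A read is assigned iff a unique best forward and a unique best
#' reverse index are found and the pair occurs in the barcode table.  Ties
#' between different indexes at the best distance, or conflicting valid
#' assignments from the two orientations, yield `ambiguous`; everything
#' else is `unassigned`.
#'
#' @param record one-row `seq_records` tibble.
#' @param specs sample-spec tibble (see [parse_barcode_table()]).
#' @param config a [demux_config()].
#' @param tags precomputed [build_tag_sets()] output (internal; supplied by
#'   [demultiplex()] to avoid recomputation).
#' @return a `demux_assignment` list: `read_id`, `category`, `sample_name`,
#'   `orientation`, `fwd_hit`, `rev_hit`, `insert_span` (0-based half-open),
#'   `tag_intervals`.
#' @export
assign_read <- function(record, specs, config = demux_config(), tags = NULL) {
  stopifnot(nrow(specs) > 0)
  maxcat <- max(nchar(specs$fwd_index) + nchar(specs$fwd_primer),
                nchar(specs$rev_index) + nchar(specs$rev_primer))
  if (config$search_window < maxcat)
    stop("search_window (", config$search_window,
         ") shorter than the longest index+primer concatenation (", maxcat, ")")
  if (is.null(tags)) tags <- build_tag_sets(specs)
  seq <- record$seq[1]
  plus <- orient_candidate(seq, specs, config, "+", tags$plus)
  minus <- orient_candidate(seq, specs, config, "-", tags$minus)
  out <- list(read_id = record$id[1], category = "unassigned",
              sample_name = NA_character_, orientation = NA_character_,
              fwd_hit = NULL, rev_hit = NULL,
              insert_span = c(0L, nchar(seq)), tag_intervals = NULL)
  pick <- NULL
  if (plus$status == "valid" && minus$status == "valid") {
    if (plus$sample != minus$sample) {
      out$category <- "ambiguous"
      class(out) <- "demux_assignment"
      return(out)
    }
    pick <- if (minus$total < plus$total) list(minus, "-") else list(plus, "+")
  } else if (plus$status == "valid" && minus$status == "none") {
    pick <- list(plus, "+")
  } else if (minus$status == "valid" && plus$status == "none") {
    pick <- list(minus, "-")
  } else if (plus$status == "tie" || minus$status == "tie") {
    out$category <- "ambiguous"
    class(out) <- "demux_assignment"
    return(out)
  }
  if (is.null(pick)) {
    class(out) <- "demux_assignment"
    return(out)
  }
  cand <- pick[[1]]
  head_end <- if (!is.null(cand$head$primer_hit)) cand$head$primer_hit$end
              else cand$head$hit$end
  tail_start <- if (!is.null(cand$tail$primer_hit)) cand$tail$primer_hit$start
                else cand$tail$hit$start
  head_start <- cand$head$hit$start
  tail_end <- cand$tail$hit$end
  if (tail_start < head_end) tail_start <- head_end  # degenerate tiny read
  out$category <- "assigned"
  out$sample_name <- cand$sample
  out$orientation <- pick[[2]]
  out$fwd_hit <- cand$fwd_hit
  out$rev_hit <- cand$rev_hit
  out$insert_span <- c(head_end, tail_start)
  out$tag_intervals <- rbind(c(head_start, head_end), c(tail_start, tail_end))
  class(out) <- "demux_assignment"
  out
}

#' Trim or mark the tag regions of an assigned read
#'
#' `"trim"` cuts sequence and quality to the insert span in sync; `"mark"`
#' keeps the full sequence and attaches the tag intervals in a `mask`
#' list-column, which [write_sequences()] lowercases in FASTA output (case
#' is not representable in FASTQ, so marking for FASTQ output is an error);
#' `"none"` returns the record unchanged.
#'
#' @param record one-row `seq_records` tibble.
#' @param assignment the read's `demux_assignment`.
#' @param trim_mode `"trim"`, `"mark"` or `"none"`.
#' @param output_format intended output format; `"fastq"` with `"mark"`
#'   errors.
#' @return a one-row `seq_records` tibble (with a `mask` column for mark).
#' @export
trim_read <- function(record, assignment,
                      trim_mode = c("trim", "mark", "none"),
                      output_format = NULL) {
  trim_mode <- match.arg(trim_mode)
  if (trim_mode == "none") return(record)
  stopifnot(assignment$category == "assigned")
  if (trim_mode == "mark") {
    if (identical(output_format, "fastq"))
      stop("mark mode is not representable in FASTQ output")
    record$mask <- list(assignment$tag_intervals)
    return(record)
  }
  s <- assignment$insert_span
  record$seq <- substr(record$seq, s[1] + 1L, s[2])
  if (!is.null(record$qual[[1]]))
    record$qual[[1]] <- record$qual[[1]][seq.int(s[1] + 1L, length.out = s[2] - s[1])]
  record
}

#' Demultiplex a read set
#'
#' Runs [assign_read()] on every read and partitions the set into one group
#' per sample plus `unassigned` and `ambiguous`.  Every read lands in
#' exactly one group and the summary counts sum to the input count.
#' Assigned reads are normalized to the template (+) strand in the output
#' groups (sequence reverse-complemented, qualities reversed), so each
#' per-sample group is strand-consistent for consensus calling; the
#' `assignments` table records each read's original orientation.
#'
#' @param records a `seq_records` tibble.
#' @param specs sample-spec tibble.
#' @param config a [demux_config()].
#' @return `list(groups, summary, assignments)`: `groups` is a named list of
#'   `seq_records` (trimmed/marked per `trim_mode`; in `single_file` mode a
#'   single `all` group with `sample=<name>` written into descriptions),
#'   `summary` a tibble of per-group read counts, `assignments` a tibble
#'   with one row per read (`read_id`, `category`, `sample_name`,
#'   `orientation`, `fwd_dist`, `rev_dist`, `insert_start`, `insert_end`).
#' @export
demultiplex <- function(records, specs, config = demux_config()) {
  tags <- if (nrow(specs)) build_tag_sets(specs) else NULL
  n <- nrow(records)
  assigns <- vector("list", n)
  for (i in seq_len(n))
    assigns[[i]] <- assign_read(records[i, , drop = FALSE], specs, config, tags)
  assignments <- tibble(
    read_id = vapply(assigns, `[[`, character(1), "read_id"),
    category = vapply(assigns, `[[`, character(1), "category"),
    sample_name = vapply(assigns, `[[`, character(1), "sample_name"),
    orientation = vapply(assigns, `[[`, character(1), "orientation"),
    fwd_dist = vapply(assigns, function(a)
      if (is.null(a$fwd_hit)) NA_integer_ else a$fwd_hit$edit_distance,
      integer(1)),
    rev_dist = vapply(assigns, function(a)
      if (is.null(a$rev_hit)) NA_integer_ else a$rev_hit$edit_distance,
      integer(1)),
    insert_start = vapply(assigns, function(a) a$insert_span[1], integer(1)),
    insert_end = vapply(assigns, function(a) a$insert_span[2], integer(1)))

  groomed <- records
  if (n > 0) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      r <- if (assigns[[i]]$category == "assigned" && config$trim_mode != "none")
        trim_read(records[i, , drop = FALSE], assigns[[i]], config$trim_mode)
      else records[i, , drop = FALSE]
      # normalize assigned reads to the template (+) strand so per-sample
      # groups are strand-consistent for downstream consensus calling
      if (assigns[[i]]$category == "assigned" &&
          assigns[[i]]$orientation == "-") {
        L <- nchar(r$seq[1])
        r$seq[1] <- reverse_complement(r$seq[1])
        if (!is.null(r$qual[[1]])) r$qual[[1]] <- rev(r$qual[[1]])
        if ("mask" %in% names(r) && !is.null(r$mask[[1]]))
          r$mask[[1]] <- cbind(L - r$mask[[1]][, 2], L - r$mask[[1]][, 1])
      }
      rows[[i]] <- r
    }
    if (!all(vapply(rows, function(x) "mask" %in% names(x), logical(1))))
      rows <- lapply(rows, function(x) { if (!"mask" %in% names(x)) x$mask <- list(NULL); x })
    groomed <- do.call(rbind, rows)
    if (all(vapply(groomed$mask, is.null, logical(1)))) groomed$mask <- NULL
  }

  group_of <- ifelse(assignments$category == "assigned",
                     assignments$sample_name, assignments$category)
  group_names <- c(specs$sample_name, "unassigned", "ambiguous")
  if (config$output_mode == "single_file") {
    out <- groomed
    if (n > 0)
      out$desc <- trimws(paste(out$desc, paste0("sample=", group_of)))
    groups <- list(all = out)
  } else {
    groups <- lapply(setNames(group_names, group_names), function(g)
      groomed[group_of == g, , drop = FALSE])
  }
  counts <- table(factor(group_of, levels = group_names))
  summary <- tibble(sample = group_names, n_reads = as.integer(counts))
  list(groups = groups, summary = summary, assignments = assignments)
}

#' Write demultiplexed groups to per-sample files
#'
#' Writes `<group>.<ext>` per group (including `unassigned` / `ambiguous`)
#' plus a `summary.tsv`, logging one line per file to stderr.
#'
#' @param result a [demultiplex()] result.
#' @param dir output directory (created if needed).
#' @param format `"fastq"` or `"fasta"`.
#' @return the output directory, invisibly.
#' @export
demux_write <- function(result, dir, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(result$groups)) {
    recs <- result$groups[[g]]
    path <- file.path(dir, paste0(g, ".", format))
    mask <- if ("mask" %in% names(recs)) recs$mask else NULL
    if (!is.null(mask) && format == "fastq")
      stop("mark mode is not representable in FASTQ output")
    write_sequences(recs, path, format = format, lowercase_mask = mask)
    message(sprintf("wrote %d reads to %s", nrow(recs), path))
  }
  write.table(result$summary, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.demux_assignment <- function(x, ...) {
  cat(sprintf("<demux_assignment> %s: %s%s%s\n", x$read_id, x$category,
              if (x$category == "assigned")
                paste0(" -> ", x$sample_name, " (", x$orientation, ")") else "",
              if (x$category == "assigned")
                sprintf(" insert [%d,%d)", x$insert_span[1], x$insert_span[2])
              else ""))
  invisible(x)
}
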