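#' Nanopore-like error model
#'
#' Per-base independent error process with separate substitution, insertion
#' and deletion rates.  Defaults sum to a 12% raw error rate (6% / 3% /
#' 3%), the lower end of the published Nanopore raw-read error range.
#' `homopolymer_factor` multiplies the indel rates inside homopolymer runs
#' of length >= 3 (1 = off).
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities in `[0,1]`,
#'   summing to at most 1.
#' @param homopolymer_factor indel-rate multiplier inside runs >= 3.
#' @return a list of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.06, ins_rate = 0.03, del_rate = 0.03,
                        homopolymer_factor = 1) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate <= 1, ins_rate <= 1, del_rate <= 1,
            sub_rate + ins_rate + del_rate <= 1, homopolymer_factor >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_factor = homopolymer_factor),
            class = "error_model")
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' @param length number of bases.
#' @param max_homopolymer cap on homopolymer run length (Inf for none).
#' @return a DNA string.
#' @export
random_dna <- function(length, max_homopolymer = Inf) {
  if (length == 0) return("")
  if (is.infinite(max_homopolymer))
    return(paste(DNA_BASES[sample.int(4, length, replace = TRUE)],
                 collapse = ""))
  out <- character(length)
  run <- 0L
  for (i in seq_len(length)) {
    choices <- DNA_BASES
    if (i > 1 && run >= max_homopolymer)
      choices <- setdiff(DNA_BASES, out[i - 1])
    out[i] <- choices[sample.int(length(choices), 1)]
    run <- if (i > 1 && out[i] == out[i - 1]) run + 1L else 1L
  }
  paste(out, collapse = "")
}

#' Design a set of mutually distant indexes
#'
#' Generates ACGT-only index sequences with homopolymer runs capped at 3
#' and every pair at Levenshtein distance >= `min_dist` (the published
#' sets used 15-bp indexes at minimum distance 10).  Candidates are drawn
#' at random under a fixed seed and accepted greedily; a candidate that
#' violates the distance floor is repaired by hill-climbing single-base
#' mutations that reduce its total distance violation, each mutation
#' counting against the attempt budget.  All pairwise distances are
#' re-verified post hoc before returning.
#'
#' @param n number of indexes required, or `NULL` for as many as the
#'   attempt budget yields (maximal-set mode).
#' @param length index length in bases.
#' @param min_dist minimum pairwise Levenshtein distance.
#' @param seed optional RNG seed (deterministic output under a fixed seed).
#' @param max_attempts total candidate/mutation budget.
#' @param repair_steps hill-climb budget per candidate.
#' @return character vector of indexes (length `n` when `n` given).
#' @export
design_indexes <- function(n = NULL, length = 15L, min_dist = 10L,
                           seed = NULL, max_attempts = 1e5,
                           repair_steps = 300L) {
  stopifnot(is.null(n) || n >= 1, length >= 1, min_dist >= 0)
  set <- with_seed(seed, {
    set <- character(0)
    attempts <- 0L
    viol <- function(x) {
      if (length(set) == 0) return(0L)
      sum(pmax(0L, min_dist - cpp_dist_to_set(x, set)))
    }
    while (attempts < max_attempts && (is.null(n) || length(set) < n)) {
      cand <- random_dna(length, max_homopolymer = 3)
      attempts <- attempts + 1L
      v <- viol(cand)
      steps <- 0L
      while (v > 0 && steps < repair_steps && attempts < max_attempts) {
        pos <- sample.int(length, 1)
        base <- DNA_BASES[sample.int(4, 1)]
        cand2 <- cand
        substr(cand2, pos, pos) <- base
        attempts <- attempts + 1L
        steps <- steps + 1L
        if (cand2 == cand) next
        if (max(rle(strsplit(cand2, "")[[1]])$lengths) > 3) next
        v2 <- viol(cand2)
        if (v2 <= v) { cand <- cand2; v <- v2 }
      }
      if (v == 0 && !(cand %in% set)) set <- c(set, cand)
    }
    set
  })
  if (!is.null(n) && length(set) < n)
    stop("could not design ", n, " indexes within ", max_attempts,
         " attempts; only ", length(set), " achievable")
  # post-hoc verification is part of the contract
  if (length(set) > 1) {
    for (i in 1:(length(set) - 1)) {
      d <- cpp_dist_to_set(set[i], set[(i + 1):length(set)])
      if (any(d < min_dist))
        stop("internal error: designed set violates the distance floor")
    }
  }
  if (any(grepl("[^ACGT]", set)))
    stop("internal error: non-ACGT index")
  set
}

# Error-process core shared by the exported mutator: returns the mutated
# character vector and the number of error events.
mutate_chars <- function(ch, model) {
  n <- length(ch)
  if (n == 0) return(list(ch = character(0), n_errors = 0L))
  if (model$sub_rate + model$ins_rate + model$del_rate == 0)
    return(list(ch = ch, n_errors = 0L))
  hp <- rep(1, n)
  if (model$homopolymer_factor != 1 && n >= 3) {
    r <- rle(ch)
    inrun <- inverse.rle(list(lengths = r$lengths, values = r$lengths >= 3))
    hp[inrun] <- model$homopolymer_factor
  }
  del <- runif(n) < pmin(1, model$del_rate * hp)
  sub <- runif(n) < model$sub_rate
  ins <- runif(n) < pmin(1, model$ins_rate * hp)
  out <- ch
  subbed <- which(sub & !del)
  if (length(subbed)) {
    # uniform over the three other bases
    off <- sample.int(3, length(subbed), replace = TRUE)
    out[subbed] <- DNA_BASES[((match(ch[subbed], DNA_BASES) - 1L + off) %% 4L) + 1L]
  }
  kept <- which(!del)
  inserted <- which(ins)
  ins_base <- DNA_BASES[sample.int(4, length(inserted), replace = TRUE)]
  # interleave: kept base at position i, insertion after it at i + 0.5
  pos <- c(kept, inserted + 0.5)
  chars <- c(out[kept], ins_base)
  list(ch = chars[order(pos)],
       n_errors = sum(del) + length(subbed) + length(inserted))
}

#' Apply a Nanopore-like error process to a sequence
#'
#' Per base: drop it with probability `del_rate`; otherwise substitute a
#' different uniform base with probability `sub_rate`; independently insert
#' a uniform random base after it with probability `ins_rate`.  The
#' returned quality string is constant at `Q = round(-10*log10(sub + ins +
#' del))` (capped at 40 for an error-free model), consistent with the
#' realized error profile in expectation.
#'
#' @param seq DNA string.
#' @param model an [error_model()].
#' @param seed optional RNG seed.
#' @return `list(seq, qual, n_errors)`.
#' @export
mutate_sequence <- function(seq, model = error_model(), seed = NULL) {
  with_seed(seed, {
    res <- mutate_chars(strsplit(seq, "")[[1]], model)
    total <- model$sub_rate + model$ins_rate + model$del_rate
    q <- if (total <= 0) 40L else
      as.integer(min(40, max(0, round(-10 * log10(total)))))
    list(seq = paste(res$ch, collapse = ""),
         qual = rep(q, length(res$ch)), n_errors = res$n_errors)
  })
}

# Resolve IUPAC degeneracies to concrete random bases (one molecule).
resolve_degenerate <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  amb <- which(!ch %in% DNA_BASES)
  for (i in amb) {
    opts <- DNA_BASES[bitwAnd(iupac_bits(ch[i]), c(1L, 2L, 4L, 8L)) > 0]
    ch[i] <- opts[sample.int(length(opts), 1)]
  }
  paste(ch, collapse = "")
}

iupac_bits <- function(c) {
  switch(c, A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
         S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
         V = 7L, N = 15L, stop("non-IUPAC character: ", c))
}

#' Simulate dual-indexed amplicon reads
#'
#' Each molecule is `fwd_index + fwd_primer + insert +
#' revcomp(rev_primer) + revcomp(rev_index)` with primer degeneracies
#' resolved per molecule; orientation is flipped with probability 0.5, the
#' error model applied, and per-read ground truth recorded.
#'
#' @param specs sample-spec tibble (see [parse_barcode_table()]).
#' @param references named character vector/list mapping every sample name
#'   to its insert sequence.
#' @param n_per_sample reads per sample.
#' @param model an [error_model()].
#' @param seed optional RNG seed (byte-identical output under a fixed seed).
#' @param force_orientation `"+"` or `"-"` to disable random flipping.
#' @return `list(records, truth)`: `records` a `seq_records` tibble,
#'   `truth` a tibble (`read_id`, `sample_name`, `orientation`,
#'   `template_length`, `insert_start`, `insert_end`, `n_errors`) with
#'   insert coordinates 0-based half-open on the clean + template.
#' @export
simulate_reads <- function(specs, references, n_per_sample, model = error_model(),
                           seed = NULL, force_orientation = NULL) {
  missing <- setdiff(specs$sample_name, names(references))
  if (length(missing))
    stop("missing reference for sample(s): ", paste(missing, collapse = ", "))
  with_seed(seed, {
    recs <- list(); truth <- list(); k <- 0L
    for (s in seq_len(nrow(specs))) {
      sm <- specs$sample_name[s]
      insert <- normalize_seq(references[[sm]])
      for (r in seq_len(n_per_sample)) {
        k <- k + 1L
        fp <- resolve_degenerate(specs$fwd_primer[s])
        rp <- resolve_degenerate(specs$rev_primer[s])
        template <- paste0(specs$fwd_index[s], fp, insert,
                           reverse_complement(rp),
                           reverse_complement(specs$rev_index[s]))
        ins_start <- nchar(specs$fwd_index[s]) + nchar(fp)
        orientation <- if (!is.null(force_orientation)) force_orientation
                       else if (runif(1) < 0.5) "-" else "+"
        mol <- if (orientation == "-") reverse_complement(template) else template
        mut <- mutate_chars(strsplit(mol, "")[[1]], model)
        total <- model$sub_rate + model$ins_rate + model$del_rate
        q <- if (total <= 0) 40L else
          as.integer(min(40, max(0, round(-10 * log10(total)))))
        recs[[k]] <- list(id = sprintf("read%06d", k),
                          seq = paste(mut$ch, collapse = ""),
                          qual = rep(q, length(mut$ch)))
        truth[[k]] <- tibble(read_id = recs[[k]]$id, sample_name = sm,
                             orientation = orientation,
                             template_length = nchar(template),
                             insert_start = ins_start,
                             insert_end = ins_start + nchar(insert),
                             n_errors = mut$n_errors)
      }
    }
    records <- seq_records(vapply(recs, `[[`, character(1), "id"),
                           vapply(recs, `[[`, character(1), "seq"),
                           qual = lapply(recs, `[[`, "qual"))
    list(records = records, truth = do.call(rbind, truth))
  })
}

#' Simulate a mock-community read set
#'
#' Per-taxon expected read shares are proportional to `input_proportions *
#' (length / min length)^(-length_bias_exponent)` (exponent 0 = unbiased;
#' positive exponents favour shorter templates, the PCR length-bias
#' hypothesis); counts are drawn multinomially and reads generated from
#' the bare amplicon templates (no indexes).
#'
#' @param references named character vector of taxon template sequences.
#' @param input_proportions named numeric vector summing to 1.
#' @param total_reads total read count.
#' @param model an [error_model()].
#' @param length_bias_exponent power-law bias exponent (default 0, off).
#' @param seed optional RNG seed.
#' @param community community name written into the output table.
#' @return `list(records, truth, community_table)`; the community table is
#'   tidy (`taxon`, `community`, `input_proportion`, `read_count`).
#' @export
simulate_community <- function(references, input_proportions, total_reads,
                               model = error_model(),
                               length_bias_exponent = 0, seed = NULL,
                               community = "mock1") {
  taxa <- names(references)
  if (is.null(taxa) || !setequal(taxa, names(input_proportions)))
    stop("references and input_proportions must share taxon names")
  p <- input_proportions[taxa]
  if (abs(sum(p) - 1) > 1e-9) stop("input proportions must sum to 1")
  with_seed(seed, {
    len <- nchar(unlist(references))[taxa]
    w <- p * (len / min(len))^(-length_bias_exponent)
    w <- w / sum(w)
    counts <- if (total_reads > 0) as.integer(rmultinom(1, total_reads, w))
              else integer(length(taxa))
    names(counts) <- taxa
    recs <- list(); truth <- list(); k <- 0L
    for (t in taxa) {
      for (r in seq_len(counts[[t]])) {
        k <- k + 1L
        mut <- mutate_chars(strsplit(normalize_seq(references[[t]]), "")[[1]],
                            model)
        total <- model$sub_rate + model$ins_rate + model$del_rate
        q <- if (total <= 0) 40L else
          as.integer(min(40, max(0, round(-10 * log10(total)))))
        recs[[k]] <- list(id = sprintf("cread%06d", k),
                          seq = paste(mut$ch, collapse = ""),
                          qual = rep(q, length(mut$ch)))
        truth[[k]] <- tibble(read_id = recs[[k]]$id, sample_name = t,
                             orientation = "+",
                             template_length = len[[t]],
                             insert_start = 0L, insert_end = len[[t]],
                             n_errors = mut$n_errors)
      }
    }
    records <- if (k > 0)
      seq_records(vapply(recs, `[[`, character(1), "id"),
                  vapply(recs, `[[`, character(1), "seq"),
                  qual = lapply(recs, `[[`, "qual"))
    else seq_records(character(), character())
    ct <- tibble(taxon = taxa, community = community,
                 input_proportion = as.numeric(p),
                 read_count = as.integer(counts))
    list(records = records,
         truth = if (k > 0) do.call(rbind, truth) else
           tibble(read_id = character(), sample_name = character(),
                  orientation = character(), template_length = integer(),
                  insert_start = integer(), insert_end = integer(),
                  n_errors = integer()),
         community_table = ct)
  })
}

#' Build a grid barcode table from designed index sets
#'
#' Convenience wrapper pairing `n_fwd x n_rev` indexes into samples named
#' `s<j>` row-major, with the given primers on every sample.
#'
#' @param fwd_indexes,rev_indexes character vectors of ACGT indexes.
#' @param fwd_primer,rev_primer primer sequences (IUPAC allowed).
#' @return a sample-spec tibble.
#' @export
index_grid_specs <- function(fwd_indexes, rev_indexes,
                             fwd_primer, rev_primer) {
  grid <- expand.grid(f = seq_along(fwd_indexes), r = seq_along(rev_indexes))
  spec <- tibble(sample_name = sprintf("s%d", seq_len(nrow(grid))),
                 fwd_index = fwd_indexes[grid$f],
                 fwd_primer = fwd_primer,
                 rev_index = rev_indexes[grid$r],
                 rev_primer = rev_primer)
  validate_sample_specs(spec)
  spec
}
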