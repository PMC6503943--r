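#' Levenshtein edit distance between DNA strings
#'
#' Unit-cost edit distance (substitutions, insertions and deletions each
#' cost 1).  With `iupac = TRUE`, two bases whose IUPAC sets intersect align
#' at cost 0 (so a degenerate primer base `R` matches `A` or `G` free);
#' indels always cost 1.  With `iupac = FALSE` only literal equality matches
#' and `N` mismatches everything, itself included.
#'
#' @param a,b character vectors of DNA strings (recycled to common length).
#' @param iupac treat IUPAC ambiguity codes as matching their base sets.
#' @return integer vector of distances.
#' @examples
#' edit_distance("ACGT", "AGT")            # 1
#' edit_distance("ACGT", "ACRT", iupac = TRUE)  # 0
#' @export
edit_distance <- function(a, b, iupac = FALSE) {
  cpp_edit_distance(toupper(as.character(a)), toupper(as.character(b)), iupac)
}

#' Semi-global (infix) search of a pattern in a text
#'
#' Locates the best approximate occurrence of a short pattern inside a text:
#' gaps before and after the pattern's span in the text are free, so only
#' edits within the span count.  Among equal-distance hits the leftmost
#' start, then the shortest span, is returned.  Coordinates are 0-based,
#' half-open.
#'
#' @param pattern non-empty DNA string (may contain IUPAC codes).
#' @param text DNA string to search in.
#' @param max_edits maximum acceptable edit distance.
#' @param iupac IUPAC-aware matching (see [edit_distance()]).
#' @param pattern_id identifier copied into the hit.
#' @param strand,window annotations copied into the hit (`"+"`/`"-"`,
#'   `"head"`/`"tail"`).
#' @return a `match_hit` list with fields `pattern_id`, `edit_distance`,
#'   `start`, `end`, `strand`, `window`; or `NULL` when no span is within
#'   `max_edits`.
#' @examples
#' infix_search("ACGT", "TTACGTTT", max_edits = 1)
#' @export
infix_search <- function(pattern, text, max_edits, iupac = TRUE,
                         pattern_id = pattern, strand = "+", window = "head") {
  stopifnot(nchar(pattern) > 0, max_edits >= 0)
  res <- cpp_infix_search(toupper(pattern), toupper(text), as.integer(max_edits),
                          iupac)
  if (res[1] < 0) return(NULL)
  structure(list(pattern_id = pattern_id, edit_distance = res[1],
                 start = res[2], end = res[3], strand = strand,
                 window = window),
            class = "match_hit")
}

COMPLEMENT_FROM <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
COMPLEMENT_TO   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"

#' Reverse complement of an IUPAC DNA string
#'
#' Complements ambiguity codes (R<->Y, K<->M, B<->V, D<->H; S, W and N are
#' self-complementary) and reverses.  Applying it twice is the identity.
#'
#' @param seq character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' @export
reverse_complement <- function(seq) {
  seq <- as.character(seq)
  bad <- grepl(sprintf("[^%s]", COMPLEMENT_FROM), seq)
  if (any(bad))
    stop("non-IUPAC character in sequence: ", seq[which(bad)[1]])
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr(COMPLEMENT_FROM, COMPLEMENT_TO, s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.match_hit <- function(x, ...) {
  cat(sprintf("<match_hit> %s: distance %d at [%d,%d) strand %s window %s\n",
              x$pattern_id, x$edit_distance, x$start, x$end, x$strand,
              x$window))
  invisible(x)
}
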