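# Shared fixtures, built in code.

# Four samples on a 2x2 index grid; all four indexes come from one designed
# set, so every pairwise index distance is >= 10.
make_grid_fixture <- function(seed = 101, insert_len = 400) {
  idx <- design_indexes(4, seed = seed)
  specs <- index_grid_specs(idx[1:2], idx[3:4],
                            fwd_primer = "TACACACCGCCCGTCRCTACTACCG",
                            rev_primer = "GGTTAGTTTCTTTTCCTCCGCTTAY")
  refs <- with_seed(seed + 1,
                    setNames(replicate(nrow(specs), random_dna(insert_len)),
                             specs$sample_name))
  list(specs = specs, refs = refs)
}

# A deliberately degraded index set: the two forward indexes sit at
# Levenshtein distance 4 from each other, as do the two reverse indexes
# (4 spread-out substitutions; distances verified by DP in the tests).
degraded_grid_fixture <- function(seed = 202, insert_len = 400) {
  f1 <- "CGAGGAAAGGGTGCC"; f2 <- "CAAGGCAAGAGTGAC"
  r1 <- "ACACTTTGACCCGCG"; r2 <- "AAACTATGAACCGAG"
  specs <- index_grid_specs(c(f1, f2), c(r1, r2),
                            fwd_primer = "TACACACCGCCCGTCRCTACTACCG",
                            rev_primer = "GGTTAGTTTCTTTTCCTCCGCTTAY")
  refs <- with_seed(seed,
                    setNames(replicate(nrow(specs), random_dna(insert_len)),
                             specs$sample_name))
  list(specs = specs, refs = refs)
}

# Brute-force infix-search oracle: minimum base-R adist() Levenshtein
# distance over all substrings of the text (substrings longer than twice
# the pattern cannot beat the empty substring, so they are skipped).
oracle_infix_min <- function(pattern, text) {
  n <- nchar(text)
  L <- nchar(pattern)
  subs <- character(0)
  for (i in 0:n) {
    jmax <- min(n, i + 2L * L)
    subs <- c(subs, substring(text, i + 1L, seq.int(i, jmax)))
  }
  min(adist(pattern, unique(subs)))
}

random_records <- function(n, len_range = c(50, 200), with_qual = TRUE) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  seq_records(sprintf("rr%03d", seq_len(n)),
              vapply(lens, random_dna, character(1)),
              qual = if (with_qual)
                lapply(lens, function(L) sample(0:40, L, replace = TRUE))
              else NULL)
}

with_seed <- longamp:::with_seed
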