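#' Uncorrected pairwise distance between two aligned sequences
#'
#' Percent p-distance with two indel policies.  `"exclude"` compares only
#' columns where both sequences have a base (pairwise deletion):
#' `100 * mismatches / comparable columns`.  `"include"` treats the gap as
#' a fifth character state, drops columns gapped in both, and scores
#' `100 * differing columns / counted columns`.
#'
#' @param a,b aligned sequences of equal length; gap character `-`.
#' @param indel_mode `"exclude"` or `"include"`.
#' @return percent distance in `[0, 100]`.
#' @examples
#' pdistance("AC-T", "ACGT", "exclude")  # 0
#' pdistance("AC-T", "ACGT", "include")  # 25
#' @export
pdistance <- function(a, b, indel_mode = c("exclude", "include")) {
  indel_mode <- match.arg(indel_mode)
  if (nchar(a) != nchar(b))
    stop("aligned sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (indel_mode == "exclude") {
    comp <- ca != "-" & cb != "-"
    if (!any(comp)) stop("no comparable columns; distance undefined")
    100 * sum(ca[comp] != cb[comp]) / sum(comp)
  } else {
    comp <- !(ca == "-" & cb == "-")
    if (!any(comp)) stop("no comparable columns; distance undefined")
    100 * sum(ca[comp] != cb[comp]) / sum(comp)
  }
}

#' Pairwise distance matrix from an alignment
#'
#' Applies [pdistance()] to every pair of an aligned record set.
#'
#' @param alignment a named character vector of gapped sequences of equal
#'   length (see [read_alignment()]), or a gap-free `seq_records` tibble.
#' @param indel_mode see [pdistance()].
#' @return a labeled symmetric numeric matrix of percent distances with a
#'   zero diagonal.
#' @export
distance_matrix <- function(alignment, indel_mode = c("exclude", "include")) {
  indel_mode <- match.arg(indel_mode)
  if (is_tibble(alignment)) alignment <- setNames(alignment$seq, alignment$id)
  n <- length(alignment)
  if (is.null(names(alignment)) || any(!nzchar(names(alignment))))
    stop("alignment sequences must be named")
  if (length(unique(nchar(alignment))) > 1)
    stop("ragged alignment: sequences differ in length")
  m <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- pdistance(alignment[i], alignment[j], indel_mode)
  m
}

#' Read a multiple sequence alignment from FASTA
#'
#' Returns the gapped sequences as an uppercase named character vector
#' (gaps `-` preserved), the shape [distance_matrix()] consumes.
#'
#' @param path aligned FASTA path.
#' @return named character vector.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  out <- toupper(as.character(ss))
  names(out) <- sub("[[:space:]].*$", "", names(ss))
  out
}

check_dist_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)), identical(rownames(m), colnames(m)))
  if (any(abs(m - t(m)) > 1e-9)) stop("distance matrix is not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix has non-zero diagonal")
  if (any(m < 0)) stop("negative distances")
  invisible(m)
}

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Classifies every off-diagonal pair of a distance matrix as within- or
#' between-species and summarises, per species, the maximum intraspecific
#' and the minimum interspecific (nearest-neighbour) distance.
#'
#' @param m labeled symmetric distance matrix.
#' @param species_of named character vector mapping every matrix label to a
#'   species.
#' @return `list(intra, inter, per_species)`: `intra`/`inter` are tibbles
#'   (`a`, `b`, `species_a`, `species_b`, `distance`), `per_species` a
#'   tibble (`species`, `n`, `max_intra`, `min_inter`).
#' @export
group_distances <- function(m, species_of) {
  check_dist_matrix(m)
  labels <- rownames(m)
  missing <- setdiff(labels, names(species_of))
  if (length(missing))
    stop("labels missing from species map: ", paste(missing, collapse = ", "))
  sp <- species_of[labels]
  idx <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- tibble(a = labels[idx[, 1]], b = labels[idx[, 2]],
                  species_a = unname(sp[idx[, 1]]),
                  species_b = unname(sp[idx[, 2]]),
                  distance = m[idx])
  intra <- pairs[pairs$species_a == pairs$species_b, , drop = FALSE]
  inter <- pairs[pairs$species_a != pairs$species_b, , drop = FALSE]
  per_species <- do.call(rbind, lapply(unique(sp), function(s) {
    tibble(species = s, n = sum(sp == s),
           max_intra = if (any(intra$species_a == s))
             max(intra$distance[intra$species_a == s]) else NA_real_,
           min_inter = if (nrow(inter))
             min(inter$distance[inter$species_a == s | inter$species_b == s])
           else NA_real_)
  }))
  list(intra = intra, inter = inter, per_species = per_species)
}

#' Barcode-gap detection
#'
#' The barcode gap is the separation between within- and between-species
#' distance distributions: `gap_size = min(inter) - max(intra)`, present
#' iff strictly positive.
#'
#' @param intra,inter numeric vectors of intra- and interspecific distances
#'   (both non-empty).
#' @return `list(gap_present, gap_size)`.
#' @export
barcode_gap <- function(intra, inter) {
  if (length(intra) == 0 || length(inter) == 0)
    stop("both intra- and interspecific distance sets must be non-empty")
  gap <- min(inter) - max(intra)
  list(gap_present = gap > 0, gap_size = gap)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries; the null distribution
#' is built by jointly permuting rows and columns of the second matrix.
#' One-sided (positive association) p-value with the add-one rule:
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 labeled symmetric distance matrices with identical labels
#'   in identical order; at least 4 labels.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed.
#' @return `list(r, p, n_perm)`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999L, seed = NULL) {
  check_dist_matrix(d1); check_dist_matrix(d2)
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 labels for a Mantel test")
  if (!identical(dimnames(d1), dimnames(d2)))
    stop("distance matrices must share labels in the same order")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- cor(v1, d2[lt])
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      if (cor(v1, d2[p, p][lt]) >= r_obs) hits <- hits + 1L
    }
    hits
  })
  list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = as.integer(n_perm))
}

#' Log2 fold change between input proportion and read proportion
#'
#' `log2(read_prop / input_prop)`: zero means a 1:1 association between a
#' taxon's input DNA share and its read share; positive/negative values
#' mean over-/under-representation among reads.  A taxon with reads absent
#' is a dropout and yields `NA` (reported separately, never -Inf).
#'
#' @param input_prop input DNA proportion(s), strictly positive.
#' @param read_prop recovered read proportion(s), `>= 0`.
#' @return numeric vector of fold changes (`NA` at dropouts).
#' @export
fold_change <- function(input_prop, read_prop) {
  if (any(input_prop <= 0)) stop("input proportions must be > 0")
  ifelse(read_prop == 0, NA_real_, log2(read_prop / input_prop))
}

check_community_table <- function(table) {
  need <- c("taxon", "community", "input_proportion", "read_count")
  if (!all(need %in% names(table)))
    stop("community table needs columns: ", paste(need, collapse = ", "))
  if (any(table$read_count < 0)) stop("negative read counts")
  sums <- tapply(table$input_proportion, table$community, sum)
  bad <- abs(sums - 1) > 1e-9
  if (any(bad))
    stop("input proportions do not sum to 1 in community: ",
         paste(names(sums)[bad], collapse = ", "))
  invisible(table)
}

#' Per-taxon fold changes for a mock-community table
#'
#' Adds read proportions (within each community), log2 fold changes and a
#' dropout flag to a tidy community table.
#'
#' @param table tidy tibble with columns `taxon`, `community`,
#'   `input_proportion` (summing to 1 per community) and `read_count`.
#' @return the table with `read_proportion`, `fold_change` and `dropout`
#'   columns appended.
#' @export
community_fold_changes <- function(table) {
  check_community_table(table)
  totals <- tapply(table$read_count, table$community, sum)
  table$read_proportion <- table$read_count / as.numeric(totals[table$community])
  table$fold_change <- fold_change(table$input_proportion,
                                   table$read_proportion)
  table$dropout <- table$read_count == 0
  table
}

#' Qualitative taxon recovery per community
#'
#' A taxon counts as recovered iff it has at least one read.  Percentages
#' are rounded to 2 decimals.
#'
#' @param table tidy community table (see [community_fold_changes()]).
#' @return `list(per_community = tibble(community, n_taxa, n_detected,
#'   percent), mean_percent)`.
#' @export
recovery <- function(table) {
  check_community_table(table)
  raw <- vapply(unique(table$community), function(cm) {
    sub <- table[table$community == cm, , drop = FALSE]
    100 * sum(sub$read_count > 0) / nrow(sub)
  }, numeric(1))
  per <- do.call(rbind, lapply(unique(table$community), function(cm) {
    sub <- table[table$community == cm, , drop = FALSE]
    tibble(community = cm, n_taxa = nrow(sub),
           n_detected = sum(sub$read_count > 0),
           percent = round(100 * sum(sub$read_count > 0) / nrow(sub), 2))
  }))
  list(per_community = per, mean_percent = round(mean(raw), 2))
}

#' Levene / Brown-Forsythe test for homogeneity of variances
#'
#' Classic Levene statistic: absolute deviations from the group center
#' (median by default, the Brown-Forsythe variant; or mean) are compared
#' across groups with a one-way ANOVA F statistic, `W ~ F(k-1, N-k)`.
#' When both the between- and within-group sums of squares of the
#' deviations vanish (all deviations equal), W is 0 and p is 1.
#'
#' @param groups list of at least two numeric vectors, each of length >= 2.
#' @param center `"median"` or `"mean"`.
#' @return `list(W, df1, df2, p)`.
#' @examples
#' levene_test(list(c(1, 3), c(5, 7)))  # W = 0, p = 1
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 values")
  cfun <- if (center == "median") median else mean
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  ni <- lengths(z)
  N <- sum(ni)
  zi <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(ni * (zi - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2),
                          numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ss_between == 0) {
    W <- 0
  } else if (ss_within == 0) {
    W <- Inf
  } else {
    W <- (ss_between / df1) / (ss_within / df2)
  }
  p <- if (is.infinite(W)) 0 else pf(W, df1, df2, lower.tail = FALSE)
  list(W = W, df1 = df1, df2 = df2, p = p)
}

#' Pairwise Wilcoxon rank-sum comparisons with FDR correction
#'
#' Utility for comparing e.g. per-condition fold-change or accuracy tables:
#' all pairwise two-sided rank-sum tests with Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param values numeric vector.
#' @param groups factor/character vector of the same length.
#' @return tibble (`group_a`, `group_b`, `p`, `p_adj`).
#' @export
pairwise_wilcox <- function(values, groups) {
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2) stop("need at least two groups")
  pairs <- utils::combn(gs, 2)
  p <- apply(pairs, 2, function(gp)
    stats::wilcox.test(values[groups == gp[1]],
                       values[groups == gp[2]], exact = FALSE)$p.value)
  tibble(group_a = pairs[1, ], group_b = pairs[2, ], p = p,
         p_adj = stats::p.adjust(p, method = "BH"))
}

#' Per-group sequence length and GC summaries
#'
#' GC percent is `100 * (G + C + S) / (A + C + G + T + S + W)`; ambiguity
#' codes other than S/W are excluded from numerator and denominator.
#' Standard deviations are sample standard deviations.  Empty sequences
#' are skipped with a warning.
#'
#' @param records a `seq_records` tibble.
#' @param group_of optional named character vector mapping record ids to
#'   groups; default puts everything in one group `"all"`.
#' @return tibble (`group`, `n`, `length_mean`, `length_sd`, `gc_mean`,
#'   `gc_sd`).
#' @export
seq_stats <- function(records, group_of = NULL) {
  empty <- !nzchar(records$seq)
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty sequence(s)")
    records <- records[!empty, , drop = FALSE]
  }
  grp <- if (is.null(group_of)) rep("all", nrow(records))
         else unname(group_of[records$id])
  gc_one <- function(s) {
    counts <- table(factor(strsplit(s, "")[[1]],
                           levels = c("A", "C", "G", "T", "S", "W")))
    denom <- sum(counts)
    if (denom == 0) return(NA_real_)
    100 * sum(counts[c("G", "C", "S")]) / denom
  }
  gc <- vapply(records$seq, gc_one, numeric(1), USE.NAMES = FALSE)
  len <- nchar(records$seq)
  do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    tibble(group = g, n = sum(sel),
           length_mean = mean(len[sel]), length_sd = sd(len[sel]),
           gc_mean = mean(gc[sel]), gc_sd = sd(gc[sel]))
  }))
}

#' Read a square distance matrix from TSV
#'
#' Expects a header row and first column of labels (square TSV; PHYLIP
#' square layout without the leading count line is the same shape).
#'
#' @param path input path.
#' @return labeled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- rownames(m)
  check_dist_matrix(m)
  m
}

#' Write a square distance matrix to TSV
#'
#' @param m labeled symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  check_dist_matrix(m)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
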