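test_that("p-distance hand counts are exact in both indel modes", {
  expect_equal(pdistance("ACGT", "ACGT", "exclude"), 0)
  expect_equal(pdistance("ACGT", "ACGT", "include"), 0)
  expect_equal(pdistance("AC-T", "ACGT", "exclude"), 0)
  expect_equal(pdistance("AC-T", "ACGT", "include"), 25)
  expect_equal(pdistance("ACGT", "ACGA", "exclude"), 25)
  expect_equal(pdistance("ACGT", "ACGA", "include"), 25)
  # gap-gap columns are excluded in include mode
  expect_equal(pdistance("AC--", "AC-T", "include"), 100 / 3)
  expect_error(pdistance("ACG", "ACGT"), "length")
  expect_error(pdistance("---", "AAA", "exclude"), "undefined")
})

test_that("p-distance is symmetric and bounded on random gapped pairs", {
  set.seed(51)
  alpha <- c("A", "C", "G", "T", "-")
  for (i in 1:50) {
    n <- sample(10:60, 1)
    a <- paste(sample(alpha, n, replace = TRUE, prob = c(rep(0.22, 4), 0.12)),
               collapse = "")
    b <- paste(sample(alpha, n, replace = TRUE, prob = c(rep(0.22, 4), 0.12)),
               collapse = "")
    for (mode in c("exclude", "include")) {
      d <- tryCatch(pdistance(a, b, mode), error = function(e) NA)
      if (is.na(d)) next
      expect_identical(d, pdistance(b, a, mode))
      expect_gte(d, 0); expect_lte(d, 100)
    }
  }
})

test_that("distance matrices are symmetric with zero diagonals", {
  aln <- c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "ACGTACGTAC")
  expect_true(all(distance_matrix(aln) == 0))
  aln2 <- c(x = strrep("A", 100), y = paste0(strrep("A", 99), "C"))
  m <- distance_matrix(aln2)
  expect_equal(m["x", "y"], 1)
  expect_equal(m, t(m))
  expect_error(distance_matrix(c(a = "ACG", b = "AC")), "ragged")
})

test_that("distances partition into intra/inter with per-species summaries", {
  m <- matrix(0.5, 4, 4, dimnames = list(c("a1", "a2", "b1", "b2"),
                                         c("a1", "a2", "b1", "b2")))
  diag(m) <- 0
  m["a1", "a2"] <- m["a2", "a1"] <- 0.1
  m["b1", "b2"] <- m["b2", "b1"] <- 0.1
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gd <- group_distances(m, sp)
  expect_identical(sort(gd$intra$distance), c(0.1, 0.1))
  expect_identical(gd$inter$distance, rep(0.5, 4))
  expect_identical(nrow(gd$intra) + nrow(gd$inter), 6L)
  expect_equal(gd$per_species$max_intra, c(0.1, 0.1))
  expect_equal(gd$per_species$min_inter, c(0.5, 0.5))

  # summaries recompute from the raw lists
  for (i in seq_len(nrow(gd$per_species))) {
    s <- gd$per_species$species[i]
    expect_equal(gd$per_species$max_intra[i],
                 max(gd$intra$distance[gd$intra$species_a == s]))
  }
  # single specimen per species: empty intra
  gd1 <- group_distances(m[c(1, 3), c(1, 3)], sp)
  expect_identical(nrow(gd1$intra), 0L)
  expect_error(group_distances(m, sp[1:3]), "missing")
})

test_that("barcode gap is min(inter) - max(intra), strictly positive to exist", {
  g <- barcode_gap(c(0.1, 0.2), c(0.5, 0.6))
  expect_true(g$gap_present)
  expect_equal(g$gap_size, 0.3)
  g2 <- barcode_gap(0.4, 0.3)
  expect_false(g2$gap_present)
  expect_equal(g2$gap_size, -0.1)
  g3 <- barcode_gap(0.2, 0.2)
  expect_false(g3$gap_present)
  expect_error(barcode_gap(numeric(0), 1), "non-empty")
})

test_that("the Mantel statistic matches vegan and self-correlation is exact", {
  set.seed(52)
  mk <- function(n) {
    m <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(m) <- list(sprintf("t%d", 1:n), sprintf("t%d", 1:n))
    m
  }
  d1 <- mk(8); d2 <- mk(8)
  res <- mantel_test(d1, d2, n_perm = 199, seed = 1)
  ref <- vegan::mantel(d1, d2, permutations = 199)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)
  expect_gte(res$p, 0); expect_lte(res$p, 1)

  self <- mantel_test(d1, d1, n_perm = 999, seed = 2)
  expect_equal(self$r, 1)
  expect_lte(self$p, 0.01)

  expect_error(mantel_test(d1[1:3, 1:3], d1[1:3, 1:3]), "at least 4")
  d3 <- d2[c(2, 1, 3:8), c(2, 1, 3:8)]
  expect_error(mantel_test(d1, d3), "same order")
})

test_that("Mantel test replays identically under a fixed seed", {
  set.seed(53)
  m <- as.matrix(dist(matrix(runif(18), 6)))
  dimnames(m) <- list(letters[1:6], letters[1:6])
  m2 <- as.matrix(dist(matrix(runif(18), 6)))
  dimnames(m2) <- dimnames(m)
  a <- mantel_test(m, m2, n_perm = 499, seed = 99)
  b <- mantel_test(m, m2, n_perm = 499, seed = 99)
  expect_identical(a, b)
})

test_that("fold change anchors zero at 1:1 recovery and flags dropouts", {
  expect_equal(fold_change(0.25, 0.25), 0)
  expect_equal(fold_change(0.25, 0.5), 1)
  expect_true(is.na(fold_change(0.2, 0)))
  expect_error(fold_change(0, 0.5), "> 0")

  tab <- tibble::tibble(
    taxon = rep(c("t1", "t2"), 2),
    community = rep(c("c1", "c2"), each = 2),
    input_proportion = c(0.5, 0.5, 0.25, 0.75),
    read_count = c(10L, 10L, 0L, 30L))
  fc <- community_fold_changes(tab)
  expect_equal(fc$fold_change[1:2], c(0, 0))
  expect_true(fc$dropout[3] && is.na(fc$fold_change[3]))
  # read-mass conservation: sum(input * 2^F) = 1 without dropouts
  c1 <- fc[fc$community == "c1", ]
  expect_equal(sum(c1$input_proportion * 2^c1$fold_change), 1)
})

test_that("recovery percentages follow detection counts", {
  tab <- tibble::tibble(
    taxon = rep(sprintf("t%d", 1:9), 4),
    community = rep(sprintf("c%d", 1:4), each = 9),
    input_proportion = rep(1 / 9, 36),
    read_count = as.integer(c(rep(1, 9),                 # 9 of 9
                              rep(1, 8), 0,              # 8 of 9
                              rep(1, 7), 0, 0,           # 7 of 9
                              rep(1, 6), 0, 0, 0)))      # 6 of 9
  r <- recovery(tab)
  expect_equal(r$per_community$percent, c(100, 88.89, 77.78, 66.67))
  expect_equal(r$mean_percent, 83.33)
  all_in <- tab; all_in$read_count <- 1L
  expect_equal(recovery(all_in)$mean_percent, 100)
})

test_that("Levene statistic matches the closed form and car's implementation", {
  r0 <- levene_test(list(c(1, 3), c(5, 7)))
  expect_equal(r0$W, 0)
  expect_equal(r0$p, 1)

  r1 <- levene_test(list(c(0, 0, 0, 0), c(-5, 5, -5, 5)))
  expect_gt(r1$W, 10)
  expect_lt(r1$p, 0.05)

  set.seed(54)
  x <- rnorm(20); y <- rnorm(15, sd = 3); z <- rnorm(10)
  ours <- levene_test(list(x, y, z), center = "median")
  ref <- car::leveneTest(c(x, y, z),
                         factor(rep(1:3, c(20, 15, 10))), center = median)
  expect_equal(ours$W, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-12)

  expect_error(levene_test(list(1, c(2, 3))), "at least 2")
  expect_error(levene_test(list(c(1, 2))), "two groups")
})

test_that("identical groups give Levene W = 0", {
  g <- list(c(2, 4, 9), c(2, 4, 9), c(2, 4, 9))
  expect_equal(levene_test(g)$W, 0)
})

test_that("sequence summaries compute GC from the stated base set", {
  r <- seq_records(c("a", "b", "c"), c("GCGC", "ATAT", "ACGT"))
  st <- seq_stats(r)
  expect_equal(st$n, 3L)
  gc_each <- c(100, 0, 50)
  expect_equal(st$gc_mean, mean(gc_each))
  expect_equal(st$gc_sd, sd(gc_each))
  # S counts as GC, W as AT, other ambiguity codes are excluded entirely
  st2 <- seq_stats(seq_records("d", "SSWWRN"))
  expect_equal(st2$gc_mean, 50)
  grouped <- seq_stats(r, group_of = c(a = "g1", b = "g2", c = "g1"))
  expect_identical(sort(grouped$group), c("g1", "g2"))
  expect_warning(st3 <- seq_stats(seq_records(c("a", "b"), c("", "ACGT"))),
                 "empty")
  expect_identical(st3$n, 1L)
})

test_that("distance matrices round-trip through TSV", {
  m <- matrix(c(0, 1.5, 1.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- withr::local_tempfile()
  write_distance_matrix(m, p)
  expect_equal(read_distance_matrix(p), m)
})

test_that("pairwise rank-sum helper applies BH correction", {
  set.seed(55)
  v <- c(rnorm(10), rnorm(10, 5), rnorm(10))
  g <- rep(c("a", "b", "c"), each = 10)
  pw <- pairwise_wilcox(v, g)
  expect_identical(nrow(pw), 3L)
  expect_true(all(pw$p_adj >= pw$p - 1e-15))
  expect_equal(pw$p_adj, p.adjust(pw$p, "BH"))
})
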