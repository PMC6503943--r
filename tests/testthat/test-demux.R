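test_that("mean quality is the probability-domain mean", {
  expect_equal(mean_quality(seq_records("a", "AAAA", qual = list(rep(20L, 4)))),
               20)
  expect_equal(mean_quality(seq_records("b", "AA", qual = list(c(10L, 20L)))),
               -10 * log10(0.055), tolerance = 1e-12)
  expect_equal(round(mean_quality(seq_records("b", "AA",
                                              qual = list(c(10L, 20L)))), 3),
               12.596)
  expect_equal(mean_quality(seq_records("c", "A", qual = list(7L))), 7)
  expect_error(mean_quality(seq_records("d", "AC")), "no quality")
})

test_that("read filters apply strict quality and length cutoffs", {
  cfg <- demux_config(min_quality = 13, min_length = 3000L)
  len_3000 <- seq_records("l0", strrep("A", 3000), qual = list(rep(30L, 3000)))
  len_3001 <- seq_records("l1", strrep("A", 3001),
                          qual = list(rep(14L, 3001)))
  expect_identical(filter_reads(len_3000, cfg)$report$n_kept, 0L)
  expect_identical(filter_reads(len_3000, cfg)$report$removed_length, 1L)
  expect_identical(filter_reads(len_3001, cfg)$report$n_kept, 1L)

  lowq <- seq_records(sprintf("q%d", 1:10),
                      rep(strrep("A", 3100), 10),
                      qual = rep(list(rep(10L, 3100)), 10))
  rep10 <- filter_reads(lowq, cfg)$report
  expect_identical(rep10$removed_quality, 10L)
  expect_identical(rep10$n_kept, 0L)
})

test_that("a constructed clean read is assigned with the exact insert span", {
  fx <- make_grid_fixture()
  sim <- simulate_reads(fx$specs, fx$refs, 1, error_model(0, 0, 0),
                        seed = 31, force_orientation = "+")
  rec <- sim$records[1, ]
  a <- assign_read(rec, fx$specs, demux_config())
  expect_identical(a$category, "assigned")
  expect_identical(a$sample_name, sim$truth$sample_name[1])
  expect_identical(a$orientation, "+")
  expect_identical(a$insert_span,
                   c(sim$truth$insert_start[1], sim$truth$insert_end[1]))
  trimmed <- trim_read(rec, a, "trim")
  expect_identical(trimmed$seq, unname(fx$refs[[a$sample_name]]))
  expect_identical(length(trimmed$qual[[1]]), nchar(trimmed$seq))

  # the reverse complement maps to the same sample on the other strand
  rc <- seq_records(rec$id, reverse_complement(rec$seq),
                    qual = list(rev(rec$qual[[1]])))
  a2 <- assign_read(rc, fx$specs, demux_config())
  expect_identical(a2$sample_name, a$sample_name)
  expect_identical(a2$orientation, "-")
})

test_that("an index carrying more errors than the threshold is unassigned", {
  fx <- make_grid_fixture()
  sim <- simulate_reads(fx$specs, fx$refs, 1, error_model(0, 0, 0),
                        seed = 32, force_orientation = "+")
  rec <- sim$records[1, ]
  ch <- strsplit(rec$seq, "")[[1]]
  for (p in c(2L, 6L, 11L))  # 3 substitutions inside the 15-bp fwd index
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  broken <- seq_records(rec$id, paste(ch, collapse = ""), qual = rec$qual)
  # the mutated index is still >= 3 edits away (verify, then assign)
  expect_gte(min(edit_distance(substr(broken$seq, 1, 15),
                               fx$specs$fwd_index)), 3L)
  a <- assign_read(broken, fx$specs, demux_config(index_max_edits = 2L))
  expect_identical(a$category, "unassigned")
  a3 <- assign_read(broken, fx$specs, demux_config(index_max_edits = 3L))
  expect_identical(a3$category, "assigned")
})

test_that("samples sharing a forward index resolve through the pair", {
  fx <- make_grid_fixture()
  # s1 and s3 share fwd_index on the 2x2 grid
  shared <- fx$specs$fwd_index[1] == fx$specs$fwd_index
  expect_identical(sum(shared), 2L)
  sim <- simulate_reads(fx$specs, fx$refs, 2, error_model(0, 0, 0), seed = 33)
  res <- demultiplex(sim$records, fx$specs, demux_config())
  merged <- merge(res$assignments, sim$truth, by = "read_id")
  expect_true(all(merged$category == "assigned"))
  expect_identical(merged$sample_name.x, merged$sample_name.y)
})

test_that("demultiplexing partitions every input read exactly once", {
  fx <- make_grid_fixture()
  sim <- simulate_reads(fx$specs, fx$refs, 25, error_model(0, 0, 0), seed = 34)
  res <- demultiplex(sim$records, fx$specs, demux_config())
  expect_identical(sum(res$summary$n_reads), nrow(sim$records))
  expect_identical(res$summary$n_reads[match(fx$specs$sample_name,
                                             res$summary$sample)],
                   rep(25L, 4))
  expect_identical(sum(unlist(lapply(res$groups, nrow))), nrow(sim$records))

  empty <- demultiplex(seq_records(character(), character()), fx$specs,
                       demux_config())
  expect_identical(sum(empty$summary$n_reads), 0L)
})

test_that("orientation invariance holds across a noisy simulated set", {
  fx <- make_grid_fixture()
  sim <- simulate_reads(fx$specs, fx$refs, 10, error_model(), seed = 35)
  res_f <- demultiplex(sim$records, fx$specs, demux_config())
  rc <- seq_records(sim$records$id, reverse_complement(sim$records$seq),
                    qual = lapply(sim$records$qual, rev))
  res_r <- demultiplex(rc, fx$specs, demux_config())
  expect_identical(res_f$assignments$category, res_r$assignments$category)
  expect_identical(res_f$assignments$sample_name, res_r$assignments$sample_name)
  flip <- c("+" = "-", "-" = "+")
  ok <- res_f$assignments$category == "assigned"
  expect_identical(unname(flip[res_f$assignments$orientation[ok]]),
                   res_r$assignments$orientation[ok])
})

test_that("trim modes behave: none is identity, mark masks, fastq mark errors", {
  fx <- make_grid_fixture()
  sim <- simulate_reads(fx$specs, fx$refs, 1, error_model(0, 0, 0), seed = 36)
  rec <- sim$records[1, ]
  a <- assign_read(rec, fx$specs, demux_config())
  expect_identical(trim_read(rec, a, "none"), rec)
  marked <- trim_read(rec, a, "mark")
  expect_identical(marked$seq, rec$seq)
  expect_identical(nrow(marked$mask[[1]]), 2L)
  expect_error(trim_read(rec, a, "mark", output_format = "fastq"),
               "not representable")
  fa <- withr::local_tempfile()
  write_sequences(marked[, c("id", "desc", "seq", "qual")], fa, "fasta",
                  lowercase_mask = marked$mask)
  body <- paste(readLines(fa)[-1], collapse = "")
  expect_identical(toupper(body), rec$seq)
  expect_true(grepl("[a-z]", body))
})

test_that("single-file mode annotates sample names in descriptions", {
  fx <- make_grid_fixture()
  sim <- simulate_reads(fx$specs, fx$refs, 3, error_model(0, 0, 0), seed = 37)
  res <- demultiplex(sim$records, fx$specs,
                     demux_config(output_mode = "single_file"))
  expect_identical(names(res$groups), "all")
  expect_identical(nrow(res$groups$all), nrow(sim$records))
  expect_true(all(grepl("sample=", res$groups$all$desc)))
})

test_that("percent mode converts to a floored per-pattern allowance", {
  cfg <- demux_config(percent_mode = 0.2)
  expect_identical(longamp:::allowance("ACGTACGTACGTACG", cfg, "index"), 3L)
  expect_identical(longamp:::allowance(strrep("A", 27), cfg, "primer"), 5L)
})

test_that("a search window shorter than index+primer is rejected", {
  fx <- make_grid_fixture()
  rec <- seq_records("r", random_dna(300))
  expect_error(assign_read(rec, fx$specs, demux_config(search_window = 20L)),
               "search_window")
})
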