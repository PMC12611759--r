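spec <- small_spec()
core <- substr(spec$sequence, nchar(spec$forward_primer) + 1,
               spec$unedited_length - nchar(spec$reverse_primer))

test_that("round 1 retains and trims exact end-to-end amplicons", {
  r <- filter_round1_end_to_end(read_tbl(spec$sequence), spec)
  expect_equal(nrow(r$reads), 1)
  expect_equal(r$reads$sequence, core)
})

test_that("round 1 canonicalizes reverse-strand reads", {
  r <- filter_round1_end_to_end(read_tbl(revcomp(spec$sequence)), spec)
  expect_equal(nrow(r$reads), 1)
  expect_equal(r$reads$sequence, core)  # emitted forward, trimmed
})

test_that("round 1 rejects reads without primers, with reasons", {
  r <- filter_round1_end_to_end(read_tbl(core), spec)
  expect_equal(nrow(r$reads), 0)
  expect_equal(r$rejected$reason, "missing 5' primer")
  # forward primer present, 3' primer absent
  half <- substr(spec$sequence, 1, 300)
  r2 <- filter_round1_end_to_end(read_tbl(half), spec)
  expect_equal(r2$rejected$reason, "missing 3' primer")
  # empty input is fine
  r3 <- filter_round1_end_to_end(read_tbl(character(0)), spec)
  expect_equal(nrow(r3$reads), 0)
})

test_that("round 2 keeps locus-matched reads and tolerates 3 edits in 30", {
  r <- filter_round2_locus(read_tbl(core), spec)
  expect_equal(nrow(r$reads), 1)
  # 3 mismatches in the 30-nt anchor are within ceiling(0.1 * 30)
  r3 <- filter_round2_locus(read_tbl(mutate_at(core, c(2, 11, 29))), spec)
  expect_equal(nrow(r3$reads), 1)
  # 4 mismatches are not
  r4 <- filter_round2_locus(read_tbl(mutate_at(core, c(2, 11, 22, 29))), spec)
  expect_equal(nrow(r4$reads), 0)
  # off-locus read (random anchors) rejected
  withr::with_seed(1, {
    off <- random_dna(1, nchar(core))
  })
  r5 <- filter_round2_locus(read_tbl(off), spec)
  expect_equal(r5$rejected$reason, "missing anchor")
})

test_that("round 3 enforces the size cap with its +20 bp buffer", {
  cap <- trimmed_length(spec)
  at_cap <- paste0(core, strrep("A", 20))
  over <- paste0(core, strrep("A", 21))
  under <- substr(core, 1, nchar(core) - 100)
  r <- filter_round3_size(read_tbl(at_cap, over, under), spec)
  expect_equal(nrow(r$reads), 2)
  expect_equal(r$rejected$reason, "oversize")
  expect_equal(nchar(r$reads$sequence), c(cap + 20, nchar(core) - 100))
})

test_that("round 3 cap accommodates the expected HDR insertion", {
  hspec <- small_spec(hdr = 120)
  hreads <- sim_long_reads(hspec, 10, hdr_fraction = 1, seed = 1)
  flt <- filter_longreads(hreads, hspec)
  expect_equal(nrow(flt$reads), 10)
})

test_that("deletion profile matches enumeration and survival is monotone", {
  L <- trimmed_length(spec)  # 550
  lengths <- c(L, L - 320, L, L - 480)
  reads <- read_tbl(core, substr(core, 1, L - 320), core,
                    substr(core, 1, L - 480))
  prof <- compute_deletion_profile(reads, spec, thresholds = c(0, 400))
  expect_equal(sort(prof$per_read$deletion_size), c(0, 0, 320, 480))
  expect_equal(unname(prof$freq_deletion_gt[["0"]]), 0.5)
  expect_equal(unname(prof$freq_deletion_gt[["400"]]), 0.25)
  expect_true(all(diff(prof$survival$fraction) <= 0))
  expect_equal(prof$mean_deletion, 400)
  # all unedited: zero frequency
  prof0 <- compute_deletion_profile(read_tbl(core, core), spec, 1000)
  expect_equal(unname(prof0$freq_deletion_gt[["1000"]]), 0)
  # no reads: flagged empty profile
  profe <- compute_deletion_profile(read_tbl(character(0)), spec)
  expect_true(profe$empty)
  expect_true(is.na(profe$freq_deletion_gt[["1000"]]))
})

test_that("length-based HDR calling counts insertion-sized reads", {
  hspec <- small_spec(hdr = 120)
  hcore_len <- trimmed_length(hspec)
  wt_read <- substr(hspec$sequence, 26, 25 + hcore_len)
  hdr_read <- paste0(wt_read, strrep("A", 120))  # length L* + 120
  reads <- read_tbl(c(rep(hdr_read, 50), rep(wt_read, 50)))
  expect_equal(call_longread_hdr(reads, hspec), 0.5)
  expect_equal(call_longread_hdr(read_tbl(wt_read), hspec), 0)
  expect_error(call_longread_hdr(read_tbl(wt_read), spec), "no hdr_insertion")
})

test_that("noise-free pipeline recovers the generator's deletion multiset", {
  reads <- sim_long_reads(spec, 120, deletion_fraction = 0.4,
                          deletion_size_range = c(80, 400),
                          contaminant_fraction = 0.1,
                          reverse_strand_fraction = 0.5, seed = 12)
  res <- run_longread_pipeline(reads, spec)
  truth <- reads[reads$class != "contaminant", ]
  expect_equal(sort(res$profile$per_read$deletion_size),
               sort(truth$deletion_size))
  expect_true(all(diff(unname(res$report$counts)) <= 0))
})

test_that("filtering is invariant to read order", {
  reads <- sim_long_reads(spec, 80, deletion_fraction = 0.3,
                          substitution_rate = 0.02, indel_noise_rate = 0.03,
                          contaminant_fraction = 0.1, seed = 13)
  res1 <- run_longread_pipeline(reads, spec)
  withr::with_seed(99, {
    perm <- reads[sample(nrow(reads)), ]
  })
  res2 <- run_longread_pipeline(perm, spec)
  expect_equal(res1$report$counts, res2$report$counts)
  expect_equal(sort(res1$profile$per_read$deletion_size),
               sort(res2$profile$per_read$deletion_size))
})

test_that("contaminants are rejected and survivors look on-target", {
  reads <- sim_long_reads(spec, 200, substitution_rate = 0.02,
                          indel_noise_rate = 0.03,
                          contaminant_fraction = 0.05, seed = 14)
  res <- run_longread_pipeline(reads, spec)
  truth <- reads[match(res$reads$read_id, reads$read_id), ]
  expect_lte(mean(truth$class == "contaminant"), 0.01)
  qc <- on_target_fraction(res$reads, spec)
  expect_gt(qc$on_target_fraction, 0.95)
})

test_that("pipeline writes per-read, report and survival outputs", {
  out <- withr::local_tempdir()
  reads <- sim_long_reads(spec, 30, deletion_fraction = 0.5,
                          deletion_size_range = c(100, 300), seed = 15)
  res <- run_longread_pipeline(reads, spec, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("per_read.tsv", "filter_report.json", "survival.csv")
  ))))
  per_read <- readr::read_tsv(file.path(out, "per_read.tsv"),
                              show_col_types = FALSE)
  expect_equal(nrow(per_read), res$profile$n_reads)
  g <- glance(res)
  expect_equal(g$n_input, 30L)
  expect_s3_class(autoplot(res), "ggplot")
})
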