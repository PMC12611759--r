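spec <- gapdh_class_spec()

test_that("anchor pair location returns the 32-nt gap, leftmost placement", {
  read <- spec$wt_amplicon
  gap <- find_anchor_pair(read, spec)
  expect_equal(nchar(gap), 32)
  expect_true(grepl(spec$wt_reference, gap, fixed = TRUE))
  # a 3-bp deletion in the gap breaks the fixed spacing
  gs <- regexpr(spec$anchor_left, read, fixed = TRUE) + 20
  broken <- paste0(substr(read, 1, gs + 2), substr(read, gs + 6, nchar(read)))
  expect_true(is.na(find_anchor_pair(broken, spec)))
  # missing right anchor
  expect_true(is.na(find_anchor_pair(substr(read, 1, gs + 31), spec)))
  # leftmost pair wins when the motif is duplicated
  double <- paste0(read, read)
  expect_equal(find_anchor_pair(double, spec), gap)
})

test_that("classification threshold is sharp at Hamming 11", {
  read <- spec$wt_amplicon
  gs <- as.integer(regexpr(spec$anchor_left, read, fixed = TRUE)) + 20L
  ref_start <- gs + spec$wt_offset_in_gap
  positions <- ref_start + 0:14
  expect_equal(classify_read(read, spec), "wt")
  expect_equal(classify_read(mutate_at(read, positions[1:10]), spec), "wt")
  expect_equal(classify_read(mutate_at(read, positions[1:11]), spec), "hdr")
  expect_equal(classify_read(mutate_at(read, positions[1:12]), spec), "hdr")
})

test_that("classifier agrees with a brute-force placement oracle", {
  withr::with_seed(21, {
    reads <- character(60)
    for (i in seq_along(reads)) {
      case <- sample(4, 1)
      base <- spec$wt_amplicon
      reads[i] <- switch(case,
        base,
        # random read, usually no anchors
        random_dna(1, sample(80:200, 1)),
        # barcode allele with random flank lengths
        paste0(random_dna(1, sample(0:30, 1)),
               sub(spec$wt_reference, spec$hdr_reference, base, fixed = TRUE),
               random_dna(1, sample(0:30, 1))),
        # random substitutions sprinkled over the amplicon
        ontarget:::apply_read_noise(base, substitution_rate = 0.05)
      )
    }
    for (r in reads) {
      expect_equal(classify_read(r, spec), oracle_classify(r, spec))
    }
  })
})

test_that("window-based indel caller respects the 30-bp window", {
  wt <- spec$wt_amplicon
  cut <- spec$cut_offset
  # 5-bp deletion at the cut site
  del5 <- paste0(substr(wt, 1, cut - 1), substr(wt, cut + 5, nchar(wt)))
  # substitution only (at the cut site): no indel
  sub1 <- mutate_at(wt, cut)
  # 1-bp insertion far outside the window (40 bp into the amplicon,
  # > 15 bp from the cut by construction of the packaged spec)
  far <- 40L
  ins_far <- paste0(substr(wt, 1, far), "A", substr(wt, far + 1, nchar(wt)))
  calls <- call_indels(read_tbl(del5, sub1, ins_far), spec)
  expect_equal(calls, c("indel", "unclassified", "unclassified"))
})

test_that("whole-read classification resolves candidates via alignment", {
  reads <- sim_short_reads(spec, 400, hdr_fraction = 0.3,
                           partial_hdr_fraction = 0.1,
                           indel_fraction = 0.2, seed = 22)
  cls <- classify_short_reads(reads, spec)
  # noise-free: partial HDR reaches the threshold, so it is called hdr
  expect_true(all(cls$class[reads$class %in% c("hdr", "partial_hdr")] == "hdr"))
  expect_true(all(cls$class[reads$class == "wt"] == "wt"))
  expect_true(all(cls$class[reads$class == "indel"] == "indel"))
})

test_that("allele summarization applies the 0.2% frequency filter", {
  # 1999 wt reads + 1 hdr read: hdr allele at 0.05% is excluded
  wt <- spec$wt_amplicon
  hdr <- sub(spec$wt_reference, spec$hdr_reference, wt, fixed = TRUE)
  reads <- tibble::tibble(
    read_id = paste0("r", 1:2000),
    sequence = c(rep(wt, 1999), hdr)
  )
  out <- summarize_outcomes(classify_short_reads(reads, spec), spec)
  expect_equal(out$n_excluded_low_freq, 1)
  expect_equal(out$table$fraction[out$table$class == "hdr"], 0)
  expect_equal(out$table$fraction[out$table$class == "wt"], 1)
})

test_that("outcome fractions are exact on a clean fixed-count mixture", {
  reads <- sim_short_reads(spec, 10000, hdr_fraction = 0.4,
                           indel_fraction = 0.1, seed = 23)
  out <- summarize_outcomes(classify_short_reads(reads, spec), spec)
  frac <- setNames(out$table$fraction, out$table$class)
  expect_equal(unname(frac[c("hdr", "wt", "indel")]), c(0.40, 0.50, 0.10))
  expect_equal(sum(out$table$fraction), 1, tolerance = 1e-12)
})

test_that("empty input yields a flagged all-zero table", {
  out <- summarize_outcomes(
    classify_short_reads(read_tbl(character(0)), spec), spec
  )
  expect_true(out$empty)
  expect_equal(sum(out$table$n), 0L)
  g <- glance(out)
  expect_equal(g$n_total, 0L)
})

test_that("pipeline writes outcome and allele tables", {
  out_dir <- withr::local_tempdir()
  reads <- sim_short_reads(spec, 500, hdr_fraction = 0.5, seed = 24)
  out <- run_shortread_pipeline(reads, spec, out_dir = out_dir)
  expect_true(all(file.exists(file.path(out_dir,
                                        c("outcomes.csv", "alleles.tsv")))))
  expect_s3_class(autoplot(out), "ggplot")
})
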