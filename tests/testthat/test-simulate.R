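test_that("noise-free unedited long reads have exactly the unedited length", {
  spec <- small_spec()
  reads <- sim_long_reads(spec, 50, seed = 1)
  expect_true(all(reads$class == "wt"))
  expect_true(all(nchar(reads$sequence) == spec$unedited_length))
})

test_that("forced fixed-size deletions shorten every read by that size", {
  spec <- small_spec()
  reads <- sim_long_reads(spec, 40, deletion_fraction = 1,
                          deletion_size_range = c(200, 200), seed = 2)
  expect_true(all(reads$class == "deletion"))
  expect_true(all(nchar(reads$sequence) == spec$unedited_length - 200))
  expect_true(all(reads$deletion_size == 200))
})

test_that("per-read length deficit equals the recorded deletion size", {
  spec <- small_spec()
  reads <- sim_long_reads(spec, 100, deletion_fraction = 0.5,
                          deletion_size_range = c(100, 400), seed = 3)
  on_locus <- reads[reads$class != "contaminant", ]
  expect_equal(spec$unedited_length - nchar(on_locus$sequence),
               on_locus$deletion_size)
})

test_that("HDR long reads carry the configured insertion size", {
  spec <- small_spec(hdr = 120)
  reads <- sim_long_reads(spec, 30, hdr_fraction = 1, seed = 4)
  expect_true(all(nchar(reads$sequence) == spec$unedited_length + 120))
})

test_that("long-read simulation is byte-deterministic per seed", {
  spec <- small_spec()
  cfg <- list(spec = spec, n_reads = 60, deletion_fraction = 0.3,
              substitution_rate = 0.02, indel_noise_rate = 0.03,
              contaminant_fraction = 0.1, reverse_strand_fraction = 0.5,
              seed = 7)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(do.call(sim_long_reads, cfg), f1)
  write_fastq(do.call(sim_long_reads, cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("fixed-count short-read mixtures hit their class counts exactly", {
  spec <- gapdh_class_spec()
  reads <- sim_short_reads(spec, 10000, hdr_fraction = 0.4,
                           indel_fraction = 0.1, seed = 5)
  counts <- table(reads$class)
  expect_equal(unname(counts[["hdr"]]), 4000)
  expect_equal(unname(counts[["wt"]]), 5000)
  expect_equal(unname(counts[["indel"]]), 1000)
})

test_that("short-read class fractions cannot exceed one", {
  spec <- gapdh_class_spec()
  expect_error(sim_short_reads(spec, 10, hdr_fraction = 0.7,
                               indel_fraction = 0.5, seed = 1),
               "sum to <= 1")
})

test_that("single-cell simulation plants an exact number of loss cells", {
  sim <- sim_sc_experiment(n_edited = 500, n_unedited = 20,
                           loss_fraction = 0.2, seed = 6)
  expect_equal(sum(sim$truth$is_loss), 100)
  expect_equal(ncol(sim$edited), 500)
  expect_equal(nrow(sim$edited), nrow(sim$genes))
})

test_that("droplet simulation follows Poisson partition statistics", {
  # lambda 0: no positives
  a0 <- sim_droplet_assay(1000, 0, 0.5, seed = 1)
  expect_equal(a0$n_positive[a0$channel == "target"], 0L)
  # lambda = ln 2: positive fraction 0.5 within 2 s.e.
  a <- sim_droplet_assay(20000, log(2), log(2), seed = 2)
  p <- a$n_positive[1] / a$n_total[1]
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(p - 0.5), 2 * se)
  # same seed, same assay
  expect_identical(sim_droplet_assay(5000, 0.3, 0.6, seed = 9),
                   sim_droplet_assay(5000, 0.3, 0.6, seed = 9))
})

test_that("sampling mode draws multinomial class counts near the target", {
  spec <- gapdh_class_spec()
  reads <- sim_short_reads(spec, 5000, hdr_fraction = 0.4,
                           fixed_counts = FALSE, seed = 8)
  n_hdr <- sum(reads$class == "hdr")
  expect_gt(n_hdr, 2000 - 4 * sqrt(5000 * 0.4 * 0.6))
  expect_lt(n_hdr, 2000 + 4 * sqrt(5000 * 0.4 * 0.6))
})
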