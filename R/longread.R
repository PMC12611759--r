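#' Round 1: keep and trim intact end-to-end amplicons
#'
#' Reads are first strand-canonicalized: a read whose 5' end does not
#' carry the forward primer is tried as its reverse complement. Retained
#' reads carry the forward primer at the 5' end and the reverse complement
#' of the reverse primer at the 3' end, each located by anchored
#' semi-global matching tolerating up to `ceiling(max_error_rate *
#' primer_length)` edits (substitutions + indels). Both primers are
#' trimmed and all retained reads are emitted in forward orientation.
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param spec an [amplicon_spec()].
#' @param max_error_rate tolerated edits per primer base (default 0.1).
#' @return list with `reads` (retained, trimmed, forward-oriented tibble)
#'   and `rejected` (tibble `read_id`, `reason`).
#' @export
filter_round1_end_to_end <- function(reads, spec, max_error_rate = 0.1) {
  fwd <- spec$forward_primer
  rev_rc <- revcomp(spec$reverse_primer)
  k_f <- ceiling(max_error_rate * nchar(fwd))
  k_r <- ceiling(max_error_rate * nchar(rev_rc))

  n <- nrow(reads)
  out_seq <- character(n)
  keep <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    m5 <- match_prefix(s, fwd, k_f)
    if (!m5$found) {
      s_rc <- revcomp(s)
      m5_rc <- match_prefix(s_rc, fwd, k_f)
      if (m5_rc$found) {
        s <- s_rc
        m5 <- m5_rc
      } else {
        reason[i] <- "missing 5' primer"
        next
      }
    }
    m3 <- match_suffix(s, rev_rc, k_r)
    if (!m3$found) {
      reason[i] <- "missing 3' primer"
      next
    }
    if (m3$start <= m5$end) {
      reason[i] <- "primers overlap"
      next
    }
    keep[i] <- TRUE
    out_seq[i] <- substr(s, m5$end + 1L, m3$start - 1L)
  }
  list(
    reads = tibble(read_id = reads$read_id[keep], sequence = out_seq[keep]),
    rejected = tibble(read_id = reads$read_id[!keep], reason = reason[!keep])
  )
}

#' Round 2: keep amplicons specific to the genomic locus
#'
#' Retained reads begin with the 30-bp forward locus anchor and end with
#' the reverse complement of the 30-bp reverse locus anchor, matched with
#' the same error tolerance as round 1. Anchors are genomic sequence and
#' are not trimmed.
#'
#' @inheritParams filter_round1_end_to_end
#' @return list with `reads` and `rejected` tibbles.
#' @export
filter_round2_locus <- function(reads, spec, max_error_rate = 0.1) {
  anchor_f <- spec$locus_anchor_fwd
  anchor_r_rc <- revcomp(spec$locus_anchor_rev)
  k <- ceiling(max_error_rate * 30)

  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    keep[i] <- match_prefix(s, anchor_f, k)$found &&
      match_suffix(s, anchor_r_rc, k)$found
  }
  list(
    reads = reads[keep, , drop = FALSE],
    rejected = tibble(read_id = reads$read_id[!keep],
                      reason = rep("missing anchor", sum(!keep)))
  )
}

#' Round 3: discard oversize amplicons
#'
#' Reads longer than the expected unedited trimmed length plus the size
#' buffer are discarded. When the spec expects an HDR insertion the cap
#' is raised by the insertion size, so knock-in alleles survive while
#' still-larger artifacts are removed.
#'
#' @inheritParams filter_round1_end_to_end
#' @return list with `reads` and `rejected` tibbles.
#' @export
filter_round3_size <- function(reads, spec) {
  cap <- trimmed_length(spec) +
    (spec$hdr_insertion_size %||% 0L) + spec$size_buffer
  len <- nchar(reads$sequence)
  keep <- len <= cap
  list(
    reads = reads[keep, , drop = FALSE],
    rejected = tibble(read_id = reads$read_id[!keep],
                      reason = rep("oversize", sum(!keep)))
  )
}

#' Run all three filtering rounds
#'
#' @inheritParams filter_round1_end_to_end
#' @return list with `reads` (surviving trimmed reads) and `report`
#'   (a `filter_report`: pass counts per round and rejection reasons).
#' @export
filter_longreads <- function(reads, spec, max_error_rate = 0.1) {
  r1 <- filter_round1_end_to_end(reads, spec, max_error_rate)
  r2 <- filter_round2_locus(r1$reads, spec, max_error_rate)
  r3 <- filter_round3_size(r2$reads, spec)
  counts <- c(
    n_input = nrow(reads),
    n_pass_round1 = nrow(r1$reads),
    n_pass_round2 = nrow(r2$reads),
    n_pass_round3 = nrow(r3$reads)
  )
  stopifnot(!is.unsorted(rev(counts)))  # monotone attrition
  reasons <- bind_rows(
    mutate(r1$rejected, round = "round1"),
    mutate(r2$rejected, round = "round2"),
    mutate(r3$rejected, round = "round3")
  )
  reasons <- count(reasons, .data$round, .data$reason, name = "n")
  report <- structure(list(counts = counts, reasons = reasons),
                      class = "filter_report")
  list(reads = r3$reads, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input        %8d\n", x$counts[["n_input"]]))
  for (r in c("round1", "round2", "round3")) {
    cat(sprintf("  pass %-7s %8d\n", r, x$counts[[paste0("n_pass_", r)]]))
  }
  if (nrow(x$reasons)) {
    cat("  rejections:\n")
    for (i in seq_len(nrow(x$reasons))) {
      cat(sprintf("    %-7s %-18s %d\n", x$reasons$round[i],
                  x$reasons$reason[i], x$reasons$n[i]))
    }
  }
  invisible(x)
}

#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  tibble(round = c("input", "round1", "round2", "round3"),
         n_pass = unname(x$counts))
}

#' Deletion profile from surviving long reads
#'
#' Per-read deletion sizes are inferred from trimmed read length:
#' `deletion_size = max(0, L - length)` where `L` is the expected trimmed
#' unedited length. The profile carries a deletion-size survival curve
#' (fraction of reads with deletion greater than each size), the deletion
#' frequency above each requested threshold (default 1 kb), summary
#' statistics over deletion-bearing reads, and — when the spec expects an
#' HDR insertion — the fraction of reads matching the insertion length.
#'
#' @param reads tibble of reads that passed all three rounds.
#' @param spec an [amplicon_spec()].
#' @param thresholds deletion-size thresholds in bp (default 1000).
#' @param hdr_tolerance_bp length tolerance for the HDR insertion call
#'   (default 20).
#' @return an object of class `deletion_profile`.
#' @export
compute_deletion_profile <- function(reads, spec, thresholds = 1000,
                                     hdr_tolerance_bp = 20) {
  L <- trimmed_length(spec)
  len <- nchar(reads$sequence)
  deletion <- pmax(0L, L - len)
  n <- length(deletion)

  if (n == 0) {
    profile <- list(
      per_read = tibble(read_id = character(), length = integer(),
                        deletion_size = integer()),
      survival = tibble(size = numeric(), fraction = numeric()),
      freq_deletion_gt = setNames(rep(NA_real_, length(thresholds)),
                                  as.character(thresholds)),
      hdr_fraction = NA_real_, n_reads = 0L, empty = TRUE,
      mean_deletion = NA_real_, median_deletion = NA_real_,
      expected_length = L
    )
    return(structure(profile, class = "deletion_profile"))
  }

  sizes <- sort(unique(c(0, deletion)))
  survival <- tibble(
    size = sizes,
    fraction = vapply(sizes, function(s) mean(deletion > s), numeric(1))
  )
  freq <- vapply(thresholds, function(s) mean(deletion > s), numeric(1))
  hdr_frac <- if (!is.null(spec$hdr_insertion_size)) {
    mean(abs(len - (L + spec$hdr_insertion_size)) <= hdr_tolerance_bp)
  } else NA_real_
  with_del <- deletion[deletion > 0]

  structure(list(
    per_read = tibble(read_id = reads$read_id, length = len,
                      deletion_size = deletion),
    survival = survival,
    freq_deletion_gt = setNames(freq, as.character(thresholds)),
    hdr_fraction = hdr_frac,
    n_reads = n, empty = FALSE,
    mean_deletion = if (length(with_del)) mean(with_del) else NA_real_,
    median_deletion = if (length(with_del)) median(with_del) else NA_real_,
    expected_length = L
  ), class = "deletion_profile")
}

#' @export
print.deletion_profile <- function(x, ...) {
  cat("<deletion_profile> ", x$n_reads, " reads (expected trimmed length ",
      x$expected_length, " bp)\n", sep = "")
  for (s in names(x$freq_deletion_gt)) {
    cat(sprintf("  freq(deletion > %s bp): %.4f\n", s,
                x$freq_deletion_gt[[s]]))
  }
  if (!is.na(x$hdr_fraction)) {
    cat(sprintf("  HDR-insertion fraction: %.4f\n", x$hdr_fraction))
  }
  invisible(x)
}

#' @method tidy deletion_profile
#' @export
tidy.deletion_profile <- function(x, ...) x$per_read

#' @method glance deletion_profile
#' @export
glance.deletion_profile <- function(x, ...) {
  tibble(
    n_reads = x$n_reads,
    freq_deletion_gt_1kb = x$freq_deletion_gt[["1000"]] %||% NA_real_,
    hdr_fraction = x$hdr_fraction,
    mean_deletion = x$mean_deletion,
    median_deletion = x$median_deletion
  )
}

#' @method autoplot deletion_profile
#' @export
autoplot.deletion_profile <- function(object, ...) {
  ggplot2::ggplot(object$survival,
                  ggplot2::aes(x = .data$size, y = .data$fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "deletion size (bp)",
                  y = "fraction of reads with larger deletion",
                  title = "Deletion-size survival curve") +
    ggplot2::theme_minimal()
}

#' HDR fraction from read lengths
#'
#' A read is called HDR when its trimmed length matches the expected
#' unedited trimmed length plus the spec's HDR insertion size, within
#' `tolerance_bp`.
#'
#' @inheritParams compute_deletion_profile
#' @param tolerance_bp length tolerance in bp (default 20).
#' @return HDR fraction of all passing reads.
#' @export
call_longread_hdr <- function(reads, spec, tolerance_bp = 20) {
  if (is.null(spec$hdr_insertion_size)) {
    stop("spec has no hdr_insertion_size; nothing to call")
  }
  if (nrow(reads) == 0) return(NA_real_)
  expected <- trimmed_length(spec) + spec$hdr_insertion_size
  mean(abs(nchar(reads$sequence) - expected) <= tolerance_bp)
}

#' On-target identity QC
#'
#' Fraction of (trimmed) reads whose global identity to the unedited
#' amplicon core is at least `min_identity`. This replaces a genome-wide
#' alignment QC with an amplicon-local equivalent: in a properly
#' configured workflow the vast majority (>95%) of reads surviving all
#' filtering rounds derive from the target region.
#'
#' Identity is `1 - edit_distance / max(length)`, computed with a banded
#' alignment; off-locus sequences fall far below any sensible cutoff.
#'
#' @inheritParams compute_deletion_profile
#' @param min_identity identity cutoff (default 0.8).
#' @return named list: `on_target_fraction`, per-read `identity` vector.
#' @export
on_target_fraction <- function(reads, spec, min_identity = 0.8) {
  if (is.null(spec$sequence)) stop("spec must carry the amplicon sequence")
  core <- substr(spec$sequence, nchar(spec$forward_primer) + 1L,
                 spec$unedited_length - nchar(spec$reverse_primer))
  ident <- vapply(reads$sequence, function(s) {
    band <- abs(nchar(s) - nchar(core)) + 150L
    d <- edit_distance_banded_cpp(s, core, band)
    1 - d / max(nchar(s), nchar(core))
  }, numeric(1), USE.NAMES = FALSE)
  list(on_target_fraction = mean(ident >= min_identity), identity = ident)
}

#' Run the full long-read deletion pipeline
#'
#' Reads FASTQ input (or takes a read tibble), applies the three
#' filtering rounds, computes the deletion profile and optionally writes
#' the per-read table, filter report and survival curve to `out_dir`.
#'
#' @param input FASTQ(.gz) path or a tibble with `read_id`, `sequence`.
#' @param spec an [amplicon_spec()].
#' @param thresholds deletion-size thresholds in bp.
#' @param max_error_rate primer/anchor matching tolerance.
#' @param hdr_tolerance_bp HDR length-call tolerance.
#' @param out_dir optional output directory; writes `per_read.tsv`,
#'   `filter_report.json` and `survival.csv`.
#' @return an object of class `longread_result` with elements `report`,
#'   `profile` and `reads`.
#' @export
run_longread_pipeline <- function(input, spec, thresholds = 1000,
                                  max_error_rate = 0.1,
                                  hdr_tolerance_bp = 20, out_dir = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else input
  flt <- filter_longreads(reads, spec, max_error_rate)
  profile <- compute_deletion_profile(flt$reads, spec, thresholds,
                                      hdr_tolerance_bp)
  res <- structure(list(report = flt$report, profile = profile,
                        reads = flt$reads, spec = spec),
                   class = "longread_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(profile$per_read, file.path(out_dir, "per_read.tsv"))
    jsonlite::write_json(
      list(counts = as.list(flt$report$counts), reasons = flt$report$reasons),
      file.path(out_dir, "filter_report.json"), auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(profile$survival, file.path(out_dir, "survival.csv"))
  }
  res
}

#' @export
print.longread_result <- function(x, ...) {
  print(x$report)
  print(x$profile)
  invisible(x)
}

#' @method tidy longread_result
#' @export
tidy.longread_result <- function(x, ...) x$profile$per_read

#' @method glance longread_result
#' @export
glance.longread_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_input = x$report$counts[["n_input"]],
           n_pass_round3 = x$report$counts[["n_pass_round3"]]),
    glance(x$profile)
  )
}

#' @method autoplot longread_result
#' @export
autoplot.longread_result <- function(object, ...) autoplot(object$profile, ...)
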