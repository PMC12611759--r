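#' Simulate long-read amplicon sequencing of an edited locus
#'
#' Generates ONT-like amplicon reads with known ground truth: unedited
#' end-to-end amplicons, alleles carrying a kilobase-scale internal
#' deletion spanning the cut site, HDR knock-in alleles carrying the
#' expected insertion, and off-locus contaminants without primer
#' sequences. Per-base substitution and short-indel noise emulate
#' long-read error; a configurable fraction of reads is emitted
#' reverse-complemented.
#'
#' Class fractions refer to on-locus reads; contaminants are added on top
#' as `round(n_reads * contaminant_fraction)` of the total. By default
#' fractions are realized as exact counts (`round(n * f)`), which makes
#' downstream recovery tests exact; set `fixed_counts = FALSE` for
#' multinomial sampling.
#'
#' @param spec an [amplicon_spec()] with `sequence` populated.
#' @param n_reads total number of reads.
#' @param deletion_fraction fraction of on-locus reads carrying an
#'   internal deletion.
#' @param hdr_fraction fraction of on-locus reads carrying the HDR
#'   insertion (requires `spec$hdr_insertion_size`).
#' @param deletion_size_range deletion sizes are drawn uniformly from this
#'   range (bp) and clamped to the available core; default 1000 bp up to
#'   core length minus 200.
#' @param substitution_rate,indel_noise_rate per-base error rates.
#' @param contaminant_fraction fraction of total reads that are random
#'   off-locus sequences of comparable length.
#' @param reverse_strand_fraction probability a read is emitted as its
#'   reverse complement.
#' @param fixed_counts realize fractions as exact counts (default) or
#'   sample classes per read.
#' @param seed RNG seed; identical configuration and seed give identical
#'   output.
#' @return tibble with columns `read_id`, `sequence`, `class`
#'   (`"wt"`, `"deletion"`, `"hdr"`, `"contaminant"`), `deletion_size`
#'   and `strand` — the sequence collection and its truth table in one.
#' @seealso [write_fastq()] to serialize, [run_longread_pipeline()] to
#'   analyze.
#' @export
sim_long_reads <- function(spec, n_reads,
                           deletion_fraction = 0, hdr_fraction = 0,
                           deletion_size_range = NULL,
                           substitution_rate = 0, indel_noise_rate = 0,
                           contaminant_fraction = 0,
                           reverse_strand_fraction = 0,
                           fixed_counts = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.null(spec$sequence)) stop("spec must carry the amplicon sequence")
  check_fraction(deletion_fraction, hdr_fraction, contaminant_fraction,
                 reverse_strand_fraction, substitution_rate, indel_noise_rate)
  if (deletion_fraction + hdr_fraction > 1) {
    stop("deletion_fraction + hdr_fraction must be <= 1")
  }
  if (hdr_fraction > 0 && is.null(spec$hdr_insertion_size)) {
    stop("hdr_fraction > 0 requires spec$hdr_insertion_size")
  }
  set.seed(seed)

  p_len <- nchar(spec$forward_primer)
  r_len <- nchar(spec$reverse_primer)
  core_start <- p_len + 30L + 1L
  core_end <- spec$unedited_length - r_len - 30L
  core_len <- core_end - core_start + 1L
  if (is.null(deletion_size_range)) {
    deletion_size_range <- c(1000L, max(1000L, core_len - 200L))
  }

  n_contam <- round(n_reads * contaminant_fraction)
  n_locus <- n_reads - n_contam
  classes <- draw_classes(
    n_locus,
    c(deletion = deletion_fraction, hdr = hdr_fraction),
    remainder = "wt", fixed = fixed_counts
  )
  classes <- c(classes, rep("contaminant", n_contam))
  classes <- sample(classes)  # interleave

  hdr_insert <- if (!is.null(spec$hdr_insertion_size)) {
    random_dna(1, spec$hdr_insertion_size)
  }
  cut <- min(max(spec$cut_offset, core_start + 1L), core_end - 1L)

  n <- length(classes)
  del_size <- integer(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (cls == "contaminant") {
      w <- round(spec$unedited_length * runif(1, 0.9, 1.1))
      seqs[i] <- random_dna(1, w)
    } else if (cls == "deletion") {
      size <- round(runif(1, deletion_size_range[1], deletion_size_range[2]))
      size <- min(size, core_len)
      del_size[i] <- size
      lo <- max(core_start, cut - size + 1L)
      hi <- min(cut, core_end - size + 1L)
      start <- if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      seqs[i] <- paste0(substr(spec$sequence, 1, start - 1L),
                        substr(spec$sequence, start + size,
                               spec$unedited_length))
    } else if (cls == "hdr") {
      seqs[i] <- paste0(substr(spec$sequence, 1, cut),
                        hdr_insert,
                        substr(spec$sequence, cut + 1L, spec$unedited_length))
    } else {
      seqs[i] <- spec$sequence
    }
  }
  if (substitution_rate > 0 || indel_noise_rate > 0) {
    seqs <- vapply(seqs, apply_read_noise, character(1),
                   substitution_rate = substitution_rate,
                   indel_rate = indel_noise_rate, USE.NAMES = FALSE)
  }
  strand <- ifelse(runif(n) < reverse_strand_fraction, "-", "+")
  flip <- strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])

  tibble(
    read_id = sprintf("read%06d", seq_len(n)),
    sequence = seqs,
    class = classes,
    deletion_size = del_size,
    strand = strand
  )
}

#' Simulate short-read amplicons with HDR barcode, partial HDR, WT and
#' indel alleles
#'
#' HDR reads carry the full substitution barcode (the spec's
#' `hdr_reference`) in place of the wild-type reference inside the
#' inter-anchor gap; partial-HDR reads carry all but one of the barcode
#' substitutions, so their Hamming distance to the wild-type reference
#' still reaches the classification threshold; indel reads carry a small
#' deletion or insertion at the cut site, which breaks the fixed anchor
#' spacing; WT reads are the unedited amplicon. Fractions are realized as
#' exact counts by default; the remainder after HDR, partial-HDR and
#' indel fractions is WT.
#'
#' @param spec an [hdr_class_spec()].
#' @param n_reads total number of reads.
#' @param hdr_fraction,partial_hdr_fraction,indel_fraction class
#'   fractions; their sum must be <= 1.
#' @param indel_size_range absolute indel sizes drawn uniformly from this
#'   range (default 1-6 bp); sign (insertion/deletion) is random.
#' @param substitution_rate per-base substitution noise.
#' @inheritParams sim_long_reads
#' @return tibble with `read_id`, `sequence`, `class`
#'   (`"hdr"`, `"partial_hdr"`, `"wt"`, `"indel"`).
#' @export
sim_short_reads <- function(spec, n_reads,
                            hdr_fraction = 0, partial_hdr_fraction = 0,
                            indel_fraction = 0, indel_size_range = c(1L, 6L),
                            substitution_rate = 0,
                            fixed_counts = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "hdr_class_spec"))
  check_fraction(hdr_fraction, partial_hdr_fraction, indel_fraction,
                 substitution_rate)
  if (hdr_fraction + partial_hdr_fraction + indel_fraction > 1) {
    stop("class fractions must sum to <= 1")
  }
  set.seed(seed)
  classes <- draw_classes(
    n_reads,
    c(hdr = hdr_fraction, partial_hdr = partial_hdr_fraction,
      indel = indel_fraction),
    remainder = "wt", fixed = fixed_counts
  )
  classes <- sample(classes)

  wt <- spec$wt_amplicon
  gap_start <- find_exact(wt, spec$anchor_left) + nchar(spec$anchor_left)
  ref_start <- gap_start + spec$wt_offset_in_gap
  ref_len <- nchar(spec$wt_reference)
  hdr_seq <- paste0(substr(wt, 1, ref_start - 1L), spec$hdr_reference,
                    substr(wt, ref_start + ref_len, nchar(wt)))
  barcode_pos <- which(strsplit(spec$hdr_reference, "")[[1]] !=
                         strsplit(spec$wt_reference, "")[[1]])

  seqs <- vapply(classes, function(cls) {
    switch(cls,
      wt = wt,
      hdr = hdr_seq,
      partial_hdr = {
        # revert one random barcode substitution to wild type
        revert <- sample(barcode_pos, 1)
        chars <- strsplit(spec$hdr_reference, "")[[1]]
        chars[revert] <- substr(spec$wt_reference, revert, revert)
        paste0(substr(wt, 1, ref_start - 1L), paste(chars, collapse = ""),
               substr(wt, ref_start + ref_len, nchar(wt)))
      },
      indel = {
        size <- sample(seq(indel_size_range[1], indel_size_range[2]), 1)
        cut <- spec$cut_offset
        if (runif(1) < 0.5) {
          paste0(substr(wt, 1, cut - 1L), substr(wt, cut + size, nchar(wt)))
        } else {
          # templated duplication, the recurrent Cas9 insertion allele
          paste0(substr(wt, 1, cut), substr(wt, cut - size + 1L, cut),
                 substr(wt, cut + 1L, nchar(wt)))
        }
      }
    )
  }, character(1), USE.NAMES = FALSE)

  if (substitution_rate > 0) {
    seqs <- vapply(seqs, apply_read_noise, character(1),
                   substitution_rate = substitution_rate,
                   USE.NAMES = FALSE)
  }
  tibble(
    read_id = sprintf("read%06d", seq_along(classes)),
    sequence = seqs,
    class = classes
  )
}

# realize class fractions as exact counts or multinomial draws;
# returns an unshuffled character vector of length n
draw_classes <- function(n, fractions, remainder, fixed = TRUE) {
  if (fixed) {
    counts <- round(n * fractions)
    if (sum(counts) > n) stop("class counts exceed n")
    c(rep(names(counts), counts), rep(remainder, n - sum(counts)))
  } else {
    p <- c(fractions, setNames(1 - sum(fractions), remainder))
    sample(names(p), n, replace = TRUE, prob = p)
  }
}

check_fraction <- function(...) {
  vals <- c(...)
  if (any(vals < 0 | vals > 1)) stop("rates and fractions must be in [0, 1]")
  invisible(TRUE)
}
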