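#' Amplicon specification for long-read deletion profiling
#'
#' Describes one target locus for the long-read workflow: the PCR primers
#' that define an end-to-end amplicon, the 30-bp genomic anchor sequences
#' immediately inside the primer binding sites (used to confirm locus
#' identity), the unedited amplicon length, the Cas9 cut position, and an
#' optional expected HDR insertion size.
#'
#' The amplicon layout, 5' to 3' on the forward strand, is
#' `forward_primer + locus_anchor_fwd + core + revcomp(locus_anchor_rev) +
#' revcomp(reverse_primer)`; `locus_anchor_rev` is given in reverse-strand
#' orientation, mirroring how a reverse primer is specified.
#'
#' @param locus_name,chrom identifiers (free text).
#' @param forward_primer,reverse_primer primer sequences, each given 5'->3'
#'   on its own strand. Palindromic primers are rejected: strand
#'   canonicalization relies on the primers distinguishing orientations.
#' @param locus_anchor_fwd,locus_anchor_rev 30-nt genomic sequences
#'   immediately following the primer binding sites, each 5'->3' on the
#'   primer's strand.
#' @param unedited_length full unedited amplicon length in bp, primers
#'   included.
#' @param cut_offset 1-based position of the Cas9 cut site from the
#'   amplicon start.
#' @param hdr_insertion_size expected HDR template insertion size in bp
#'   (e.g. 228), or `NULL` when the experiment has no knock-in allele.
#' @param size_buffer bp of extra length tolerated above the size cap in
#'   the oversize filter (default 20, accommodating residual long-read
#'   indel error).
#' @param sequence optional full unedited amplicon sequence. Required by
#'   the read simulator and by the on-target identity QC; an analysis of
#'   externally generated reads only needs primers/anchors/lengths.
#' @return an object of class `amplicon_spec` (a validated list).
#' @seealso [random_amplicon_spec()] for a simulation-ready spec,
#'   [read_amplicon_spec()] for JSON/YAML loading.
#' @export
amplicon_spec <- function(locus_name, chrom, forward_primer, reverse_primer,
                          locus_anchor_fwd, locus_anchor_rev,
                          unedited_length, cut_offset,
                          hdr_insertion_size = NULL, size_buffer = 20,
                          sequence = NULL) {
  spec <- list(
    locus_name = as.character(locus_name),
    chrom = as.character(chrom),
    forward_primer = norm_dna(forward_primer),
    reverse_primer = norm_dna(reverse_primer),
    locus_anchor_fwd = norm_dna(locus_anchor_fwd),
    locus_anchor_rev = norm_dna(locus_anchor_rev),
    unedited_length = as.integer(unedited_length),
    cut_offset = as.integer(cut_offset),
    hdr_insertion_size = if (!is.null(hdr_insertion_size))
      as.integer(hdr_insertion_size),
    size_buffer = as.integer(size_buffer),
    sequence = if (!is.null(sequence)) norm_dna(sequence)
  )
  class(spec) <- "amplicon_spec"
  validate_amplicon_spec(spec)
}

validate_amplicon_spec <- function(spec) {
  if (nchar(spec$locus_anchor_fwd) != 30 || nchar(spec$locus_anchor_rev) != 30) {
    stop("locus anchors must be exactly 30 nt")
  }
  flank <- nchar(spec$forward_primer) + nchar(spec$reverse_primer) + 60L
  if (spec$unedited_length <= flank) {
    stop("unedited_length must exceed combined primer and anchor lengths (",
         flank, " bp)")
  }
  for (p in c("forward_primer", "reverse_primer")) {
    if (spec[[p]] == revcomp(spec[[p]])) {
      stop(p, " is palindromic; strand canonicalization would be ambiguous")
    }
  }
  if (spec$cut_offset < 1 || spec$cut_offset > spec$unedited_length) {
    stop("cut_offset must lie within the amplicon")
  }
  if (!is.null(spec$hdr_insertion_size) && spec$hdr_insertion_size <= 0) {
    stop("hdr_insertion_size must be positive")
  }
  if (spec$size_buffer < 0) stop("size_buffer must be >= 0")
  if (!is.null(spec$sequence)) {
    if (nchar(spec$sequence) != spec$unedited_length) {
      stop("sequence length (", nchar(spec$sequence),
           ") disagrees with unedited_length (", spec$unedited_length, ")")
    }
    if (!startsWith(spec$sequence, spec$forward_primer) ||
        !endsWith(spec$sequence, revcomp(spec$reverse_primer))) {
      stop("sequence must start with forward_primer and end with ",
           "revcomp(reverse_primer)")
    }
  }
  spec
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat("<amplicon_spec> ", x$locus_name, " (", x$chrom, ")\n", sep = "")
  cat("  unedited length : ", x$unedited_length, " bp (trimmed core ",
      trimmed_length(x), " bp)\n", sep = "")
  cat("  cut offset      : ", x$cut_offset, "\n", sep = "")
  cat("  HDR insertion   : ",
      if (is.null(x$hdr_insertion_size)) "none"
      else paste0(x$hdr_insertion_size, " bp"), "\n", sep = "")
  invisible(x)
}

#' Expected primer-trimmed length of the unedited amplicon
#'
#' @param spec an [amplicon_spec()].
#' @return integer: `unedited_length - nchar(forward_primer) -
#'   nchar(reverse_primer)`.
#' @export
trimmed_length <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  spec$unedited_length - nchar(spec$forward_primer) - nchar(spec$reverse_primer)
}

#' Generate a simulation-ready random amplicon spec
#'
#' Builds an [amplicon_spec()] with a concrete random unedited sequence,
#' suitable for the read simulator and for end-to-end tests. The cut site
#' defaults to the amplicon midpoint.
#'
#' @param unedited_length total amplicon length in bp (default 3500,
#'   a typical long-range PCR window around a cut site).
#' @param primer_length length of each primer (default 25).
#' @param hdr_insertion_size optional expected knock-in size in bp.
#' @param cut_offset cut position; default `unedited_length %/% 2`.
#' @param seed RNG seed (the function calls `set.seed()`).
#' @inheritParams amplicon_spec
#' @return an `amplicon_spec` with `sequence` populated.
#' @export
random_amplicon_spec <- function(unedited_length = 3500, primer_length = 25,
                                 hdr_insertion_size = NULL, cut_offset = NULL,
                                 size_buffer = 20,
                                 locus_name = "synthetic_locus",
                                 chrom = "chrS", seed = 1L) {
  set.seed(seed)
  repeat {
    fwd <- random_dna(1, primer_length)
    rev <- random_dna(1, primer_length)
    if (fwd != revcomp(fwd) && rev != revcomp(rev)) break
  }
  anchor_f <- random_dna(1, 30)
  anchor_r <- random_dna(1, 30)
  core_len <- unedited_length - 2L * primer_length - 60L
  core <- random_dna(1, core_len)
  seq <- paste0(fwd, anchor_f, core, revcomp(anchor_r), revcomp(rev))
  amplicon_spec(
    locus_name = locus_name, chrom = chrom,
    forward_primer = fwd, reverse_primer = rev,
    locus_anchor_fwd = anchor_f, locus_anchor_rev = anchor_r,
    unedited_length = unedited_length,
    cut_offset = cut_offset %||% (unedited_length %/% 2L),
    hdr_insertion_size = hdr_insertion_size,
    size_buffer = size_buffer,
    sequence = seq
  )
}

#' HDR classifier specification for short-read outcomes
#'
#' Describes the anchor-pair classifier for one locus: two fixed anchor
#' sequences separated by a fixed-length gap, a wild-type reference 15-mer
#' inside the gap, and the Hamming-distance threshold separating HDR
#' barcode alleles from unedited reads. Also carries the wild-type
#' amplicon and cut position used by the window-based indel caller.
#'
#' @param anchor_left,anchor_right anchor sequences flanking the
#'   quantification gap (20 nt in the packaged example).
#' @param inter_anchor_distance exact gap length in bp between the anchors
#'   (default 32).
#' @param wt_reference wild-type sequence located inside the gap; reads
#'   whose gap segment differs from it by at least `hamming_threshold`
#'   substitutions are called HDR.
#' @param wt_offset_in_gap 0-based offset of `wt_reference` within the gap.
#'   Default `NULL`: computed by exact search of `wt_reference` in the gap
#'   segment of `wt_amplicon`, which makes the packaged spec reproducible
#'   without guessing a coordinate.
#' @param hamming_threshold minimum Hamming distance calling HDR
#'   (default 11, one below a full 12-nt barcode so that partial barcode
#'   integration is still recognized).
#' @param allele_freq_min minimum allele frequency retained when
#'   summarizing outcomes (default 0.002, i.e. 0.2%).
#' @param quant_window width in bp of the indel quantification window
#'   centered on the cut site (default 30).
#' @param wt_amplicon full wild-type amplicon sequence; must contain
#'   `anchor_left`, a gap of `inter_anchor_distance` bp, then
#'   `anchor_right`.
#' @param cut_offset 1-based cut position in `wt_amplicon`; default the
#'   center of the inter-anchor gap.
#' @param hdr_reference the HDR allele's version of `wt_reference`
#'   (the substitution barcode). Default: `wt_reference` with its first 12
#'   positions substituted, giving Hamming distance 12. Only the simulator
#'   uses it; classification needs just the threshold.
#' @param anchor_max_mismatch mismatch budget for anchor location
#'   (default 0, exact matching).
#' @return an object of class `hdr_class_spec`.
#' @export
hdr_class_spec <- function(anchor_left, anchor_right,
                           inter_anchor_distance = 32,
                           wt_reference, wt_offset_in_gap = NULL,
                           hamming_threshold = 11, allele_freq_min = 0.002,
                           quant_window = 30, wt_amplicon, cut_offset = NULL,
                           hdr_reference = NULL, anchor_max_mismatch = 0) {
  spec <- list(
    anchor_left = norm_dna(anchor_left),
    anchor_right = norm_dna(anchor_right),
    inter_anchor_distance = as.integer(inter_anchor_distance),
    wt_reference = norm_dna(wt_reference),
    wt_offset_in_gap = if (!is.null(wt_offset_in_gap))
      as.integer(wt_offset_in_gap),
    hamming_threshold = as.integer(hamming_threshold),
    allele_freq_min = as.numeric(allele_freq_min),
    quant_window = as.integer(quant_window),
    wt_amplicon = norm_dna(wt_amplicon),
    cut_offset = if (!is.null(cut_offset)) as.integer(cut_offset),
    hdr_reference = if (!is.null(hdr_reference)) norm_dna(hdr_reference),
    anchor_max_mismatch = as.integer(anchor_max_mismatch)
  )
  class(spec) <- "hdr_class_spec"
  validate_hdr_class_spec(spec)
}

validate_hdr_class_spec <- function(spec) {
  if (spec$hamming_threshold > nchar(spec$wt_reference)) {
    stop("hamming_threshold (", spec$hamming_threshold,
         ") exceeds wt_reference length (", nchar(spec$wt_reference), ")")
  }
  gap_start <- find_exact(spec$wt_amplicon, spec$anchor_left)
  if (is.na(gap_start)) stop("wt_amplicon does not contain anchor_left")
  gap_start <- gap_start + nchar(spec$anchor_left)
  gap_end <- gap_start + spec$inter_anchor_distance - 1L
  right_at <- substr(spec$wt_amplicon, gap_end + 1L,
                     gap_end + nchar(spec$anchor_right))
  if (right_at != spec$anchor_right) {
    stop("anchor_right not found at distance ", spec$inter_anchor_distance,
         " bp after anchor_left in wt_amplicon")
  }
  gap <- substr(spec$wt_amplicon, gap_start, gap_end)
  if (is.null(spec$wt_offset_in_gap)) {
    off <- find_exact(gap, spec$wt_reference)
    if (is.na(off)) stop("wt_reference not found in the inter-anchor gap; ",
                         "supply wt_offset_in_gap explicitly")
    spec$wt_offset_in_gap <- off - 1L
  }
  if (spec$wt_offset_in_gap + nchar(spec$wt_reference) >
      spec$inter_anchor_distance) {
    stop("wt_reference at wt_offset_in_gap does not fit inside the gap")
  }
  gap_wt <- substr(gap, spec$wt_offset_in_gap + 1L,
                   spec$wt_offset_in_gap + nchar(spec$wt_reference))
  if (gap_wt != spec$wt_reference) {
    stop("wt_amplicon gap segment at wt_offset_in_gap ('", gap_wt,
         "') does not equal wt_reference")
  }
  if (is.null(spec$cut_offset)) {
    spec$cut_offset <- gap_start + spec$inter_anchor_distance %/% 2L
  }
  if (is.null(spec$hdr_reference)) {
    spec$hdr_reference <- default_hdr_barcode(spec$wt_reference, 12L)
  }
  if (nchar(spec$hdr_reference) != nchar(spec$wt_reference)) {
    stop("hdr_reference and wt_reference must have equal length")
  }
  if (hamming_distance(spec$hdr_reference, spec$wt_reference) <
      spec$hamming_threshold) {
    stop("hdr_reference is closer than hamming_threshold to wt_reference; ",
         "HDR reads would be unclassifiable")
  }
  if (spec$allele_freq_min < 0 || spec$allele_freq_min >= 1) {
    stop("allele_freq_min must be in [0, 1)")
  }
  spec
}

# substitute the first n_sub positions of x by the next base in A->C->G->T->A
default_hdr_barcode <- function(x, n_sub) {
  n_sub <- min(n_sub, nchar(x))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- seq_len(n_sub)
  chars[i] <- DNA_BASES[(match(chars[i], DNA_BASES) %% 4L) + 1L]
  paste(chars, collapse = "")
}

#' @export
print.hdr_class_spec <- function(x, ...) {
  cat("<hdr_class_spec>\n")
  cat("  anchors      : ", x$anchor_left, " .. ", x$anchor_right,
      " (gap ", x$inter_anchor_distance, " bp)\n", sep = "")
  cat("  wt reference : ", x$wt_reference, " at gap offset ",
      x$wt_offset_in_gap, "\n", sep = "")
  cat("  HDR if Hamming >= ", x$hamming_threshold,
      "; allele filter ", x$allele_freq_min * 100, "%\n", sep = "")
  invisible(x)
}

#' Packaged GAPDH-style HDR classifier spec
#'
#' The classifier configuration used for the GAPDH UTR editing assay: the
#' two published 20-nt anchors with a fixed 32-bp gap, the wild-type
#' 15-mer `CCTCACAGTTGCCAT` inside the gap, Hamming threshold 11, a 12-nt
#' substitution barcode marking HDR, a 0.2% allele-frequency filter and a
#' 30-bp indel quantification window. The flanking amplicon context is
#' synthetic (fixed arbitrary sequence): only the anchors, gap and
#' reference matter for classification.
#'
#' @return an [hdr_class_spec()].
#' @export
gapdh_class_spec <- function() {
  anchor_left <- "CCCCCACCACACTGAATCTC"
  anchor_right <- "AGAGGGGAGGGGCCTAGGGA"
  wt_reference <- "CCTCACAGTTGCCAT"
  # synthetic flanks and gap padding; fixed so the spec is deterministic
  left_flank <- "TGACCTGAGCGTTAGCCATTGACGATTACCAGGCTTGACA"
  right_flank <- "CATTGGACGTTAGGATCCAGTTCAGGATTACCGTTAGCAT"
  gap <- paste0("ATCGGTAC", wt_reference, "TAGCCATTG")
  stopifnot(nchar(gap) == 32)
  wt_amplicon <- paste0(left_flank, anchor_left, gap, anchor_right,
                        right_flank)
  hdr_class_spec(
    anchor_left = anchor_left, anchor_right = anchor_right,
    inter_anchor_distance = 32, wt_reference = wt_reference,
    hamming_threshold = 11, allele_freq_min = 0.002, quant_window = 30,
    wt_amplicon = wt_amplicon
  )
}

norm_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) stop("sequence contains non-ACGTN characters")
  x
}

find_exact <- function(subject, pattern) {
  hit <- regexpr(pattern, subject, fixed = TRUE)
  if (hit == -1L) NA_integer_ else as.integer(hit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
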