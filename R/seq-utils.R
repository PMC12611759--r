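#' Sequence utilities
#'
#' Small helpers used across the simulators and classifiers: reverse
#' complement, random DNA, Hamming distance and global edit
#' distance / identity.
#'
#' @name seq-utils
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' Draws uniform i.i.d. bases; uses the current RNG state, so wrap in a
#' seed for reproducibility.
#'
#' @param n number of sequences.
#' @param width integer vector of lengths (recycled).
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, width) {
  width <- rep_len(as.integer(width), n)
  vapply(width, function(w) {
    paste(sample(DNA_BASES, w, replace = TRUE), collapse = "")
  }, character(1))
}

#' Hamming distance between equal-length sequences
#'
#' Number of mismatched positions. Unequal lengths are an error: the
#' classifier only compares fixed-width windows, so a length mismatch
#' signals a caller bug rather than a biological outcome.
#'
#' @param a,b DNA strings of equal length.
#' @return integer mismatch count.
#' @export
#' @examples
#' hamming_distance("ACGT", "ACGA")
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance() requires equal-length sequences (got ",
         nchar(a), " and ", nchar(b), ")")
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Global edit distance and identity
#'
#' Levenshtein distance with unit costs, and the derived global identity
#' `1 - distance / max(nchar(a), nchar(b))`. Used for the on-target
#' amplicon-identity QC of the long-read pipeline.
#'
#' @param a,b DNA strings.
#' @return `edit_distance()`: integer; `global_identity()`: numeric in \[0, 1\].
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  edit_distance_cpp(a, b)
}

#' @rdname edit_distance
#' @export
global_identity <- function(a, b) {
  1 - edit_distance(a, b) / max(nchar(a), nchar(b))
}

# Anchored prefix match of `pattern` at the start of `read`, tolerating
# `max_edits` substitutions + indels. Returns list(found, end) where `end`
# is the last read position covered by the pattern (for trimming).
match_prefix <- function(read, pattern, max_edits) {
  window <- substr(read, 1, nchar(pattern) + max_edits)
  hit <- prefix_match_cpp(pattern, window)
  list(found = hit[1] <= max_edits, edits = hit[1], end = hit[2])
}

# Suffix-anchored counterpart: pattern must match at the end of the read.
# Returns list(found, start) with `start` = first read position covered.
match_suffix <- function(read, pattern, max_edits) {
  hit <- match_prefix(reverse_chars(read), reverse_chars(pattern), max_edits)
  list(found = hit$found, edits = hit$edits,
       start = nchar(read) - hit$end + 1L)
}

reverse_chars <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Per-base i.i.d. substitution + short-indel noise, the ONT-like error
# model of the simulators. Indel events occur per base; each is an
# insertion or deletion with equal probability and length 1 bp (70%) or
# 2 bp (30%). Operates on one sequence.
apply_read_noise <- function(seq, substitution_rate = 0, indel_rate = 0) {
  if (substitution_rate <= 0 && indel_rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (substitution_rate > 0) {
    idx <- which(runif(n) < substitution_rate)
    if (length(idx)) {
      shift <- sample.int(3L, length(idx), replace = TRUE)
      chars[idx] <- DNA_BASES[((match(chars[idx], DNA_BASES) - 1L + shift) %% 4L) + 1L]
    }
  }
  if (indel_rate > 0) {
    idx <- which(runif(n) < indel_rate)
    if (length(idx)) {
      is_del <- runif(length(idx)) < 0.5
      lens <- 1L + as.integer(runif(length(idx)) < 0.3)
      keep <- rep(TRUE, n)
      if (any(is_del)) {
        del_pos <- unlist(Map(function(p, l) p:min(p + l - 1L, n),
                              idx[is_del], lens[is_del]))
        keep[del_pos] <- FALSE
      }
      ins_count <- integer(n)
      if (any(!is_del)) {
        ins_tab <- tapply(lens[!is_del], idx[!is_del], sum)
        ins_count[as.integer(names(ins_tab))] <- as.integer(ins_tab)
      }
      expanded <- rep.int(seq_len(n), 1L + ins_count)
      out <- chars[expanded]
      # rep.int() puts inserted copies right after the original base
      dup <- duplicated(expanded)
      if (any(dup)) out[dup] <- sample(DNA_BASES, sum(dup), replace = TRUE)
      out <- out[!(!dup & !keep[expanded])]
      chars <- out
    }
  }
  paste(chars, collapse = "")
}
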