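#' Locate the anchor pair in a read
#'
#' Finds `anchor_left` and `anchor_right` separated by exactly
#' `inter_anchor_distance` bp and returns the intervening gap segment.
#' Matching is exact by default; a mismatch budget
#' (`spec$anchor_max_mismatch`) switches to Hamming scanning. When
#' several placements exist the leftmost pair is chosen.
#'
#' @param read a single read sequence.
#' @param spec an [hdr_class_spec()].
#' @return the gap segment (character) or `NA_character_` when no valid
#'   placement exists.
#' @export
find_anchor_pair <- function(read, spec) {
  la <- nchar(spec$anchor_left)
  gap_len <- spec$inter_anchor_distance
  starts <- if (spec$anchor_max_mismatch > 0) {
    hamming_scan_cpp(spec$anchor_left, read, spec$anchor_max_mismatch)
  } else {
    as.integer(gregexpr(spec$anchor_left, read, fixed = TRUE)[[1]])
  }
  starts <- starts[starts > 0]
  for (s in starts) {
    gap_start <- s + la
    right_start <- gap_start + gap_len
    right <- substr(read, right_start, right_start + nchar(spec$anchor_right) - 1L)
    ok <- if (spec$anchor_max_mismatch > 0) {
      nchar(right) == nchar(spec$anchor_right) &&
        hamming_distance(right, spec$anchor_right) <= spec$anchor_max_mismatch
    } else {
      right == spec$anchor_right
    }
    if (ok) return(substr(read, gap_start, right_start - 1L))
  }
  NA_character_
}

#' Classify a single read as HDR, WT or candidate indel
#'
#' When the anchor pair is found at its fixed spacing, the wild-type
#' reference window is extracted from the gap and compared by Hamming
#' distance: at or above the threshold the read is HDR (a barcode
#' allele), below it WT. Reads without a valid anchor placement — e.g.
#' because an indel changed the spacing — are candidate indels and are
#' forwarded to the window-based indel caller.
#'
#' @inheritParams find_anchor_pair
#' @return one of `"hdr"`, `"wt"`, `"candidate_indel"`.
#' @export
classify_read <- function(read, spec) {
  gap <- find_anchor_pair(read, spec)
  if (is.na(gap)) return("candidate_indel")
  ref_len <- nchar(spec$wt_reference)
  window <- substr(gap, spec$wt_offset_in_gap + 1L,
                   spec$wt_offset_in_gap + ref_len)
  if (hamming_distance(window, spec$wt_reference) >= spec$hamming_threshold) {
    "hdr"
  } else {
    "wt"
  }
}

#' Window-based indel calling for candidate reads
#'
#' Globally aligns each read to the wild-type amplicon (affine gaps:
#' match 2, mismatch -1, open -5, extend -1) and calls an indel when any
#' inserted or deleted base overlaps the quantification window of
#' `spec$quant_window` bp centered on the cut site. Reads whose
#' alignment has no indel in the window (e.g. pure substitutions) are
#' `"unclassified"`.
#'
#' Insertion positions are taken from the alignment's gap ranges; for the
#' single-indel alleles this caller is aimed at, the mapping to reference
#' coordinates is exact.
#'
#' @param reads tibble with `read_id`, `sequence` (candidate reads).
#' @param spec an [hdr_class_spec()].
#' @return character vector (per read) of `"indel"` / `"unclassified"`.
#' @export
call_indels <- function(reads, spec) {
  if (nrow(reads) == 0) return(character(0))
  half <- spec$quant_window %/% 2L
  ws <- spec$cut_offset - half + 1L
  we <- spec$cut_offset + half
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::DNAString(spec$wt_amplicon),
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 1,
    type = "global"
  )
  deletions <- Biostrings::indel(Biostrings::pattern(aln))
  insertions <- Biostrings::indel(Biostrings::subject(aln))
  vapply(seq_len(nrow(reads)), function(i) {
    del <- deletions[[i]]
    ins <- insertions[[i]]
    hit <- FALSE
    if (length(del)) {
      hit <- any(pmax(BiocGenerics::start(del), ws) <=
                   pmin(BiocGenerics::end(del), we))
    }
    if (!hit && length(ins)) {
      p <- BiocGenerics::start(ins) - 1L  # inserted between p and p+1
      hit <- any(pmax(p, ws) <= pmin(p + 1L, we))
    }
    if (hit) "indel" else "unclassified"
  }, character(1))
}

#' Classify a set of short reads
#'
#' Applies the anchor-pair classifier to every read, then resolves
#' candidate indels with the window-based caller.
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param spec an [hdr_class_spec()].
#' @return the input tibble with a `class` column
#'   (`"hdr"`, `"wt"`, `"indel"`, `"unclassified"`).
#' @export
classify_short_reads <- function(reads, spec) {
  cls <- vapply(reads$sequence, classify_read, character(1),
                spec = spec, USE.NAMES = FALSE)
  cand <- cls == "candidate_indel"
  if (any(cand)) {
    cls[cand] <- call_indels(reads[cand, , drop = FALSE], spec)
  }
  mutate(reads, class = cls)
}

#' Summarize edit outcomes into an allele-frequency table
#'
#' Groups identical read sequences into alleles, removes alleles below
#' the minimum allele frequency (default 0.2% of all reads), and
#' computes class fractions over the retained reads. Partial-HDR alleles
#' carry enough barcode substitutions to reach the Hamming threshold, so
#' they are classified — and hence reported — within the HDR fraction.
#'
#' @param classified output of [classify_short_reads()].
#' @param spec an [hdr_class_spec()].
#' @return an object of class `edit_outcomes`: class counts/fractions,
#'   the allele table, `n_total` and `n_excluded_low_freq`.
#' @export
summarize_outcomes <- function(classified, spec) {
  n_total <- nrow(classified)
  classes <- c("hdr", "wt", "indel", "unclassified")
  if (n_total == 0) {
    out <- list(
      table = tibble(class = classes, n = 0L, fraction = NA_real_),
      alleles = tibble(sequence = character(), count = integer(),
                       frequency = numeric(), class = character()),
      n_total = 0L, n_retained = 0L, n_excluded_low_freq = 0L, empty = TRUE
    )
    return(structure(out, class = "edit_outcomes"))
  }
  alleles <- classified |>
    count(.data$sequence, .data$class, name = "count") |>
    mutate(frequency = .data$count / n_total) |>
    arrange(dplyr::desc(.data$count))
  retained <- filter(alleles, .data$frequency >= spec$allele_freq_min)
  n_retained <- sum(retained$count)
  tab <- retained |>
    group_by(class = factor(.data$class, levels = classes)) |>
    summarise(n = sum(.data$count), .groups = "drop") |>
    tidyr::complete(class, fill = list(n = 0L)) |>
    mutate(class = as.character(class),
           n = as.integer(.data$n),
           fraction = .data$n / n_retained)
  structure(list(
    table = tab,
    alleles = alleles,
    n_total = n_total,
    n_retained = n_retained,
    n_excluded_low_freq = n_total - n_retained,
    empty = FALSE
  ), class = "edit_outcomes")
}

#' @export
print.edit_outcomes <- function(x, ...) {
  cat("<edit_outcomes> ", x$n_total, " reads (",
      x$n_excluded_low_freq, " in low-frequency alleles excluded)\n",
      sep = "")
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-12s %8d  %s\n", x$table$class[i], x$table$n[i],
                ifelse(is.na(x$table$fraction[i]), "-",
                       sprintf("%6.2f%%", 100 * x$table$fraction[i]))))
  }
  invisible(x)
}

#' @method tidy edit_outcomes
#' @export
tidy.edit_outcomes <- function(x, ...) x$table

#' @method glance edit_outcomes
#' @export
glance.edit_outcomes <- function(x, ...) {
  frac <- setNames(x$table$fraction, x$table$class)
  tibble(
    n_total = x$n_total,
    n_excluded_low_freq = x$n_excluded_low_freq,
    hdr_fraction = frac[["hdr"]],
    wt_fraction = frac[["wt"]],
    indel_fraction = frac[["indel"]],
    unclassified_fraction = frac[["unclassified"]]
  )
}

#' @method autoplot edit_outcomes
#' @export
autoplot.edit_outcomes <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of retained reads",
                  title = "Edit outcome fractions") +
    ggplot2::theme_minimal()
}

#' Run the short-read outcome pipeline
#'
#' @param input FASTQ(.gz) path or tibble with `read_id`, `sequence`.
#' @param spec an [hdr_class_spec()].
#' @param out_dir optional; writes `outcomes.csv` and `alleles.tsv`.
#' @return an `edit_outcomes` object.
#' @export
run_shortread_pipeline <- function(input, spec, out_dir = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else input
  outcomes <- summarize_outcomes(classify_short_reads(reads, spec), spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(outcomes$table, file.path(out_dir, "outcomes.csv"))
    readr::write_tsv(outcomes$alleles, file.path(out_dir, "alleles.tsv"))
  }
  outcomes
}
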