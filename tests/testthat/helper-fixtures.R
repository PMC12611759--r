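# Shared fixtures, built in code.

# small amplicon (fast): 600 bp total, 25-nt primers, 30-nt anchors
small_spec <- function(hdr = NULL, seed = 101) {
  random_amplicon_spec(unedited_length = 600, primer_length = 25,
                       hdr_insertion_size = hdr, seed = seed)
}

# read built from spec parts: primers + anchors + core, optionally with an
# internal deletion of `del` bp taken out of the middle of the core
spec_read <- function(spec, del = 0) {
  s <- spec$sequence
  if (del > 0) {
    mid <- nchar(s) %/% 2
    s <- paste0(substr(s, 1, mid - del %/% 2 - del %% 2),
                substr(s, mid + del %/% 2 + 1, nchar(s)))
  }
  s
}

# mutate `n` fixed positions of a sequence (deterministic substitutions)
mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- swap[chars[positions]]
  paste(chars, collapse = "")
}

read_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(read_id = paste0("r", seq_along(seqs)), sequence = seqs)
}

# brute-force anchor-pair classifier: scan every substring placement
oracle_classify <- function(read, spec) {
  la <- nchar(spec$anchor_left)
  ra <- nchar(spec$anchor_right)
  gap_len <- spec$inter_anchor_distance
  for (s in seq_len(max(0, nchar(read) - la + 1))) {
    if (substr(read, s, s + la - 1) != spec$anchor_left) next
    rs <- s + la + gap_len
    if (substr(read, rs, rs + ra - 1) != spec$anchor_right) next
    gap <- substr(read, s + la, rs - 1)
    win <- substr(gap, spec$wt_offset_in_gap + 1,
                  spec$wt_offset_in_gap + nchar(spec$wt_reference))
    d <- sum(utf8ToInt(win) != utf8ToInt(spec$wt_reference))
    return(if (d >= spec$hamming_threshold) "hdr" else "wt")
  }
  "candidate_indel"
}
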