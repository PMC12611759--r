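#' Read a FASTQ file into a tibble
#'
#' Thin wrapper around `Biostrings::readDNAStringSet(format = "fastq")`;
#' handles plain and gzip-compressed files and preserves read identifiers.
#' Ambiguous bases (N) are permitted and counted.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return tibble with columns `read_id`, `sequence`, `n_ambiguous`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bad_line <- diagnose_fastq(path)
  if (!is.na(bad_line)) {
    stop("malformed FASTQ '", path, "' near line ", bad_line, call. = FALSE)
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      diag <- diagnose_fastq(path)
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           if (!is.na(diag)) paste0(" (near line ", diag, ")"), call. = FALSE)
    }
  )
  seqs <- as.character(reads)
  ids <- names(reads) %||% paste0("read", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)
  tibble(
    read_id = ids,
    sequence = unname(seqs),
    n_ambiguous = stringr::str_count(unname(seqs), "N")
  )
}

# best-effort line diagnosis for a malformed FASTQ
diagnose_fastq <- function(path) {
  lines <- tryCatch(readr::read_lines(path), error = function(e) NULL)
  if (is.null(lines)) return(NA_integer_)
  n <- length(lines)
  if (n %% 4 != 0) return(n)
  headers <- seq(1, n, by = 4)
  bad <- headers[!startsWith(lines[headers], "@")]
  if (length(bad)) return(bad[1])
  plus <- seq(3, n, by = 4)
  bad <- plus[!startsWith(lines[plus], "+")]
  if (length(bad)) bad[1] else NA_integer_
}

#' Write reads to FASTQ
#'
#' Emits constant Q20 base qualities: the downstream workflows are
#' length- and sequence-based and never consult qualities.
#'
#' @param reads tibble with columns `read_id` and `sequence`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("5", nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a 10x-style sparse count matrix directory
#'
#' Expects `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv`
#' (columns `gene_id`, `chrom`, `start`, optional `is_mito`; tab-separated,
#' no header) and `barcodes.tsv` (one barcode per line).
#'
#' @param dir directory containing the three files.
#' @return list with `counts` (dgCMatrix, genes x cells, dimnames set),
#'   `genes` (tibble) and `barcodes` (character).
#' @export
read_sc_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  counts <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  genes <- readr::read_tsv(
    paths[2],
    col_names = c("gene_id", "chrom", "start", "is_mito"),
    col_types = "ccil", progress = FALSE
  )
  if (all(is.na(genes$is_mito))) genes$is_mito <- genes$chrom %in% c("chrM", "MT")
  barcodes <- readr::read_lines(paths[3])
  if (nrow(genes) != nrow(counts)) {
    stop("genes.tsv has ", nrow(genes), " rows but matrix has ",
         nrow(counts), " rows")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("barcodes.tsv has ", length(barcodes), " entries but matrix has ",
         ncol(counts), " columns")
  }
  if (ncol(counts) == 0) stop("no cells in matrix")
  dimnames(counts) <- list(genes$gene_id, barcodes)
  list(counts = counts, genes = genes, barcodes = barcodes)
}

#' Write a sparse count matrix in 10x-style triplet format
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param genes tibble with `gene_id`, `chrom`, `start` and optionally
#'   `is_mito`.
#' @param dir output directory (created if needed).
#' @param barcodes cell barcodes; default taken from `colnames(counts)`.
#' @return `dir`, invisibly.
#' @export
write_sc_matrix <- function(counts, genes, dir,
                            barcodes = colnames(counts)) {
  stopifnot(nrow(genes) == nrow(counts))
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(ncol(counts)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  gene_cols <- genes[, intersect(c("gene_id", "chrom", "start", "is_mito"),
                                 names(genes))]
  readr::write_tsv(gene_cols, file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_lines(barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write droplet count tables
#'
#' The CSV layout is one row per well and channel:
#' `sample, channel, n_total, n_positive, replicate`.
#'
#' @param path CSV file.
#' @return tibble of droplet counts.
#' @export
read_droplet_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample = readr::col_character(), channel = readr::col_character(),
    n_total = readr::col_integer(), n_positive = readr::col_integer(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  if (any(tbl$n_positive > tbl$n_total)) {
    stop("n_positive exceeds n_total in ", path)
  }
  tbl
}

#' @rdname read_droplet_csv
#' @param assay tibble of droplet counts.
#' @export
write_droplet_csv <- function(assay, path) {
  readr::write_csv(assay, path)
  invisible(path)
}

#' Load an amplicon or classifier spec from JSON or YAML
#'
#' Field names match the constructor arguments; sequences are
#' uppercase-normalized, derived fields (gap offset, default cut site)
#' are recomputed and all invariants re-validated on load.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return an [amplicon_spec()] or [hdr_class_spec()].
#' @export
read_amplicon_spec <- function(path) {
  do.call(amplicon_spec, read_spec_fields(path, names(formals(amplicon_spec))))
}

#' @rdname read_amplicon_spec
#' @export
read_class_spec <- function(path) {
  do.call(hdr_class_spec, read_spec_fields(path, names(formals(hdr_class_spec))))
}

read_spec_fields <- function(path, allowed) {
  if (!file.exists(path)) stop("no such file: ", path)
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown)) stop("unknown spec field(s): ",
                            paste(unknown, collapse = ", "))
  fields
}

#' @rdname read_amplicon_spec
#' @param spec an `amplicon_spec` or `hdr_class_spec`.
#' @export
write_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec)[!vapply(unclass(spec), is.null, TRUE)],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
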