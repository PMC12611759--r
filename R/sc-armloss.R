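#' QC filtering of cells
#'
#' Removes cells outside a total-count window or above a mitochondrial
#' read fraction — the standard proxy filters for empty droplets,
#' doublets and unhealthy cells.
#'
#' @param counts genes x cells count matrix (sparse or dense) with gene
#'   ids as rownames.
#' @param genes gene annotation tibble with `gene_id` and `is_mito`.
#' @param min_counts,max_counts per-cell total count window
#'   (defaults 500 and 50000).
#' @param max_mito_frac maximum mitochondrial fraction (default 0.2).
#' @return the matrix restricted to passing cells.
#' @export
qc_filter_cells <- function(counts, genes, min_counts = 500,
                            max_counts = 50000, max_mito_frac = 0.2) {
  stopifnot(nrow(counts) == nrow(genes))
  totals <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[genes$is_mito, , drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito / totals, 1)
  keep <- totals >= min_counts & totals <= max_counts &
    mito_frac <= max_mito_frac
  counts[, keep, drop = FALSE]
}

#' Residual relative expression of edited versus unedited cells
#'
#' For every gene shared by both matrices: library-size-normalize each
#' cell (counts scaled to `scale_factor` total), `log1p`-transform,
#' subtract the mean of the unedited cells from every edited cell, smooth
#' the per-cell residuals along each chromosome with a centered moving
#' average of `smooth_window_genes` genes (shrinking windows at
#' chromosome edges), and exponentiate back, so neutral expression sits
#' at 1.0 and a clean monoallelic loss approaches 0.5. Mitochondrial
#' genes are excluded: they carry no copy-number signal.
#'
#' @param edited,unedited genes x cells count matrices with shared gene
#'   ids as rownames.
#' @param genes annotation tibble (`gene_id`, `chrom`, `start`,
#'   `is_mito`); genes absent from it are dropped with a warning.
#' @param smooth_window_genes centered moving-average window (odd;
#'   default 51). Window 1 disables smoothing.
#' @param scale_factor library-size normalization target (default 1e4).
#' @return an object of class `residual_matrix`: position-ordered genes x
#'   edited-cells matrix of residual relative expression plus the gene
#'   annotation used.
#' @export
compute_residual <- function(edited, unedited, genes,
                             smooth_window_genes = 51,
                             scale_factor = 1e4) {
  if (ncol(unedited) < 1) stop("need at least one unedited cell")
  if (smooth_window_genes %% 2 != 1) {
    stop("smooth_window_genes must be odd")
  }
  shared <- intersect(rownames(edited), rownames(unedited))
  if (length(shared) == 0) stop("edited and unedited share no genes")
  unknown <- setdiff(shared, genes$gene_id)
  if (length(unknown)) {
    warning(length(unknown), " gene(s) absent from annotations; excluded")
    shared <- setdiff(shared, unknown)
  }
  ann <- genes |>
    filter(.data$gene_id %in% shared, !.data$is_mito) |>
    arrange(.data$chrom, .data$start)

  norm_log <- function(m) {
    m <- m[ann$gene_id, , drop = FALSE]
    totals <- Matrix::colSums(m)
    if (any(totals == 0)) stop("cell with zero counts; run QC first")
    log1p(sweep(as.matrix(m), 2, totals / scale_factor, "/"))
  }
  ve <- norm_log(edited)
  vu <- norm_log(unedited)
  resid <- ve - rowMeans(vu)

  # smooth within each chromosome block, all cells at once
  if (smooth_window_genes > 1) {
    half <- (smooth_window_genes - 1L) %/% 2L
    for (ch in unique(ann$chrom)) {
      idx <- which(ann$chrom == ch)
      resid[idx, ] <- smooth_ma_cols(resid[idx, , drop = FALSE], half)
    }
  }
  structure(list(
    values = exp(resid),
    genes = ann,
    smooth_window_genes = as.integer(smooth_window_genes)
  ), class = "residual_matrix")
}

# centered moving average down each column with shrinking edge windows
smooth_ma_cols <- function(m, half) {
  n <- nrow(m)
  if (n == 0 || half == 0) return(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat("<residual_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (smoothing window ", x$smooth_window_genes, " genes)\n",
      sep = "")
  invisible(x)
}

#' @method tidy residual_matrix
#' @export
tidy.residual_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_id",
                        values_to = "residual") |>
    left_join(x$genes, by = "gene_id")
}

#' @method autoplot residual_matrix
#' @export
autoplot.residual_matrix <- function(object, chrom = NULL, ...) {
  ann <- object$genes
  keep <- if (is.null(chrom)) rep(TRUE, nrow(ann)) else ann$chrom == chrom
  m <- object$values[keep, , drop = FALSE]
  df <- as_tibble(m, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_id",
                        values_to = "residual") |>
    mutate(gene_id = factor(.data$gene_id, levels = rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$cell_id,
                                   fill = .data$residual)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "blue", high = "red",
                                  mid = "white", limits = c(0.5, 1.5),
                                  oob = scales_squish) +
    ggplot2::labs(x = "genes (genomic order)", y = "edited cells",
                  fill = "residual") +
    ggplot2::theme_void()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Per-cell segment means of residual expression
#'
#' The telomeric segment runs from the chromosome start up to (but
#' excluding) the target site; the comparison segment covers the
#' following `comparison_extent_bp` (default 7 Mb), target site
#' included — the half-open convention `[start, site)` / `[site, site +
#' extent)`.
#'
#' @param residuals a [compute_residual()] result.
#' @param target_chrom chromosome of the edit.
#' @param target_site_bp 1-based target coordinate.
#' @param comparison_extent_bp comparison segment width (default 7 Mb).
#' @return tibble: `cell_id`, `telomeric_mean`, `comparison_mean`.
#' @export
segment_means <- function(residuals, target_chrom, target_site_bp,
                          comparison_extent_bp = 7e6) {
  stopifnot(inherits(residuals, "residual_matrix"))
  ann <- residuals$genes
  tel <- ann$chrom == target_chrom & ann$start < target_site_bp
  cmp <- ann$chrom == target_chrom & ann$start >= target_site_bp &
    ann$start < target_site_bp + comparison_extent_bp
  if (!any(tel)) stop("no genes in the telomeric segment; check annotations")
  if (!any(cmp)) stop("no genes in the comparison segment; check annotations")
  tibble(
    cell_id = colnames(residuals$values),
    telomeric_mean = unname(colMeans(residuals$values[tel, , drop = FALSE])),
    comparison_mean = unname(colMeans(residuals$values[cmp, , drop = FALSE]))
  )
}

#' Call segment expression loss per cell
#'
#' A cell is flagged as having lost the segment when its mean residual
#' expression is strictly below the threshold (default 0.95); a mean of
#' exactly 0.95 is not a loss.
#'
#' @param seg_table output of [segment_means()].
#' @param threshold loss threshold on the residual scale (default 0.95).
#' @param segment which segment mean to threshold: `"telomeric"`
#'   (default) or `"comparison"`.
#' @return an object of class `segment_calls`: the per-cell table with an
#'   `is_loss` flag, plus the cohort loss frequency.
#' @export
call_loss <- function(seg_table, threshold = 0.95,
                      segment = c("telomeric", "comparison")) {
  segment <- match.arg(segment)
  col <- paste0(segment, "_mean")
  tbl <- mutate(seg_table, is_loss = .data[[col]] < threshold)
  structure(list(
    cells = tbl,
    threshold = threshold,
    segment = segment,
    loss_frequency = mean(tbl$is_loss)
  ), class = "segment_calls")
}

#' @export
print.segment_calls <- function(x, ...) {
  cat("<segment_calls> ", nrow(x$cells), " cells; ", sum(x$cells$is_loss),
      " flagged (", sprintf("%.1f%%", 100 * x$loss_frequency),
      ") with ", x$segment, " mean < ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' @method tidy segment_calls
#' @export
tidy.segment_calls <- function(x, ...) x$cells

#' @method glance segment_calls
#' @export
glance.segment_calls <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n_loss = sum(x$cells$is_loss),
    loss_frequency = x$loss_frequency,
    threshold = x$threshold,
    segment = x$segment
  )
}

#' Hierarchical clustering of cells on telomeric residuals
#'
#' Clusters edited cells on their residual expression over the genes up
#' to the target site, using Ward linkage on Euclidean distances — a
#' deterministic procedure given the input order.
#'
#' @inheritParams segment_means
#' @param k number of clusters to cut (default 2).
#' @return tibble `cell_id`, `cluster`; the `hclust` tree and the
#'   clustering input matrix are attached as attributes `"hclust"` and
#'   `"matrix"`.
#' @export
cluster_cells <- function(residuals, target_chrom, target_site_bp, k = 2) {
  stopifnot(inherits(residuals, "residual_matrix"))
  ann <- residuals$genes
  tel <- ann$chrom == target_chrom & ann$start < target_site_bp
  if (!any(tel)) stop("no genes before the target site")
  m <- t(residuals$values[tel, , drop = FALSE])
  hc <- hclust(dist(m), method = "ward.D2")
  out <- tibble(cell_id = rownames(m),
                cluster = unname(cutree(hc, k = k)))
  attr(out, "hclust") <- hc
  attr(out, "matrix") <- m
  out
}

#' Run the arm-loss pipeline on edited/unedited matrices
#'
#' Convenience wrapper: QC-filter both populations, compute residual
#' relative expression, average over the telomeric and comparison
#' segments and call loss cells.
#'
#' @param edited,unedited count matrices or directories readable by
#'   [read_sc_matrix()].
#' @param genes annotation tibble; ignored (taken from the directory)
#'   when `edited` is a path.
#' @param target_chrom,target_site_bp,comparison_extent_bp segment
#'   definition (see [segment_means()]).
#' @param threshold loss threshold (default 0.95).
#' @param smooth_window_genes smoothing window (default 51).
#' @param qc named list overriding [qc_filter_cells()] defaults.
#' @return a `segment_calls` object; the `residual_matrix` is attached as
#'   attribute `"residuals"`.
#' @export
run_armloss_pipeline <- function(edited, unedited, genes = NULL,
                                 target_chrom = "chr12",
                                 target_site_bp = 6538000,
                                 comparison_extent_bp = 7e6,
                                 threshold = 0.95,
                                 smooth_window_genes = 51,
                                 qc = list()) {
  if (is.character(edited)) {
    ed <- read_sc_matrix(edited)
    edited <- ed$counts
    genes <- ed$genes
  }
  if (is.character(unedited)) unedited <- read_sc_matrix(unedited)$counts
  if (is.null(genes)) stop("gene annotations required")
  qc_args <- utils::modifyList(
    list(min_counts = 500, max_counts = 50000, max_mito_frac = 0.2), qc
  )
  edited <- do.call(qc_filter_cells, c(list(edited, genes), qc_args))
  unedited <- do.call(qc_filter_cells, c(list(unedited, genes), qc_args))
  res <- compute_residual(edited, unedited, genes, smooth_window_genes)
  calls <- call_loss(
    segment_means(res, target_chrom, target_site_bp, comparison_extent_bp),
    threshold = threshold
  )
  attr(calls, "residuals") <- res
  calls
}
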