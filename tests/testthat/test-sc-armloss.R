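genes_small <- default_gene_table(n_telomeric = 40, n_comparison = 40,
                                  n_distal = 20, n_other = 20, n_mito = 5)

test_that("cell QC removes empty, saturated and high-mito cells", {
  sim <- sim_sc_experiment(genes_small, n_edited = 20, n_unedited = 5,
                           seed = 31)
  m <- as.matrix(sim$edited)
  m[, 1] <- 0L                                     # empty cell
  m[, 2] <- m[, 2] * 50L                           # way over max_counts
  m[!sim$genes$is_mito, 3] <- 0L                   # mito fraction 1
  kept <- qc_filter_cells(m, sim$genes, min_counts = 100,
                          max_counts = 100000, max_mito_frac = 0.2)
  expect_false(any(colnames(kept) %in% colnames(m)[1:3]))
  expect_equal(ncol(kept), 17)
  # all cells within bounds: unchanged
  ok <- qc_filter_cells(sim$unedited, sim$genes, min_counts = 1,
                        max_counts = 1e9, max_mito_frac = 1)
  expect_equal(dim(ok), dim(sim$unedited))
})

test_that("residuals are neutral at 1.0 for a null comparison", {
  sim <- sim_sc_experiment(n_edited = 150, n_unedited = 150,
                           loss_fraction = 0, seed = 32)
  res <- compute_residual(sim$edited, sim$unedited, sim$genes)
  # per-gene mean residual across cells stays within 2% of baseline
  gene_means <- rowMeans(res$values)
  expect_true(all(gene_means > 0.98 & gene_means < 1.02))
  seg <- segment_means(res, "chr12", 6538000)
  expect_true(all(abs(seg$telomeric_mean - 1) < 0.1))
  # false-positive rate at the 0.95 threshold stays low
  calls <- call_loss(seg)
  expect_lte(calls$loss_frequency, 0.05)
})

test_that("mitochondrial genes are excluded from residuals", {
  sim <- sim_sc_experiment(genes_small, n_edited = 10, n_unedited = 10,
                           seed = 33)
  res <- compute_residual(sim$edited, sim$unedited, sim$genes)
  expect_false(any(res$genes$is_mito))
})

test_that("smoothing window 1 reproduces unsmoothed residuals", {
  sim <- sim_sc_experiment(genes_small, n_edited = 8, n_unedited = 30,
                           seed = 34)
  r1 <- compute_residual(sim$edited, sim$unedited, sim$genes,
                         smooth_window_genes = 1)
  ann <- r1$genes
  # recompute one cell by hand (no smoothing): normalize, log1p, subtract
  norm1 <- function(m) {
    m <- as.matrix(m)[ann$gene_id, , drop = FALSE]
    log1p(sweep(m, 2, Matrix::colSums(m[, , drop = FALSE]) / 1e4, "/"))
  }
  ve <- norm1(sim$edited[rownames(sim$edited) %in% ann$gene_id, ])
  vu <- norm1(sim$unedited[rownames(sim$unedited) %in% ann$gene_id, ])
  expect_equal(r1$values[, 3], exp(ve[, 3] - rowMeans(vu)),
               tolerance = 1e-12)
})

test_that("segment means follow the half-open boundary convention", {
  # constant residual matrix built directly
  ann <- genes_small[!genes_small$is_mito, ]
  vals <- matrix(1, nrow = nrow(ann), ncol = 3,
                 dimnames = list(ann$gene_id, paste0("c", 1:3)))
  res <- structure(list(values = vals, genes = ann,
                        smooth_window_genes = 1L),
                   class = "residual_matrix")
  seg <- segment_means(res, "chr12", 6538000)
  expect_true(all(seg$telomeric_mean == 1 & seg$comparison_mean == 1))
  # telomeric genes at 0.5
  tel <- ann$chrom == "chr12" & ann$start < 6538000
  vals2 <- vals
  vals2[tel, ] <- 0.5
  res2 <- structure(list(values = vals2, genes = ann,
                         smooth_window_genes = 1L),
                    class = "residual_matrix")
  seg2 <- segment_means(res2, "chr12", 6538000)
  expect_true(all(seg2$telomeric_mean == 0.5 & seg2$comparison_mean == 1))
  # a gene exactly at the target site belongs to the comparison segment
  ann3 <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr12",
                         start = c(6537999, 6538000), is_mito = FALSE)
  vals3 <- matrix(c(0.4, 0.8), nrow = 2, ncol = 1,
                  dimnames = list(ann3$gene_id, "c1"))
  res3 <- structure(list(values = vals3, genes = ann3,
                         smooth_window_genes = 1L),
                    class = "residual_matrix")
  seg3 <- segment_means(res3, "chr12", 6538000)
  expect_equal(seg3$telomeric_mean, 0.4)
  expect_equal(seg3$comparison_mean, 0.8)
  # empty segment errors
  expect_error(segment_means(res3, "chr5", 100), "telomeric")
})

test_that("loss calling is strict at the 0.95 threshold", {
  seg <- tibble::tibble(cell_id = c("a", "b", "c"),
                        telomeric_mean = c(0.949, 0.95, 0.951),
                        comparison_mean = 1)
  calls <- call_loss(seg)
  expect_equal(calls$cells$is_loss, c(TRUE, FALSE, FALSE))
  # frequency is flagged / total
  seg100 <- tibble::tibble(cell_id = paste0("c", 1:100),
                           telomeric_mean = c(rep(0.9, 20), rep(1, 80)),
                           comparison_mean = 1)
  expect_equal(call_loss(seg100)$loss_frequency, 0.2)
})

test_that("planted segment loss is recovered near its true frequency", {
  sim <- sim_sc_experiment(n_edited = 300, n_unedited = 300,
                           loss_fraction = 0.2, seed = 35)
  calls <- run_armloss_pipeline(sim$edited, sim$unedited, sim$genes)
  expect_lt(abs(calls$loss_frequency - 0.2), 0.03)
  merged <- dplyr::inner_join(tidy(calls), sim$truth, by = "cell_id")
  expect_gt(mean(merged$is_loss.x == merged$is_loss.y), 0.95)
})

test_that("deeper loss never reduces the detected frequency", {
  freqs <- vapply(c(0.9, 0.7, 0.5), function(effect) {
    sim <- sim_sc_experiment(genes_small, n_edited = 150, n_unedited = 150,
                             loss_fraction = 0.3, loss_effect = effect,
                             seed = 36)
    run_armloss_pipeline(sim$edited, sim$unedited, sim$genes)$loss_frequency
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("Ward clustering separates planted populations deterministically", {
  sim <- sim_sc_experiment(n_edited = 400, n_unedited = 200,
                           loss_fraction = 0.5, seed = 37)
  res <- compute_residual(sim$edited, sim$unedited, sim$genes)
  cl <- cluster_cells(res, "chr12", 6538000, k = 2)
  merged <- dplyr::inner_join(cl, sim$truth, by = "cell_id")
  agree <- max(
    mean((merged$cluster == 1) == merged$is_loss),
    mean((merged$cluster == 2) == merged$is_loss)
  )
  expect_gte(agree, 0.95)
  # deterministic: same input, same labels
  cl2 <- cluster_cells(res, "chr12", 6538000, k = 2)
  expect_identical(cl$cluster, cl2$cluster)
  # identical cells: zero-height dendrogram
  ann <- res$genes
  const <- structure(list(
    values = matrix(1, nrow(ann), 5,
                    dimnames = list(ann$gene_id, paste0("c", 1:5))),
    genes = ann, smooth_window_genes = 1L
  ), class = "residual_matrix")
  hc <- attr(cluster_cells(const, "chr12", 6538000, k = 1), "hclust")
  expect_equal(max(hc$height), 0)
})
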