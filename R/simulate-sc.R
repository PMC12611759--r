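#' Default gene annotation table for single-cell simulations
#'
#' A deterministic, evenly spaced gene map emulating the expressed genes
#' of a target chromosome around an editing site: a telomeric block
#' upstream of the target site, a comparison block covering the following
#' 7 Mb, a distal block further along the chromosome, genes on an
#' unrelated chromosome, and mitochondrial genes for QC.
#'
#' @param target_chrom chromosome carrying the edit (default `"chr12"`).
#' @param target_site_bp 1-based target coordinate (default 6,538,000).
#' @param comparison_extent_bp width of the comparison segment
#'   (default 7 Mb).
#' @param n_telomeric,n_comparison,n_distal,n_other,n_mito gene counts
#'   per block.
#' @return tibble with `gene_id`, `chrom`, `start`, `is_mito`, ordered by
#'   `(chrom, start)`.
#' @export
default_gene_table <- function(target_chrom = "chr12",
                               target_site_bp = 6538000,
                               comparison_extent_bp = 7000000,
                               n_telomeric = 150, n_comparison = 150,
                               n_distal = 100, n_other = 100, n_mito = 10) {
  blocks <- list(
    tibble(chrom = target_chrom,
           start = round(seq(100000, target_site_bp - 1000,
                             length.out = n_telomeric))),
    tibble(chrom = target_chrom,
           start = round(seq(target_site_bp,
                             target_site_bp + comparison_extent_bp - 1000,
                             length.out = n_comparison))),
    tibble(chrom = target_chrom,
           start = round(seq(target_site_bp + comparison_extent_bp + 100000,
                             target_site_bp + comparison_extent_bp + 60e6,
                             length.out = n_distal))),
    tibble(chrom = "chr7",
           start = round(seq(1e6, 120e6, length.out = n_other))),
    tibble(chrom = "chrM",
           start = round(seq(100, 16000, length.out = n_mito)))
  )
  genes <- bind_rows(blocks)
  genes$is_mito <- genes$chrom == "chrM"
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes[, c("gene_id", "chrom", "start", "is_mito")]
}

#' Simulate edited and unedited single-cell count matrices
#'
#' Draws per-gene negative-binomial counts for an unedited and an edited
#' cell population sharing the same expression program, then plants a
#' monoallelic segment loss in a fraction of edited cells: every gene in
#' `loss_segment` has its expected expression multiplied by `loss_effect`
#' (0.5 for a clean one-copy loss). Mitochondrial genes are boosted to a
#' realistic share of the library so QC filtering is exercised.
#'
#' Loss cells are assigned as an exact count, `round(n_edited *
#' loss_fraction)`, and recorded in the returned truth table.
#'
#' @param gene_table gene annotation (see [default_gene_table()]).
#' @param n_edited,n_unedited cell numbers.
#' @param loss_fraction fraction of edited cells carrying the loss.
#' @param loss_segment list with `chrom`, `start`, `end` (1-based,
#'   inclusive); default: chromosome 12 start to just before the default
#'   target site, i.e. the telomeric segment.
#' @param loss_effect expression multiplier for lost-segment genes in
#'   loss cells, in (0, 1]; default 0.5.
#' @param nb_mean_range per-gene expected counts are drawn uniformly from
#'   this range (default 5-30, a deeply sampled regime).
#' @param nb_dispersion negative-binomial `size` parameter (default 20;
#'   larger = closer to Poisson).
#' @param mito_mean_multiplier expression boost for mitochondrial genes
#'   (default 4).
#' @param seed RNG seed.
#' @return list with `edited` and `unedited` (sparse genes x cells
#'   matrices, dimnames set), `genes` (the annotation), and `truth`
#'   (tibble `cell_id`, `is_loss` for edited cells).
#' @export
sim_sc_experiment <- function(gene_table = default_gene_table(),
                              n_edited = 500, n_unedited = 500,
                              loss_fraction = 0.2,
                              loss_segment = list(chrom = "chr12", start = 1,
                                                  end = 6537999),
                              loss_effect = 0.5,
                              nb_mean_range = c(5, 30), nb_dispersion = 20,
                              mito_mean_multiplier = 4, seed = 1L) {
  stopifnot(loss_effect > 0, loss_effect <= 1)
  check_fraction(loss_fraction)
  set.seed(seed)
  n_genes <- nrow(gene_table)
  mu <- runif(n_genes, nb_mean_range[1], nb_mean_range[2])
  mu[gene_table$is_mito] <- mu[gene_table$is_mito] * mito_mean_multiplier

  in_segment <- gene_table$chrom == loss_segment$chrom &
    gene_table$start >= loss_segment$start &
    gene_table$start <= loss_segment$end

  n_loss <- round(n_edited * loss_fraction)
  is_loss <- sample(rep(c(TRUE, FALSE), c(n_loss, n_edited - n_loss)))

  unedited <- matrix(rnbinom(n_genes * n_unedited,
                             mu = rep(mu, n_unedited), size = nb_dispersion),
                     nrow = n_genes)
  mu_loss <- ifelse(in_segment, mu * loss_effect, mu)
  mu_edit <- matrix(mu, nrow = n_genes, ncol = n_edited)
  mu_edit[, is_loss] <- mu_loss
  edited <- matrix(rnbinom(n_genes * n_edited, mu = as.vector(mu_edit),
                           size = nb_dispersion),
                   nrow = n_genes)
  gene_ids <- gene_table$gene_id
  dimnames(unedited) <- list(gene_ids, sprintf("uned%04d", seq_len(n_unedited)))
  dimnames(edited) <- list(gene_ids, sprintf("edit%04d", seq_len(n_edited)))

  list(
    edited = methods::as(Matrix::Matrix(edited, sparse = TRUE), "CsparseMatrix"),
    unedited = methods::as(Matrix::Matrix(unedited, sparse = TRUE),
                           "CsparseMatrix"),
    genes = gene_table,
    truth = tibble(cell_id = colnames(edited), is_loss = is_loss)
  )
}

#' Simulate a droplet digital PCR assay
#'
#' Each droplet receives a Poisson number of template copies with the
#' channel's mean occupancy; a droplet is positive when it received at
#' least one copy.
#'
#' @param n_droplets accepted droplets per channel.
#' @param lambda_target,lambda_reference mean copies per droplet.
#' @param sample sample label.
#' @param replicate replicate id.
#' @param seed RNG seed.
#' @return tibble with one row per channel: `sample`, `channel`
#'   (`"target"`, `"reference"`), `n_total`, `n_positive`, `replicate`.
#' @export
sim_droplet_assay <- function(n_droplets = 20000, lambda_target,
                              lambda_reference, sample = "sim",
                              replicate = 1L, seed = 1L) {
  stopifnot(lambda_target >= 0, lambda_reference >= 0, n_droplets > 0)
  set.seed(seed)
  pos_t <- sum(rpois(n_droplets, lambda_target) >= 1L)
  pos_r <- sum(rpois(n_droplets, lambda_reference) >= 1L)
  tibble(
    sample = sample,
    channel = c("target", "reference"),
    n_total = as.integer(n_droplets),
    n_positive = as.integer(c(pos_t, pos_r)),
    replicate = as.integer(replicate)
  )
}
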