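#' Mean copies per droplet from Poisson partition statistics
#'
#' With template molecules Poisson-distributed over droplets, the mean
#' occupancy follows from the negative-droplet fraction:
#' `lambda = -ln(1 - n_positive / n_total)`. Zero positives give
#' `lambda = 0`; a fully positive (saturated) assay carries no
#' information about the mean and is an error.
#'
#' @param n_total,n_positive droplet counts (vectorized).
#' @return numeric vector of mean copies per droplet.
#' @export
#' @examples
#' droplet_lambda(1000, 500)  # ln 2
droplet_lambda <- function(n_total, n_positive) {
  stopifnot(n_total > 0, n_positive >= 0, length(n_total) == length(n_positive))
  if (any(n_positive > n_total)) stop("n_positive exceeds n_total")
  if (any(n_positive == n_total)) {
    stop("saturated assay: all droplets positive; dilute and repeat")
  }
  -log(1 - n_positive / n_total)
}

#' Normal-approximation confidence interval for lambda
#'
#' Delta-method interval on the log-lambda scale, back-transformed; the
#' usual droplet-digital-PCR approximation at moderate occupancy.
#'
#' @inheritParams droplet_lambda
#' @param conf_level confidence level (default 0.95).
#' @return tibble with `lambda`, `lower`, `upper`.
#' @export
droplet_lambda_ci <- function(n_total, n_positive, conf_level = 0.95) {
  lambda <- droplet_lambda(n_total, n_positive)
  p <- n_positive / n_total
  se_lambda <- sqrt(p / ((1 - p) * n_total))
  z <- qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(lambda))
  pos <- lambda > 0
  se_log <- se_lambda[pos] / lambda[pos]
  lower[pos] <- lambda[pos] * exp(-z * se_log)
  upper[pos] <- lambda[pos] * exp(z * se_log)
  tibble(lambda = lambda, lower = lower, upper = upper)
}

#' Target/reference copy ratio of a droplet assay
#'
#' Computes the per-replicate ratio of target to reference mean
#' occupancy, then summarizes over replicates (mean and s.d.), matching
#' per-well instrument practice. `mode = "pooled"` instead sums droplet
#' counts over replicates before computing a single ratio.
#'
#' @param assay droplet tibble with columns `channel`, `n_total`,
#'   `n_positive` and optionally `replicate` (see [sim_droplet_assay()],
#'   [read_droplet_csv()]).
#' @param target_channel,reference_channel channel labels.
#' @param mode `"per_replicate"` (default) or `"pooled"`.
#' @return tibble with one row per replicate (`replicate`,
#'   `lambda_target`, `lambda_reference`, `ratio`); the replicate mean
#'   and s.d. are attached as attributes `"ratio"` and `"ratio_sd"`.
#' @export
copy_ratio <- function(assay, target_channel = "target",
                       reference_channel = "reference",
                       mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  if (!"replicate" %in% names(assay)) assay$replicate <- 1L
  tgt <- filter(assay, .data$channel == target_channel)
  ref <- filter(assay, .data$channel == reference_channel)
  if (nrow(tgt) == 0) stop("no rows for target channel '", target_channel, "'")
  if (nrow(ref) == 0) {
    stop("no rows for reference channel '", reference_channel, "'")
  }
  if (mode == "pooled") {
    tgt <- summarise(tgt, replicate = 1L, n_total = sum(.data$n_total),
                     n_positive = sum(.data$n_positive))
    ref <- summarise(ref, replicate = 1L, n_total = sum(.data$n_total),
                     n_positive = sum(.data$n_positive))
  }
  merged <- dplyr::inner_join(
    select(tgt, "replicate", t_total = "n_total", t_pos = "n_positive"),
    select(ref, "replicate", r_total = "n_total", r_pos = "n_positive"),
    by = "replicate"
  )
  if (nrow(merged) == 0) stop("target and reference replicates do not match")
  out <- merged |>
    mutate(
      lambda_target = droplet_lambda(.data$t_total, .data$t_pos),
      lambda_reference = droplet_lambda(.data$r_total, .data$r_pos)
    )
  if (any(out$lambda_reference == 0)) stop("reference not amplified")
  out <- out |>
    mutate(ratio = .data$lambda_target / .data$lambda_reference) |>
    select("replicate", "lambda_target", "lambda_reference", "ratio")
  attr(out, "ratio") <- mean(out$ratio)
  attr(out, "ratio_sd") <- stats::sd(out$ratio)
  out
}

#' Condition-normalized copy number
#'
#' Divides a condition's target/reference copy ratio by the control
#' (unedited) condition's ratio; the fractional change is the normalized
#' value minus 1, so a mean copy loss of 14% reads as -0.14.
#'
#' @param ratio_condition,ratio_control numeric ratios or [copy_ratio()]
#'   results (replicate means are used).
#' @return an object of class `copy_number_result` with
#'   `normalized_cnv` and `fractional_change`.
#' @export
normalized_cnv <- function(ratio_condition, ratio_control) {
  rc <- as_ratio(ratio_condition)
  r0 <- as_ratio(ratio_control)
  if (r0 == 0) stop("control ratio is zero; cannot normalize")
  structure(list(
    ratio_condition = rc,
    ratio_control = r0,
    normalized_cnv = rc / r0,
    fractional_change = rc / r0 - 1
  ), class = "copy_number_result")
}

as_ratio <- function(x) {
  if (is.numeric(x) && length(x) == 1) return(as.numeric(x))
  r <- attr(x, "ratio")
  if (is.null(r)) stop("expected a numeric ratio or a copy_ratio() result")
  r
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat("<copy_number_result>\n")
  cat(sprintf("  ratio (condition / control): %.4f / %.4f\n",
              x$ratio_condition, x$ratio_control))
  cat(sprintf("  normalized CNV   : %.4f\n", x$normalized_cnv))
  cat(sprintf("  fractional change: %+.4f\n", x$fractional_change))
  invisible(x)
}

#' @method tidy copy_number_result
#' @export
tidy.copy_number_result <- function(x, ...) {
  tibble(
    ratio_condition = x$ratio_condition,
    ratio_control = x$ratio_control,
    normalized_cnv = x$normalized_cnv,
    fractional_change = x$fractional_change
  )
}

#' @method glance copy_number_result
#' @export
glance.copy_number_result <- function(x, ...) tidy(x)

#' Lentiviral vector copy number
#'
#' `VCN = reference_copies_per_genome * lambda_target / lambda_reference`,
#' with the reference a diploid housekeeping locus (RPP30-style), so
#' `reference_copies_per_genome = 2` by default.
#'
#' @param lambda_target,lambda_reference mean copies per droplet for the
#'   integrated-vector and reference channels (see [droplet_lambda()]).
#' @param reference_copies_per_genome copies of the reference locus per
#'   genome (default 2).
#' @return numeric VCN (vectorized).
#' @export
vcn <- function(lambda_target, lambda_reference,
                reference_copies_per_genome = 2) {
  stopifnot(lambda_target >= 0)
  if (any(lambda_reference == 0)) stop("reference not amplified")
  reference_copies_per_genome * lambda_target / lambda_reference
}
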