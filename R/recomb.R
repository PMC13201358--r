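# Recombination-rate stratified transferability: window-averaged rate
# interpolation from the cumulative map, balanced rate binning and per-bin
# accuracy from partitioned sub-scores.

#' Window-averaged recombination rate at positions
#'
#' Mean rate over a window centered on each position, computed exactly from
#' the piecewise-linear cumulative map:
#' `(map(pos + w/2) - map(pos - w/2)) / width_Mb` with the map linearly
#' interpolated. Windows extending past the map ends are truncated to the
#' map extent and normalized by the retained width, with a logged count
#' (attribute `n_truncated`).
#'
#' @param map a [recombination_map()].
#' @param pos vector of 1-based bp positions.
#' @param window_bp full window width in bp (default 20000, i.e. +/- 10 kb).
#' @return numeric vector of rates in cM/Mb.
#' @export
interpolate_rate <- function(map, pos, window_bp = 20000) {
  lo_map <- min(map$pos)
  hi_map <- max(map$pos)
  mfun <- stats::approxfun(map$pos, map$map, rule = 2)
  lo <- pmax(pos - window_bp / 2, lo_map)
  hi <- pmin(pos + window_bp / 2, hi_map)
  truncated <- (pos - window_bp / 2 < lo_map) | (pos + window_bp / 2 > hi_map)
  width_mb <- (hi - lo) / 1e6
  rate <- numeric(length(pos))
  zero <- width_mb <= 0
  if (any(zero)) {
    # position entirely outside the map: nearest endpoint's rate
    nearest <- ifelse(pos[zero] < lo_map, map$rate[1],
                      map$rate[nrow(map)])
    rate[zero] <- nearest
  }
  rate[!zero] <- (mfun(hi[!zero]) - mfun(lo[!zero])) / width_mb[!zero]
  attr(rate, "n_truncated") <- sum(truncated)
  rate
}

#' Annotate PRS weights with recombination rates and rate bins
#'
#' Adds the window-averaged rate and a balanced bin label (default
#' quartiles, sizes within +/- 1 variant) to a weight table. Rate ties are
#' broken by (chromosome, position) order.
#'
#' @param weights a [prs_weights()].
#' @param map a [recombination_map()].
#' @param n_bins number of rate bins (default 4).
#' @param window_bp interpolation window in bp.
#' @return the weights with added `rate` and `rate_bin` columns.
#' @export
annotate_rates <- function(weights, map, n_bins = 4, window_bp = 20000) {
  rate <- interpolate_rate(map, weights$pos, window_bp = window_bp)
  # round far beyond map precision so float jitter cannot break rate ties
  ord <- order(round(rate, 9), weights$chrom, weights$pos)
  weights$rate <- as.numeric(rate)
  weights$rate_bin <- balanced_bins(ord, n_bins)
  attr(weights, "n_truncated") <- attr(rate, "n_truncated")
  weights
}

#' Accuracy profile across recombination-rate bins
#'
#' Splits the PRS SNPs into `n_bins` equal-sized bins of window-averaged
#' recombination rate, scores each sub-set separately in the target panel
#' and evaluates the incremental R2 of each sub-score with
#' percentile-bootstrap CIs. The bin sub-scores sum to the full score.
#'
#' @param weights a [prs_weights()] (>= 2 SNPs per bin required).
#' @param map a [recombination_map()].
#' @param panel target [genotype_panel()] to score and evaluate in.
#' @param phenotype outcome vector for the panel samples.
#' @param covariates optional covariate matrix.
#' @param n_bins number of rate bins (default 4: quartiles).
#' @param binary binary outcome (liability scale)?
#' @param prevalence population prevalence for the liability conversion.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param window_bp interpolation window in bp.
#' @return data.frame with one row per bin: `bin, n_snps, mean_rate, r2,
#'   ci_low, ci_high`.
#' @export
quartile_profile <- function(weights, map, panel, phenotype, covariates = NULL,
                             n_bins = 4, binary = FALSE, prevalence = NULL,
                             n_boot = 1000, seed = 1, window_bp = 20000) {
  if (nrow(weights) < 2 * n_bins) {
    stop2("need at least ", 2 * n_bins, " PRS SNPs for ", n_bins, " rate bins")
  }
  ann <- annotate_rates(weights, map, n_bins = n_bins, window_bp = window_bp)
  rows <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    sub <- ann[ann$rate_bin == b, , drop = FALSE]
    if (nrow(sub) == 0) stop2("empty rate bin ", b)
    sub_w <- prs_weights(sub[, c("chrom", "pos", "id", "effect_allele", "weight")],
                         params = attr(weights, "params"))
    s <- score(panel, sub_w)
    res <- suppressWarnings(accuracy_eval(
      phenotype, s, covariates = covariates, binary = binary,
      prevalence = prevalence, n_boot = n_boot, seed = stage_seed(seed, b)))
    rows[[b]] <- data.frame(bin = b, n_snps = nrow(sub),
                            mean_rate = mean(sub$rate),
                            r2 = res$r2_incremental,
                            ci_low = res$ci_low, ci_high = res$ci_high)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
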