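# Relative-accuracy decomposition: candidate-causal selection, the full
# LD+MAF+h2 prediction and its constrained variants, loss-of-accuracy
# statistics and SNP-bootstrap standard errors.
#
# Notation: population 1 is the discovery GWAS population, population 2 the
# target. For PRS SNP k with per-allele weight b_k, frequencies p_k1/p_k2
# and candidate causal neighbors j, write v_kp = p_kp (1 - p_kp),
# rbar2_k = mean_j r1_kj^2 and rxr_k = mean_j r1_kj * r2_kj. The full
# prediction is
#   RA = (rho_b^2 h2_2 / h2_1)
#        * ( sum_k rxr_k sqrt(v_k2 / v_k1) / sum_k rbar2_k )^2
#        * ( sum_k v_k1 b_k^2 / sum_k v_k2 b_k^2 ).

#' Candidate causal SNP selection
#'
#' For every PRS SNP, takes each variant within `window_kb` (same
#' chromosome) whose squared dosage correlation with it in the discovery
#' panel exceeds `r2_min` as a candidate causal SNP; a SNP is always its own
#' candidate (r = 1). Signed correlations are computed in both panels
#' against the identical (harmonized) allele coding, giving the per-SNP
#' candidate means `mean_r2_pop1` and `mean_cross_r`.
#'
#' @param weights a [prs_weights()].
#' @param panel_pop1 discovery-population LD panel (defines the candidate
#'   screen).
#' @param panel_pop2 target-population LD panel, same variant list and
#'   allele orientation.
#' @param window_kb physical window (default 100 kb).
#' @param r2_min candidate LD threshold (default 0.45), exceeded strictly.
#' @return data.frame with one row per retained PRS SNP: `id, chrom, pos,
#'   n_candidates, mean_r2_pop1, mean_cross_r`; dropped-SNP and
#'   dropped-candidate counts as attributes `n_dropped_snps`,
#'   `n_dropped_candidates`; candidate id lists as attribute `candidates`.
#' @export
find_candidate_causals <- function(weights, panel_pop1, panel_pop2,
                                   window_kb = 100, r2_min = 0.45) {
  key1 <- variant_key(panel_pop1$variants$chrom, panel_pop1$variants$pos)
  key2 <- variant_key(panel_pop2$variants$chrom, panel_pop2$variants$pos)
  wkey <- variant_key(weights$chrom, weights$pos)
  i1 <- match(wkey, key1)
  i2 <- match(wkey, key2)
  ok <- !is.na(i1) & !is.na(i2)
  n_dropped <- sum(!ok)
  w <- weights[ok, , drop = FALSE]
  i1 <- i1[ok]
  win <- window_kb * 1000
  X1 <- panel_pop1$dosage
  X2 <- panel_pop2$dosage
  v1 <- panel_pop1$variants
  rows <- vector("list", nrow(w))
  cand_ids <- vector("list", nrow(w))
  dropped_cand <- 0L
  for (k in seq_len(nrow(w))) {
    focal <- i1[k]
    nb <- which(v1$chrom == v1$chrom[focal] & abs(v1$pos - v1$pos[focal]) <= win)
    r1 <- suppressWarnings(
      as.vector(stats::cor(X1[, focal], X1[, nb, drop = FALSE])))
    r1[is.na(r1)] <- 0
    sel <- nb[r1^2 > r2_min | nb == focal]
    r1 <- r1[match(sel, nb)]
    # candidates must exist (same key) in the target panel for signed r there
    j2 <- match(key1[sel], key2)
    have <- !is.na(j2)
    dropped_cand <- dropped_cand + sum(!have)
    sel <- sel[have]
    r1 <- r1[have]
    j2 <- j2[have]
    r2v <- suppressWarnings(
      as.vector(stats::cor(X2[, match(wkey[ok][k], key2)], X2[, j2, drop = FALSE])))
    r2v[is.na(r2v)] <- 0
    rows[[k]] <- data.frame(id = w$id[k], chrom = w$chrom[k], pos = w$pos[k],
                            n_candidates = length(sel),
                            mean_r2_pop1 = mean(r1^2),
                            mean_cross_r = mean(r1 * r2v))
    cand_ids[[k]] <- v1$id[sel]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "candidates") <- stats::setNames(cand_ids, out$id)
  attr(out, "n_dropped_snps") <- n_dropped
  attr(out, "n_dropped_candidates") <- dropped_cand
  out
}

#' Inputs for the relative-accuracy decomposition
#'
#' Bundles per-SNP weights, frequencies in both populations, heritabilities,
#' the cross-population effect correlation and (optionally) candidate-causal
#' LD summaries. PRS SNPs monomorphic in either population are excluded with
#' a logged count (the frequency-ratio terms are undefined at
#' `p(1 - p) = 0`). Without candidate summaries every SNP is treated as its
#' own sole candidate (the all-SNPs-causal assumption).
#'
#' @param beta per-SNP effect sizes (per-allele, harmonized orientation).
#' @param freq_pop1,freq_pop2 per-SNP effect-allele frequencies.
#' @param h2_pop1,h2_pop2 SNP heritabilities.
#' @param rho_b cross-population causal-effect correlation (default 1).
#' @param candidates optional output of [find_candidate_causals()] aligned
#'   to `beta` (matched by position in the vector or by `id` names).
#' @param ids optional SNP ids for matching against `candidates`.
#' @return object of class `ra_inputs`.
#' @export
ra_inputs <- function(beta, freq_pop1, freq_pop2, h2_pop1, h2_pop2,
                      rho_b = 1, candidates = NULL, ids = NULL) {
  m <- length(beta)
  if (m < 1) stop2("need at least one PRS SNP")
  if (length(freq_pop1) != m || length(freq_pop2) != m) {
    stop2("frequencies must align with beta")
  }
  if (h2_pop1 < 0 || h2_pop1 > 1 || h2_pop2 < 0 || h2_pop2 > 1) {
    stop2("heritabilities must lie in [0, 1]")
  }
  if (abs(rho_b) > 1) stop2("rho_b must lie in [-1, 1]")
  mono <- freq_pop1 <= 0 | freq_pop1 >= 1 | freq_pop2 <= 0 | freq_pop2 >= 1 |
    !is.finite(freq_pop1) | !is.finite(freq_pop2)
  if (all(mono)) stop2("all PRS SNPs monomorphic in one of the populations")
  if (!is.null(candidates)) {
    if (!is.null(ids)) {
      ridx <- match(ids, candidates$id)
      if (anyNA(ridx)) stop2("candidates missing for some SNP ids")
      mean_r2 <- candidates$mean_r2_pop1[ridx]
      mean_cross <- candidates$mean_cross_r[ridx]
    } else {
      if (nrow(candidates) != m) stop2("candidates must align with beta")
      mean_r2 <- candidates$mean_r2_pop1
      mean_cross <- candidates$mean_cross_r
    }
  } else {
    mean_r2 <- rep(1, m)
    mean_cross <- rep(1, m)
  }
  keep <- !mono
  structure(list(beta = beta[keep],
                 freq_pop1 = freq_pop1[keep], freq_pop2 = freq_pop2[keep],
                 h2_pop1 = h2_pop1, h2_pop2 = h2_pop2, rho_b = rho_b,
                 mean_r2_pop1 = mean_r2[keep], mean_cross_r = mean_cross[keep],
                 n_dropped_monomorphic = sum(mono)),
            class = "ra_inputs")
}

ra_factors <- function(inputs) {
  v1 <- inputs$freq_pop1 * (1 - inputs$freq_pop1)
  v2 <- inputs$freq_pop2 * (1 - inputs$freq_pop2)
  ratio <- sqrt(v2 / v1)
  den_tag <- sum(inputs$mean_r2_pop1)
  den_beta <- sum(v2 * inputs$beta^2)
  if (den_tag == 0) stop2("zero tagging denominator (no candidate LD)")
  if (den_beta == 0) stop2("zero effect-variance denominator")
  list(v1 = v1, v2 = v2, ratio = ratio, M = length(inputs$beta),
       tag_plain = sum(inputs$mean_cross_r) / den_tag,
       tag_maf = sum(inputs$mean_cross_r * ratio) / den_tag,
       beta_fac = sum(v1 * inputs$beta^2) / den_beta)
}

#' Predicted relative accuracy: full LD + MAF + h2 model
#'
#' Three-factor product: the heritability/effect-correlation ratio
#' `rho_b^2 h2_2 / h2_1`, the squared LD/MAF tagging ratio, and the
#' beta-weighted allele-frequency variance ratio.
#'
#' @param inputs an [ra_inputs()].
#' @return scalar predicted RA.
#' @export
ra_full <- function(inputs) {
  if (inputs$h2_pop1 <= 0) stop2("h2_pop1 must be > 0")
  inputs$rho_b^2 * inputs$h2_pop2 / inputs$h2_pop1 * ra_ld_maf(inputs)
}

#' Predicted relative accuracy: MAF-only model
#'
#' Assumes every PRS SNP is itself causal: the tagging ratio reduces to the
#' mean square root of the per-SNP frequency-variance ratio (divided by M),
#' squared, times the beta-weighted variance-ratio factor.
#'
#' @inheritParams ra_full
#' @return scalar predicted RA.
#' @export
ra_maf <- function(inputs) {
  f <- ra_factors(inputs)
  (sum(f$ratio) / f$M)^2 * f$beta_fac
}

#' Predicted relative accuracy: LD-only model
#'
#' Isolates the candidate-causal tagging ratio, holding the MAF and
#' heritability terms at 1.
#'
#' @inheritParams ra_full
#' @return scalar predicted RA.
#' @export
ra_ld <- function(inputs) {
  f <- ra_factors(inputs)
  f$tag_plain^2
}

#' Predicted relative accuracy: LD + MAF model
#'
#' The full model under equal heritabilities and perfect effect correlation.
#'
#' @inheritParams ra_full
#' @return scalar predicted RA.
#' @export
ra_ld_maf <- function(inputs) {
  f <- ra_factors(inputs)
  f$tag_maf^2 * f$beta_fac
}

#' Loss of accuracy explained
#'
#' `LOA = (1 - RA_predicted) / (1 - RA_observed) * 100`, the percentage of
#' the observed transferability loss a prediction accounts for. Undefined
#' when no loss is observed (`ra_obs >= 1`).
#'
#' @param ra_predicted predicted relative accuracy.
#' @param ra_obs observed relative accuracy (< 1).
#' @return percentage.
#' @export
loa <- function(ra_predicted, ra_obs) {
  if (any(ra_obs >= 1)) stop2("LOA undefined: observed RA >= 1 (no loss)")
  (1 - ra_predicted) / (1 - ra_obs) * 100
}

#' SNP-bootstrap standard errors for the RA terms
#'
#' Resamples the M PRS SNPs with replacement and recomputes each predicted
#' RA (and LOA when an observed RA is supplied); the SE is the standard
#' deviation across replicates, with normal-approximation 95% CIs
#' (estimate +/- 1.96 SE).
#'
#' @param inputs an [ra_inputs()].
#' @param ra_obs optional observed RA for LOA terms.
#' @param n_rep bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `term, estimate, se, ci_low, ci_high`.
#' @export
ra_se <- function(inputs, ra_obs = NULL, n_rep = 1000, seed = 1) {
  m <- length(inputs$beta)
  if (m < 10) warning("fewer than 10 PRS SNPs: bootstrap SE is unstable",
                      call. = FALSE)
  set.seed(seed)
  terms <- c(ra_maf = ra_maf, ra_ld = ra_ld, ra_ld_maf = ra_ld_maf,
             ra_full = ra_full)
  est <- vapply(terms, function(f) f(inputs), numeric(1))
  reps <- matrix(NA_real_, n_rep, length(terms))
  for (r in seq_len(n_rep)) {
    idx <- sample.int(m, m, replace = TRUE)
    bi <- inputs
    for (fld in c("beta", "freq_pop1", "freq_pop2", "mean_r2_pop1",
                  "mean_cross_r")) {
      bi[[fld]] <- inputs[[fld]][idx]
    }
    reps[r, ] <- vapply(terms, function(f) f(bi), numeric(1))
  }
  se <- apply(reps, 2, stats::sd)
  out <- data.frame(term = names(terms), estimate = unname(est),
                    se = unname(se))
  if (!is.null(ra_obs)) {
    loa_est <- loa(out$estimate, ra_obs)
    loa_se <- apply(reps, 2, function(x) stats::sd(loa(x, ra_obs)))
    out <- rbind(out,
                 data.frame(term = paste0("loa_", sub("^ra_", "", names(terms))),
                            estimate = loa_est, se = unname(loa_se)))
  }
  out$ci_low <- out$estimate - 1.96 * out$se
  out$ci_high <- out$estimate + 1.96 * out$se
  rownames(out) <- NULL
  out
}

#' Assemble a relative-accuracy report
#'
#' Combines the observed RA with all four predictions, their LOA statistics
#' and SNP-bootstrap SEs/CIs.
#'
#' @inheritParams ra_se
#' @param ra_obs observed relative accuracy.
#' @return object of class `ra_report`: list with `ra_obs`, point estimates
#'   (`ra_maf`, `ra_ld`, `ra_ld_maf`, `ra_full`), matching `loa_*` values
#'   and the `se_table` from [ra_se()].
#' @export
ra_report <- function(inputs, ra_obs, n_rep = 1000, seed = 1) {
  est <- list(ra_maf = ra_maf(inputs), ra_ld = ra_ld(inputs),
              ra_ld_maf = ra_ld_maf(inputs), ra_full = ra_full(inputs))
  loas <- lapply(est, loa, ra_obs = ra_obs)
  names(loas) <- paste0("loa_", sub("^ra_", "", names(est)))
  se_table <- ra_se(inputs, ra_obs = ra_obs, n_rep = n_rep, seed = seed)
  structure(c(list(ra_obs = ra_obs), est, loas, list(se_table = se_table)),
            class = "ra_report")
}

#' @export
print.ra_report <- function(x, ...) {
  cat("Relative accuracy decomposition\n")
  cat(sprintf("  RA_OBS      %.4f\n", x$ra_obs))
  cat(sprintf("  RA_MAF      %.4f  (LOA %.1f%%)\n", x$ra_maf, x$loa_maf))
  cat(sprintf("  RA_LD       %.4f  (LOA %.1f%%)\n", x$ra_ld, x$loa_ld))
  cat(sprintf("  RA_LD+MAF   %.4f  (LOA %.1f%%)\n", x$ra_ld_maf, x$loa_ld_maf))
  cat(sprintf("  RA_full     %.4f  (LOA %.1f%%)\n", x$ra_full, x$loa_full))
  invisible(x)
}
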