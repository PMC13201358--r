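# Clumping + thresholding PRS construction and scoring.

#' Clumping parameters
#'
#' @param p_threshold index-SNP p-value cutoff in (0, 1].
#' @param r2_threshold LD r-squared cutoff in [0, 1].
#' @param window_kb physical window in kb (> 0); the window is the closed
#'   interval `|pos_index - pos_other| <= window_kb * 1000` on the same
#'   chromosome.
#' @return list of class `clump_params`.
#' @export
clump_params <- function(p_threshold, r2_threshold, window_kb) {
  if (p_threshold <= 0 || p_threshold > 1) stop2("p_threshold must be in (0, 1]")
  if (r2_threshold < 0 || r2_threshold > 1) stop2("r2_threshold must be in [0, 1]")
  if (window_kb <= 0) stop2("window_kb must be > 0")
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb), class = "clump_params")
}

#' PRS weights container
#'
#' @param df data.frame with columns `chrom, pos, id, effect_allele, weight`.
#' @param params the [clump_params()] (or list) that produced the weights.
#' @param source_population label of the discovery population.
#' @return data.frame of class `prs_weights`.
#' @export
prs_weights <- function(df, params = NULL, source_population = NULL) {
  need <- c("chrom", "pos", "id", "effect_allele", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("weights missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(variant_key(df$chrom, df$pos))) stop2("weight variants must be unique")
  if (any(!is.finite(df$weight))) stop2("weights must be finite")
  structure(as.data.frame(df), class = c("prs_weights", "data.frame"),
            params = params, source_population = source_population)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p remaining variant with
#' `p <= p_threshold` as an index SNP and removes all remaining variants
#' within `window_kb` of it (same chromosome) whose dosage r-squared with it
#' in `ld_panel` exceeds `r2_threshold`. Ties in p are broken toward smaller
#' (chromosome, position). The returned index SNPs are mutually compatible
#' under this rule. LD is the squared Pearson correlation of dosages
#' (composite LD on unphased genotypes).
#'
#' @param sumstats `summary_stats` harmonized to `ld_panel`.
#' @param ld_panel [genotype_panel()] used as the LD reference, drawn from a
#'   population matched to the discovery GWAS.
#' @param params a [clump_params()].
#' @return a [prs_weights()] object carrying the GWAS effect sizes of the
#'   retained index SNPs (empty, with a warning, when nothing passes the
#'   p-value threshold).
#' @export
clump <- function(sumstats, ld_panel, params) {
  stopifnot(inherits(params, "clump_params") || is.list(params))
  pkey <- variant_key(ld_panel$variants$chrom, ld_panel$variants$pos)
  cand <- sumstats[sumstats$p <= params$p_threshold, , drop = FALSE]
  cand$panel_col <- match(variant_key(cand$chrom, cand$pos), pkey)
  cand <- cand[!is.na(cand$panel_col), , drop = FALSE]
  empty <- function() {
    warning("no variant passes the p-value threshold; returning empty weights",
            call. = FALSE)
    prs_weights(data.frame(chrom = character(), pos = integer(),
                           id = character(), effect_allele = character(),
                           weight = numeric()),
                params = params)
  }
  if (nrow(cand) == 0) return(empty())
  ord <- order(cand$p, cand$chrom, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(cand))
  index <- logical(nrow(cand))
  win <- params$window_kb * 1000
  X <- ld_panel$dosage
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    alive[i] <- FALSE
    index[i] <- TRUE
    nb <- which(alive & cand$chrom == cand$chrom[i] &
                  abs(cand$pos - cand$pos[i]) <= win)
    if (!length(nb)) next
    r <- suppressWarnings(
      as.vector(stats::cor(X[, cand$panel_col[i]],
                           X[, cand$panel_col[nb], drop = FALSE]))
    )
    r2 <- r^2
    r2[is.na(r2)] <- 0  # zero-variance partner: no evidence of LD
    alive[nb[r2 > params$r2_threshold]] <- FALSE
  }
  sel <- cand[index, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
  prs_weights(data.frame(chrom = sel$chrom, pos = sel$pos, id = sel$id,
                         effect_allele = sel$a1, weight = sel$beta),
              params = params,
              source_population = attr(sumstats, "population"))
}

#' Clump over a tuning grid
#'
#' Enumerates the full cross of p-value, r-squared and window thresholds
#' (defaults are the 3 x 2 x 2 grid giving 12 scores per discovery
#' population and phenotype).
#'
#' @inheritParams clump
#' @param p_thresholds,r2_thresholds,windows_kb grid axes.
#' @return named list of [prs_weights()], one per parameter combination.
#' @export
clump_grid <- function(sumstats, ld_panel,
                       p_thresholds = c(5e-5, 0.01, 0.5),
                       r2_thresholds = c(0.1, 0.5),
                       windows_kb = c(100, 250)) {
  grid <- expand.grid(p = p_thresholds, r2 = r2_thresholds, w = windows_kb,
                      KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    clump(sumstats, ld_panel,
          clump_params(grid$p[i], grid$r2[i], grid$w[i]))
  })
  names(out) <- sprintf("p%g_r2%g_w%g", grid$p, grid$r2, grid$w)
  out
}

#' Compute polygenic scores
#'
#' `PRS_i = sum_j w_j * G_ij` over the weight variants, where `G_ij` is the
#' effect-allele dosage. Weight variants are matched to the panel by
#' chromosome and position; swapped-allele matches are scored on the
#' complementary dosage `2 - G`. Missing dosages are mean-imputed at `2p`
#' from the scoring panel's frequency. Weight variants absent from the panel
#' are dropped with a logged count (attribute `n_dropped`); if all are
#' absent an error is raised.
#'
#' @param panel a [genotype_panel()].
#' @param weights a [prs_weights()].
#' @return named numeric vector of per-sample scores.
#' @export
score <- function(panel, weights) {
  if (nrow(weights) == 0) {
    return(stats::setNames(rep(0, nrow(panel$dosage)), panel$samples$sample_id))
  }
  pkey <- variant_key(panel$variants$chrom, panel$variants$pos)
  idx <- match(variant_key(weights$chrom, weights$pos), pkey)
  present <- !is.na(idx)
  if (!any(present)) stop2("no weight variant present in the scoring panel")
  w <- weights[present, , drop = FALSE]
  cols <- idx[present]
  pv <- panel$variants[cols, , drop = FALSE]
  swapped <- w$effect_allele == pv$a2
  X <- panel$dosage[, cols, drop = FALSE]
  if (anyNA(X)) {
    af <- colMeans(X, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(X)) > 0)) {
      X[is.na(X[, j]), j] <- 2 * af[j]
    }
  }
  if (any(swapped)) X[, swapped] <- 2 - X[, swapped]
  s <- as.vector(X %*% w$weight)
  if (any(!present)) attr(s, "n_dropped") <- sum(!present)
  stats::setNames(s, panel$samples$sample_id)
}
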