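# Joint ancestry coordinate system: shrinkage-adjusted PC projection of
# study samples onto a reference panel, classical MDS of population allele
# frequencies, Procrustes alignment of the MDS configuration onto the PC
# centroids, and the per-individual genetic distance to a discovery GWAS
# sample with binned accuracy profiles.

ref_standardizer <- function(reference) {
  X <- reference$dosage
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  list(mu = mu[keep], sd = sdv[keep], keep = keep, n_dropped = sum(!keep))
}

#' Project study samples onto reference principal components
#'
#' Reference PCs come from the SVD of the centered/standardized reference
#' genotype matrix. Study individuals are projected either naively
#' (`Y V_k`, which shrinks coordinates toward zero when variants greatly
#' outnumber reference samples) or with an online augment-decompose-align
#' adjustment (`"oadp"`, the default): each study sample is appended to the
#' reference, the augmented spectral decomposition is obtained from a small
#' `(K+1) x (K+1)` eigenproblem, and a Procrustes transform mapping the
#' reference's augmented coordinates back onto its original PC scores is
#' applied to the study sample's augmented coordinates.
#'
#' @param study,reference [genotype_panel()] objects on a shared, harmonized
#'   variant set (matched by chromosome/position; zero-variance reference
#'   variants are dropped from both with a logged count).
#' @param k number of dimensions to return (default 5).
#' @param method `"oadp"` or `"naive"`.
#' @param extra_dims additional reference dimensions carried internally by
#'   the OADP adjustment (K = k + extra_dims, capped at the reference rank).
#' @return object of class `pc_projection`: list with `study_scores`
#'   (n_study x k), `ref_scores` (n_ref x k), singular values `d`, `k` and
#'   `method`.
#' @export
project_pcs <- function(study, reference, k = 5,
                        method = c("oadp", "naive"), extra_dims = k) {
  method <- match.arg(method)
  skey <- variant_key(study$variants$chrom, study$variants$pos)
  rkey <- variant_key(reference$variants$chrom, reference$variants$pos)
  idx <- match(rkey, skey)
  if (anyNA(idx)) stop2("study and reference must share a harmonized variant set")
  std <- ref_standardizer(reference)
  Xr <- scale(reference$dosage[, std$keep, drop = FALSE],
              center = std$mu, scale = std$sd)
  n_ref <- nrow(Xr)
  rank_max <- min(n_ref - 1L, ncol(Xr))
  if (k > rank_max) stop2("k exceeds the reference rank")
  K <- min(k + extra_dims, rank_max)
  sv <- svd(Xr, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  ref_scores_K <- sv$u %*% diag(d, K)
  ref_scores <- ref_scores_K[, seq_len(k), drop = FALSE]
  Ys <- scale(study$dosage[, idx, drop = FALSE][, std$keep, drop = FALSE],
              center = std$mu, scale = std$sd)
  B <- Ys %*% sv$v  # n_study x K
  if (method == "naive") {
    study_scores <- B[, seq_len(k), drop = FALSE]
  } else {
    UD <- ref_scores_K
    norms2 <- rowSums(Ys^2)
    study_scores <- matrix(0, nrow(Ys), k)
    for (i in seq_len(nrow(Ys))) {
      b <- B[i, ]
      r2 <- max(norms2[i] - sum(b^2), 0)
      r <- sqrt(r2)
      # Gram matrix of the augmented data in the (V, y_perp) basis
      A <- rbind(cbind(diag(d^2, K) + tcrossprod(b), r * b),
                 c(r * b, r2))
      eg <- eigen(A, symmetric = TRUE)
      W <- eg$vectors
      ref_aug <- UD %*% W[seq_len(K), , drop = FALSE]
      y_aug <- as.vector(c(b, r) %*% W)
      fit <- procrustes_fit(ref_aug[, seq_len(k), drop = FALSE], ref_scores)
      study_scores[i, ] <- procrustes_apply(fit, rbind(y_aug[seq_len(k)]))
    }
  }
  rownames(study_scores) <- study$samples$sample_id
  rownames(ref_scores) <- reference$samples$sample_id
  structure(list(study_scores = study_scores, ref_scores = ref_scores,
                 d = d, k = k, method = method, n_dropped = std$n_dropped),
            class = "pc_projection")
}

#' Classical (Torgerson) MDS of population allele frequencies
#'
#' Embeds population frequency vectors by classical multidimensional scaling
#' of their pairwise Euclidean distance matrix. Component signs are fixed
#' deterministically (largest-magnitude loading positive).
#'
#' @param freq_table numeric matrix, populations in rows (rownames required),
#'   variants in columns.
#' @param k number of components (requires at least `k + 1` populations).
#' @return matrix of MDS coordinates (populations x k).
#' @export
mds_from_freqs <- function(freq_table, k = 5) {
  freq_table <- as.matrix(freq_table)
  if (is.null(rownames(freq_table))) stop2("freq_table needs population rownames")
  if (nrow(freq_table) < k + 1) stop2("need at least k + 1 populations")
  cfg <- stats::cmdscale(stats::dist(freq_table), k = k)
  if (ncol(cfg) < k) {  # degenerate configuration: pad zero coordinates
    cfg <- cbind(cfg, matrix(0, nrow(cfg), k - ncol(cfg)))
  }
  for (j in seq_len(ncol(cfg))) {
    pivot <- which.max(abs(cfg[, j]))
    if (cfg[pivot, j] < 0) cfg[, j] <- -cfg[, j]
  }
  colnames(cfg) <- paste0("MDS", seq_len(k))
  cfg
}

#' Orthogonal Procrustes fit with scaling and translation
#'
#' Finds scale `s > 0`, orthogonal `R` (reflections allowed by default) and
#' translation `t` minimizing the Frobenius error of `s * X %*% R + t`
#' against the target configuration, in closed form via the SVD of the
#' centered cross-product.
#'
#' @param source,target numeric matrices with matching dimensions.
#' @param allow_reflection permit `det(R) = -1`? When `FALSE`, the fit is
#'   constrained to proper rotations.
#' @return object of class `procrustes_transform`: list with `s`, `R`, `t`
#'   and the residual sum of squares `rss`.
#' @export
procrustes_fit <- function(source, target, allow_reflection = TRUE) {
  X <- as.matrix(source)
  Y <- as.matrix(target)
  if (!all(dim(X) == dim(Y))) stop2("source and target dimensions differ")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  ssx <- sum(Xc^2)
  if (ssx == 0) stop2("degenerate source configuration (all points identical)")
  sv <- svd(crossprod(Xc, Yc))
  sign_last <- 1
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) sign_last <- -1
  D <- diag(c(rep(1, length(sv$d) - 1), sign_last), length(sv$d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(sv$d * diag(D)) / ssx
  t_vec <- cy - s * as.vector(cx %*% R)
  rss <- sum((s * Xc %*% R - Yc)^2)
  structure(list(s = s, R = R, t = t_vec, rss = rss),
            class = "procrustes_transform")
}

#' Apply a fitted Procrustes transform
#'
#' @param fit a `procrustes_transform`.
#' @param X matrix of points (rows) in the source space.
#' @return transformed matrix `s * X %*% R + t`.
#' @export
procrustes_apply <- function(fit, X) {
  X <- as.matrix(X)
  sweep(fit$s * X %*% fit$R, 2, fit$t, `+`)
}

#' Build the joint ancestry coordinate system
#'
#' Projects study samples onto reference PCs, embeds reference and
#' discovery-GWAS population allele frequencies by classical MDS, fits a
#' Procrustes transform taking the reference populations' MDS rows onto
#' their PC centroids, and maps every MDS row (including the GWAS
#' populations) into PC space.
#'
#' @inheritParams project_pcs
#' @param ref_freqs matrix of reference population frequencies
#'   (populations x variants, rownames = population labels matching
#'   `reference$samples$population`).
#' @param gwas_freqs matrix of discovery-GWAS population frequencies on the
#'   same variant columns.
#' @return object of class `ancestry_space`: per-individual `pc_coords`,
#'   `ref_centroids`, `mds_coords`, the fitted `procrustes` transform,
#'   `mapped` coordinates for all MDS rows and `mapped_gwas` for the GWAS
#'   populations.
#' @export
build_ancestry_space <- function(study, reference, ref_freqs, gwas_freqs,
                                 k = 5, method = c("oadp", "naive")) {
  method <- match.arg(method)
  if (!identical(colnames(ref_freqs), colnames(gwas_freqs))) {
    stop2("ref_freqs and gwas_freqs must share identical variant columns")
  }
  proj <- project_pcs(study, reference, k = k, method = method)
  pops <- rownames(ref_freqs)
  cent <- t(vapply(pops, function(p) {
    rows <- reference$samples$population == p
    if (!any(rows)) stop2("reference has no samples for population ", p)
    colMeans(proj$ref_scores[rows, , drop = FALSE])
  }, numeric(k)))
  mds <- mds_from_freqs(rbind(ref_freqs, gwas_freqs), k = k)
  fit <- procrustes_fit(mds[pops, , drop = FALSE], cent)
  mapped <- procrustes_apply(fit, mds)
  structure(list(pc_coords = proj$study_scores, ref_scores = proj$ref_scores,
                 ref_centroids = cent, mds_coords = mds, procrustes = fit,
                 mapped = mapped,
                 mapped_gwas = mapped[rownames(gwas_freqs), , drop = FALSE],
                 projection = proj),
            class = "ancestry_space")
}

#' Map MDS rows into PC space with the fitted Procrustes transform
#'
#' @param space an `ancestry_space`.
#' @return matrix of mapped coordinates for every MDS row, with the
#'   reference-row residual (the Procrustes objective) as attribute
#'   `residual`.
#' @export
map_gwas_points <- function(space) {
  if (is.null(space$procrustes)) stop2("Procrustes transform not fitted")
  mapped <- procrustes_apply(space$procrustes, space$mds_coords)
  attr(mapped, "residual") <- space$procrustes$rss
  mapped
}

#' Per-individual genetic distance to a discovery GWAS point
#'
#' Euclidean distance between each individual's PC coordinates and the
#' mapped GWAS population coordinate across the first `k` (default 5)
#' dimensions.
#'
#' @param pc_coords individuals x k coordinate matrix.
#' @param gwas_point length-k coordinate vector in the same mapped space.
#' @return named numeric vector of distances.
#' @export
genetic_distance <- function(pc_coords, gwas_point) {
  pc_coords <- as.matrix(pc_coords)
  gwas_point <- as.numeric(gwas_point)
  if (ncol(pc_coords) != length(gwas_point)) stop2("dimension mismatch")
  sqrt(rowSums(sweep(pc_coords, 2, gwas_point)^2))
}

#' Accuracy profile across bins of genetic distance
#'
#' Assigns individuals to `n_bins` equal-sized bins of genetic distance
#' (sizes differ by at most one), evaluates the incremental R2 of the score
#' within each bin (liability scale for binary traits) and reports the
#' Pearson correlation between bin mean distance and accuracy from the
#' bin-level regression. Bins with undefined accuracy (e.g. constant
#' phenotype) are excluded with a logged count.
#'
#' @param gd per-individual genetic distance.
#' @param phenotype outcome vector.
#' @param prs per-individual score.
#' @param covariates optional covariate matrix.
#' @param n_bins number of quantile bins (default 20; use 10 for
#'   within-ancestry decile profiles).
#' @param binary binary outcome (liability-scale accuracy)?
#' @param prevalence population prevalence for the liability conversion.
#' @param n_boot bootstrap replicates per bin (0 = no CIs).
#' @param seed integer seed for per-bin bootstraps.
#' @return object of class `gd_profile`: `table` (bin, n, mean_gd, r2,
#'   ci_low, ci_high), `cor`, `p_value`, `n_excluded`.
#' @export
binned_accuracy_profile <- function(gd, phenotype, prs, covariates = NULL,
                                    n_bins = 20, binary = FALSE,
                                    prevalence = NULL, n_boot = 0, seed = 1) {
  if (n_bins < 3) stop2("n_bins must be >= 3")
  n <- length(gd)
  if (n_bins > n) stop2("more bins than individuals")
  ord <- order(gd)
  bins <- balanced_bins(ord, n_bins)
  cv <- as_cov_matrix(covariates, n)
  rows <- vector("list", n_bins)
  excluded <- 0L
  for (b in seq_len(n_bins)) {
    sel <- bins == b
    res <- tryCatch({
      suppressWarnings(accuracy_eval(
        phenotype[sel], prs[sel],
        covariates = if (is.null(cv)) NULL else cv[sel, , drop = FALSE],
        binary = binary, prevalence = prevalence,
        n_boot = n_boot, seed = stage_seed(seed, b)))
    }, error = function(e) NULL)
    if (is.null(res) || stats::sd(phenotype[sel]) == 0) {
      excluded <- excluded + 1L
      next
    }
    rows[[b]] <- data.frame(bin = b, n = sum(sel), mean_gd = mean(gd[sel]),
                            r2 = res$r2_incremental,
                            ci_low = res$ci_low, ci_high = res$ci_high)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3) {
    stop2("accuracy undefined in too many bins (", excluded, " excluded)")
  }
  ct <- stats::cor.test(tab$mean_gd, tab$r2)
  structure(list(table = tab, cor = unname(ct$estimate),
                 p_value = ct$p.value, n_bins = n_bins,
                 n_excluded = excluded),
            class = "gd_profile")
}

#' @export
print.gd_profile <- function(x, ...) {
  cat(sprintf("GD accuracy profile: %d bins, r = %.3f (p = %.3g)\n",
              nrow(x$table), x$cor, x$p_value))
  invisible(x)
}
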