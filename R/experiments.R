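# Generative recovery experiments: simulation designs under which the RA
# predictions, the genetic-distance profile and the recombination-rate
# stratification have a known expected behavior. These drive the analysis
# scripts and the acceptance checks.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generative recovery of the relative-accuracy predictions
#'
#' Runs replicate two-population simulations and compares the observed
#' relative accuracy of a discovery-trained score against the model
#' predictions.
#'
#' Mode `"maf"`: independent variants (no LD), every PRS SNP causal,
#' shared standardized effects (`rho_b = 1`), equal heritabilities, only
#' allele frequencies differing between populations - the regime in which
#' the MAF-only prediction should be unbiased for the observed RA.
#'
#' Mode `"ld"`: adds population-divergent LD on top of the frequency
#' differences. Variants come in three-SNP causal blocks, tightly linked in
#' the discovery population (latent AR(1) 0.95) but loosely in the target
#' population; the PRS uses each block's center SNP, which tags its causal
#' neighbors well only in the discovery population. Here the MAF-only
#' prediction over-predicts accuracy and the LD+MAF prediction captures
#' part of the additional LD-driven loss.
#'
#' @param mode `"maf"` or `"ld"`.
#' @param n_seeds number of replicate simulations (default 20).
#' @param n_per_pop samples per cohort (discovery and each evaluation
#'   cohort; default 50,000).
#' @param n_snps number of variants (default 500; rounded down to a
#'   multiple of the block size in `"ld"` mode).
#' @param h2 SNP heritability in both populations (default 0.3).
#' @param rho_b cross-population correlation of causal effects (default 1).
#' @param seed base seed; replicate seeds derive from it.
#' @param ld_ref_size LD-reference subsample for candidate-causal LD.
#' @return data.frame with one row per replicate: `rep`, `ra_obs`,
#'   `ra_maf`, `ra_ld_maf`.
#' @export
experiment_ra_recovery <- function(mode = c("maf", "ld"), n_seeds = 20,
                                   n_per_pop = 50000, n_snps = 500,
                                   h2 = 0.3, rho_b = 1, seed = 1,
                                   ld_ref_size = 10000) {
  mode <- match.arg(mode)
  rows <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    s0 <- stage_seed(seed, r * 97)
    set.seed(s0)
    if (mode == "maf") {
      m <- n_snps
      blocks <- rep(1L, m)
      rho1 <- 0
      rho2 <- 0
      prs_idx <- seq_len(m)
    } else {
      n_blocks <- n_snps %/% 3L
      m <- 3L * n_blocks
      blocks <- rep(3L, n_blocks)
      rho1 <- rep(0.95, n_blocks)
      rho2 <- stats::runif(n_blocks, 0.15, 0.45)
      prs_idx <- seq(2L, m, by = 3L)   # block centers
    }
    causal <- seq_len(m)
    p1 <- stats::runif(m, 0.15, 0.85)
    p2 <- clamp(p1 + stats::runif(m, -0.2, 0.2), 0.03, 0.97)
    spec1 <- population_spec("P1", n_per_pop, blocks, p1, ld_rho = rho1, h2 = h2)
    spec2 <- population_spec("P2", n_per_pop, blocks, p2, ld_rho = rho2, h2 = h2)
    disc1 <- simulate_genotypes(spec1, stage_seed(s0, 1))
    eval1 <- simulate_genotypes(spec1, stage_seed(s0, 2))
    eval2 <- simulate_genotypes(spec2, stage_seed(s0, 3))
    sim <- simulate_effects_and_phenotypes(
      list(disc1 = disc1, eval1 = eval1, eval2 = eval2),
      architecture_spec(causal, rho_b = rho_b),
      h2_per_pop = c(h2, h2), seed = stage_seed(s0, 4),
      panel_pops = c(1, 1, 2))
    ss <- simulate_sumstats(disc1, sim$phenotypes$disc1$quantitative)
    ss <- ss[match(disc1$variants$id[prs_idx], ss$id), , drop = FALSE]
    ss <- ss[!is.na(ss$beta), , drop = FALSE]
    w <- prs_weights(data.frame(chrom = ss$chrom, pos = ss$pos, id = ss$id,
                                effect_allele = ss$a1, weight = ss$beta))
    a1 <- suppressWarnings(incremental_r2(sim$phenotypes$eval1$quantitative,
                                          score(eval1, w)))
    a2 <- suppressWarnings(incremental_r2(sim$phenotypes$eval2$quantitative,
                                          score(eval2, w)))
    ra_obs <- relative_accuracy_observed(a2, a1)
    f1 <- panel_freq(eval1)[match(w$id, eval1$variants$id)]
    f2 <- panel_freq(eval2)[match(w$id, eval2$variants$id)]
    in_maf <- ra_inputs(w$weight, f1, f2, h2, h2, rho_b = 1)
    pred_maf <- ra_maf(in_maf)
    pred_ld_maf <- if (mode == "ld") {
      set.seed(stage_seed(s0, 5))
      idx <- sample.int(n_per_pop, min(ld_ref_size, n_per_pop))
      cand <- find_candidate_causals(w, eval1[idx, ], eval2[idx, ])
      in_ld <- ra_inputs(w$weight[match(cand$id, w$id)],
                         f1[match(cand$id, w$id)], f2[match(cand$id, w$id)],
                         h2, h2, rho_b = 1, candidates = cand, ids = cand$id)
      ra_ld_maf(in_ld)
    } else {
      ra_ld_maf(in_maf)
    }
    rows[[r]] <- data.frame(rep = r, ra_obs = ra_obs, ra_maf = pred_maf,
                            ra_ld_maf = pred_ld_maf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genetic-distance gradient experiment
#'
#' Simulates an admixture gradient between a discovery-like population A
#' (causal variants common) and a diverged population B (causal variants
#' rarer), builds the joint ancestry space, and profiles the accuracy of a
#' true-effect score across bins of genetic distance from the A discovery
#' sample. Under the gradient the per-bin accuracy declines with distance
#' (negative bin-level correlation); with `null = TRUE` the study cohort is
#' a single homogeneous population and the correlation has no signal.
#'
#' @param n_study study-cohort size (default 4000).
#' @param n_ref_per_pop reference samples per population.
#' @param n_snps number of variants.
#' @param n_bins genetic-distance bins (default 20).
#' @param h2 heritability of the trait in the pure-A background.
#' @param seed integer seed.
#' @param null homogeneous-population null instead of the gradient?
#' @return list with `profile` (a `gd_profile`), `alpha` (admixture
#'   fractions or NULL), `gd`, and `cor_alpha_pc1`.
#' @export
experiment_gd_gradient <- function(n_study = 4000, n_ref_per_pop = 150,
                                   n_snps = 500, n_bins = 20, h2 = 0.25,
                                   seed = 1, null = FALSE) {
  set.seed(stage_seed(seed, 1))
  pA <- stats::runif(n_snps, 0.25, 0.5)
  pB <- clamp(pA - stats::runif(n_snps, 0.1, 0.3), 0.02, 0.98)
  specA <- population_spec("A", n_ref_per_pop, rep(1L, n_snps), pA, h2 = h2)
  specB <- population_spec("B", n_ref_per_pop, rep(1L, n_snps), pB, h2 = h2)
  refA <- simulate_genotypes(specA, stage_seed(seed, 2))
  refB <- simulate_genotypes(specB, stage_seed(seed, 3))
  reference <- genotype_panel(rbind(refA$dosage, refB$dosage), refA$variants,
                              rbind(refA$samples, refB$samples))
  if (null) {
    specS <- specA; specS$n_samples <- as.integer(n_study)
    study <- simulate_genotypes(specS, stage_seed(seed, 4))
    alpha <- NULL
  } else {
    study <- simulate_admixture_gradient(specA, specB, n_study,
                                         stage_seed(seed, 4))
    alpha <- study$samples$alpha
  }
  # causal effects calibrated in the pure-A background
  sim <- simulate_effects_and_phenotypes(
    list(A = refA), architecture_spec(seq_len(n_snps)),
    h2_per_pop = h2, seed = stage_seed(seed, 5))
  w_allele <- sim$effects$A$beta_allele
  weights <- prs_weights(data.frame(chrom = study$variants$chrom,
                                    pos = study$variants$pos,
                                    id = study$variants$id,
                                    effect_allele = study$variants$a1,
                                    weight = w_allele))
  g <- as.vector(study$dosage %*% w_allele)
  var_gA <- sum(2 * pA * (1 - pA) * w_allele^2)
  set.seed(stage_seed(seed, 6))
  y <- g + stats::rnorm(n_study, 0, sqrt(var_gA * (1 - h2) / h2))
  ref_freqs <- rbind(A = panel_freq(refA), B = panel_freq(refB))
  colnames(ref_freqs) <- refA$variants$id
  gwas_freqs <- rbind(GWAS_A = panel_freq(refA))
  colnames(gwas_freqs) <- refA$variants$id
  space <- build_ancestry_space(study, reference, ref_freqs, gwas_freqs, k = 2)
  gd <- genetic_distance(space$pc_coords, space$mapped_gwas["GWAS_A", ])
  prof <- binned_accuracy_profile(gd, y, score(study, weights), n_bins = n_bins)
  cor_alpha_pc1 <- if (is.null(alpha)) NA_real_ else {
    stats::cor(alpha, space$pc_coords[, 1])
  }
  list(profile = prof, alpha = alpha, gd = gd, space = space,
       cor_alpha_pc1 = cor_alpha_pc1)
}

#' Recombination-rate divergence experiment
#'
#' Constructs a genome in which the recombination rate rises along the
#' chromosome while cross-population LD similarity falls: variants come in
#' tag/causal pairs, the discovery population tags tightly everywhere, and
#' the target population's tagging decays in step with the local rate. The
#' target-population accuracy of the discovery-trained tag-SNP score is then
#' profiled across recombination-rate quartiles, where it should decline
#' from the lowest to the highest quartile.
#'
#' @param n_blocks number of tag/causal pairs (default 200).
#' @param n_per_pop cohort size (discovery and target; default 20,000).
#' @param h2 heritability (default 0.4).
#' @param seed integer seed.
#' @param n_boot bootstrap replicates per quartile.
#' @return list with `profile` (quartile table) and `map`.
#' @export
experiment_recomb_divergence <- function(n_blocks = 200, n_per_pop = 20000,
                                         h2 = 0.4, seed = 1, n_boot = 200) {
  set.seed(stage_seed(seed, 1))
  n_snps <- 2L * n_blocks
  p <- stats::runif(n_snps, 0.2, 0.8)
  frac <- (seq_len(n_blocks) - 1) / (n_blocks - 1)
  rho1 <- rep(0.9, n_blocks)
  rho2 <- 0.9 - 0.75 * frac
  spec1 <- population_spec("P1", n_per_pop, rep(2L, n_blocks), p,
                           ld_rho = rho1, h2 = h2)
  spec2 <- population_spec("P2", n_per_pop, rep(2L, n_blocks), p,
                           ld_rho = rho2, h2 = h2)
  disc1 <- simulate_genotypes(spec1, stage_seed(seed, 2))
  eval2 <- simulate_genotypes(spec2, stage_seed(seed, 3))
  causal <- seq(2L, n_snps, by = 2L)
  sim <- simulate_effects_and_phenotypes(
    list(disc1 = disc1, eval2 = eval2), architecture_spec(causal),
    h2_per_pop = c(h2, h2), seed = stage_seed(seed, 4),
    panel_pops = c(1, 2))
  ss <- simulate_sumstats(disc1, sim$phenotypes$disc1$quantitative)
  tags <- disc1$variants$id[seq(1L, n_snps, by = 2L)]
  ss <- ss[match(tags, ss$id), , drop = FALSE]
  ss <- ss[!is.na(ss$beta), , drop = FALSE]
  w <- prs_weights(data.frame(chrom = ss$chrom, pos = ss$pos, id = ss$id,
                              effect_allele = ss$a1, weight = ss$beta))
  # rate ramps linearly along the chromosome, matching the LD decay
  extent <- max(disc1$variants$pos) + 5000
  grid <- seq(1, extent, by = 5000)
  rate <- 0.5 + (20 - 0.5) * (grid - 1) / (extent - 1)
  rmap <- recombination_map(grid, rate)
  prof <- quartile_profile(w, rmap, eval2,
                           sim$phenotypes$eval2$quantitative,
                           n_boot = n_boot, seed = stage_seed(seed, 5))
  list(profile = prof, map = rmap, weights = w)
}

#' Bootstrap coverage experiment
#'
#' Repeatedly draws a normal sample, computes the percentile-bootstrap CI
#' of its mean, and reports the fraction of repetitions whose CI covers the
#' true mean (0).
#'
#' @param n sample size per repetition.
#' @param n_outer number of outer repetitions.
#' @param n_boot bootstrap replicates per CI.
#' @param seed integer seed.
#' @return coverage fraction in `[0, 1]`.
#' @export
experiment_bootstrap_coverage <- function(n = 500, n_outer = 200,
                                          n_boot = 1000, seed = 1) {
  covered <- logical(n_outer)
  for (i in seq_len(n_outer)) {
    set.seed(stage_seed(seed, i))
    x <- stats::rnorm(n)
    ci <- bootstrap_ci(mean, x, n_boot = n_boot,
                       seed = stage_seed(seed, i + n_outer))$ci
    covered[i] <- ci[1] <= 0 && 0 <= ci[2]
  }
  mean(covered)
}
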