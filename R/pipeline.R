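# End-to-end orchestration of the synthetic transferability study: score
# grid, model selection, per-population accuracy, genetic-distance profile,
# RA decomposition and recombination-rate profile from a single config.

#' Configuration for a full synthetic run
#'
#' Defaults define a compact two-population study; the tuning grid, bin
#' counts, bootstrap replicates and LD-reference subsample size default to
#' the analysis's standard settings (3 x 2 x 2 grid, 20 GD bins, 1000
#' replicates, 10,000 LD-reference genotypes).
#'
#' @param seed global seed; per-stage seeds derive from it deterministically.
#' @param n_discovery discovery-cohort size (population 1).
#' @param n_eval evaluation-cohort size per population.
#' @param n_variants number of variants.
#' @param block_size variants per LD block.
#' @param ld_rho_pop1,ld_rho_pop2 latent AR(1) LD per population.
#' @param maf_shift maximum per-variant frequency perturbation between
#'   populations.
#' @param n_causal number of causal variants.
#' @param h2_pop1,h2_pop2 SNP heritabilities.
#' @param rho_b cross-population causal-effect correlation.
#' @param prevalence liability prevalence for the binary trait.
#' @param p_thresholds,r2_thresholds,windows_kb tuning grid.
#' @param n_boot bootstrap replicates for reported CIs.
#' @param n_gd_bins genetic-distance bins.
#' @param n_gd_dims ancestry-space dimensions (the two-population synthetic
#'   design spans two; real multi-reference analyses use five).
#' @param gd_study_n admixed study-cohort size for the GD profile.
#' @param ld_ref_size LD-reference subsample size.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_discovery = 6000, n_eval = 4000,
                       n_variants = 600, block_size = 3,
                       ld_rho_pop1 = 0.8, ld_rho_pop2 = 0.35,
                       maf_shift = 0.2, n_causal = 150,
                       h2_pop1 = 0.3, h2_pop2 = 0.25, rho_b = 0.8,
                       prevalence = 0.3,
                       p_thresholds = c(5e-5, 0.01, 0.5),
                       r2_thresholds = c(0.1, 0.5),
                       windows_kb = c(100, 250),
                       n_boot = 1000, n_gd_bins = 20, n_gd_dims = 2,
                       gd_study_n = 3000, ld_ref_size = 10000,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  if (!length(p_thresholds) || !length(r2_thresholds) || !length(windows_kb)) {
    stop2("tuning grid must be non-empty")
  }
  if (n_variants %% block_size != 0) stop2("n_variants must be a multiple of block_size")
  if (n_causal > n_variants) stop2("n_causal exceeds n_variants")
  structure(cfg, class = "run_config")
}

#' Select the best score from a tuning grid
#'
#' Argmax of incremental R2 within the tuning population; ties are broken
#' toward the smaller p-value threshold, then the smaller r2 threshold.
#' Undefined (NA) results are ignored; an error is raised if none remain.
#'
#' @param grid_results data.frame with columns `p_threshold`,
#'   `r2_threshold`, `window_kb`, `r2_incremental` (one row per grid cell).
#' @return the selected row of `grid_results`.
#' @export
select_best_score <- function(grid_results) {
  if (nrow(grid_results) < 1) stop2("empty grid")
  ok <- is.finite(grid_results$r2_incremental)
  if (!any(ok)) stop2("all grid results undefined")
  g <- grid_results[ok, , drop = FALSE]
  ord <- order(-g$r2_incremental, g$p_threshold, g$r2_threshold)
  g[ord[1], , drop = FALSE]
}

#' Prune related individuals from a pairwise kinship table
#'
#' For every pair whose kinship coefficient exceeds the threshold, one
#' member is removed at random; removal cascades so that no retained pair
#' exceeds the threshold.
#'
#' @param kinship data.frame with columns `id1`, `id2`, `kinship`.
#' @param threshold kinship cutoff (default 0.1).
#' @param seed integer seed for the random member choice.
#' @return character vector of ids to remove.
#' @export
prune_related <- function(kinship, threshold = 0.1, seed = 1) {
  set.seed(seed)
  removed <- character()
  above <- kinship[kinship$kinship > threshold, , drop = FALSE]
  for (i in seq_len(nrow(above))) {
    pair <- c(above$id1[i], above$id2[i])
    if (any(pair %in% removed)) next
    removed <- c(removed, sample(pair, 1))
  }
  removed
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic transferability analysis
#'
#' Generates the two-population study (discovery cohort, per-population
#' evaluation cohorts, admixed study cohort), estimates summary statistics,
#' clumps the tuning grid, selects the best score, evaluates accuracy and
#' observed relative accuracy, decomposes RA into LD/MAF/h2 components,
#' profiles accuracy by genetic distance and by recombination-rate
#' quartiles, and (optionally) writes all tables plus a run log.
#'
#' @param config a [run_config()].
#' @return list with elements `sumstats`, `grid` (per-cell accuracy),
#'   `best`, `weights`, `accuracy` (per population), `ra_obs`, `ra_report`,
#'   `gd_profile`, `recomb_profile`, `log` (drop counts and stage seeds).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  log <- list(seed = cfg$seed)
  n_blocks <- cfg$n_variants %/% cfg$block_size

  # --- stage 1: population specs ----------------------------------------
  set.seed(stage_seed(cfg$seed, 1))
  causal <- sort(sample.int(cfg$n_variants, cfg$n_causal))
  p1 <- stats::runif(cfg$n_variants, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + stats::runif(cfg$n_variants, -cfg$maf_shift,
                                    cfg$maf_shift), 0.02), 0.98)
  # discovery-bias mechanism: causal variants have systematically lower
  # minor-allele frequency (less heterozygosity) in the target population
  shift <- stats::runif(cfg$n_causal, 0.05, cfg$maf_shift + 0.05)
  p2[causal] <- ifelse(p1[causal] < 0.5,
                       pmax(p1[causal] - shift, 0.02),
                       pmin(p1[causal] + shift, 0.98))
  spec1 <- population_spec("POP1", cfg$n_discovery,
                           rep(cfg$block_size, n_blocks), p1,
                           ld_rho = cfg$ld_rho_pop1, h2 = cfg$h2_pop1,
                           prevalence = cfg$prevalence)
  spec1e <- spec1; spec1e$n_samples <- as.integer(cfg$n_eval)
  spec2 <- population_spec("POP2", cfg$n_eval,
                           rep(cfg$block_size, n_blocks), p2,
                           ld_rho = cfg$ld_rho_pop2, h2 = cfg$h2_pop2,
                           prevalence = cfg$prevalence)

  # --- stage 2: genotypes ------------------------------------------------
  disc1 <- simulate_genotypes(spec1, stage_seed(cfg$seed, 2))
  eval1 <- simulate_genotypes(spec1e, stage_seed(cfg$seed, 3))
  eval2 <- simulate_genotypes(spec2, stage_seed(cfg$seed, 4))

  # --- stage 3: effects and phenotypes ----------------------------------
  arch <- architecture_spec(causal, rho_b = cfg$rho_b)
  sim <- simulate_effects_and_phenotypes(
    list(disc1 = disc1, eval1 = eval1, eval2 = eval2), arch,
    h2_per_pop = c(cfg$h2_pop1, cfg$h2_pop2),
    prevalence_per_pop = cfg$prevalence,
    seed = stage_seed(cfg$seed, 6),
    panel_pops = c(1, 1, 2))

  # --- stage 4: discovery GWAS and LD reference -------------------------
  ss <- simulate_sumstats(disc1, sim$phenotypes$disc1$quantitative,
                          population = "POP1")
  log$sumstats_dropped <- attr(ss, "n_dropped")
  set.seed(stage_seed(cfg$seed, 7))
  ld_idx <- sample.int(cfg$n_discovery, min(cfg$ld_ref_size, cfg$n_discovery))
  ld_ref <- disc1[ld_idx, ]
  ss <- harmonize(ss, ld_ref)

  # --- stage 5: tuning grid and selection -------------------------------
  grid_weights <- clump_grid(ss, ld_ref, cfg$p_thresholds,
                             cfg$r2_thresholds, cfg$windows_kb)
  grid_tab <- do.call(rbind, lapply(grid_weights, function(w) {
    p <- attr(w, "params")
    r2 <- if (nrow(w) == 0) NA_real_ else {
      suppressWarnings(incremental_r2(sim$phenotypes$eval1$quantitative,
                                      score(eval1, w))$r2_incremental)
    }
    data.frame(p_threshold = p$p_threshold, r2_threshold = p$r2_threshold,
               window_kb = p$window_kb, n_snps = nrow(w), r2_incremental = r2)
  }))
  rownames(grid_tab) <- NULL
  best_row <- select_best_score(grid_tab)
  best_w <- grid_weights[[which(grid_tab$p_threshold == best_row$p_threshold &
                                  grid_tab$r2_threshold == best_row$r2_threshold &
                                  grid_tab$window_kb == best_row$window_kb)[1]]]

  # --- stage 6: accuracy and observed RA --------------------------------
  acc1 <- accuracy_eval(sim$phenotypes$eval1$quantitative, score(eval1, best_w),
                        n_boot = cfg$n_boot, seed = stage_seed(cfg$seed, 8))
  acc2 <- accuracy_eval(sim$phenotypes$eval2$quantitative, score(eval2, best_w),
                        n_boot = cfg$n_boot, seed = stage_seed(cfg$seed, 9))
  ra_obs <- relative_accuracy_observed(acc2, acc1)

  # --- stage 7: RA decomposition ----------------------------------------
  cand <- find_candidate_causals(best_w, ld_ref, eval2)
  keep <- match(cand$id, best_w$id)
  inputs <- ra_inputs(best_w$weight[keep],
                      panel_freq(eval1)[match(cand$id, eval1$variants$id)],
                      panel_freq(eval2)[match(cand$id, eval2$variants$id)],
                      h2_pop1 = cfg$h2_pop1, h2_pop2 = cfg$h2_pop2,
                      rho_b = cfg$rho_b, candidates = cand, ids = cand$id)
  report <- if (ra_obs < 1) {
    ra_report(inputs, ra_obs, n_rep = cfg$n_boot,
              seed = stage_seed(cfg$seed, 10))
  } else {
    # no observed loss: report predictions without LOA terms
    list(ra_obs = ra_obs, ra_maf = ra_maf(inputs), ra_ld = ra_ld(inputs),
         ra_ld_maf = ra_ld_maf(inputs), ra_full = ra_full(inputs))
  }

  # --- stage 8: genetic-distance profile --------------------------------
  n_ref <- min(300, cfg$n_eval)
  ref_panel <- eval1[seq_len(n_ref %/% 2), ]
  ref2 <- eval2[seq_len(n_ref %/% 2), ]
  combined_ref <- genotype_panel(rbind(ref_panel$dosage, ref2$dosage),
                                 ref_panel$variants,
                                 rbind(ref_panel$samples, ref2$samples))
  study <- simulate_admixture_gradient(spec1, spec2, cfg$gd_study_n,
                                       stage_seed(cfg$seed, 11))
  ref_freqs <- rbind(POP1 = panel_freq(ref_panel), POP2 = panel_freq(ref2))
  colnames(ref_freqs) <- ref_panel$variants$id
  gwas_freqs <- rbind(GWAS_POP1 = panel_freq(disc1))
  colnames(gwas_freqs) <- ref_panel$variants$id
  space <- build_ancestry_space(study, combined_ref, ref_freqs, gwas_freqs,
                                k = cfg$n_gd_dims)
  gd <- genetic_distance(space$pc_coords, space$mapped_gwas["GWAS_POP1", ])
  w_allele <- sim$effects$disc1
  study_g <- as.vector(study$dosage[, w_allele$index, drop = FALSE] %*%
                         w_allele$beta_allele)
  set.seed(stage_seed(cfg$seed, 12))
  sigma1 <- sqrt(max(stats::var(sim$phenotypes$eval1$genetic), 1e-12) *
                   (1 - cfg$h2_pop1) / max(cfg$h2_pop1, 1e-12))
  study_y <- study_g + stats::rnorm(cfg$gd_study_n, 0, sigma1)
  gd_prof <- binned_accuracy_profile(gd, study_y, score(study, best_w),
                                     n_bins = cfg$n_gd_bins)

  # --- stage 9: recombination profile -----------------------------------
  extent <- max(eval2$variants$pos) + 5000
  rmap <- simulate_recomb_map(extent,
                              hotspot_positions = seq(extent / 10, extent,
                                                      by = extent / 5),
                              background_rate = 1, hotspot_rate = 15)
  # profile the best score when it has enough SNPs to partition, else the
  # largest weight set on the grid
  rec_w <- best_w
  if (nrow(rec_w) < 8) {
    rec_w <- grid_weights[[which.max(vapply(grid_weights, nrow, integer(1)))]]
  }
  rec_prof <- if (nrow(rec_w) >= 8) {
    quartile_profile(rec_w, rmap, eval2, sim$phenotypes$eval2$quantitative,
                     n_boot = cfg$n_boot, seed = stage_seed(cfg$seed, 13))
  } else NULL

  bundle <- list(sumstats = ss, grid = grid_tab, best = best_row,
                 weights = best_w,
                 accuracy = list(pop1 = acc1, pop2 = acc2),
                 ra_obs = ra_obs, ra_report = report,
                 gd_profile = gd_prof, recomb_profile = rec_prof,
                 log = log, config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sumstats(ss, file.path(cfg$out_dir, "sumstats_pop1.tsv.gz"))
    write_weights(best_w, file.path(cfg$out_dir, "best_weights.tsv"))
    write_tsv(grid_tab, file.path(cfg$out_dir, "grid_accuracy.tsv"))
    write_tsv(gd_prof$table, file.path(cfg$out_dir, "gd_profile.tsv"))
    if (!is.null(rec_prof)) {
      write_tsv(rec_prof, file.path(cfg$out_dir, "recomb_profile.tsv"))
    }
    ra_out <- report[c("ra_obs", "ra_maf", "ra_ld", "ra_ld_maf", "ra_full")]
    jsonlite::write_json(ra_out, file.path(cfg$out_dir, "ra_report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("seed: %d", cfg$seed),
                 sprintf("sumstats variants dropped: %d",
                         log$sumstats_dropped %||% 0),
                 sprintf("best score: p=%g r2=%g window=%gkb (%d SNPs)",
                         best_row$p_threshold, best_row$r2_threshold,
                         best_row$window_kb, best_row$n_snps)),
               file.path(cfg$out_dir, "run_log.txt"))
  }
  bundle
}
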