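# Relative-accuracy decomposition: candidate causal selection, the four RA
# predictions, LOA and SNP-bootstrap SEs.

random_inputs <- function(m, seed, ld = TRUE, h2 = c(0.3, 0.2), rho_b = 1) {
  set.seed(seed)
  cand <- if (ld) {
    r1 <- runif(m, 0.5, 1)
    data.frame(id = paste0("s", 1:m), mean_r2_pop1 = r1,
               mean_cross_r = r1 * runif(m, 0.2, 1))
  } else NULL
  ra_inputs(beta = rnorm(m), freq_pop1 = runif(m, 0.05, 0.95),
            freq_pop2 = runif(m, 0.05, 0.95),
            h2_pop1 = h2[1], h2_pop2 = h2[2], rho_b = rho_b,
            candidates = cand)
}

test_that("candidate causal sets default to self-candidacy", {
  pan1 <- tiny_panel(n = 300, m = 6, seed = 81)  # 5 kb spacing, no LD
  pan2 <- tiny_panel(n = 300, m = 6, seed = 82)
  w <- prs_weights(data.frame(chrom = "1", pos = pan1$variants$pos[1],
                              id = pan1$variants$id[1],
                              effect_allele = pan1$variants$a1[1], weight = 1))
  # window too small to reach the 5 kb neighbor: only the SNP itself
  cand <- find_candidate_causals(w, pan1, pan2, window_kb = 2)
  expect_equal(cand$n_candidates, 1)
  expect_equal(cand$mean_r2_pop1, 1)
  expect_equal(cand$mean_cross_r, 1)
})

test_that("the candidate r2 threshold is exceeded strictly", {
  pan1 <- tiny_panel(n = 500, m = 2, ld_rho = 0.85, seed = 83,
                     freq = c(0.5, 0.5), block_size = 2)
  pan2 <- tiny_panel(n = 500, m = 2, ld_rho = 0.85, seed = 84,
                     freq = c(0.5, 0.5), block_size = 2)
  r2_emp <- cor(pan1$dosage[, 1], pan1$dosage[, 2])^2
  w <- prs_weights(data.frame(chrom = "1", pos = pan1$variants$pos[1],
                              id = pan1$variants$id[1],
                              effect_allele = pan1$variants$a1[1], weight = 1))
  below <- find_candidate_causals(w, pan1, pan2, r2_min = r2_emp - 1e-6)
  above <- find_candidate_causals(w, pan1, pan2, r2_min = r2_emp + 1e-6)
  expect_equal(below$n_candidates, 2)
  expect_equal(above$n_candidates, 1)
})

test_that("candidate sets match an exhaustive all-pairs oracle", {
  pan1 <- tiny_panel(n = 400, m = 15, ld_rho = 0.8, seed = 85, block_size = 5)
  pan2 <- tiny_panel(n = 400, m = 15, ld_rho = 0.4, seed = 86, block_size = 5)
  w <- prs_weights(data.frame(chrom = pan1$variants$chrom,
                              pos = pan1$variants$pos,
                              id = pan1$variants$id,
                              effect_allele = pan1$variants$a1,
                              weight = rnorm(15)))
  cand <- find_candidate_causals(w, pan1, pan2, window_kb = 20, r2_min = 0.3)
  r1 <- cor(pan1$dosage)
  r2 <- cor(pan2$dosage)
  pos <- pan1$variants$pos
  for (k in 1:15) {
    sel <- which(abs(pos - pos[k]) <= 20000 & (r1[k, ]^2 > 0.3 | seq_len(15) == k))
    expect_equal(cand$n_candidates[k], length(sel))
    expect_equal(cand$mean_r2_pop1[k], mean(r1[k, sel]^2), tolerance = 1e-12)
    expect_equal(cand$mean_cross_r[k], mean(r1[k, sel] * r2[k, sel]),
                 tolerance = 1e-12)
  }
})

test_that("the single-SNP MAF prediction collapses to 1", {
  inp <- ra_inputs(beta = 0.37, freq_pop1 = 0.5, freq_pop2 = 0.1,
                   h2_pop1 = 0.3, h2_pop2 = 0.3)
  expect_equal(ra_maf(inp), 1, tolerance = 1e-12)
})

test_that("the MAF prediction matches an independent evaluation", {
  # two SNPs, p1 = (0.5, 0.5), p2 = (0.1, 0.5), beta = (1, 1)
  v1 <- c(0.25, 0.25)
  v2 <- c(0.09, 0.25)
  oracle <- (sum(sqrt(v2 / v1)) / 2)^2 * (sum(v1) / sum(v2))
  inp <- ra_inputs(beta = c(1, 1), freq_pop1 = c(0.5, 0.5),
                   freq_pop2 = c(0.1, 0.5), h2_pop1 = 0.3, h2_pop2 = 0.3)
  expect_equal(ra_maf(inp), oracle, tolerance = 1e-12)

  set.seed(87)
  m <- 25
  b <- rnorm(m); p1 <- runif(m, 0.1, 0.9); p2 <- runif(m, 0.1, 0.9)
  w1 <- p1 * (1 - p1); w2 <- p2 * (1 - p2)
  oracle2 <- (mean(sqrt(w2 / w1)))^2 * sum(w1 * b^2) / sum(w2 * b^2)
  inp2 <- ra_inputs(b, p1, p2, 0.4, 0.2)
  expect_equal(ra_maf(inp2), oracle2, tolerance = 1e-12)
})

test_that("the LD prediction matches a hand-evaluated 3-SNP configuration", {
  cand <- data.frame(id = c("a", "b", "c"),
                     mean_r2_pop1 = c(0.9, 0.7, 0.8),
                     mean_cross_r = c(0.81, 0.35, 0.0))
  inp <- ra_inputs(beta = c(1, -2, 0.5), freq_pop1 = rep(0.4, 3),
                   freq_pop2 = rep(0.4, 3), h2_pop1 = 0.3, h2_pop2 = 0.3,
                   candidates = cand)
  expect_equal(ra_ld(inp), ((0.81 + 0.35 + 0) / (0.9 + 0.7 + 0.8))^2,
               tolerance = 1e-12)
  # total tagging loss in the target population
  cand0 <- cand; cand0$mean_cross_r <- 0
  inp0 <- ra_inputs(beta = c(1, -2, 0.5), freq_pop1 = rep(0.4, 3),
                    freq_pop2 = rep(0.4, 3), h2_pop1 = 0.3, h2_pop2 = 0.3,
                    candidates = cand0)
  expect_equal(ra_ld(inp0), 0)
})

test_that("all predictions hit the identity limit for duplicated populations", {
  set.seed(88)
  m <- 40
  r1 <- runif(m, 0.5, 1)
  cand <- data.frame(id = paste0("s", 1:m), mean_r2_pop1 = r1,
                     mean_cross_r = r1)  # identical LD in both populations
  p <- runif(m, 0.1, 0.9)
  inp <- ra_inputs(rnorm(m), p, p, 0.25, 0.25, rho_b = 1, candidates = cand)
  expect_equal(ra_maf(inp), 1, tolerance = 1e-12)
  expect_equal(ra_ld(inp), 1, tolerance = 1e-12)
  expect_equal(ra_ld_maf(inp), 1, tolerance = 1e-12)
  expect_equal(ra_full(inp), 1, tolerance = 1e-12)
})

test_that("nesting identities hold on random inputs", {
  for (i in 1:100) {
    h2 <- runif(2, 0.05, 0.5)
    rho_b <- runif(1, 0.5, 1)
    inp <- random_inputs(20, seed = 1000 + i, h2 = h2, rho_b = rho_b)
    # the full model factors exactly into the h2/rho term and RA_LD+MAF
    expect_equal(ra_full(inp), rho_b^2 * h2[2] / h2[1] * ra_ld_maf(inp),
                 tolerance = 1e-12)
    # equal h2 and rho_b = 1 collapse the full model onto RA_LD+MAF
    inp_eq <- inp; inp_eq$h2_pop2 <- inp$h2_pop1; inp_eq$rho_b <- 1
    expect_equal(ra_full(inp_eq), ra_ld_maf(inp_eq), tolerance = 1e-12)
    # no-LD architecture: RA_LD+MAF equals RA_MAF
    inp_nold <- random_inputs(20, seed = 2000 + i, ld = FALSE, h2 = h2)
    expect_equal(ra_ld_maf(inp_nold), ra_maf(inp_nold), tolerance = 1e-12)
    expect_equal(ra_ld(inp_nold), 1, tolerance = 1e-12)
  }
})

test_that("predictions are invariant to a global rescaling of the weights", {
  inp <- random_inputs(30, seed = 89)
  scaled <- inp
  scaled$beta <- 17 * inp$beta
  for (f in list(ra_maf, ra_ld, ra_ld_maf, ra_full)) {
    expect_equal(f(scaled), f(inp), tolerance = 1e-12)
  }
})

test_that("LOA follows the printed ratio and guards its domain", {
  expect_equal(loa(0.5, 0.5), 100)
  expect_equal(loa(1, 0.5), 0)
  expect_equal(loa(0.649, 0.360), 54.84375, tolerance = 1e-10)
  expect_error(loa(0.5, 1), "no loss")
})

test_that("monomorphic target SNPs are excluded with a logged count", {
  inp <- ra_inputs(beta = c(1, 1, 1), freq_pop1 = c(0.5, 0.5, 0.5),
                   freq_pop2 = c(0.3, 1, 0), h2_pop1 = 0.3, h2_pop2 = 0.3)
  expect_equal(length(inp$beta), 1)
  expect_equal(inp$n_dropped_monomorphic, 2)
  expect_error(ra_inputs(1, 0.5, 1, 0.3, 0.3), "monomorphic")
})

test_that("SNP-bootstrap SEs are zero for degenerate inputs and CIs use 1.96 SE", {
  m <- 20
  inp <- ra_inputs(beta = rep(0.2, m), freq_pop1 = rep(0.4, m),
                   freq_pop2 = rep(0.2, m), h2_pop1 = 0.3, h2_pop2 = 0.2)
  se <- ra_se(inp, ra_obs = 0.5, n_rep = 100, seed = 3)
  expect_true(all(se$se < 1e-12))
  expect_equal(se$ci_low, se$estimate - 1.96 * se$se)
  expect_equal(se$ci_high, se$estimate + 1.96 * se$se)

  inp2 <- random_inputs(60, seed = 90)
  s1 <- ra_se(inp2, n_rep = 500, seed = 4)
  s2 <- ra_se(inp2, n_rep = 1000, seed = 5)
  expect_true(all(abs(s1$se - s2$se) / s2$se < 0.12))
  expect_warning(ra_se(random_inputs(5, seed = 91), n_rep = 50), "unstable")
})

test_that("ra_report bundles estimates, LOA terms and SEs coherently", {
  inp <- random_inputs(40, seed = 92)
  rep_ <- ra_report(inp, ra_obs = 0.4, n_rep = 200, seed = 6)
  expect_equal(rep_$loa_ld_maf, (1 - rep_$ra_ld_maf) / (1 - 0.4) * 100,
               tolerance = 1e-12)
  expect_equal(nrow(rep_$se_table), 8)
  expect_output(print(rep_), "RA_OBS")
})

test_that("unmodeled effect-size divergence lowers the explained share of the loss", {
  # with rho_b < 1 the observed loss grows while the LD+MAF prediction is
  # unchanged in expectation, so LOA_LD+MAF drops relative to rho_b = 1
  base <- experiment_ra_recovery("ld", n_seeds = 20, n_per_pop = 10000,
                                 n_snps = 210, seed = 301)
  div <- experiment_ra_recovery("ld", n_seeds = 20, n_per_pop = 10000,
                                n_snps = 210, rho_b = 0.7, seed = 301)
  expect_lt(mean(div$ra_obs), mean(base$ra_obs))
  loa_base <- loa(mean(base$ra_ld_maf), mean(base$ra_obs))
  loa_div <- loa(mean(div$ra_ld_maf), mean(div$ra_obs))
  expect_lt(loa_div, loa_base)
  expect_lt(loa_div, 100)
})
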