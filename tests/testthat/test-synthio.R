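# Copula genotype simulator, effect/phenotype generation, marginal summary
# statistics, admixture gradient and recombination maps.

test_that("population_spec validates its inputs", {
  expect_error(population_spec("A", 10, c(2), c(0.5, 1.0)), "inside \\(0, 1\\)")
  expect_error(population_spec("A", 10, c(3), c(0.5, 0.5)), "block_sizes")
  expect_error(population_spec("A", 10, c(2), c(0.5, 0.5), ld_rho = 1), "ld_rho")
  expect_error(population_spec("A", 10, c(2), c(0.5, 0.5), h2 = 1.2), "h2")
})

test_that("independent blocks yield uncorrelated genotypes at target frequency", {
  n <- 4000
  freq <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pan <- tiny_panel(n = n, m = 5, ld_rho = 0, seed = 11, freq = freq)
  expect_true(all(pan$dosage %in% 0:2))
  emp <- colMeans(pan$dosage) / 2
  expect_true(all(abs(emp - freq) < 3 * sqrt(freq * (1 - freq) / (2 * n))))
  cc <- cor(pan$dosage)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(n))
})

test_that("realized LD matches the thresholded bivariate-normal oracle", {
  n <- 5000
  cases <- list(c(p = 0.5, q = 0.5, rho = 0.9),
                c(p = 0.3, q = 0.6, rho = 0.7),
                c(p = 0.2, q = 0.2, rho = 0.4))
  for (cs in cases) {
    spec <- population_spec("A", n, 2, c(cs[["p"]], cs[["q"]]),
                            ld_rho = cs[["rho"]])
    pan <- simulate_genotypes(spec, 101)
    r_emp <- cor(pan$dosage[, 1], pan$dosage[, 2])
    r_exp <- copula_genotype_cor(cs[["p"]], cs[["q"]], cs[["rho"]])
    # two independent haplotypes: correlation SE ~ (1 - r^2) / sqrt(n)
    expect_lt(abs(r_emp - r_exp), 3 * (1 - r_exp^2) / sqrt(n))
  }
})

test_that("within-block correlation rises with ld_rho, cross-block stays null", {
  r_at <- function(rho) {
    pan <- tiny_panel(n = 3000, m = 4, ld_rho = rho, seed = 7,
                      freq = rep(0.4, 4), block_size = 2)
    cc <- cor(pan$dosage)
    c(within = mean(c(cc[1, 2], cc[3, 4])), cross = mean(abs(cc[1:2, 3:4])))
  }
  lo <- r_at(0.3)
  hi <- r_at(0.9)
  expect_gt(hi[["within"]], lo[["within"]])
  expect_lt(hi[["cross"]], 3 / sqrt(3000))
})

test_that("identical seeds give bit-identical panels", {
  spec <- population_spec("A", 200, rep(2, 10), runif(20, 0.2, 0.8),
                          ld_rho = 0.5)
  expect_identical(simulate_genotypes(spec, 42), simulate_genotypes(spec, 42))
  expect_false(identical(simulate_genotypes(spec, 42)$dosage,
                         simulate_genotypes(spec, 43)$dosage))
})

test_that("effects are shared across populations according to rho_b", {
  set.seed(5)
  freq <- runif(60, 0.2, 0.8)
  spec <- population_spec("A", 400, rep(1, 60), freq)
  pA <- simulate_genotypes(spec, 1)
  pB <- simulate_genotypes(spec, 2)
  # rho_b = 1, shared per-allele effects: exactly identical
  sim1 <- simulate_effects_and_phenotypes(
    list(A = pA, B = pB),
    architecture_spec(1:60, rho_b = 1, effect_scale_mode = "per_allele"),
    h2_per_pop = 0.4, seed = 9)
  expect_identical(sim1$effects$A$beta_allele, sim1$effects$B$beta_allele)
  # rho_b = 1, standardized sharing: proportional up to calibration scalar
  sim2 <- simulate_effects_and_phenotypes(
    list(A = pA, B = pB), architecture_spec(1:60, rho_b = 1),
    h2_per_pop = 0.4, seed = 9)
  ratio <- sim2$effects$A$beta_std / sim2$effects$B$beta_std
  expect_lt(diff(range(ratio)), 1e-10)
  # rho_b = 0: empirical effect correlation near 0
  pA2 <- tiny_panel(n = 300, m = 500, seed = 3)
  pB2 <- tiny_panel(n = 300, m = 500, seed = 4)
  sim0 <- simulate_effects_and_phenotypes(
    list(A = pA2, B = pB2), architecture_spec(1:500, rho_b = 0),
    h2_per_pop = 0.4, seed = 10)
  expect_lt(abs(cor(sim0$effects$A$beta_std, sim0$effects$B$beta_std)),
            2 / sqrt(500))
})

test_that("heritability calibration and the null-h2 limit hold", {
  pan <- tiny_panel(n = 10000, m = 150, seed = 6)
  for (h2 in c(0.1, 0.4)) {
    sim <- simulate_effects_and_phenotypes(
      list(A = pan), architecture_spec(1:150), h2_per_pop = h2, seed = 13)
    r2 <- summary(lm(sim$phenotypes$A$quantitative ~
                       sim$phenotypes$A$genetic))$r.squared
    expect_lt(abs(r2 - h2), 0.02)
  }
  sim0 <- simulate_effects_and_phenotypes(
    list(A = pan), architecture_spec(1:150), h2_per_pop = 0, seed = 13)
  prs <- as.vector(pan$dosage %*% rnorm(150))
  res <- incremental_r2(sim0$phenotypes$A$quantitative, prs)
  expect_lt(res$r2_incremental, 0.002)
  expect_error(simulate_effects_and_phenotypes(
    list(A = pan), architecture_spec(1:150), h2_per_pop = 1.5), "h2")
})

test_that("binary traits hit the target prevalence", {
  pan <- tiny_panel(n = 8000, m = 50, seed = 8)
  for (K in c(0.1, 0.3)) {
    sim <- simulate_effects_and_phenotypes(
      list(A = pan), architecture_spec(1:50), h2_per_pop = 0.3,
      prevalence_per_pop = K, seed = 14)
    frac <- mean(sim$phenotypes$A$binary)
    expect_lt(abs(frac - K), 3 * sqrt(K * (1 - K) / 8000))
  }
})

test_that("summary statistics behave as marginal OLS", {
  # null phenotype: p-values uniform
  pan <- tiny_panel(n = 800, m = 1000, seed = 15)
  set.seed(16)
  y <- rnorm(800)
  ss <- simulate_sumstats(pan, y)
  frac <- mean(ss$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  # a variant with true standardized effect 0.1 is recovered
  n <- 10000
  pan2 <- tiny_panel(n = n, m = 5, seed = 17, freq = rep(0.5, 5))
  x_std <- scale(pan2$dosage[, 3])
  set.seed(18)
  y2 <- 0.1 * as.vector(x_std) + rnorm(n, 0, sqrt(1 - 0.01))
  ss2 <- simulate_sumstats(pan2, y2)
  beta_std <- ss2$beta[3] * sd(pan2$dosage[, 3])
  expect_lt(abs(beta_std - 0.1), 3 * ss2$se[3] * sd(pan2$dosage[, 3]))

  # duplicate variant columns give identical estimates
  dup <- manual_panel(cbind(pan2$dosage[, 1], pan2$dosage[, 1]))
  ss3 <- simulate_sumstats(dup, y2)
  expect_identical(ss3$beta[1], ss3$beta[2])

  # monomorphic variants are excluded with a logged count
  mono <- manual_panel(cbind(pan2$dosage[, 1], rep(2, n)))
  ss4 <- simulate_sumstats(mono, y2)
  expect_equal(nrow(ss4), 1)
  expect_equal(attr(ss4, "n_dropped"), 1)
})

test_that("admixture gradient stores alpha and mixes frequencies", {
  specA <- population_spec("A", 10, rep(1, 300), rep(0.9, 300))
  specB <- population_spec("B", 10, rep(1, 300), rep(0.1, 300))
  adm <- simulate_admixture_gradient(specA, specB, 400, seed = 19)
  a <- adm$samples$alpha
  expect_true(all(a >= 0 & a <= 1))
  # per-individual mean dosage tracks 2 * (alpha pA + (1 - alpha) pB)
  expected <- 2 * (a * 0.9 + (1 - a) * 0.1)
  observed <- rowMeans(adm$dosage)
  expect_gt(cor(expected, observed), 0.99)
  expect_lt(max(abs(expected - observed)), 3 * sqrt(2 * 0.25 / 300) + 0.1)
  specC <- population_spec("C", 10, rep(1, 10), rep(0.5, 10))
  expect_error(simulate_admixture_gradient(specA, specC, 10, seed = 1),
               "share")
})

test_that("simulated recombination maps integrate correctly", {
  cm <- simulate_recomb_map(2e6, background_rate = 2.5)
  x <- 1.2e6
  expect_equal(approx(cm$pos, cm$map, xout = x)$y, 2.5 * x / 1e6,
               tolerance = 1e-4)
  z <- simulate_recomb_map(2e6, background_rate = 0)
  expect_true(all(z$map == 0))
  hs <- simulate_recomb_map(2e6, hotspot_positions = 1e6,
                            background_rate = 1, hotspot_rate = 10)
  expect_gt(interpolate_rate(hs, 1e6, window_bp = 2000),
            interpolate_rate(hs, 2e5, window_bp = 2000))
  expect_error(simulate_recomb_map(1e6, hotspot_positions = c(5e5, 4e5)),
               "sorted")
  expect_error(simulate_recomb_map(1e6, background_rate = -1), "rates")
})
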