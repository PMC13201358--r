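# Synthetic input generator: genotypes with controlled MAF and blockwise LD,
# effects/phenotypes with cross-population correlation and target
# heritability, marginal GWAS summary statistics, an admixture gradient and
# piecewise-linear recombination maps.

#' Population specification for the genotype simulator
#'
#' Describes one population: sample size, variant count (as LD blocks),
#' per-variant alternate-allele frequency, per-block latent AR(1) correlation
#' of the Gaussian copula, SNP heritability and (for binary traits) liability
#' prevalence.
#'
#' @param label population identifier.
#' @param n_samples number of individuals.
#' @param block_sizes integer vector of variants per LD block; their sum must
#'   equal `length(freq)`.
#' @param freq per-variant alternate-allele frequency, strictly in (0, 1).
#' @param ld_rho latent AR(1) correlation per block, each in `[0, 1)`;
#'   recycled if scalar.
#' @param h2 SNP heritability in `[0, 1]`.
#' @param prevalence liability-threshold case fraction in (0, 1).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(label, n_samples, block_sizes, freq,
                            ld_rho = 0, h2 = 0.5, prevalence = 0.25) {
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) != length(freq)) {
    stop2("sum(block_sizes) must equal length(freq)")
  }
  check_prob(freq, "freq")
  if (length(ld_rho) == 1) ld_rho <- rep(ld_rho, length(block_sizes))
  if (length(ld_rho) != length(block_sizes)) {
    stop2("ld_rho must be scalar or one value per block")
  }
  if (any(!is.finite(ld_rho)) || any(ld_rho < 0 | ld_rho >= 1)) {
    stop2("ld_rho must lie in [0, 1)")
  }
  check_prob(h2, "h2", open = FALSE)
  check_prob(prevalence, "prevalence")
  structure(list(label = label, n_samples = as.integer(n_samples),
                 block_sizes = block_sizes, freq = freq, ld_rho = ld_rho,
                 h2 = h2, prevalence = prevalence),
            class = "population_spec")
}

#' Genetic architecture specification
#'
#' @param causal_indices unique variant indices carrying causal effects.
#' @param rho_b cross-population correlation of causal effect sizes, in
#'   `[-1, 1]`. Effects are drawn jointly on the standardized-genotype scale.
#' @param effect_scale_mode `"standardized"` shares effects across
#'   populations on the standardized-genotype scale (each population then
#'   realizes its own target heritability); `"per_allele"` shares the
#'   per-allele effects of the first population, so downstream populations
#'   inherit whatever genetic variance those effects produce.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(causal_indices, rho_b = 1,
                              effect_scale_mode = c("standardized", "per_allele")) {
  causal_indices <- as.integer(causal_indices)
  if (anyDuplicated(causal_indices)) stop2("causal_indices must be unique")
  if (!is.finite(rho_b) || rho_b < -1 || rho_b > 1) stop2("rho_b must lie in [-1, 1]")
  structure(list(causal_indices = causal_indices, rho_b = rho_b,
                 effect_scale_mode = match.arg(effect_scale_mode)),
            class = "architecture_spec")
}

# Latent AR(1) Gaussian matrix (n x m) built blockwise.
ar1_latent <- function(n, block_sizes, ld_rho) {
  m <- sum(block_sizes)
  z <- matrix(0, n, m)
  col <- 0L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    rho <- ld_rho[b]
    z[, col + 1L] <- stats::rnorm(n)
    if (sz > 1L) {
      w <- sqrt(1 - rho^2)
      for (j in 2L:sz) {
        z[, col + j] <- rho * z[, col + j - 1L] + w * stats::rnorm(n)
      }
    }
    col <- col + sz
  }
  z
}

# Deterministic, strand-unambiguous allele assignment shared by panels that
# simulate the same variant list.
default_alleles <- function(m) {
  pairs <- matrix(c("A", "G", "T", "C", "G", "A", "C", "T"), ncol = 2, byrow = TRUE)
  idx <- ((seq_len(m) - 1L) %% 4L) + 1L
  list(a1 = pairs[idx, 1], a2 = pairs[idx, 2])
}

#' Simulate genotypes under a Gaussian copula with blockwise AR(1) LD
#'
#' Each haplotype allele is an indicator that a latent standard normal falls
#' below the frequency quantile; latent variables share an AR(1) correlation
#' within LD blocks and are independent across blocks. A genotype is the sum
#' of two independent haplotypes, so marginal frequencies and within-block LD
#' are controlled separately.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @param chrom chromosome label for the simulated variants.
#' @param bp_spacing physical spacing between adjacent variants in bp.
#' @param pos_start position of the first variant (1-based).
#' @return a [genotype_panel()] whose `samples$population` is `spec$label`.
#' @export
simulate_genotypes <- function(spec, seed, chrom = "1", bp_spacing = 5000,
                               pos_start = 1) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  n <- spec$n_samples
  m <- length(spec$freq)
  q <- stats::qnorm(spec$freq)
  if (all(spec$ld_rho == 0)) {
    # Independent variants: binomial shortcut, same law as the copula.
    dos <- matrix(stats::rbinom(n * m, 2L, rep(spec$freq, each = n)), n, m)
  } else {
    qm <- matrix(q, n, m, byrow = TRUE)
    h1 <- ar1_latent(n, spec$block_sizes, spec$ld_rho) < qm
    h2 <- ar1_latent(n, spec$block_sizes, spec$ld_rho) < qm
    dos <- h1 + h2
  }
  storage.mode(dos) <- "integer"
  al <- default_alleles(m)
  variants <- data.frame(
    chrom = chrom,
    pos = as.integer(pos_start + (seq_len(m) - 1L) * bp_spacing),
    id = sprintf("v%05d", seq_len(m)),
    a1 = al$a1, a2 = al$a2,
    freq = spec$freq,
    block = rep(seq_along(spec$block_sizes), times = spec$block_sizes)
  )
  samples <- data.frame(
    sample_id = sprintf("%s_%05d", spec$label, seq_len(n)),
    population = spec$label
  )
  genotype_panel(dos, variants, samples)
}

#' Simulate causal effects and phenotypes for a set of panels
#'
#' Causal effects are drawn jointly across populations with correlation
#' `rho_b` on the standardized-genotype scale (the first population carries
#' the shared factor). Each population's genetic value is rescaled so the
#' realized genetic fraction of phenotypic variance equals its `h2`; a binary
#' trait is obtained by thresholding the unit-variance liability at the
#' normal `(1 - prevalence)` quantile.
#'
#' @param panels named list of [genotype_panel()] objects sharing a variant list.
#' @param arch an [architecture_spec()].
#' @param h2_per_pop heritability per population (recycled).
#' @param prevalence_per_pop liability prevalence per population (recycled),
#'   used only for the binary trait.
#' @param seed integer seed.
#' @param panel_pops population index per panel (defaults to each panel
#'   being its own population). Panels mapped to the same population share
#'   one effect vector: the first panel of a population calibrates the
#'   per-allele effects to its target heritability and later panels (e.g.
#'   an evaluation cohort for the discovery population) reuse them.
#' @return list with `effects` (per panel: `index`, `beta_std`,
#'   `beta_allele`), `phenotypes` (per panel: `quantitative`, `genetic`,
#'   `binary`, `prevalence`) and the realized heritability `h2_realized`.
#' @export
simulate_effects_and_phenotypes <- function(panels, arch, h2_per_pop,
                                            prevalence_per_pop = 0.25, seed = 1,
                                            panel_pops = NULL) {
  stopifnot(inherits(arch, "architecture_spec"))
  if (is.null(names(panels))) names(panels) <- paste0("pop", seq_along(panels))
  npanel <- length(panels)
  panel_pops <- panel_pops %||% seq_len(npanel)
  npop <- max(panel_pops)
  h2_per_pop <- rep_len(h2_per_pop, npop)
  prevalence_per_pop <- rep_len(prevalence_per_pop, npop)
  check_prob(h2_per_pop, "h2", open = FALSE)
  m <- ncol(panels[[1]]$dosage)
  ci <- arch$causal_indices
  if (any(ci < 1 | ci > m)) stop2("causal_indices out of range")
  set.seed(seed)
  nc <- length(ci)
  u <- stats::rnorm(nc)
  b_std <- vector("list", npop)
  b_std[[1]] <- u
  if (npop > 1) {
    for (j in 2:npop) {
      b_std[[j]] <- arch$rho_b * u + sqrt(1 - arch$rho_b^2) * stats::rnorm(nc)
    }
  }
  effects <- vector("list", npanel)
  phenotypes <- vector("list", npanel)
  h2_real <- numeric(npanel)
  calibrated <- vector("list", npop)  # per population: beta_allele, sigma
  for (j in seq_len(npanel)) {
    panel <- panels[[j]]
    pop <- panel_pops[j]
    X <- panel$dosage[, ci, drop = FALSE]
    exp_sd <- sqrt(2 * panel$variants$freq[ci] * (1 - panel$variants$freq[ci]))
    inherit <- if (arch$effect_scale_mode == "per_allele" && pop > 1) {
      calibrated[[1]]
    } else {
      calibrated[[pop]]
    }
    if (!is.null(inherit)) {
      b_allele <- inherit$beta_allele
      sigma <- inherit$sigma
      g <- as.vector(X %*% b_allele)
      g <- g - mean(g)
    } else {
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd)
      sdv[sdv == 0] <- 1  # monomorphic columns contribute nothing
      g_raw <- as.vector(scale(X, center = mu, scale = sdv) %*% b_std[[pop]])
      h2 <- h2_per_pop[pop]
      cal <- if (h2 > 0 && stats::sd(g_raw) > 0) sqrt(h2) / stats::sd(g_raw) else 0
      b_allele <- b_std[[pop]] * cal / exp_sd
      g <- g_raw * cal
      sigma <- sqrt(1 - h2)
      calibrated[[pop]] <- list(beta_allele = b_allele, sigma = sigma)
    }
    e <- stats::rnorm(nrow(X), 0, sigma)
    liab <- g + e
    K <- prevalence_per_pop[pop]
    yb <- as.integer(liab > stats::qnorm(1 - K))
    h2_real[j] <- if (stats::var(liab) > 0) stats::var(g) / stats::var(liab) else 0
    effects[[j]] <- data.frame(index = ci, beta_std = b_allele * exp_sd,
                               beta_allele = b_allele)
    phenotypes[[j]] <- list(quantitative = liab, genetic = g, binary = yb,
                            prevalence = K)
  }
  names(effects) <- names(panels)
  names(phenotypes) <- names(panels)
  list(effects = effects, phenotypes = phenotypes, h2_realized = h2_real)
}

#' Marginal GWAS summary statistics by per-variant regression
#'
#' Regresses the phenotype on each variant's dosage separately (simple OLS)
#' and records effect size, standard error, two-sided t-based p-value,
#' realized effect-allele frequency and sample size. Monomorphic variants
#' are excluded with a logged count (attribute `n_dropped`).
#'
#' @param panel a [genotype_panel()].
#' @param phenotype numeric vector, one value per sample.
#' @param population label recorded for the output.
#' @return a `summary_stats` data.frame with columns
#'   `chrom, pos, id, a1, a2, beta, se, p, af, n`.
#' @export
simulate_sumstats <- function(panel, phenotype, population = NULL) {
  y <- as.numeric(phenotype)
  n <- nrow(panel$dosage)
  if (length(y) != n) stop2("phenotype length must equal panel sample count")
  X <- panel$dosage
  mx <- colMeans(X)
  sxx <- colSums(X^2) - n * mx^2
  my <- mean(y)
  sxy <- as.vector(crossprod(X, y)) - n * mx * my
  syy <- sum(y^2) - n * my^2
  mono <- sxx <= 0
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  out <- data.frame(
    chrom = panel$variants$chrom, pos = panel$variants$pos,
    id = panel$variants$id, a1 = panel$variants$a1, a2 = panel$variants$a2,
    beta = beta, se = se, p = p, af = mx / 2, n = n
  )
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "n_dropped") <- sum(mono)
  attr(out, "population") <- population
  out
}

#' Simulate an admixture gradient between two populations
#'
#' Each individual receives an admixture fraction `alpha ~ Uniform(0, 1)`;
#' their per-variant frequency is `alpha * p_A + (1 - alpha) * p_B` and
#' genotypes are drawn independently per variant at that frequency. `alpha`
#' is stored in the sample metadata.
#'
#' @param spec_a,spec_b [population_spec()] objects sharing a variant list
#'   (same variant count).
#' @param n number of admixed individuals.
#' @param seed integer seed.
#' @param label population label for the output panel.
#' @inheritParams simulate_genotypes
#' @return a [genotype_panel()] with `samples$alpha`.
#' @export
simulate_admixture_gradient <- function(spec_a, spec_b, n, seed,
                                        label = "ADMIX", chrom = "1",
                                        bp_spacing = 5000, pos_start = 1) {
  if (length(spec_a$freq) != length(spec_b$freq)) {
    stop2("spec_a and spec_b must share a variant list")
  }
  set.seed(seed)
  m <- length(spec_a$freq)
  alpha <- stats::runif(n)
  p <- outer(alpha, spec_a$freq) + outer(1 - alpha, spec_b$freq)
  dos <- matrix(stats::rbinom(n * m, 2L, p), n, m)
  storage.mode(dos) <- "integer"
  al <- default_alleles(m)
  variants <- data.frame(
    chrom = chrom,
    pos = as.integer(pos_start + (seq_len(m) - 1L) * bp_spacing),
    id = sprintf("v%05d", seq_len(m)),
    a1 = al$a1, a2 = al$a2,
    freq = colMeans(p)
  )
  samples <- data.frame(
    sample_id = sprintf("%s_%05d", label, seq_len(n)),
    population = label, alpha = alpha
  )
  genotype_panel(dos, variants, samples)
}

#' Simulate a piecewise-linear recombination map
#'
#' Produces a background-rate map with optional rectangular hotspots. The
#' rate column applies to the interval starting at each position (HapMap
#' convention), so the cumulative map is piecewise linear with the rate as
#' its derivative.
#'
#' @param length_bp map extent in bp.
#' @param hotspot_positions sorted hotspot centers in bp (may be empty).
#' @param background_rate background rate in cM/Mb.
#' @param hotspot_rate rate inside hotspots in cM/Mb.
#' @param hotspot_width hotspot width in bp.
#' @return a [recombination_map()].
#' @export
simulate_recomb_map <- function(length_bp, hotspot_positions = numeric(),
                                background_rate = 1, hotspot_rate = 10,
                                hotspot_width = 2000) {
  if (background_rate < 0 || hotspot_rate < 0) stop2("rates must be >= 0")
  if (is.unsorted(hotspot_positions, strictly = TRUE) && length(hotspot_positions) > 1) {
    stop2("hotspot_positions must be sorted")
  }
  pos <- c(1)
  rate <- c(background_rate)
  for (h in hotspot_positions) {
    lo <- max(h - hotspot_width / 2, 1)
    hi <- min(h + hotspot_width / 2, length_bp)
    pos <- c(pos, lo, hi)
    rate <- c(rate, hotspot_rate, background_rate)
  }
  pos <- c(pos, length_bp)
  rate <- c(rate, background_rate)
  keep <- !duplicated(pos)
  recombination_map(pos[keep], rate[keep])
}
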