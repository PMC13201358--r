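# Shared fixture builders. Everything is generated in code at test time.

# Small single-population panel with optional LD.
tiny_panel <- function(n = 500, m = 40, ld_rho = 0, seed = 1, label = "A",
                       freq = NULL, block_size = 1, h2 = 0.5) {
  freq <- freq %||% stats::runif(m, 0.15, 0.85)
  spec <- population_spec(label, n, rep(block_size, m / block_size), freq,
                          ld_rho = ld_rho, h2 = h2)
  simulate_genotypes(spec, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built panel from an explicit dosage matrix.
manual_panel <- function(dosage, pos = NULL, chrom = "1", a1 = NULL, a2 = NULL) {
  m <- ncol(dosage)
  variants <- data.frame(
    chrom = chrom, pos = pos %||% as.integer(seq_len(m) * 1000),
    id = paste0("m", seq_len(m)),
    a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m)
  )
  genotype_panel(dosage, variants)
}

# Summary statistics table built by hand.
manual_sumstats <- function(chrom, pos, a1, a2, beta, p = NULL, af = 0.5,
                            n = 1000, id = NULL) {
  out <- data.frame(chrom = chrom, pos = pos,
                    id = id %||% paste0("s", seq_along(pos)),
                    a1 = a1, a2 = a2, beta = beta, se = 0.1,
                    p = p %||% rep(0.01, length(pos)),
                    af = rep_len(af, length(pos)), n = n)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# Bivariate standard-normal orthant probability P(Z1 < x, Z2 < y | rho),
# by one-dimensional numerical integration (independent copula oracle).
phi2_oracle <- function(x, y, rho) {
  f <- function(u) {
    stats::dnorm(u) * stats::pnorm((y - rho * u) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -Inf, x, rel.tol = 1e-10)$value
}

# Expected genotype (= haplotype) correlation of the thresholded
# bivariate-normal copula model.
copula_genotype_cor <- function(pa, pb, rho) {
  p11 <- phi2_oracle(stats::qnorm(pa), stats::qnorm(pb), rho)
  (p11 - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
}

# Brute-force greedy clumping oracle with a full pairwise r2 matrix.
clump_oracle <- function(sumstats, panel, p_thr, r2_thr, window_kb) {
  key <- prsport:::variant_key(panel$variants$chrom, panel$variants$pos)
  cand <- sumstats[sumstats$p <= p_thr, , drop = FALSE]
  cand <- cand[!is.na(match(prsport:::variant_key(cand$chrom, cand$pos), key)), ]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), , drop = FALSE]
  r2 <- suppressWarnings(stats::cor(panel$dosage))^2
  r2[is.na(r2)] <- 0
  rownames(r2) <- colnames(r2) <- key
  alive <- rep(TRUE, nrow(cand))
  kept <- character()
  ckey <- prsport:::variant_key(cand$chrom, cand$pos)
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept <- c(kept, cand$id[i])
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (cand$chrom[j] == cand$chrom[i] &&
          abs(cand$pos[j] - cand$pos[i]) <= window_kb * 1000 &&
          r2[ckey[i], ckey[j]] > r2_thr) {
        alive[j] <- FALSE
      }
    }
  }
  sort(kept)
}
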