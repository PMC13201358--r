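#!/usr/bin/env Rscript
# Generate the synthetic two-population study inputs and write them in the
# interchange formats (VCF/TSV sumstats/HapMap map), so later steps can be
# rerun from files alone. Writes under results/inputs/.

suppressPackageStartupMessages(library(prsport))
seed <- 42
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- run_config(seed = seed)
set.seed(seed)
n_blocks <- cfg$n_variants %/% cfg$block_size
causal <- sort(sample.int(cfg$n_variants, cfg$n_causal))
p1 <- runif(cfg$n_variants, 0.1, 0.9)
shift <- runif(cfg$n_variants, -cfg$maf_shift, cfg$maf_shift)
p2 <- pmin(pmax(p1 + shift, 0.02), 0.98)

spec1 <- population_spec("POP1", 2000, rep(cfg$block_size, n_blocks), p1,
                         ld_rho = cfg$ld_rho_pop1, h2 = cfg$h2_pop1)
spec2 <- population_spec("POP2", 2000, rep(cfg$block_size, n_blocks), p2,
                         ld_rho = cfg$ld_rho_pop2, h2 = cfg$h2_pop2)
pan1 <- simulate_genotypes(spec1, seed + 1)
pan2 <- simulate_genotypes(spec2, seed + 2)
sim <- simulate_effects_and_phenotypes(list(POP1 = pan1, POP2 = pan2),
                                       architecture_spec(causal,
                                                         rho_b = cfg$rho_b),
                                       h2_per_pop = c(cfg$h2_pop1, cfg$h2_pop2),
                                       seed = seed + 3)
ss <- simulate_sumstats(pan1, sim$phenotypes$POP1$quantitative,
                        population = "POP1")
map <- simulate_recomb_map(max(pan1$variants$pos) + 5000,
                           hotspot_positions = c(8e5, 1.8e6),
                           background_rate = 1, hotspot_rate = 12)

write_vcf(pan1, file.path(out, "pop1.vcf.gz"))
write_vcf(pan2, file.path(out, "pop2.vcf.gz"))
write_sumstats(ss, file.path(out, "sumstats_pop1.tsv.gz"))
write_recomb_map(map, file.path(out, "recomb_map.tsv"))

message("Simulated ", cfg$n_variants, " variants (", cfg$n_causal,
        " causal) for two populations; discovery GWAS on ",
        nrow(pan1$dosage), " samples.")
rt <- read_genotypes(file.path(out, "pop1.vcf.gz"))
message("Round-trip check: ",
        isTRUE(all.equal(unname(rt$dosage), unname(pan1$dosage),
                         check.attributes = FALSE)))
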