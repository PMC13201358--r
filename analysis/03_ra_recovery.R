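#!/usr/bin/env Rscript
# Generative recovery of the relative-accuracy model: 20 replicate
# two-population simulations per regime. In the MAF-only regime the MAF
# prediction should be unbiased for the observed RA; adding divergent LD it
# should over-predict while the LD+MAF prediction captures part of the
# additional loss. Writes results/ra_recovery.tsv.

suppressPackageStartupMessages(library(prsport))
dir.create("results", showWarnings = FALSE)

maf <- experiment_ra_recovery("maf", n_seeds = 20, seed = 101)
ld <- experiment_ra_recovery("ld", n_seeds = 20, seed = 102)
maf$mode <- "maf"
ld$mode <- "ld"
out <- rbind(maf, ld)
write.table(out, "results/ra_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("MAF-only: mean RA_OBS %.4f vs RA_MAF %.4f (bias %+.4f)",
                mean(maf$ra_obs), mean(maf$ra_maf),
                mean(maf$ra_obs - maf$ra_maf)))
message(sprintf("+LD:      mean RA_OBS %.4f vs RA_MAF %.4f vs RA_LD+MAF %.4f",
                mean(ld$ra_obs), mean(ld$ra_maf), mean(ld$ra_ld_maf)))
message("The MAF-only prediction tracks observed RA when PRS SNPs are the")
message("causal variants; with divergent LD it over-predicts, and the")
message("candidate-causal LD correction recovers part of the gap.")
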