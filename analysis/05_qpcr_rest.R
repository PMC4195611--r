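#!/usr/bin/env Rscript
# qPCR arm of the study: efficiency-corrected relative expression of two
# antimicrobial peptides (Diptericin, Drosomycin) and Dscam1, normalized
# to rpL13a, comparing E. coli-exposed to control samples with the
# pair-wise fixed reallocation randomization test (2000 reallocations).
# The simulated Cp shifts emulate the study outcome: strong Diptericin
# induction, mild Drosomycin induction, no Dscam1 change.

suppressPackageStartupMessages(library(mxsplice))

dir.create("results/qpcr", showWarnings = FALSE, recursive = TRUE)

# fly arm: 2 biological replicates per group; Diptericin induced ~93-fold
# (E = 1.979 => shift of log(93)/log(1.979) ~ -6.6 cycles)
fly_cp <- simulate_cp_table(
  effects = c(Diptericin = -6.6, Drosomycin = -0.6, Dscam1 = 0),
  noise_sd = 0.25, n_reps = 2,
  baseline = c(Diptericin = 27, Drosomycin = 25, Dscam1 = 26,
               rpL13a = 18),
  seed = 11)

# S2-cell arm: 3 replicates per group; milder AMP induction
s2_cp <- simulate_cp_table(
  effects = c(Diptericin = -2.5, Drosomycin = -1.8, Dscam1 = 0),
  noise_sd = 0.25, n_reps = 3,
  baseline = c(Diptericin = 26, Drosomycin = 24, Dscam1 = 25,
               rpL13a = 17),
  seed = 12)

run_arm <- function(cp, arm) {
  rows <- lapply(c("Diptericin", "Drosomycin", "Dscam1"), function(g) {
    res <- fixed_reallocation_test(cp, g, "rpL13a",
                                   n_reallocations = 2000, seed = 99)
    print(res)
    data.frame(arm = arm, gene = g, ratio = res$ratio,
               mean_ratio = res$mean_ratio, se_ratio = res$se_ratio,
               p_value = res$p_value,
               n_reallocations = res$n_reallocations,
               exhaustive = res$exhaustive)
  })
  do.call(rbind, rows)
}

cat("== fly arm (2 replicates per group) ==\n")
fly <- run_arm(fly_cp, "fly")
cat("\n== S2-cell arm (3 replicates per group) ==\n")
s2 <- run_arm(s2_cp, "s2")

out <- rbind(fly, s2)
write.table(out, "results/qpcr/relative_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

write.table(fly_cp$values, "results/qpcr/fly_cp_values.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s2_cp$values, "results/qpcr/s2_cp_values.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nNote: with 2 replicates per group the exhaustive reallocation\n")
cat("test has only 6 distinct reallocations (minimum attainable\n")
cat("two-sided p = 1/3), so the fly arm reports effect sizes rather\n")
cat("than significance; the S2 arm (20 reallocations) is similarly\n")
cat("granular, which is why ratios and reallocation SEs are the\n")
cat("primary readout at these sample sizes.\n")
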