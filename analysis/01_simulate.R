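#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohorts.
#
# Builds the default European chromosome pool (published allele-frequency
# marginals and pairwise r2 structure, CNV chromosomes with the nonclassic
# ORF riding duplicated CNR1), then draws:
#   - a case-control sample (405 cases / 919 controls) under an additive
#     model with OR 1.46 per classic-ORF copy and OR 1.2 per 131H copy,
#   - 300 affected-child trios under the same model,
#   - a noisy MLPA probe-ratio table for the controls.
# Everything is seeded; outputs land under results/.

suppressPackageStartupMessages(library(fcgrhap))
dir.create("results", showWarnings = FALSE)
seed <- 20190321

message("building European chromosome pool ...")
pool <- population_pool("EUR")
message(sprintf("  %d chromosome haplotypes; ORF~2B.2 r2 = %.3f",
                nrow(pool),
                pool_r2(pool, "FCGR2C_HAP", "ORF", "FCGR2C_PROM", "2B.2")))

model <- disease_model(log_or = c(FCGR2C_ORF = log(1.46),
                                  FCGR2A_H = log(1.2)),
                       prevalence = 0.01)

message("sampling 405 cases / 919 controls ...")
cc <- sample_case_control(pool, model, 405, 919, seed = seed)
write_genotypes(cc$cases, "results/sim_cases.tsv")
write_genotypes(cc$controls, "results/sim_controls.tsv")

message("sampling 300 affected-child trios ...")
trios <- sample_trios(pool, model, 300, seed = seed + 1)
write_trios(trios, "results/sim_trios.tsv")

message("simulating MLPA probe ratios for the controls (noise sd 0.05) ...")
probes <- simulate_mlpa(cc$controls, noise_sd = 0.05, seed = seed + 2)
write_probe_ratios(probes, "results/sim_probe_ratios.tsv")

message("done: results/sim_cases.tsv, sim_controls.tsv, sim_trios.tsv, ",
        "sim_probe_ratios.tsv")
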