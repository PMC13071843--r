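#!/usr/bin/env Rscript
# Step 2 -- base-case comparison: SOC vs SOC + eConsult triage.
#
# Runs paired (common-random-number) replications of both strategies at the
# calibrated arrival rate, reports per-patient means/SDs of wait times,
# costs, QALYs and net monetary benefit, the incremental comparison, and the
# population totals, from both the societal and healthcare perspectives.

suppressPackageStartupMessages(library(headsim))
dir.create("results", showWarnings = FALSE)

params <- make_base_fixture()
n_reps <- 10  # replication count for the stored tables

soc <- run_replications(params, "SOC", n_reps = n_reps)
las <- run_replications(params, "LASOO_SOC", n_reps = n_reps)
print(soc)
print(las)
cmp <- compare_strategies(las, soc, params$wtp)
print(cmp)
pop <- population_scale(cmp, params$alberta_headache_population,
                        cad_to_usd = params$cad_to_usd)
cat(sprintf("Population totals (n = %.1fM over 5 y): savings CAD %.2fB, %.0f QALYs, iNMB CAD %.2fB\n",
            params$alberta_headache_population / 1e6,
            pop$cost_savings_cad / 1e9, pop$qalys_gained, pop$inmb_cad / 1e9))

write_replication_csv(soc, "results/base_replications_soc.csv")
write_replication_csv(las, "results/base_replications_lasoo.csv")

pooled <- rbind(
  data.frame(strategy = "SOC", stat = "mean", t(soc$pooled_mean), check.names = FALSE),
  data.frame(strategy = "SOC", stat = "sd", t(soc$pooled_sd), check.names = FALSE),
  data.frame(strategy = "LASOO_SOC", stat = "mean", t(las$pooled_mean), check.names = FALSE),
  data.frame(strategy = "LASOO_SOC", stat = "sd", t(las$pooled_sd), check.names = FALSE))
write.csv(pooled, "results/base_pooled_summary.csv", row.names = FALSE)
write_comparison_json(cmp, "results/base_comparison.json",
                      extra = list(population = as.list(pop)))

# healthcare perspective (productivity losses excluded from totals)
soc_hc <- run_replications(params, "SOC", n_reps = n_reps,
                           perspective = "healthcare")
las_hc <- run_replications(params, "LASOO_SOC", n_reps = n_reps,
                           perspective = "healthcare")
cmp_hc <- compare_strategies(las_hc, soc_hc, params$wtp)
cat("\nHealthcare perspective:\n")
print(cmp_hc)
write_comparison_json(cmp_hc, "results/base_comparison_healthcare.json")

write_manifest("results/base_manifest.json", headsim_config_path(),
               seed = params$seed, command = "analysis/02_base_case.R",
               outputs = c("results/base_replications_soc.csv",
                           "results/base_replications_lasoo.csv",
                           "results/base_pooled_summary.csv",
                           "results/base_comparison.json",
                           "results/base_comparison_healthcare.json"))
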