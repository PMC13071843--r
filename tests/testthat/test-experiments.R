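test_that("replication sets pool their members and are reproducible", {
  p <- small_params(arrival_rate = 80, horizon = 120)
  rs <- run_replications(p, "SOC", n_reps = 3, base_seed = 7)
  expect_equal(rs$pooled_mean, colMeans(rs$rep_means))
  expect_equal(nrow(rs$rep_means), 3)
  rs2 <- run_replications(p, "SOC", n_reps = 3, base_seed = 7)
  expect_identical(rs$rep_means, rs2$rep_means)
  expect_identical(rs$seeds, rs2$seeds)

  one <- run_replications(p, "SOC", n_reps = 1, base_seed = 7)
  expect_false(one$sd_defined)
  expect_true(all(is.na(one$pooled_sd)))
  expect_equal(one$pooled_mean, one$rep_means[1, ])
})

test_that("paired comparison deltas vanish when strategies coincide", {
  p <- small_params(arrival_rate = 100, horizon = 120)
  p$consent_rate <- 0
  soc <- run_replications(p, "SOC", n_reps = 3, base_seed = 5)
  las <- run_replications(p, "LASOO_SOC", n_reps = 3, base_seed = 5)
  cmp <- compare_strategies(las, soc, p$wtp)
  expect_true(cmp$paired)
  expect_true(all(cmp$deltas == 0))
  expect_identical(cmp$inmb, 0)
})

test_that("iNMB equals the economics-layer identity on pooled deltas", {
  p <- small_params(arrival_rate = 120, horizon = 150)
  soc <- run_replications(p, "SOC", n_reps = 3, base_seed = 2)
  las <- run_replications(p, "LASOO_SOC", n_reps = 3, base_seed = 2)
  cmp <- compare_strategies(las, soc, p$wtp)
  expect_identical(cmp$inmb,
                   p$wtp * cmp$delta_qaly - cmp$delta_cost)
  expect_warning(compare_strategies(
    run_replications(p, "LASOO_SOC", n_reps = 3, base_seed = 99), soc, p$wtp),
    "unpaired")
})

test_that("scenario tables have one row per scenario x strategy", {
  base <- small_params(arrival_rate = 120, horizon = 120)
  scn <- run_scenarios(base, specs = scenario_specs(c(1, 6)), n_reps = 2,
                       seed = 3)
  expect_equal(nrow(scn$table), 3 * 2)            # base + 2 scenarios
  expect_equal(nrow(scn$rep_table), 3 * 2 * 2)
  expect_equal(nrow(scn$comparisons), 3)
  expect_setequal(unique(scn$table$scenario), c(0, 1, 6))

  only_base <- run_scenarios(base, specs = list(), n_reps = 2, seed = 3)
  expect_equal(nrow(only_base$table), 2)
  expect_equal(only_base$table$scenario, c(0, 0))

  one <- run_scenarios(base, specs = scenario_specs(2), n_reps = 2, seed = 3,
                       include_base = FALSE)
  expect_equal(nrow(one$table), 2)
  expect_true(all(one$table$scenario == 2))
})

test_that("consent threshold analysis pins zero consent at exactly zero iNMB", {
  base <- small_params(arrival_rate = 120, horizon = 120)
  th <- consent_threshold_analysis(base, c(0, 0.5), n_reps = 3, seed = 4)
  expect_equal(nrow(th), 2)
  expect_identical(th$inmb[1], 0)
  expect_true(all(is.finite(th$inmb_se)))
})

test_that("population scaling is linear and zero at zero population", {
  p <- small_params(arrival_rate = 100, horizon = 120)
  soc <- run_replications(p, "SOC", n_reps = 2, base_seed = 6)
  las <- run_replications(p, "LASOO_SOC", n_reps = 2, base_seed = 6)
  cmp <- compare_strategies(las, soc, p$wtp)
  z <- population_scale(cmp, 0)
  expect_true(all(z[c("cost_savings_cad", "qalys_gained", "inmb_cad")] == 0))
  a <- population_scale(cmp, 1.5e6)
  b <- population_scale(cmp, 3.0e6)
  expect_equal(2 * a$cost_savings_cad, b$cost_savings_cad)
  expect_equal(2 * a$inmb_cad, b$inmb_cad)
  expect_equal(b$inmb_usd, convert_cad_usd(b$inmb_cad))
})

test_that("common random numbers shrink the variance of estimated deltas", {
  p <- small_params(arrival_rate = 150, horizon = 150)
  n <- 8
  soc <- run_replications(p, "SOC", n_reps = n, base_seed = 10)
  las_crn <- run_replications(p, "LASOO_SOC", n_reps = n, base_seed = 10)
  las_ind <- run_replications(p, "LASOO_SOC", n_reps = n, base_seed = 7777)
  d_crn <- las_crn$rep_means[, "wait_days"] - soc$rep_means[, "wait_days"]
  d_ind <- las_ind$rep_means[, "wait_days"] - soc$rep_means[, "wait_days"]
  expect_lt(var(d_crn), var(d_ind))
})

test_that("reporting writers produce re-readable files with a faithful manifest", {
  p <- small_params(arrival_rate = 80, horizon = 100)
  rs <- run_replications(p, "SOC", n_reps = 2, base_seed = 1)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "reps.csv")
  write_replication_csv(rs, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 2)
  expect_equal(back$wait_days, unname(rs$rep_means[, "wait_days"]))

  las <- run_replications(p, "LASOO_SOC", n_reps = 2, base_seed = 1)
  cmp <- compare_strategies(las, rs, p$wtp)
  js <- file.path(dir, "cmp.json")
  write_comparison_json(cmp, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$inmb, cmp$inmb)

  r <- simulate_pathways(p, "LASOO_SOC", seed = 2, collect_log = TRUE)
  ev_csv <- file.path(dir, "events.csv")
  write_event_log(r, ev_csv)
  ev <- read.csv(ev_csv)
  expect_equal(nrow(ev), nrow(r$event_log))
  ev_jsonl <- file.path(dir, "events.jsonl")
  write_event_log(r, ev_jsonl, format = "jsonl")
  first <- jsonlite::fromJSON(readLines(ev_jsonl, n = 1))
  expect_equal(first$time, r$event_log$time[1])
  expect_error(write_event_log(simulate_pathways(p, "SOC", seed = 2),
                               ev_csv), "collect_log")

  sj <- file.path(dir, "summary.json")
  write_summary_json(summarize_result(r, p), sj)
  expect_equal(jsonlite::read_json(sj)$strategy, "LASOO_SOC")

  man_path <- file.path(dir, "manifest.json")
  man <- write_manifest(man_path, headsim_config_path(), seed = 1,
                        command = "unit test", outputs = c(csv, js))
  expect_identical(man$config_md5,
                   unname(tools::md5sum(headsim_config_path())))
  expect_true(all(file.exists(unlist(man$outputs))))
  expect_true(file.exists(man_path))
})
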