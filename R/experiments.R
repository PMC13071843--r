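# Experiments layer: paired replications, base-case strategy comparison, the
# seven scenario analyses, the consent-rate threshold analysis, and
# population scaling.

#' Run independent replications of one strategy
#'
#' Replication `k` uses the seed `derive_seed(base_seed, k)`, a deterministic
#' function of the base seed and the replication index only -- not of the
#' strategy -- so SOC and LASOO_SOC replication sets run from the same seeds
#' and are paired by common random numbers.
#'
#' @param params a validated `headsim_params` object.
#' @param strategy `"SOC"` or `"LASOO_SOC"`.
#' @param n_reps number of replications (>= 1).
#' @param base_seed base seed.
#' @param perspective costing perspective passed to [summarize_result()].
#' @return a `headsim_repset`: per-replication summaries, the pooled mean and
#'   the across-replication SD of every outcome, and the seeds used. With a
#'   single replication the SD is `NA` and flagged.
#' @export
run_replications <- function(params, strategy, n_reps = params$n_replications,
                             base_seed = params$seed,
                             perspective = "societal") {
  stopifnot(n_reps >= 1)
  seeds <- vapply(seq_len(n_reps), function(k) derive_seed(base_seed, k),
                  integer(1))
  summaries <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    res <- simulate_pathways(params, strategy, seed = seeds[k])
    summaries[[k]] <- summarize_result(res, params, perspective)
    rm(res)
  }
  mm <- do.call(rbind, lapply(summaries, function(s) s$means))
  extra <- cbind(prop_em = vapply(summaries, `[[`, numeric(1), "prop_em"),
                 nmb = vapply(summaries, `[[`, numeric(1), "nmb"))
  mm <- cbind(mm, extra)
  structure(list(
    strategy = strategy, perspective = perspective, n_reps = n_reps,
    seeds = seeds, summaries = summaries,
    rep_means = mm,
    pooled_mean = colMeans(mm),
    pooled_sd = if (n_reps > 1) apply(mm, 2, sd) else
      setNames(rep(NA_real_, ncol(mm)), colnames(mm)),
    sd_defined = n_reps > 1,
    n_patients = vapply(summaries, function(s) as.numeric(s$n), numeric(1)),
    wtp = params$wtp
  ), class = "headsim_repset")
}

#' Compare two paired replication sets
#'
#' Per-replication deltas (a - b, i.e. intervention minus comparator) are
#' pooled; the incremental net monetary benefit is computed from the pooled
#' mean QALY and cost differences, so `inmb = wtp * delta_qaly - delta_cost`
#' holds exactly. Replication sets run from different seeds trigger a
#' warning (the comparison is then unpaired and its standard errors larger).
#'
#' @param a intervention `headsim_repset` (LASOO_SOC).
#' @param b comparator `headsim_repset` (SOC).
#' @param wtp willingness to pay (CAD/QALY).
#' @return a `headsim_comparison` augmented with per-replication deltas and
#'   their standard errors.
#' @export
compare_strategies <- function(a, b, wtp) {
  stopifnot(inherits(a, "headsim_repset"), inherits(b, "headsim_repset"),
            a$n_reps == b$n_reps)
  paired <- identical(a$seeds, b$seeds)
  if (!paired)
    warning("replication sets use different seeds; comparison is unpaired",
            call. = FALSE)
  deltas <- a$rep_means - b$rep_means
  dm <- colMeans(deltas)
  dse <- if (a$n_reps > 1) apply(deltas, 2, sd) / sqrt(a$n_reps) else
    setNames(rep(NA_real_, ncol(deltas)), colnames(deltas))
  inmb_rep <- wtp * deltas[, "qaly"] - deltas[, "cost_total"]
  structure(list(
    strategy_a = a$strategy, strategy_b = b$strategy, paired = paired,
    n_reps = a$n_reps,
    delta_qaly = dm[["qaly"]], delta_cost = dm[["cost_total"]],
    delta_wait = dm[["wait_days"]],
    delta_means = dm, delta_se = dse, deltas = deltas,
    nmb_a = net_monetary_benefit(a$pooled_mean[["qaly"]],
                                 a$pooled_mean[["cost_total"]], wtp),
    nmb_b = net_monetary_benefit(b$pooled_mean[["qaly"]],
                                 b$pooled_mean[["cost_total"]], wtp),
    inmb = net_monetary_benefit(dm[["qaly"]], dm[["cost_total"]], wtp),
    inmb_se = if (a$n_reps > 1) sd(inmb_rep) / sqrt(a$n_reps) else NA_real_,
    wtp = wtp
  ), class = c("headsim_comparison_reps", "headsim_comparison"))
}

#' Run the scenario analyses
#'
#' Runs the base case plus each scenario under both strategies with paired
#' replications. A scenario flagged `recalibrate` (scenario 5) first re-fits
#' the arrival rate so the SOC mean wait matches the configuration's
#' calibration target under the scenario's capacity.
#'
#' @param base base-case `headsim_params`.
#' @param specs list of scenario specs (see [scenario_specs()]); may be empty,
#'   in which case only the base case is run.
#' @param n_reps replications per strategy.
#' @param wtp willingness to pay.
#' @param seed base seed.
#' @param reps_per_eval replications per calibration evaluation for
#'   recalibrated scenarios.
#' @param include_base include the base case as scenario 0.
#' @return a `headsim_scenarios` list: `table` (one row per scenario x
#'   strategy, pooled outcome means), `rep_table` (one row per scenario x
#'   strategy x replication), and `comparisons` (one row per scenario).
#' @export
run_scenarios <- function(base, specs = scenario_specs(), n_reps = 10,
                          wtp = base$wtp, seed = base$seed,
                          reps_per_eval = 2, include_base = TRUE) {
  runs <- list()
  if (include_base)
    runs <- list(list(id = 0L, description = "base case", params = base))
  for (sp in specs) {
    pars <- make_scenario(base, sp)
    if (isTRUE(attr(pars, "recalibrate"))) {
      cal <- calibrate_arrival_rate(pars, reps_per_eval = reps_per_eval,
                                    seed = seed)
      pars$arrival_rate <- cal$arrival_rate
    }
    runs[[length(runs) + 1]] <- list(id = sp$id, description = sp$description,
                                     params = pars)
  }
  rows <- list()
  reprows <- list()
  cmps <- list()
  for (rn in runs) {
    soc <- run_replications(rn$params, "SOC", n_reps, seed)
    las <- run_replications(rn$params, "LASOO_SOC", n_reps, seed)
    cmp <- compare_strategies(las, soc, wtp)
    for (rs in list(soc, las)) {
      rows[[length(rows) + 1]] <- data.frame(
        scenario = rn$id, description = rn$description, strategy = rs$strategy,
        t(rs$pooled_mean), prop_em = rs$pooled_mean[["prop_em"]],
        check.names = FALSE)
      reprows[[length(reprows) + 1]] <- data.frame(
        scenario = rn$id, strategy = rs$strategy, rep = seq_len(rs$n_reps),
        seed = rs$seeds, rs$rep_means, check.names = FALSE)
    }
    cmps[[length(cmps) + 1]] <- data.frame(
      scenario = rn$id, description = rn$description,
      delta_wait = cmp$delta_wait, delta_cost = cmp$delta_cost,
      delta_qaly = cmp$delta_qaly, inmb = cmp$inmb, inmb_se = cmp$inmb_se,
      arrival_rate = rn$params$arrival_rate)
  }
  structure(list(table = do.call(rbind, rows),
                 rep_table = do.call(rbind, reprows),
                 comparisons = do.call(rbind, cmps),
                 n_reps = n_reps, wtp = wtp, seed = seed),
            class = "headsim_scenarios")
}

#' Consent-rate threshold analysis
#'
#' Sweeps the eConsult consent rate over a grid and reports the incremental
#' net monetary benefit (with Monte-Carlo standard errors from paired
#' replications) at each grid point. With consent 0 the strategies coincide
#' patient-by-patient, so the iNMB there is exactly 0.
#'
#' @param base base-case `headsim_params`.
#' @param consent_grid probabilities in \[0, 1\].
#' @param n_reps paired replications per grid point.
#' @param wtp willingness to pay.
#' @param seed base seed.
#' @return data frame: `consent_rate`, `inmb`, `inmb_se`, `delta_wait`,
#'   `delta_qaly`, `delta_cost`.
#' @export
consent_threshold_analysis <- function(base, consent_grid, n_reps = 10,
                                       wtp = base$wtp, seed = base$seed) {
  stopifnot(all(consent_grid >= 0 & consent_grid <= 1))
  soc <- run_replications(base, "SOC", n_reps, seed)
  out <- lapply(consent_grid, function(cr) {
    p <- base
    p$consent_rate <- cr
    las <- run_replications(p, "LASOO_SOC", n_reps, seed)
    cmp <- compare_strategies(las, soc, wtp)
    data.frame(consent_rate = cr, inmb = cmp$inmb, inmb_se = cmp$inmb_se,
               delta_wait = cmp$delta_wait, delta_qaly = cmp$delta_qaly,
               delta_cost = cmp$delta_cost)
  })
  do.call(rbind, out)
}

#' Scale per-patient differences to a population
#'
#' Multiplies the per-patient deltas of a comparison by the number of
#' patients with headaches in the population over the analytic horizon.
#'
#' @param delta a `headsim_comparison`.
#' @param population patient count (>= 0).
#' @param years span the totals describe (metadata only).
#' @param cad_to_usd display conversion rate.
#' @return data frame with total cost savings, QALYs gained, and total iNMB,
#'   in CAD and USD.
#' @export
population_scale <- function(delta, population, years = 5,
                             cad_to_usd = 0.7048) {
  stopifnot(population >= 0)
  tot_cost_saving <- -delta$delta_cost * population
  tot_qaly <- delta$delta_qaly * population
  tot_inmb <- delta$inmb * population
  data.frame(
    population = population, years = years,
    cost_savings_cad = tot_cost_saving,
    cost_savings_usd = convert_cad_usd(tot_cost_saving, cad_to_usd),
    qalys_gained = tot_qaly,
    inmb_cad = tot_inmb,
    inmb_usd = convert_cad_usd(tot_inmb, cad_to_usd)
  )
}

#' @export
print.headsim_repset <- function(x, ...) {
  cat(sprintf("<headsim_repset> %s: %d replications (%s perspective)\n",
              x$strategy, x$n_reps, x$perspective))
  m <- x$pooled_mean
  s <- x$pooled_sd
  cat(sprintf("  wait %.1f (SD %.2f) d | cost %.0f (SD %.0f) CAD | QALY %.4f | EM %.1f%%\n",
              m[["wait_days"]], s[["wait_days"]], m[["cost_total"]],
              s[["cost_total"]], m[["qaly"]], 100 * m[["prop_em"]]))
  invisible(x)
}
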