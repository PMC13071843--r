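# Economic layer: discounted costs (societal or healthcare perspective),
# QALYs, and (incremental) net monetary benefit.
#
# Discounting uses the continuous-time factor (1 + r)^(-t/365.25) by default;
# an annual-step variant ((1 + r)^(-floor(t/365.25))) is available through
# the `discount_method` parameter. Visit costs are charged at event
# occurrence and discounted to t = 0; treatment and productivity costs accrue
# at per-day rates and are discounted by exact integrals of the factor.

#' Discount factor at time t
#' @param t time in days since model start.
#' @param rate annual discount rate.
#' @param method `"continuous"` or `"annual_step"`.
#' @return the discount factor(s) in (0, 1].
#' @export
discount_factor <- function(t, rate, method = "continuous") {
  if (rate == 0) return(rep(1, length(t)))
  if (method == "annual_step") (1 + rate)^(-floor(t / DAYS_PER_YEAR))
  else (1 + rate)^(-t / DAYS_PER_YEAR)
}

#' Exact integral of the discount factor over an interval (in days)
#' @param a,b interval endpoints in days (vectors; `b >= a`).
#' @inheritParams discount_factor
#' @return vector of integral values (days).
#' @export
discount_integral <- function(a, b, rate, method = "continuous") {
  b <- pmax(a, b)
  if (rate == 0) return(b - a)
  if (method == "annual_step") {
    out <- numeric(length(a))
    y_max <- ceiling(max(b, 0) / DAYS_PER_YEAR)
    for (y in seq_len(max(y_max, 1)) - 1) {
      lo <- y * DAYS_PER_YEAR
      hi <- lo + DAYS_PER_YEAR
      out <- out + (1 + rate)^(-y) * pmax(0, pmin(b, hi) - pmax(a, lo))
    }
    out
  } else {
    k <- DAYS_PER_YEAR / log(1 + rate)
    k * ((1 + rate)^(-a / DAYS_PER_YEAR) - (1 + rate)^(-b / DAYS_PER_YEAR))
  }
}

#' Health-state utility from monthly headache days
#'
#' Piecewise-linear interpolation between the MHD knots of the utility map;
#' non-increasing in MHD by construction of the map. MHD values outside the
#' map's domain are clamped to the nearest endpoint with a warning.
#'
#' @param mhd monthly headache days (vector, >= 0).
#' @param utility_map list with parallel `mhd` and `utility` vectors.
#' @return utilities in \[0, 1\].
#' @export
utility_from_mhd <- function(mhd, utility_map) {
  if (any(mhd < 0, na.rm = TRUE)) stop("mhd must be >= 0", call. = FALSE)
  lo <- min(utility_map$mhd)
  hi <- max(utility_map$mhd)
  if (any(mhd < lo | mhd > hi, na.rm = TRUE)) {
    warning("MHD outside the utility map domain [", lo, ", ", hi,
            "]; clamped to the nearest endpoint", call. = FALSE)
    mhd <- pmin(pmax(mhd, lo), hi)
  }
  approx(utility_map$mhd, utility_map$utility, xout = mhd, rule = 2)$y
}

#' Discounted QALYs of a piecewise-constant utility trajectory
#'
#' Integrates utility times the discount factor over each segment and returns
#' the total in years.
#'
#' @param trajectory data frame with columns `start`, `end` (days) and
#'   `utility` (each segment's constant utility in \[0, 1\]).
#' @param discount_rate annual rate.
#' @param method discounting method.
#' @return discounted QALYs (years).
#' @examples
#' tr <- data.frame(start = 0, end = 2 * 365.25, utility = 1)
#' discounted_qaly(tr, 0.015)  # (1 - 1.015^-2) / log(1.015)
#' @export
discounted_qaly <- function(trajectory, discount_rate, method = "continuous") {
  stopifnot(all(c("start", "end", "utility") %in% names(trajectory)))
  if (any(trajectory$utility < 0)) stop("negative utilities are not allowed",
                                        call. = FALSE)
  sum(trajectory$utility *
        discount_integral(trajectory$start, trajectory$end, discount_rate, method)) /
    DAYS_PER_YEAR
}

#' Productivity cost of missed workdays
#' @param missed_days number of missed workdays (>= 0).
#' @param daily_wage average daily wage (CAD/day, >= 0).
#' @return cost in CAD (`missed_days * daily_wage`).
#' @export
productivity_cost <- function(missed_days, daily_wage) {
  if (any(missed_days < 0) || any(daily_wage < 0))
    stop("missed_days and daily_wage must be >= 0", call. = FALSE)
  missed_days * daily_wage
}

#' Discounted cost of effective treatment from its start to the horizon
#'
#' Treatment cost accrues at `annual_cost / 365.25` per day from the start of
#' effective management to the end of the simulation.
#'
#' @param t_start treatment start (days; `0 <= t_start <= horizon`).
#' @param horizon simulation end (days).
#' @param annual_cost CAD per year on treatment.
#' @param discount_rate annual rate.
#' @param method discounting method.
#' @return discounted cost in CAD.
#' @export
treatment_cost <- function(t_start, horizon, annual_cost, discount_rate,
                           method = "continuous") {
  if (any(t_start > horizon)) stop("t_start must not exceed the horizon",
                                   call. = FALSE)
  annual_cost / DAYS_PER_YEAR *
    discount_integral(t_start, rep(horizon, length(t_start)), discount_rate, method)
}

#' Net monetary benefit
#' @param qalys total QALYs.
#' @param total_cost total cost (CAD).
#' @param wtp willingness to pay (CAD/QALY, >= 0).
#' @return NMB in CAD: `wtp * qalys - total_cost`.
#' @export
net_monetary_benefit <- function(qalys, total_cost, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * qalys - total_cost
}

#' Convert CAD to USD for display
#' @param cad amount in CAD.
#' @param rate conversion rate (USD per CAD).
#' @return amount in USD.
#' @export
convert_cad_usd <- function(cad, rate = 0.7048) {
  cad * rate
}

#' Per-patient outcomes of one simulation result
#'
#' Converts a `headsim_result` into one row per patient: wait, visit costs by
#' category, treatment cost, productivity cost, missed workdays, discounted
#' QALYs, end-of-simulation MHD, and the EM flag. Under the healthcare
#' perspective the productivity column is still reported but excluded from
#' `cost_total`; under the societal perspective (default) it is included.
#' `cost_total` equals the sum of the included categories exactly.
#'
#' Missed workdays accrue at `missed_days_coef * MHD / 30.4375` per calendar
#' day (capped at `workdays_per_year / 365.25`), reduced by the same factor
#' as MHD once the patient is effectively managed; recurring NEM visit costs
#' are spread uniformly over the patient's NEM window for discounting
#' (the expected discount factor of a uniformly placed visit).
#'
#' @param result a `headsim_result`.
#' @param params the `headsim_params` the result was generated from.
#' @param perspective `"societal"` or `"healthcare"`.
#' @return a data frame, one row per patient.
#' @export
patient_outcomes <- function(result, params,
                             perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  p <- params
  pt <- result$patients
  rf <- result$referred
  horizon <- result$horizon
  N <- nrow(pt)
  r <- p$discount_rate
  meth <- p$discount_method
  if (N == 0) {
    out <- data.frame(id = integer(0), wait_days = numeric(0),
                      wait_censored = logical(0), cost_pcp = numeric(0),
                      cost_ed = numeric(0), cost_specialist = numeric(0),
                      cost_econsult = numeric(0), cost_visits = numeric(0),
                      cost_treatment = numeric(0), cost_productivity = numeric(0),
                      cost_total = numeric(0), missed_workdays = numeric(0),
                      qaly = numeric(0), mhd_end = numeric(0), em = logical(0))
    return(out)
  }

  arr <- pt$arrival_time
  nem_end <- pmin(pt$t_effective_treatment, horizon)
  nem_end[is.na(nem_end)] <- horizon
  em <- pt$state == "EM"

  # the two discount integrals every accrual reuses: over the NEM window
  # [arrival, nem_end] and over the EM remainder [nem_end, horizon]
  di_nem <- discount_integral(arr, nem_end, r, meth)
  di_em <- discount_integral(nem_end, rep(horizon, N), r, meth)

  # visit costs: the arrival PCP visit at its instant, recurring NEM visits at
  # the average discount over the NEM window, one-off specialist events at
  # their instants
  nem_len <- nem_end - arr
  pos <- nem_len > 0
  avg_disc <- rep(1, N)
  avg_disc[pos] <- di_nem[pos] / nem_len[pos]
  cost_pcp <- p$costs$pcp_visit *
    (discount_factor(arr, r, meth) + (pt$n_pcp_visits - 1L) * avg_disc)
  cost_ed <- p$costs$ed_visit * pt$n_ed_visits * avg_disc

  cost_specialist <- numeric(N)
  ip_ok <- !is.na(rf$ip_start) & rf$ip_start <= horizon
  cost_specialist[rf$patient[ip_ok]] <-
    p$costs$specialist_visit * discount_factor(rf$ip_start[ip_ok], r, meth)

  cost_econsult <- numeric(N)
  r1_ok <- !is.na(rf$r1_end) & rf$r1_end <= horizon
  cost_econsult[rf$patient[r1_ok]] <-
    p$costs$econsult_review * discount_factor(rf$r1_end[r1_ok], r, meth)
  r2_ok <- !is.na(rf$r2_end) & rf$r2_end <= horizon
  cost_econsult[rf$patient[r2_ok]] <- cost_econsult[rf$patient[r2_ok]] +
    p$costs$econsult_review * discount_factor(rf$r2_end[r2_ok], r, meth)

  # treatment accrues over the EM remainder
  cost_treat <- numeric(N)
  cost_treat[em] <- p$costs$treatment_annual / DAYS_PER_YEAR * di_em[em]

  # missed workdays and productivity
  cap <- p$workdays_per_year / DAYS_PER_YEAR
  rate_pre <- pmin(p$missed_days_coef * pt$mhd_baseline / DAYS_PER_MONTH, cap)
  rate_post <- pmin(p$missed_days_coef * pt$mhd_current / DAYS_PER_MONTH, cap)
  missed <- rate_pre * nem_len + rate_post * (horizon - nem_end)
  cost_prod <- if (p$discount_productivity) {
    p$daily_wage * (rate_pre * di_nem + rate_post * di_em)
  } else {
    productivity_cost(missed, p$daily_wage)
  }

  u_pre <- utility_from_mhd(pt$mhd_baseline, p$utility_map)
  u_post <- utility_from_mhd(pt$mhd_current, p$utility_map)
  qaly <- (u_pre * di_nem + u_post * di_em) / DAYS_PER_YEAR

  cost_visits <- cost_pcp + cost_ed + cost_specialist + cost_econsult
  cost_total <- cost_visits + cost_treat +
    if (perspective == "societal") cost_prod else 0

  wait <- rep(NA_real_, N)
  cens <- rep(NA, N)
  idx <- rf$patient
  cens_ref <- is.na(pt$t_specialist_assessment[idx])
  w_ref <- pt$t_specialist_assessment[idx] - rf$t_referral
  w_ref[cens_ref] <- horizon - rf$t_referral[cens_ref]
  wait[idx] <- w_ref
  cens[idx] <- cens_ref

  fast_df(list(id = pt$id, wait_days = wait, wait_censored = cens,
               cost_pcp = cost_pcp, cost_ed = cost_ed,
               cost_specialist = cost_specialist, cost_econsult = cost_econsult,
               cost_visits = cost_visits, cost_treatment = cost_treat,
               cost_productivity = cost_prod, cost_total = cost_total,
               missed_workdays = missed, qaly = qaly,
               mhd_end = pt$mhd_current, em = em))
}

.outcome_cols <- c("wait_days", "cost_pcp", "cost_ed", "cost_specialist",
                   "cost_econsult", "cost_visits", "cost_treatment",
                   "cost_productivity", "cost_total", "missed_workdays",
                   "qaly", "mhd_end")
.count_cols <- c("n_pcp_visits", "n_ed_visits", "n_specialist_visits",
                 "n_econsult_reviews")

#' Summarize one simulation result for one strategy
#'
#' Per-patient means and standard deviations of every outcome (waits over
#' referred patients only, everything else over all patients), visit counts,
#' the proportion effectively managed at the horizon, and the strategy's net
#' monetary benefit at the parameter set's willingness to pay.
#'
#' @inheritParams patient_outcomes
#' @return a `headsim_summary` list.
#' @export
summarize_result <- function(result, params,
                             perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  po <- patient_outcomes(result, params, perspective)
  pt <- result$patients
  n <- nrow(po)
  if (n == 0) {
    return(structure(list(strategy = result$strategy, perspective = perspective,
                          n = 0L, n_referred = 0L, n_censored_wait = 0L,
                          prop_em = NA_real_, means = setNames(
                            rep(NA_real_, length(.outcome_cols) + length(.count_cols)),
                            c(.outcome_cols, .count_cols)),
                          sds = NULL, nmb = NA_real_, seed = result$seed,
                          empty = TRUE),
                     class = "headsim_summary"))
  }
  col <- function(nm) if (nm %in% names(po)) po[[nm]] else pt[[nm]]
  cols <- c(.outcome_cols, .count_cols)
  means <- vapply(cols, function(nm) mean(col(nm), na.rm = TRUE), numeric(1))
  sds <- vapply(cols, function(nm) sd(col(nm), na.rm = TRUE), numeric(1))
  structure(list(
    strategy = result$strategy, perspective = perspective, n = n,
    n_referred = sum(pt$referred),
    n_censored_wait = sum(po$wait_censored, na.rm = TRUE),
    prop_em = mean(po$em),
    means = means, sds = sds,
    nmb = net_monetary_benefit(means[["qaly"]], means[["cost_total"]], params$wtp),
    wtp = params$wtp, seed = result$seed, empty = FALSE
  ), class = "headsim_summary")
}

#' Incremental net monetary benefit between two strategy summaries
#'
#' Differences are intervention minus comparator (`a - b`); a negative cost
#' difference is a saving. The identity `iNMB = wtp * dQALY - dCost` holds
#' exactly.
#'
#' @param a intervention `headsim_summary` (e.g. LASOO_SOC).
#' @param b comparator `headsim_summary` (e.g. SOC).
#' @param wtp willingness to pay (CAD/QALY).
#' @return a `headsim_comparison` list with `delta_qaly`, `delta_cost`,
#'   per-strategy NMB, `inmb`, and `wtp`.
#' @export
incremental_nmb <- function(a, b, wtp) {
  stopifnot(inherits(a, "headsim_summary"), inherits(b, "headsim_summary"))
  dq <- a$means[["qaly"]] - b$means[["qaly"]]
  dc <- a$means[["cost_total"]] - b$means[["cost_total"]]
  structure(list(
    strategy_a = a$strategy, strategy_b = b$strategy,
    delta_qaly = dq, delta_cost = dc,
    delta_wait = a$means[["wait_days"]] - b$means[["wait_days"]],
    nmb_a = net_monetary_benefit(a$means[["qaly"]], a$means[["cost_total"]], wtp),
    nmb_b = net_monetary_benefit(b$means[["qaly"]], b$means[["cost_total"]], wtp),
    inmb = net_monetary_benefit(dq, dc, wtp),
    wtp = wtp
  ), class = "headsim_comparison")
}

#' @export
print.headsim_summary <- function(x, ...) {
  cat(sprintf("<headsim_summary> %s (%s perspective), n = %s\n", x$strategy,
              x$perspective, format(x$n, big.mark = ",")))
  if (!isTRUE(x$empty)) {
    m <- x$means
    cat(sprintf("  wait %.1f d (censored %s/%s) | total cost CAD %.0f | QALY %.4f | EM %.1f%%\n",
                m[["wait_days"]], format(x$n_censored_wait, big.mark = ","),
                format(x$n_referred, big.mark = ","), m[["cost_total"]],
                m[["qaly"]], 100 * x$prop_em))
    cat(sprintf("  NMB at WTP %s: CAD %.0f\n", format(x$wtp, big.mark = ","), x$nmb))
  }
  invisible(x)
}

#' @export
print.headsim_comparison <- function(x, ...) {
  cat(sprintf("<headsim_comparison> %s - %s\n", x$strategy_a, x$strategy_b))
  cat(sprintf("  dWait %.1f d | dCost CAD %.2f | dQALY %.5f\n",
              x$delta_wait, x$delta_cost, x$delta_qaly))
  cat(sprintf("  iNMB at WTP %s: CAD %.0f (USD %.0f)\n",
              format(x$wtp, big.mark = ","), x$inmb, convert_cad_usd(x$inmb)))
  invisible(x)
}
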