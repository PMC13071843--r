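#' @useDynLib headsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx pgamma qpois rexp rgamma rpois runif sd setNames
#' @importFrom utils modifyList write.csv
"_PACKAGE"

HEADACHE_TYPES <- c("migraine", "tension_type", "cluster", "secondary")
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

# Schema of a parameter set: every required field with a short description.
# Grouped exactly as in the YAML configuration.
.param_schema <- function() {
  list(
    arrival_rate = "patients/day presenting at primary care with headache",
    headache_type_probs = "categorical distribution over the four headache types",
    mhd_by_type = "monthly-headache-days specification per type (gamma or fixed)",
    mhd_max = "upper truncation for sampled MHD (days/month)",
    referral_rate_primary = "P(specialist referral | primary headache)",
    referral_rate_secondary = "P(specialist referral | secondary headache)",
    consent_rate = "P(consent to eConsult | referred), intervention arm only",
    p_effective_primary_care = "P(effective management at primary care | not referred)",
    revisit_process_nem = "recurring PCP/ED visit rates per year while NEM",
    capacity = "specialist capacity block",
    workweek = "working days per week and daily service window",
    service_time = "gamma shape/scale of in-person assessment time (minutes)",
    econsult_review_time = "gamma shape/scale of eConsult review time (minutes)",
    more_info_delay_days = "calendar days before a re-review after a more-information request",
    econsult_outcomes = "P over {approve, more_information, in_person}",
    treatment_effectiveness_by_type = "fractional MHD reduction on effective treatment",
    costs = "unit costs in CAD",
    daily_wage = "average daily wage (CAD/day)",
    workdays_per_year = "workdays per year (caps the missed-day accrual rate)",
    missed_days_coef = "missed workdays per headache day",
    utility_map = "MHD -> utility lookup (piecewise-linear)",
    discount_rate = "annual discount rate",
    discount_method = "continuous or annual_step",
    discount_productivity = "whether productivity losses are discounted",
    wtp = "willingness to pay (CAD/QALY)",
    cad_to_usd = "display conversion rate",
    horizon_days = "simulation horizon (days)",
    n_replications = "default number of replications",
    seed = "base random seed",
    alberta_headache_population = "population count for scaling only",
    calibration = "target wait (days) and tolerance for arrival-rate calibration"
  )
}

.optional_fields <- c("provenance", "on_unknown", "stability")

.stop_field <- function(field, msg) {
  stop(sprintf("parameter `%s`: %s", field, msg), call. = FALSE)
}

.chk_num <- function(p, field, lo = 0, hi = Inf, strict_lo = FALSE) {
  x <- p[[field]]
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    .stop_field(field, "must be a single number")
  if (x < lo || x > hi || (strict_lo && x <= lo))
    .stop_field(field, sprintf("value %g outside [%g, %g]%s", x, lo, hi,
                               if (strict_lo) " (must be > lower bound)" else ""))
  invisible(x)
}

.chk_probs <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    .stop_field(field, sprintf("probabilities must lie in [0,1]; got %s",
                               paste(signif(x, 4), collapse = ", ")))
  if (abs(sum(x) - 1) > 1e-9)
    .stop_field(field, sprintf("probabilities must sum to 1 within 1e-9; sum = %.12f",
                               sum(x)))
  invisible(x)
}

#' Validate a parameter set
#'
#' Enforces every structural invariant of the model parameterization: all
#' probability fields in \[0,1\] (categorical distributions summing to 1
#' within 1e-9), non-negative rates/costs/counts, strictly positive gamma
#' shape/scale, and a utility map with values in \[0,1\] that is
#' non-increasing in monthly headache days. Called by [load_parameters()] and
#' by the fixture generators; errors name the offending field and the
#' observed value.
#'
#' @param p a `headsim_params` object or plain named list with the same fields.
#' @return `p`, invisibly, with class `headsim_params`.
#' @export
validate_parameters <- function(p) {
  schema <- .param_schema()
  missing <- setdiff(names(schema), names(p))
  if (length(missing))
    stop("missing required parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  .chk_num(p, "arrival_rate", lo = 0)
  tp <- unlist(p$headache_type_probs)
  if (!setequal(names(tp), HEADACHE_TYPES))
    .stop_field("headache_type_probs",
                paste("must name exactly:", paste(HEADACHE_TYPES, collapse = ", ")))
  .chk_probs(tp[HEADACHE_TYPES], "headache_type_probs")

  for (ty in HEADACHE_TYPES) {
    m <- p$mhd_by_type[[ty]]
    if (is.null(m) || is.null(m$dist))
      .stop_field("mhd_by_type", paste("missing specification for type", ty))
    if (m$dist == "gamma") {
      if (!is.numeric(m$mean) || m$mean <= 0 || !is.numeric(m$sd) || m$sd <= 0)
        .stop_field("mhd_by_type", sprintf("%s: gamma mean and sd must be > 0", ty))
    } else if (m$dist == "fixed") {
      if (!is.numeric(m$value) || m$value < 0)
        .stop_field("mhd_by_type", sprintf("%s: fixed value must be >= 0", ty))
    } else .stop_field("mhd_by_type", sprintf("%s: unknown dist '%s'", ty, m$dist))
  }
  .chk_num(p, "mhd_max", lo = 0, strict_lo = TRUE)

  for (f in c("referral_rate_primary", "referral_rate_secondary", "consent_rate",
              "p_effective_primary_care"))
    .chk_num(p, f, 0, 1)

  rv <- p$revisit_process_nem
  for (f in c("pcp_per_year", "ed_per_year"))
    if (!is.numeric(rv[[f]]) || rv[[f]] < 0)
      .stop_field("revisit_process_nem", paste(f, "must be a number >= 0"))

  cp <- p$capacity
  for (f in c("n_neurologists", "patients_per_specialist_day"))
    if (!is.numeric(cp[[f]]) || cp[[f]] < 0)
      .stop_field("capacity", paste(f, "must be >= 0"))
  for (f in c("frac_headache_neurologists", "frac_headache_visits"))
    if (!is.numeric(cp[[f]]) || cp[[f]] < 0 || cp[[f]] > 1)
      .stop_field("capacity", paste(f, "must lie in [0,1]"))

  ww <- p$workweek
  if (!is.numeric(ww$days_per_week) || ww$days_per_week < 1 || ww$days_per_week > 7)
    .stop_field("workweek", "days_per_week must be in 1..7")
  if (!is.numeric(ww$start_hour) || !is.numeric(ww$end_hour) ||
      ww$start_hour < 0 || ww$end_hour > 24 || ww$end_hour <= ww$start_hour)
    .stop_field("workweek", "need 0 <= start_hour < end_hour <= 24")

  for (f in c("service_time", "econsult_review_time")) {
    g <- p[[f]]
    if (!is.numeric(g$shape) || g$shape <= 0 || !is.numeric(g$scale) || g$scale <= 0)
      .stop_field(f, "gamma shape and scale must be > 0")
  }
  .chk_num(p, "more_info_delay_days", lo = 0)

  eo <- unlist(p$econsult_outcomes)
  need <- c("approve", "more_information", "in_person")
  if (!setequal(names(eo), need))
    .stop_field("econsult_outcomes",
                paste("must name exactly:", paste(need, collapse = ", ")))
  .chk_probs(eo[need], "econsult_outcomes")

  eff <- unlist(p$treatment_effectiveness_by_type)
  if (!setequal(names(eff), HEADACHE_TYPES))
    .stop_field("treatment_effectiveness_by_type", "must cover all four types")
  if (any(eff < 0 | eff > 1))
    .stop_field("treatment_effectiveness_by_type",
                sprintf("values must lie in [0,1]; got %s",
                        paste(signif(eff, 4), collapse = ", ")))

  for (f in c("pcp_visit", "ed_visit", "specialist_visit", "econsult_review",
              "treatment_annual"))
    if (!is.numeric(p$costs[[f]]) || p$costs[[f]] < 0)
      .stop_field("costs", paste(f, "must be a cost >= 0 (CAD)"))

  .chk_num(p, "daily_wage", lo = 0)
  .chk_num(p, "workdays_per_year", lo = 0, hi = 366)
  .chk_num(p, "missed_days_coef", lo = 0, hi = 1)

  um <- p$utility_map
  if (is.null(um$mhd) || is.null(um$utility) || length(um$mhd) != length(um$utility) ||
      length(um$mhd) < 2)
    .stop_field("utility_map", "needs parallel `mhd` and `utility` vectors (>= 2 knots)")
  if (is.unsorted(um$mhd, strictly = TRUE))
    .stop_field("utility_map", "mhd knots must be strictly increasing")
  if (any(um$utility < 0 | um$utility > 1))
    .stop_field("utility_map", sprintf("utilities must lie in [0,1]; got %s",
                                       paste(signif(um$utility, 4), collapse = ", ")))
  if (any(diff(um$utility) > 1e-12))
    .stop_field("utility_map", "utilities must be non-increasing in MHD")

  .chk_num(p, "discount_rate", lo = 0, hi = 1)
  if (!p$discount_method %in% c("continuous", "annual_step"))
    .stop_field("discount_method", "must be 'continuous' or 'annual_step'")
  if (!is.logical(p$discount_productivity))
    .stop_field("discount_productivity", "must be TRUE or FALSE")
  .chk_num(p, "wtp", lo = 0)
  .chk_num(p, "cad_to_usd", lo = 0)
  .chk_num(p, "horizon_days", lo = 0, strict_lo = TRUE)
  .chk_num(p, "n_replications", lo = 1)
  .chk_num(p, "seed", lo = 0, hi = 2^31 - 1)
  .chk_num(p, "alberta_headache_population", lo = 0)

  cb <- p$calibration
  if (!is.numeric(cb$target_wait_days) || cb$target_wait_days <= 0 ||
      !is.numeric(cb$tolerance_days) || cb$tolerance_days <= 0)
    .stop_field("calibration", "target_wait_days and tolerance_days must be > 0")

  class(p) <- "headsim_params"
  invisible(p)
}

#' Load a model parameterization from YAML (or a list)
#'
#' Reads the complete model configuration -- the single source of truth for
#' every rate, probability, distribution, cost, and economic constant the
#' simulation consumes -- and validates it. Unknown top-level keys are
#' rejected or warned about according to the document's own `on_unknown`
#' policy (`"error"`, the default, or `"warn"`).
#'
#' @param config_source path to a YAML file, or an already-parsed named list.
#' @return a validated `headsim_params` object.
#' @examples
#' p <- load_parameters(headsim_config_path())
#' p$consent_rate
#' @export
load_parameters <- function(config_source) {
  if (is.character(config_source)) {
    if (!file.exists(config_source))
      stop("config file not found: ", config_source, call. = FALSE)
    p <- yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    p <- config_source
  } else stop("config_source must be a file path or a named list", call. = FALSE)

  known <- c(names(.param_schema()), .optional_fields)
  unknown <- setdiff(names(p), known)
  if (length(unknown)) {
    policy <- if (is.null(p$on_unknown)) "error" else p$on_unknown
    msg <- paste("unknown parameter field(s):", paste(unknown, collapse = ", "))
    if (identical(policy, "warn")) {
      warning(msg, call. = FALSE)
      p <- p[setdiff(names(p), unknown)]
    } else stop(msg, call. = FALSE)
  }
  p$discount_productivity <- isTRUE(p$discount_productivity)
  validate_parameters(p)
}

#' Path to the shipped base-case configuration
#' @return path of the installed YAML fixture.
#' @export
headsim_config_path <- function() {
  system.file("extdata", "base_params.yaml", package = "headsim", mustWork = TRUE)
}

#' Serialize a parameter set back to YAML
#'
#' Inverse of [load_parameters()]: `load -> write -> load` round-trips to an
#' equal object (numbers are written with 15 significant digits).
#'
#' @param p a `headsim_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "headsim_params") || is.list(p))
  x <- unclass(p)
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' Nominal specialist capacity in headache assessments per workday
#'
#' The transparency/sanity product of the four capacity inputs: neurologist
#' count x fraction assessing headaches x patients seen per specialist-day x
#' fraction of visits that are headache assessments. The simulation itself
#' does not consume this number -- capacity there is parallel servers with
#' gamma service times during working hours -- but the product is the
#' back-of-envelope throughput implied by the capacity block.
#'
#' @param params a `headsim_params` object.
#' @return headache assessment slots per workday.
#' @examples
#' headache_slots_per_day(make_base_fixture())  # 100 x 0.5 x 15 x 0.5 = 375
#' @export
headache_slots_per_day <- function(params) {
  cp <- params$capacity
  cp$n_neurologists * cp$frac_headache_neurologists *
    cp$patients_per_specialist_day * cp$frac_headache_visits
}

# Number of parallel servers (specialists assessing headaches).
n_servers <- function(params) {
  max(1L, as.integer(round(params$capacity$n_neurologists *
                             params$capacity$frac_headache_neurologists)))
}

# Work-hours calendar derived from the workweek block: the daily service
# window is shrunk by the fraction of specialist visits that are headache
# assessments (that fraction of the workday is available to this patient
# stream).
calendar_from <- function(params) {
  ww <- params$workweek
  list(dpw = as.integer(ww$days_per_week),
       s = ww$start_hour / 24,
       h = (ww$end_hour - ww$start_hour) / 24 * params$capacity$frac_headache_visits)
}

#' Convert calendar time to cumulative specialist work time
#'
#' Calendar time is in days with `t = 0` at Monday 00:00; the work clock
#' accumulates only during the daily service window on workdays. A calendar
#' instant outside any window maps to the cumulative work time at the next
#' window opening, so converting a referral time gives the earliest moment
#' service could start.
#'
#' @param t calendar times (days).
#' @param cal calendar as returned by the internal constructor; defaults to
#'   the calendar of `params`.
#' @param params a `headsim_params` object (used when `cal` is missing).
#' @return work-clock times (days of service availability).
#' @export
cal_to_work <- function(t, params = NULL, cal = calendar_from(params)) {
  cal_to_work_cpp(as.numeric(t), cal$dpw, cal$s, cal$h)
}

#' Convert cumulative work time back to calendar time
#' @rdname cal_to_work
#' @param w work-clock times.
#' @export
work_to_cal <- function(w, params = NULL, cal = calendar_from(params)) {
  work_to_cal_cpp(as.numeric(w), cal$dpw, cal$s, cal$h)
}

# Mean in-person service time in days of work-clock time.
mean_service_days <- function(params) {
  params$service_time$shape * params$service_time$scale / 1440
}

#' Offered utilization of the in-person specialist queue
#'
#' Referral inflow times mean in-person service time divided by the service
#' capacity the work calendar provides per calendar day. Values above 1 mean
#' the waitlist grows without bound over the horizon.
#'
#' @param params a `headsim_params` object.
#' @return a scalar utilization (rho).
#' @export
queue_utilization <- function(params) {
  tp <- unlist(params$headache_type_probs)[HEADACHE_TYPES]
  frac_ref <- sum(tp[1:3]) * params$referral_rate_primary +
    tp["secondary"] * params$referral_rate_secondary
  lam_ref <- params$arrival_rate * unname(frac_ref)
  cal <- calendar_from(params)
  cap_per_day <- n_servers(params) * cal$dpw * cal$h / 7  # work-days per calendar day
  lam_ref * mean_service_days(params) / cap_per_day
}

#' @export
print.headsim_params <- function(x, ...) {
  cat("<headsim_params>\n")
  cat(sprintf("  arrival rate        : %.4g patients/day\n", x$arrival_rate))
  cat(sprintf("  horizon             : %.2f days; %d replications; seed %d\n",
              x$horizon_days, as.integer(x$n_replications), as.integer(x$seed)))
  cat(sprintf("  referral (prim/sec) : %.3g / %.3g; consent %.3g\n",
              x$referral_rate_primary, x$referral_rate_secondary, x$consent_rate))
  cat(sprintf("  capacity            : %d servers, %d d/wk %g-%gh, slots/day %.0f\n",
              n_servers(x), x$workweek$days_per_week, x$workweek$start_hour,
              x$workweek$end_hour, headache_slots_per_day(x)))
  cat(sprintf("  economics           : WTP %s CAD/QALY, discount %.3g%% (%s)\n",
              format(x$wtp, big.mark = ","), 100 * x$discount_rate, x$discount_method))
  invisible(x)
}
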