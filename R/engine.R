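# Discrete-event simulation of the headache care pathways.
#
# Every patient enters at primary care as NEM (not effectively managed).
# Secondary headaches are referred with probability 1, primary headaches with
# the primary referral rate; non-referred patients become EM at primary care
# with p_effective_primary_care or remain NEM with recurring PCP/ED visits.
# Referred patients join a single FIFO specialist waitlist served by parallel
# specialists during working hours. Under the standard of care (SOC) the
# queued episode is an in-person assessment; under LASOO_SOC a consenting
# patient's episode is instead a short asynchronous eConsult review whose
# outcome is approve (EM without an in-person visit), a more-information
# request (fixed delay, then one re-review), or an in-person visit (a new
# in-person episode joins the waitlist). There is no priority between
# episode kinds: first come, first served in both strategies. Becoming EM
# multiplies MHD (and the missed-workday accrual) by (1 - effectiveness) and
# stops further PCP/ED revisits.

#' Sample exponential interarrival times
#'
#' @param n number of draws.
#' @param arrival_rate arrivals per day (> 0).
#' @return `n` positive interarrival times (days) with mean `1/arrival_rate`.
#' @export
sample_interarrival <- function(n, arrival_rate) {
  if (!is.numeric(arrival_rate) || arrival_rate <= 0)
    stop("arrival_rate must be > 0", call. = FALSE)
  rexp(n, rate = arrival_rate)
}

#' Sample headache types from the categorical distribution
#'
#' @param n number of draws.
#' @param probs named probabilities over the four headache types.
#' @return a character vector of types.
#' @export
assign_headache_type <- function(n, probs) {
  tp <- unlist(probs)[HEADACHE_TYPES]
  if (any(is.na(tp))) stop("probs must name all four headache types", call. = FALSE)
  .chk_probs(tp, "headache_type_probs")
  HEADACHE_TYPES[.type_from_u(runif(n), tp)]
}

# data.frame constructor without per-column validation copies (columns are
# already equal-length atomic vectors; essential at ~1e7 rows).
fast_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}

# Integer type codes (1..4) from pre-drawn uniforms.
.type_from_u <- function(u, probs) {
  findInterval(u, cumsum(probs)[-length(probs)]) + 1L
}

# Per-type MHD draws, truncated at mhd_max. Iterates over the (four) types so
# mixed fixed/gamma specifications work; draw order is deterministic.
sample_mhd <- function(type, params) {
  out <- numeric(length(type))
  for (ti in seq_along(HEADACHE_TYPES)) {
    spec <- params$mhd_by_type[[HEADACHE_TYPES[ti]]]
    idx <- which(type == ti)
    if (!length(idx)) next
    out[idx] <- if (identical(spec$dist, "fixed")) spec$value else {
      sh <- (spec$mean / spec$sd)^2
      rgamma(length(idx), shape = sh, scale = spec$mean / sh)
    }
  }
  pmin(out, params$mhd_max)
}

# Arrival process: cumulative exponential interarrivals on [0, horizon).
draw_arrivals <- function(rate, horizon) {
  if (rate <= 0) return(numeric(0))
  out <- numeric(0)
  t0 <- 0
  repeat {
    n <- max(1000L, ceiling(rate * (horizon - t0) + 6 * sqrt(rate * (horizon - t0) + 1)))
    out <- c(out, t0 + cumsum(rexp(n, rate)))
    t0 <- out[length(out)]
    if (t0 >= horizon) break
  }
  out[out < horizon]
}

.empty_patients <- function() {
  data.frame(id = integer(0), arrival_time = numeric(0),
             headache_type = factor(character(0), levels = HEADACHE_TYPES),
             mhd_baseline = numeric(0), mhd_current = numeric(0),
             state = factor(character(0), levels = c("NEM", "EM")),
             referred = logical(0), consented = logical(0),
             t_referral = numeric(0), t_specialist_assessment = numeric(0),
             t_effective_treatment = numeric(0),
             n_pcp_visits = integer(0), n_ed_visits = integer(0),
             n_specialist_visits = integer(0), n_econsult_reviews = integer(0))
}

.empty_referred <- function() {
  data.frame(patient = integer(0), consented = logical(0),
             outcome1 = integer(0), outcome2 = integer(0),
             t_referral = numeric(0),
             r1_start = numeric(0), r1_end = numeric(0),
             r2_start = numeric(0), r2_end = numeric(0),
             ip_join = numeric(0), ip_start = numeric(0), ip_end = numeric(0),
             resolved_by_review = logical(0),
             resolve_start = numeric(0), resolve_end = numeric(0))
}

#' Run one replication of the pathway simulation
#'
#' Simulates all patient arrivals on `[0, horizon_days)` under one strategy
#' and returns per-patient records, the referred-patient queue detail, and
#' (optionally) a full event log. All randomness is drawn from a single
#' stream seeded with `seed` *before* any strategy-dependent branching, so
#' two calls with the same seed and different strategies see identical
#' patients, identical referral/consent/outcome uniforms, and identical
#' service-time draws: the strategies are coupled by common random numbers,
#' and with `consent_rate = 0` the intervention arm reproduces the SOC arm
#' exactly, patient by patient.
#'
#' @param params a validated `headsim_params` object.
#' @param strategy `"SOC"` or `"LASOO_SOC"`.
#' @param seed integer seed for this replication.
#' @param collect_log also assemble an event log (one row per event; sampled
#'   revisit times are drawn only for the log). Meant for small runs.
#' @return a `headsim_result`: list with `strategy`, `seed`, `horizon`,
#'   `n_patients`, `patients` (one row per patient), `referred` (queue detail
#'   for referred patients, uncensored times), and `event_log` (or `NULL`).
#' @export
simulate_pathways <- function(params, strategy = c("SOC", "LASOO_SOC"),
                              seed = params$seed, collect_log = FALSE) {
  strategy <- match.arg(strategy)
  p <- validate_parameters(params)
  horizon <- p$horizon_days
  cal <- calendar_from(p)
  set.seed(as.integer(seed))

  ## ---- attribute phase: identical across strategies given the seed ----
  t_arr <- draw_arrivals(p$arrival_rate, horizon)
  N <- length(t_arr)
  if (N == 0) {
    res <- list(strategy = strategy, seed = as.integer(seed), horizon = horizon,
                n_patients = 0L, patients = .empty_patients(),
                referred = .empty_referred(),
                event_log = if (collect_log) .empty_log() else NULL)
    class(res) <- "headsim_result"
    return(res)
  }

  tp <- unlist(p$headache_type_probs)[HEADACHE_TYPES]
  type <- .type_from_u(runif(N), tp)
  mhd0 <- sample_mhd(type, p)

  p_ref_by_type <- c(rep(p$referral_rate_primary, 3), p$referral_rate_secondary)
  referred <- runif(N) < p_ref_by_type[type]
  pc_em <- !referred & (runif(N) < p$p_effective_primary_care)

  idx_ref <- which(referred)
  nR <- length(idx_ref)
  u_consent <- runif(nR)
  svc_ip <- rgamma(nR, shape = p$service_time$shape,
                   scale = p$service_time$scale) / 1440
  svc_r1 <- rgamma(nR, shape = p$econsult_review_time$shape,
                   scale = p$econsult_review_time$scale) / 1440
  svc_r2 <- rgamma(nR, shape = p$econsult_review_time$shape,
                   scale = p$econsult_review_time$scale) / 1440
  u_out1 <- runif(nR)
  u_out2 <- runif(nR)
  u_pcp_ref <- runif(nR)
  u_ed_ref <- runif(nR)

  # Revisit windows of non-referred patients do not depend on the strategy,
  # so their Poisson counts are part of the shared attribute block.
  lam_pcp <- p$revisit_process_nem$pcp_per_year / DAYS_PER_YEAR
  lam_ed <- p$revisit_process_nem$ed_per_year / DAYS_PER_YEAR
  len_nonref <- (horizon - t_arr) * (!referred & !pc_em)
  n_pcp_rev <- rpois(N, lam_pcp * len_nonref)
  n_ed_rev <- rpois(N, lam_ed * len_nonref)
  rm(len_nonref)

  ## ---- strategy-dependent pathway ----
  consent <- if (strategy == "LASOO_SOC") u_consent < p$consent_rate
             else rep(FALSE, nR)
  eo <- unlist(p$econsult_outcomes)[c("approve", "more_information", "in_person")]
  out1 <- findInterval(u_out1, cumsum(eo)[-3])        # 0 approve, 1 more info, 2 in person
  p_appr2 <- eo[["approve"]] / (eo[["approve"]] + eo[["in_person"]])
  out2 <- ifelse(u_out2 < p_appr2, 0L, 2L)            # re-review cannot ask again

  t_ref_cal <- t_arr[idx_ref]
  q <- queue_sim_cpp(cal_to_work(t_ref_cal, cal = cal), as.integer(consent),
                     as.integer(out1), as.integer(out2),
                     svc_ip, svc_r1, svc_r2, p$more_info_delay_days,
                     n_servers(p), cal$dpw, cal$s, cal$h)
  qc <- work_to_cal(q, cal = cal)
  dim(qc) <- dim(q)
  colnames(qc) <- c("r1_start", "r1_end", "r2_start", "r2_end",
                    "ip_join", "ip_start", "ip_end")
  rm(q)

  resolved_by_review <- consent & (out1 == 0L | (out1 == 1L & out2 == 0L))
  resolve_start <- qc[, "ip_start"]
  resolve_end <- qc[, "ip_end"]
  first_rev <- resolved_by_review & out1 == 0L
  resolve_start[first_rev] <- qc[first_rev, "r1_start"]
  resolve_end[first_rev] <- qc[first_rev, "r1_end"]
  re_rev <- resolved_by_review & out1 == 1L
  resolve_start[re_rev] <- qc[re_rev, "r2_start"]
  resolve_end[re_rev] <- qc[re_rev, "r2_end"]

  ## ---- per-patient outcomes at the horizon ----
  em_time <- rep(Inf, N)
  em_time[pc_em] <- t_arr[pc_em]
  em_time[idx_ref] <- resolve_end
  em <- em_time <= horizon

  t_assess <- rep(NA_real_, N)
  t_assess[idx_ref] <- ifelse(resolve_start <= horizon, resolve_start, NA_real_)

  eff_by_type <- unlist(p$treatment_effectiveness_by_type)[HEADACHE_TYPES]
  mhd_cur <- mhd0
  mhd_cur[em] <- mhd0[em] * (1 - eff_by_type[type[em]])

  # Referred patients' revisit window ends at effective management (coupled
  # across strategies through per-patient uniforms and the Poisson inverse).
  len_ref <- pmin(em_time[idx_ref], horizon) - t_ref_cal
  n_pcp_rev[idx_ref] <- qpois(u_pcp_ref, lam_pcp * len_ref)
  n_ed_rev[idx_ref] <- qpois(u_ed_ref, lam_ed * len_ref)

  t_em <- rep(NA_real_, N)
  t_em[em] <- em_time[em]

  consented_full <- rep(FALSE, N)
  consented_full[idx_ref] <- consent

  n_spec <- integer(N)
  n_spec[idx_ref] <- as.integer(!is.na(qc[, "ip_start"]) & qc[, "ip_start"] <= horizon)
  n_rev <- integer(N)
  n_rev[idx_ref] <- as.integer(
    (!is.na(qc[, "r1_end"]) & qc[, "r1_end"] <= horizon) +
      (!is.na(qc[, "r2_end"]) & qc[, "r2_end"] <= horizon))

  patients <- fast_df(list(
    id = seq_len(N),
    arrival_time = t_arr,
    headache_type = structure(type, levels = HEADACHE_TYPES, class = "factor"),
    mhd_baseline = mhd0,
    mhd_current = mhd_cur,
    state = structure(1L + as.integer(em), levels = c("NEM", "EM"),
                      class = "factor"),
    referred = referred,
    consented = consented_full,
    t_referral = replace(rep(NA_real_, N), idx_ref, t_ref_cal),
    t_specialist_assessment = t_assess,
    t_effective_treatment = t_em,
    n_pcp_visits = 1L + n_pcp_rev,
    n_ed_visits = n_ed_rev,
    n_specialist_visits = n_spec,
    n_econsult_reviews = n_rev
  ))

  referred_df <- fast_df(list(
    patient = idx_ref, consented = consent,
    outcome1 = as.integer(out1), outcome2 = as.integer(out2),
    t_referral = t_ref_cal,
    r1_start = qc[, "r1_start"], r1_end = qc[, "r1_end"],
    r2_start = qc[, "r2_start"], r2_end = qc[, "r2_end"],
    ip_join = qc[, "ip_join"], ip_start = qc[, "ip_start"], ip_end = qc[, "ip_end"],
    resolved_by_review = resolved_by_review,
    resolve_start = resolve_start, resolve_end = resolve_end
  ))
  # Outcome codes are only meaningful where an eConsult happened.
  referred_df$outcome1[!consent] <- NA_integer_
  referred_df$outcome2[!(consent & out1 == 1L)] <- NA_integer_

  res <- list(strategy = strategy, seed = as.integer(seed), horizon = horizon,
              n_patients = N, patients = patients, referred = referred_df,
              more_info_delay_days = p$more_info_delay_days, event_log = NULL)
  class(res) <- "headsim_result"
  if (collect_log) res$event_log <- .build_event_log(res, p)
  res
}

.empty_log <- function() {
  data.frame(time = numeric(0), patient = integer(0),
             kind = character(0), stringsAsFactors = FALSE)
}

# Assemble the event log from a finished result. Revisit instants are sampled
# uniformly over each patient's NEM window (the order-statistics property of
# the Poisson process) -- they are needed only for the log, not for outcomes.
.build_event_log <- function(res, params) {
  pt <- res$patients
  rf <- res$referred
  horizon <- res$horizon
  ev <- function(time, patient, kind) {
    keep <- !is.na(time) & time <= horizon
    data.frame(time = time[keep], patient = patient[keep],
               kind = rep_len(kind, sum(keep)), stringsAsFactors = FALSE)
  }
  nem_end <- pmin(ifelse(is.na(pt$t_effective_treatment), Inf,
                         pt$t_effective_treatment), horizon)
  rev_times <- function(counts) {
    idx <- rep.int(pt$id, counts)
    len <- (nem_end - pt$arrival_time)[idx]
    data.frame(time = pt$arrival_time[idx] + runif(length(idx)) * len,
               patient = idx, stringsAsFactors = FALSE)
  }
  pcp_rev <- rev_times(pt$n_pcp_visits - 1L)
  ed_rev <- rev_times(pt$n_ed_visits)
  logs <- rbind(
    ev(pt$arrival_time, pt$id, "arrival"),
    ev(pt$arrival_time, pt$id, "pcp_visit"),
    data.frame(pcp_rev, kind = "pcp_visit", stringsAsFactors = FALSE),
    data.frame(ed_rev, kind = "ed_visit", stringsAsFactors = FALSE),
    ev(pt$t_referral, pt$id, "referral"),
    ev(ifelse(pt$consented, pt$t_referral, NA_real_), pt$id, "consent"),
    ev(ifelse(rf$consented, rf$t_referral, NA_real_), rf$patient, "econsult_submitted"),
    ev(ifelse(rf$consented, rf$t_referral, NA_real_), rf$patient, "waitlist_join"),
    ev(ifelse(rf$consented, NA_real_, rf$t_referral), rf$patient, "waitlist_join"),
    ev(rf$ip_join, rf$patient, "waitlist_join"),
    ev(rf$r1_end, rf$patient, "econsult_reviewed"),
    ev(rf$r2_end, rf$patient, "econsult_reviewed"),
    ev(pt$t_specialist_assessment, pt$id, "specialist_assessment"),
    ev(pt$t_effective_treatment, pt$id, "effective_treatment_start")
  )
  # one waitlist_join per queue episode: consenters' first join was logged
  # twice above (submission row + join row) -- drop the duplicated ip_join for
  # non-consenters whose ip_join equals t_referral.
  dup <- logs$kind == "waitlist_join"
  logs <- logs[!duplicated(logs[c("time", "patient", "kind")]) | !dup, ]
  logs <- logs[order(logs$time, logs$patient, logs$kind), ]
  rownames(logs) <- NULL
  logs
}

#' Long-format queue episodes of a result
#'
#' One row per waitlist episode (eConsult review, re-review, or in-person
#' assessment) with calendar join/start/end times, uncensored.
#'
#' @param result a `headsim_result`.
#' @return a data frame with `patient`, `kind`, `join`, `start`, `end`.
#' @export
queue_jobs <- function(result) {
  rf <- result$referred
  piece <- function(keep, kind, join, start, end) {
    data.frame(patient = rf$patient[keep], kind = rep_len(kind, sum(keep)),
               join = join[keep], start = start[keep], end = end[keep],
               stringsAsFactors = FALSE)
  }
  rbind(
    piece(rf$consented, "review", rf$t_referral, rf$r1_start, rf$r1_end),
    # a re-review joins the waitlist a fixed delay after the first review ends
    piece(!is.na(rf$r2_start), "re_review",
          rf$r1_end + result$more_info_delay_days, rf$r2_start, rf$r2_end),
    piece(!is.na(rf$ip_join), "in_person", rf$ip_join, rf$ip_start, rf$ip_end)
  )
}

#' Waitlist statistics of one simulation result
#'
#' The wait per referred patient is the duration between referral and the
#' start of the specialist service episode that resolves them (eConsult
#' review whose outcome is approval, or the in-person assessment). Patients
#' still unresolved at the horizon are censored and contribute their elapsed
#' wait (referral to horizon); the censored count is always reported. Also
#' returns the time-averaged waitlist length (episodes joined but not yet
#' started, averaged over the horizon).
#'
#' @param result a `headsim_result`.
#' @param trajectory also return the queue-length step trajectory.
#' @return a list: `n_referred`, `n_censored`, `mean_wait`, `sd_wait`,
#'   `mean_queue_length`, `empty` flag, and optionally `trajectory`.
#' @export
waitlist_stats <- function(result, trajectory = FALSE) {
  pt <- result$patients
  horizon <- result$horizon
  ref <- pt[pt$referred, ]
  if (nrow(ref) == 0) {
    return(list(n_referred = 0L, n_censored = 0L, mean_wait = NA_real_,
                sd_wait = NA_real_, mean_queue_length = 0, empty = TRUE))
  }
  censored <- is.na(ref$t_specialist_assessment)
  wait <- ifelse(censored, horizon - ref$t_referral,
                 ref$t_specialist_assessment - ref$t_referral)

  # waiting-time integral over episodes: sum of (min(start, T) - min(join, T))
  jobs <- queue_jobs(result)
  wt <- pmin(jobs$start, horizon) - pmin(jobs$join, horizon)
  wt[is.na(wt) | wt < 0] <- 0
  out <- list(n_referred = nrow(ref), n_censored = sum(censored),
              mean_wait = mean(wait), sd_wait = sd(wait),
              mean_queue_length = sum(wt) / horizon, empty = FALSE)
  if (trajectory) {
    tj <- pmin(jobs$join, horizon)
    ts <- pmin(jobs$start, horizon)
    ok <- !is.na(ts) & ts > tj
    times <- c(tj[ok], ts[ok])
    steps <- c(rep(1, sum(ok)), rep(-1, sum(ok)))
    o <- order(times)
    out$trajectory <- data.frame(time = times[o], queue_length = cumsum(steps[o]))
  }
  out
}

#' Exact accounting of referred patients at the horizon
#'
#' Partitions every referred patient into exactly one of: resolved through
#' the eConsult (approved review completed), assessed in person (visit
#' completed), in service (an episode started but not finished at the
#' horizon), or still waiting (in queue, in a more-information delay, or not
#' yet joined). The four counts sum to the number of referred patients.
#'
#' @param result a `headsim_result`.
#' @return named integer vector with components `econsult_resolved`,
#'   `assessed`, `in_service`, `still_waiting`, `referred`.
#' @export
partition_referred <- function(result) {
  rf <- result$referred
  horizon <- result$horizon
  resolved <- rf$resolved_by_review & rf$resolve_end <= horizon
  assessed <- !resolved & !is.na(rf$ip_end) & rf$ip_end <= horizon
  started <- function(s, e) !is.na(s) & s <= horizon & e > horizon
  in_service <- !resolved & !assessed &
    (started(rf$r1_start, rf$r1_end) | started(rf$r2_start, rf$r2_end) |
       started(rf$ip_start, rf$ip_end))
  waiting <- !resolved & !assessed & !in_service
  c(econsult_resolved = sum(resolved), assessed = sum(assessed),
    in_service = sum(in_service), still_waiting = sum(waiting),
    referred = nrow(rf))
}

#' @export
print.headsim_result <- function(x, ...) {
  cat(sprintf("<headsim_result> %s, seed %d: %s patients over %.0f days\n",
              x$strategy, x$seed, format(x$n_patients, big.mark = ","), x$horizon))
  if (x$n_patients > 0) {
    ws <- waitlist_stats(x)
    cat(sprintf("  referred %s (censored %s), mean wait %.1f days; EM at horizon %.1f%%\n",
                format(ws$n_referred, big.mark = ","),
                format(ws$n_censored, big.mark = ","), ws$mean_wait,
                100 * mean(x$patients$state == "EM")))
  }
  invisible(x)
}
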