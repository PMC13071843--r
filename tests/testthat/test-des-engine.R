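test_that("interarrival sampler is exponential with the requested rate", {
  set.seed(101)
  x <- sample_interarrival(1e5, 2)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 0.5) / 0.5, 0.01)
  set.seed(7); a <- sample_interarrival(10, 3)
  set.seed(7); b <- sample_interarrival(10, 3)
  expect_identical(a, b)
  expect_error(sample_interarrival(5, 0), "arrival_rate")
})

test_that("headache types follow the categorical distribution", {
  set.seed(202)
  deg <- assign_headache_type(500, list(migraine = 1, tension_type = 0,
                                        cluster = 0, secondary = 0))
  expect_true(all(deg == "migraine"))

  p <- make_base_fixture()
  x <- assign_headache_type(1e5, p$headache_type_probs)
  probs <- unlist(p$headache_type_probs)
  counts <- table(factor(x, levels = names(probs)))
  gof <- chisq.test(counts, p = probs)
  expect_gt(gof$p.value, 0.001)

  y <- assign_headache_type(1e5, list(migraine = 0.25, tension_type = 0.25,
                                      cluster = 0.25, secondary = 0.25))
  expect_true(all(abs(table(y) / 1e5 - 0.25) < 0.01))
})

test_that("zero arrival rate yields an empty, well-formed result", {
  p <- small_params()
  p$arrival_rate <- 0
  r <- simulate_pathways(p, "SOC", seed = 1, collect_log = TRUE)
  expect_equal(r$n_patients, 0L)
  expect_equal(nrow(r$patients), 0L)
  expect_equal(nrow(r$event_log), 0L)
  ws <- waitlist_stats(r)
  expect_true(ws$empty)
})

test_that("with consent 0 the intervention reproduces SOC patient by patient", {
  p <- small_params(arrival_rate = 120, horizon = 150)
  p$consent_rate <- 0
  a <- simulate_pathways(p, "SOC", seed = 42, collect_log = TRUE)
  b <- simulate_pathways(p, "LASOO_SOC", seed = 42, collect_log = TRUE)
  expect_identical(a$patients, b$patients)
  expect_identical(a$referred[setdiff(names(a$referred), "consented")],
                   b$referred[setdiff(names(b$referred), "consented")])
  expect_identical(a$event_log, b$event_log)
})

test_that("an uncontended referral waits only for the next service window", {
  p <- small_params(arrival_rate = 0.05, horizon = 100)
  p$referral_rate_primary <- 1  # every patient referred, servers mostly idle
  r <- simulate_pathways(p, "SOC", seed = 3)
  pt <- r$patients
  expect_gt(nrow(pt), 0)
  waits <- pt$t_specialist_assessment - pt$t_referral
  expect_true(all(waits[!is.na(waits)] < 4))  # worst case: Friday noon -> Monday 8am
})

test_that("identical (params, strategy, seed) reproduce the event log bitwise", {
  p <- small_params(arrival_rate = 80, horizon = 120)
  a <- simulate_pathways(p, "LASOO_SOC", seed = 9, collect_log = TRUE)
  b <- simulate_pathways(p, "LASOO_SOC", seed = 9, collect_log = TRUE)
  expect_identical(a$event_log, b$event_log)
  expect_identical(a$patients, b$patients)
  c <- simulate_pathways(p, "LASOO_SOC", seed = 10, collect_log = TRUE)
  expect_false(identical(a$patients, c$patients))
})

test_that("event log and patient records satisfy the pathway ordering invariants", {
  p <- small_params(arrival_rate = 150, horizon = 200)
  r <- simulate_pathways(p, "LASOO_SOC", seed = 5, collect_log = TRUE)
  log <- r$event_log
  expect_true(all(log$time <= r$horizon))
  kinds <- c("arrival", "pcp_visit", "ed_visit", "referral", "consent",
             "econsult_submitted", "econsult_reviewed", "waitlist_join",
             "specialist_assessment", "effective_treatment_start")
  expect_true(all(log$kind %in% kinds))
  # per-patient: arrival is the earliest event
  first <- tapply(log$time, log$patient, min)
  arr <- r$patients$arrival_time[as.integer(names(first))]
  expect_equal(as.vector(first), arr)
  # every specialist assessment is preceded by a waitlist join
  asmt <- log[log$kind == "specialist_assessment", ]
  joins <- log[log$kind == "waitlist_join", ]
  jmin <- tapply(joins$time, joins$patient, min)
  expect_true(all(asmt$patient %in% joins$patient))
  expect_true(all(jmin[as.character(asmt$patient)] <= asmt$time + 1e-9))

  # patient-record ordering: arrival <= referral <= assessment <= treatment
  pt <- r$patients
  ok <- function(a, b) all(is.na(a) | is.na(b) | a <= b + 1e-9)
  expect_true(ok(pt$arrival_time, pt$t_referral))
  expect_true(ok(pt$t_referral, pt$t_specialist_assessment))
  expect_true(ok(pt$t_specialist_assessment, pt$t_effective_treatment))
  # EM never reverts and rescales MHD by (1 - effectiveness)
  em <- pt$state == "EM"
  eff <- unlist(p$treatment_effectiveness_by_type)[as.character(pt$headache_type)]
  expect_equal(pt$mhd_current[em], unname((pt$mhd_baseline * (1 - eff))[em]))
  expect_equal(pt$mhd_current[!em], pt$mhd_baseline[!em])
  expect_true(all(pt$mhd_current >= 0))
})

test_that("referred patients are conserved across the four horizon states", {
  for (strat in c("SOC", "LASOO_SOC")) {
    r <- simulate_pathways(small_params(arrival_rate = 200, horizon = 150),
                           strat, seed = 8)
    part <- partition_referred(r)
    expect_identical(sum(part[c("econsult_resolved", "assessed", "in_service",
                                "still_waiting")]), part[["referred"]])
    expect_identical(part[["referred"]], sum(r$patients$referred))
    if (strat == "SOC") expect_identical(part[["econsult_resolved"]], 0L)
  }
})

test_that("waitlist statistics handle a fully censored horizon", {
  p <- small_params(arrival_rate = 400, horizon = 10)  # swamped, tiny horizon
  p$capacity$n_neurologists <- 2
  r <- simulate_pathways(p, "SOC", seed = 2)
  ws <- waitlist_stats(r)
  expect_gt(ws$n_censored, 0)
  pt <- r$patients[r$patients$referred, ]
  cens <- is.na(pt$t_specialist_assessment)
  manual <- mean(ifelse(cens, r$horizon - pt$t_referral,
                        pt$t_specialist_assessment - pt$t_referral))
  expect_equal(ws$mean_wait, manual)
})

test_that("queue waits agree with Erlang-C and Little's law on a toy M/M/2", {
  tq <- make_toy_queue_params(2, 1.5, 1.0, horizon_days = 3000)
  wq <- erlang_wq(2, 1.5, 1)
  waits <- vapply(1:10, function(k) toy_mean_wait(tq, k, warmup = 500),
                  numeric(1))
  ci <- mean(waits) + c(-1, 1) * qt(0.975, 9) * sd(waits) / sqrt(10)
  expect_gt(wq, ci[1])
  expect_lt(wq, ci[2])

  # Little's law: time-averaged queue length ~= arrival rate x mean wait
  r <- simulate_pathways(tq, "SOC", seed = 21)
  ws <- waitlist_stats(r, trajectory = TRUE)
  lam_hat <- ws$n_referred / r$horizon
  expect_lt(abs(ws$mean_queue_length - lam_hat * ws$mean_wait) /
              (lam_hat * ws$mean_wait), 0.05)
  # trajectory integral agrees with the episode-sum computation
  tr <- ws$trajectory
  integ <- sum(diff(c(tr$time, r$horizon)) * tr$queue_length) / r$horizon
  expect_equal(integ, ws$mean_queue_length, tolerance = 1e-8)
})
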