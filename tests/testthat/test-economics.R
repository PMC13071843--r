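test_that("utility lookup interpolates the MHD map and clamps outside it", {
  um <- make_base_fixture()$utility_map
  expect_equal(utility_from_mhd(0, um), max(um$utility))        # best health
  expect_equal(utility_from_mhd(9, um), 0.77)                   # exact knot
  # hand-computed linear interpolation between knots 4 and 9
  expect_equal(utility_from_mhd(6.5, um),
               0.84 + (6.5 - 4) / (9 - 4) * (0.77 - 0.84))
  expect_warning(u <- utility_from_mhd(45, um), "clamped")
  expect_equal(u, min(um$utility))
  expect_error(utility_from_mhd(-1, um), ">= 0")
  # non-increasing on a fine grid
  g <- utility_from_mhd(seq(0, 30, by = 0.25), um)
  expect_true(all(diff(g) <= 1e-12))
})

test_that("discounted QALYs match closed-form integrals", {
  expect_equal(discounted_qaly(data.frame(start = 0, end = 400, utility = 0),
                               0.015), 0)
  expect_equal(discounted_qaly(data.frame(start = 0, end = 365.25, utility = 1),
                               0), 1)
  # u = 1 over two years at 1.5%: integral of 1.015^(-t) dt over [0, 2] years
  expect_equal(discounted_qaly(data.frame(start = 0, end = 2 * 365.25,
                                          utility = 1), 0.015),
               (1 - 1.015^-2) / log(1.015))
  expect_error(discounted_qaly(data.frame(start = 0, end = 1, utility = -0.1),
                               0.015), "negative")
})

test_that("annual-step discounting sums whole-year factors", {
  expect_equal(discount_integral(0, 2 * 365.25, 0.015, "annual_step"),
               365.25 * (1 + 1.015^-1))
  expect_equal(discount_factor(400, 0.015, "annual_step"), 1.015^-1)
  # both methods collapse to the plain interval length at rate 0
  a <- runif(20, 0, 1000); b <- a + runif(20, 0, 1000)
  expect_equal(discount_integral(a, b, 0, "continuous"), b - a)
  expect_equal(discount_integral(a, b, 0, "annual_step"), b - a)
})

test_that("productivity and treatment costs follow their definitions", {
  expect_equal(productivity_cost(0, 250), 0)
  expect_equal(productivity_cost(10, 250), 2500)
  expect_error(productivity_cost(-1, 250), ">= 0")

  expect_equal(treatment_cost(1826.25, 1826.25, 1200, 0.015), 0)
  expect_equal(treatment_cost(0, 365.25, 1200, 0), 1200)
  expect_equal(treatment_cost(0, 5 * 365.25, 1200, 0.015),
               1200 * (1 - 1.015^-5) / log(1.015))
  expect_error(treatment_cost(10, 5, 1200, 0.015), "horizon")
})

test_that("net monetary benefit identities hold exactly", {
  expect_equal(net_monetary_benefit(0.02, 0, 50000), 1000)
  # arithmetic on rounded published deltas: 50,000 x 0.0007 + 1,032 = 1,067
  expect_equal(net_monetary_benefit(0.0007, -1032, 50000), 1067)
  set.seed(33)
  for (i in 1:50) {
    q <- runif(1, 0, 5); cost <- runif(1, -1e5, 1e5); wtp <- runif(1, 0, 1e5)
    expect_identical(net_monetary_benefit(q, cost, wtp), wtp * q - cost)
  }
})

test_that("CAD to USD conversion uses the display rate", {
  expect_equal(convert_cad_usd(50000), 35240)
  expect_equal(convert_cad_usd(0), 0)
  expect_equal(round(convert_cad_usd(1069)), 753)
})

test_that("per-patient cost accounting is exact across perspectives", {
  p <- small_params(arrival_rate = 100, horizon = 150)
  r <- simulate_pathways(p, "LASOO_SOC", seed = 14)
  soc_po <- patient_outcomes(r, p, "societal")
  hc_po <- patient_outcomes(r, p, "healthcare")
  # decomposition sums to the total exactly
  expect_equal(soc_po$cost_total,
               soc_po$cost_pcp + soc_po$cost_ed + soc_po$cost_specialist +
                 soc_po$cost_econsult + soc_po$cost_treatment +
                 soc_po$cost_productivity)
  expect_equal(soc_po$cost_visits,
               soc_po$cost_pcp + soc_po$cost_ed + soc_po$cost_specialist +
                 soc_po$cost_econsult)
  # healthcare total = societal total - productivity, patient by patient
  expect_equal(hc_po$cost_total, soc_po$cost_total - soc_po$cost_productivity)
  expect_true(all(soc_po$cost_total >= hc_po$cost_total))
  expect_true(all(soc_po$cost_total >= 0 & soc_po$qaly >= 0))
})

test_that("universal immediate treatment with full effectiveness zeroes MHD", {
  p <- small_params(arrival_rate = 50, horizon = 100)
  p$referral_rate_primary <- 0
  p$referral_rate_secondary <- 0
  p$p_effective_primary_care <- 1
  for (ty in names(p$treatment_effectiveness_by_type))
    p$treatment_effectiveness_by_type[[ty]] <- 1
  r <- simulate_pathways(p, "SOC", seed = 6)
  s <- summarize_result(r, p)
  expect_equal(s$prop_em, 1)
  expect_equal(s$means[["mhd_end"]], 0)
})

test_that("zero discounting equals undiscounted accrual in patient outcomes", {
  p <- small_params(arrival_rate = 80, horizon = 150)
  p$discount_rate <- 0
  r <- simulate_pathways(p, "LASOO_SOC", seed = 4)
  po <- patient_outcomes(r, p)
  pt <- r$patients
  em <- pt$state == "EM"
  t_em <- pmin(ifelse(is.na(pt$t_effective_treatment), Inf,
                      pt$t_effective_treatment), r$horizon)
  expect_equal(po$cost_treatment[em],
               1200 / 365.25 * (r$horizon - t_em[em]))
  expect_equal(po$cost_productivity, po$missed_workdays * p$daily_wage)
})

test_that("costs are monotone in unit costs and QALYs in utility", {
  p <- small_params(arrival_rate = 80, horizon = 150)
  r <- simulate_pathways(p, "LASOO_SOC", seed = 4)
  po <- patient_outcomes(r, p)
  p2 <- p
  p2$costs$ed_visit <- p$costs$ed_visit * 2
  p2$costs$treatment_annual <- p$costs$treatment_annual * 2
  po2 <- patient_outcomes(r, p2)
  expect_true(all(po2$cost_total >= po$cost_total))
  p3 <- p
  p3$utility_map$utility <- pmin(1, p$utility_map$utility + 0.05)
  po3 <- patient_outcomes(r, p3)
  expect_true(all(po3$qaly >= po$qaly))
})

test_that("incremental NMB of a summary against itself is zero", {
  p <- small_params(arrival_rate = 60, horizon = 100)
  s <- summarize_result(simulate_pathways(p, "SOC", seed = 1), p)
  cmp <- incremental_nmb(s, s, p$wtp)
  expect_identical(cmp$inmb, 0)
  expect_identical(cmp$delta_qaly, 0)
  expect_identical(cmp$delta_cost, 0)
})
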