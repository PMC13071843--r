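test_that("the shipped base configuration carries the published model constants", {
  p <- load_parameters(headsim_config_path())
  expect_s3_class(p, "headsim_params")
  expect_identical(p$consent_rate, 0.75)
  expect_identical(p$referral_rate_primary, 0.02)
  expect_identical(p$referral_rate_secondary, 1.0)
  expect_identical(p$discount_rate, 0.015)
  expect_identical(p$wtp, 50000)
  expect_identical(p$horizon_days, 1826.25)
  expect_identical(p$cad_to_usd, 0.7048)
  expect_identical(p$n_replications, 50L)
  expect_identical(p$workweek$days_per_week, 5L)
  expect_identical(p$workweek$start_hour, 8L)
  expect_identical(p$workweek$end_hour, 16L)
})

test_that("nominal headache slots per workday is the product of the capacity factors", {
  p <- make_base_fixture()
  expect_equal(headache_slots_per_day(p), 100 * 0.5 * 15 * 0.5)  # 375
  p$capacity$frac_headache_visits <- 1.0
  expect_equal(headache_slots_per_day(p), 750)
  p$capacity$n_neurologists <- 0
  expect_equal(headache_slots_per_day(p), 0)
})

test_that("validation names the offending field", {
  base <- unclass(make_base_fixture())

  bad <- base
  bad$headache_type_probs$migraine <- 0.45  # sums to 0.9
  expect_error(load_parameters(bad), "headache_type_probs")

  bad <- base
  bad$wtp <- NULL
  expect_error(load_parameters(bad), "wtp")

  bad <- base
  bad$utility_map$utility <- rev(bad$utility_map$utility)  # increasing in MHD
  expect_error(load_parameters(bad), "utility_map")

  bad <- base
  bad$econsult_outcomes$approve <- 0.80  # sums to 0.9
  expect_error(load_parameters(bad), "econsult_outcomes")
})

test_that("unknown keys follow the document's own policy", {
  base <- unclass(make_base_fixture())
  base$mystery_knob <- 1
  expect_error(load_parameters(base), "mystery_knob")
  base$on_unknown <- "warn"
  expect_warning(p <- load_parameters(base), "mystery_knob")
  expect_null(p$mystery_knob)
})

test_that("load -> serialize -> load round-trips the parameter set", {
  p <- make_base_fixture()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  p2 <- load_parameters(path)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
})

test_that("corrupting any single field is caught at load time", {
  corruptions <- list(
    function(p) { p$consent_rate <- 1.5; p },
    function(p) { p$referral_rate_primary <- -0.1; p },
    function(p) { p$arrival_rate <- -5; p },
    function(p) { p$service_time$shape <- 0; p },
    function(p) { p$econsult_review_time$scale <- -1; p },
    function(p) { p$costs$ed_visit <- -100; p },
    function(p) { p$daily_wage <- -1; p },
    function(p) { p$utility_map$utility[2] <- 1.4; p },
    function(p) { p$utility_map$mhd <- rev(p$utility_map$mhd); p },
    function(p) { p$horizon_days <- 0; p },
    function(p) { p$discount_rate <- -0.01; p },
    function(p) { p$discount_method <- "weekly"; p },
    function(p) { p$mhd_by_type$migraine$sd <- 0; p },
    function(p) { p$treatment_effectiveness_by_type$cluster <- 2; p },
    function(p) { p$workweek$days_per_week <- 9; p },
    function(p) { p$capacity$frac_headache_visits <- 1.2; p },
    function(p) { p$calibration$tolerance_days <- 0; p }
  )
  base <- unclass(make_base_fixture())
  for (corrupt in corruptions) {
    expect_error(load_parameters(corrupt(base)))
  }
})
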