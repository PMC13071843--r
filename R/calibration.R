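# Arrival-rate calibration: tune the arrival rate so the SOC strategy
# reproduces a target mean specialist-assessment wait, leaving every other
# parameter fixed. The objective is the CRN-averaged SOC mean wait (the same
# replication seeds are reused at every candidate rate, which makes the
# search deterministic given a seed and smooths the Monte-Carlo noise), and
# the search is monotone bracketing followed by bisection.

# Deterministic replication seed, shared across strategies so runs pair up.
derive_seed <- function(base_seed, k) {
  s <- (as.numeric(base_seed) + 1000003 * as.numeric(k)) %% 2147483647
  as.integer(s) + 1L
}

.soc_wait <- function(params, rate, reps, seed) {
  waits <- vapply(seq_len(reps), function(k) {
    params$arrival_rate <- rate
    waitlist_stats(simulate_pathways(params, "SOC", seed = derive_seed(seed, k)))$mean_wait
  }, numeric(1))
  c(mean = mean(waits), se = if (reps > 1) sd(waits) / sqrt(reps) else 0)
}

#' Calibrate the arrival rate to a target SOC wait time
#'
#' Finds the arrival rate at which the standard-of-care mean wait (averaged
#' over `reps_per_eval` common-random-number replications) matches
#' `target_wait` within `tolerance`. Bracketing expands geometrically from
#' the parameter set's current rate and checks that the averaged wait is
#' non-decreasing in the rate (beyond Monte-Carlo noise) before bisecting; a
#' target outside the attainable bracket raises an error of class
#' `headsim_calibration_error` carrying the bracket diagnostics.
#'
#' @param params a validated `headsim_params` object.
#' @param target_wait target mean wait in days (> 0).
#' @param tolerance acceptable |achieved - target| in days (> 0).
#' @param reps_per_eval replications averaged per candidate rate.
#' @param seed seed from which per-replication seeds are derived.
#' @param max_iterations bisection iteration cap.
#' @return a `headsim_calibration` list: `arrival_rate`, `achieved_wait`,
#'   `se`, `target_wait`, `tolerance`, `iterations`, `reps_per_eval`,
#'   `converged`, and the `evaluations` table.
#' @export
calibrate_arrival_rate <- function(params,
                                   target_wait = params$calibration$target_wait_days,
                                   tolerance = params$calibration$tolerance_days,
                                   reps_per_eval = 3,
                                   seed = params$seed,
                                   max_iterations = 30) {
  stopifnot(target_wait > 0, tolerance > 0, reps_per_eval >= 1)
  p <- validate_parameters(params)
  evals <- list()
  f <- function(rate) {
    w <- .soc_wait(p, rate, reps_per_eval, seed)
    evals[[length(evals) + 1]] <<- data.frame(rate = rate, wait = w[["mean"]],
                                              se = w[["se"]])
    w
  }
  done <- function(rate, w, iters, converged) {
    structure(list(arrival_rate = rate, achieved_wait = w[["mean"]],
                   se = w[["se"]], target_wait = target_wait,
                   tolerance = tolerance, iterations = iters,
                   reps_per_eval = reps_per_eval, converged = converged,
                   seed = as.integer(seed),
                   evaluations = do.call(rbind, evals)),
              class = "headsim_calibration")
  }
  fail <- function(msg, lo, hi, wlo, whi) {
    stop(structure(class = c("headsim_calibration_error", "error", "condition"),
                   list(message = sprintf(
                     "%s (bracket [%.6g, %.6g] with waits [%.3f, %.3f], target %.3f)",
                     msg, lo, hi, wlo, whi, target_wait),
                     call = NULL)))
  }

  rate0 <- p$arrival_rate
  if (rate0 <= 0) rate0 <- 1
  w0 <- f(rate0)
  if (abs(w0[["mean"]] - target_wait) <= tolerance)
    return(done(rate0, w0, 1L, TRUE))

  lo <- hi <- rate0
  wlo <- whi <- w0
  max_expand <- 12L
  if (w0[["mean"]] < target_wait) {
    for (i in seq_len(max_expand)) {
      hi <- hi * 1.6
      whi <- f(hi)
      if (whi[["mean"]] < wlo[["mean"]] - 3 * (whi[["se"]] + wlo[["se"]] + 1e-9))
        fail("wait decreased while raising the arrival rate", lo, hi,
             wlo[["mean"]], whi[["mean"]])
      if (whi[["mean"]] >= target_wait) break
      lo <- hi
      wlo <- whi
    }
    if (whi[["mean"]] < target_wait)
      fail("target wait unreachable within the rate bracket", lo, hi,
           wlo[["mean"]], whi[["mean"]])
  } else {
    for (i in seq_len(max_expand)) {
      lo <- lo / 1.6
      wlo <- f(lo)
      if (wlo[["mean"]] > whi[["mean"]] + 3 * (whi[["se"]] + wlo[["se"]] + 1e-9))
        fail("wait increased while lowering the arrival rate", lo, hi,
             wlo[["mean"]], whi[["mean"]])
      if (wlo[["mean"]] <= target_wait) break
      hi <- lo
      whi <- wlo
    }
    if (wlo[["mean"]] > target_wait)
      fail("target wait unreachable within the rate bracket", lo, hi,
           wlo[["mean"]], whi[["mean"]])
  }

  iters <- 1L
  repeat {
    mid <- (lo + hi) / 2
    wm <- f(mid)
    iters <- iters + 1L
    if (abs(wm[["mean"]] - target_wait) <= tolerance)
      return(done(mid, wm, iters, TRUE))
    if (iters >= max_iterations)
      return(done(mid, wm, iters, FALSE))
    if (wm[["mean"]] < target_wait) lo <- mid else hi <- mid
  }
}

#' @export
print.headsim_calibration <- function(x, ...) {
  cat(sprintf("<headsim_calibration> rate %.6g/day -> wait %.2f d (target %.1f +/- %.1f)\n",
              x$arrival_rate, x$achieved_wait, x$target_wait, x$tolerance))
  cat(sprintf("  %sconverged in %d iterations (%d reps/eval, MC se %.2f d)\n",
              if (x$converged) "" else "NOT ", x$iterations, x$reps_per_eval, x$se))
  invisible(x)
}
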