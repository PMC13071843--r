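# Closed-form M/M/c oracles, written independently of the simulation engine.

# Erlang-C probability of waiting, offered load a = lambda/mu, c servers.
erlang_c_prob <- function(c, a) {
  stopifnot(a < c)
  k <- 0:(c - 1)
  num <- a^c / factorial(c) * c / (c - a)
  num / (sum(a^k / factorial(k)) + num)
}

# Steady-state expected queue wait Wq of an M/M/c queue.
erlang_wq <- function(c, lambda, mu) {
  erlang_c_prob(c, lambda / mu) / (c * mu - lambda)
}

# Arrival rate that yields a given M/M/1 queue wait (inverse of
# Wq = lambda / (mu * (mu - lambda))).
mm1_rate_for_wq <- function(wq, mu) {
  wq * mu^2 / (1 + wq * mu)
}

# Mean simulated queue wait of a toy configuration, discarding a warm-up
# window and censored patients (steady-state comparison).
toy_mean_wait <- function(params, seed, warmup) {
  r <- simulate_pathways(params, "SOC", seed = seed)
  pt <- r$patients
  keep <- pt$referred & pt$arrival_time > warmup &
    !is.na(pt$t_specialist_assessment)
  mean(pt$t_specialist_assessment[keep] - pt$t_referral[keep])
}
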