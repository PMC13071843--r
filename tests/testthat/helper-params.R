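# Scaled-down configurations for fast tests: same pathway structure as the
# base case but a 2-server system over a shorter horizon.

small_params <- function(arrival_rate = 150, horizon = 200, n_neuro = 4,
                         seed = 1L) {
  p <- make_base_fixture()
  p$arrival_rate <- arrival_rate
  p$horizon_days <- horizon
  p$capacity$n_neurologists <- n_neuro
  p$seed <- as.integer(seed)
  validate_parameters(p)
  p
}
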