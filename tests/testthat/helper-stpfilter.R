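# shared fixtures: the packaged operating point and a smaller synapse for
# cheap property loops
defaults <- default_synapse_params()

small_params <- synapse_params(n_sites = 4, p_release = 0.6, tau_rec = 0.3,
                               tau_syn = 0.002)

# parameter grid for property-style loops over the theory
param_grid <- list(
  list(params = synapse_params(10, 0.5, 0.5, 0.002), rate = 20),
  list(params = synapse_params(5, 0.9, 0.1, 0.005), rate = 5),
  list(params = synapse_params(1, 0.2, 1.0, 0.003), rate = 50),
  list(params = synapse_params(20, 0.7, 0.8, 0.002), rate = 2)
)

expect_within_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * abs(expected))
}
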