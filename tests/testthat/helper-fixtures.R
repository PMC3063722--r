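# shared fixtures; heavyweight simulations are built once per session

# tight options for comparisons against the brute-force oracle: no ridge,
# generous cap, sub-tolerance stopping
tight_ctl <- mne_control(tolerance = 1e-7, l2_penalty = 0,
                         coefficient_cap = 200, max_iterations = 10000)

# a strictly stochastic 2-input gate (interior conditional probabilities)
stochastic_gate <- function() {
  truth_gate(expand.grid(x1 = 0:1, x2 = 0:1)[, c(1, 2)],
             p = c(0.2, 0.6, 0.7, 0.9))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the reference synthetic neuron used by recovery / diagnostic tests
sim_200k <- function() cached("sim_200k", simulate_neuron(200000, seed = 11))
sim_20k <- function() cached("sim_20k", simulate_neuron(20000, seed = 11))

fit2_200k <- function() cached("fit2_200k", fit_mne(sim_200k()$data, order = 2))
fit1_200k <- function() cached("fit1_200k", fit_mne(sim_200k()$data, order = 1))
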