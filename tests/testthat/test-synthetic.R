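test_that("stimulus generation is reproducible and seed-sensitive", {
  a <- generate_stimulus(2000, seed = 5)
  b <- generate_stimulus(2000, seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_false(identical(as.numeric(a),
                         as.numeric(generate_stimulus(2000, seed = 6))))
  expect_error(generate_stimulus(1000), "seed")
})

test_that("the stimulus has the designed correlation time and shape", {
  s <- generate_stimulus(500000, seed = 17)
  # lag equal to the correlation time (10 bins at the defaults): the
  # exponentiation distorts the underlying 1/e decay slightly
  ac <- stats::acf(as.numeric(s), lag.max = 10, plot = FALSE)$acf[11]
  expect_equal(ac, exp(-1), tolerance = 0.2)
  expect_lt(abs(ac - exp(-1)), 0.06)
  mu <- mean(s); sd_ <- stats::sd(s)
  expect_lt(abs(mu), 0.02)
  expect_equal(sd_, 1, tolerance = 0.05)
  skew <- mean((s - mu)^3) / sd_^3
  kurt <- mean((s - mu)^4) / sd_^4 - 3
  expect_gt(skew, 0.5)   # positively skewed
  expect_gt(kurt, 0.5)   # heavy-tailed
  # sigma = 0 falls back to the Gaussian process
  g <- generate_stimulus(200000, seed = 17, sigma = 0)
  expect_lt(abs(mean((g - mean(g))^3)), 0.05)
})

test_that("generated filters are orthonormal and windowed", {
  for (w in c(20, 50)) {
    fl <- generate_filters(w)
    expect_equal(dim(fl), c(w, 2))
    expect_lt(max(abs(crossprod(fl) - diag(2))), 1e-10)
  }
  expect_identical(generate_filters(50), generate_filters(50))
})

test_that("a constant planted model reproduces its firing rate", {
  # P = 0.1 everywhere: exponent log 9
  sim <- simulate_neuron(20000, seed = 23,
                         coefficients = c(log(9), 0, 0))
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(sim$rate - 0.1), 3 * se)
})

test_that("simulation is reproducible and flags degenerate rate regimes", {
  s1 <- simulate_neuron(5000, seed = 42)
  s2 <- simulate_neuron(5000, seed = 42)
  expect_identical(s1$data$y, s2$data$y)
  expect_warning(simulate_neuron(2000, seed = 1,
                                 coefficients = c(-10, 0, 0)),
                 "rate")
})

test_that("planted coefficients are recovered and improve with duration", {
  sim_small <- sim_20k()
  sim_big <- sim_200k()
  tru <- unname(sim_big$model$coefficients)
  rel_err <- function(fit) {
    est <- unname(fit$model$coefficients)
    sqrt(sum((est - tru)^2)) / sqrt(sum(tru^2))
  }
  err_small <- rel_err(fit_mne(sim_small$data, order = 2))
  err_big <- rel_err(fit2_200k())
  expect_lt(err_big, err_small)   # recovery sharpens with duration
  expect_lt(err_big, 0.05)
})

test_that("matched-order fits dominate under-ordered fits in information", {
  sim <- sim_200k()
  i1 <- model_information(fit1_200k(), sim$data)
  i2 <- model_information(fit2_200k(), sim$data)
  expect_lt(i1, i2)
  res <- fit_reduced_models(sim$data, orders = 2) |> suppressWarnings()
  expect_gt(res$reports$percent, 95)
})

test_that("simulation files round trip through the plain-text readers", {
  sim <- simulate_neuron(2000, seed = 3)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  stim <- read_stimulus(file.path(dir, "stimulus.csv"))
  expect_equal(as.numeric(stim), as.numeric(sim$stimulus), tolerance = 1e-12)
  expect_equal(read_spike_times(file.path(dir, "spikes.txt")),
               sim$spike_times, tolerance = 1e-9)
  fl <- read_filters(file.path(dir, "filters.txt"))
  expect_equal(unname(fl), unname(sim$filters), tolerance = 1e-12)
  m <- read_mne_model(file.path(dir, "planted_model.json"))
  expect_identical(unname(m$coefficients), unname(sim$model$coefficients))
})
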