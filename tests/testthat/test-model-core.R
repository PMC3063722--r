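test_that("the logistic convention maps coefficients to probabilities", {
  fm <- feature_map(2, 2, binary_inputs = TRUE)
  m0 <- mne_model(fm, rep(0, 4))
  X <- expand.grid(x1 = 0:1, x2 = 0:1)
  expect_equal(predict(m0, X), rep(0.5, 4))

  # probability is decreasing in the exponent: large positive constant -> 0,
  # large negative -> 1
  expect_lt(predict(mne_model(fm, c(30, 0, 0, 0)), X)[1], 1e-12)
  expect_gt(predict(mne_model(fm, c(-30, 0, 0, 0)), X)[1], 1 - 1e-12)
})

test_that("model constructor validates coefficients", {
  fm <- feature_map(2, 1)
  expect_error(mne_model(fm, c(0, 0)), "coefficients")
  expect_error(mne_model(fm, c(0, 0, Inf)), "finite")
})

test_that("predict is invariant under permuting monomials with coefficients", {
  fm <- feature_map(3, 2)
  set.seed(4)
  theta <- rnorm(length(fm$monomials))
  X <- matrix(rnorm(30), ncol = 3)
  base <- predict(mne_model(fm, theta), X)
  perm <- sample(length(fm$monomials))
  fm_perm <- fm
  fm_perm$monomials <- fm$monomials[perm]
  expect_equal(predict(mne_model(fm_perm, theta[perm]), X), base)
})

test_that("model moments equal direct enumeration over states", {
  fm <- feature_map(2, 1, binary_inputs = TRUE)
  ens <- input_ensemble(expand.grid(x1 = 0:1, x2 = 0:1))
  # constant-zero model: every moment is half the ensemble feature mean
  m0 <- mne_model(fm, rep(0, 3))
  expect_equal(model_moments(m0, ens)$value, c(0.5, 0.25, 0.25))
  # constant model with P = 0.25 everywhere (exponent log 3)
  m25 <- mne_model(fm, c(log(3), 0, 0))
  mm <- model_moments(m25, ens)
  expect_equal(mm$value[mm$term == "1"], 0.25, tolerance = 1e-12)
  expect_equal(mm$value[mm$term == "x1"], 0.125, tolerance = 1e-12)
})

test_that("constant-zero model moments are half the feature means", {
  for (seed in 1:3) {
    set.seed(seed)
    D <- sample(2:4, 1)
    fm <- feature_map(D, 2)
    ens <- input_ensemble(matrix(rnorm(20 * D), ncol = D),
                          weights = runif(20))
    m0 <- mne_model(fm, rep(0, length(fm$monomials)))
    feats <- feature_matrix(fm, ens[seq_len(D)])
    expect_equal(model_moments(m0, ens)$value,
                 unname(0.5 * drop(crossprod(feats, ens$.weight))))
  }
})

test_that("repeated-index monomials are redundant for binary inputs", {
  # the same stochastic table is reached with and without square features
  d <- gate_dataset(stochastic_gate())
  fm_bin <- feature_map(2, 2, binary_inputs = TRUE)
  fm_sq <- feature_map(2, 2, binary_inputs = FALSE)
  f_bin <- fit_mne(d, fm = fm_bin, control = tight_ctl)
  f_sq <- fit_mne(d, fm = fm_sq, control = tight_ctl)
  states <- expand.grid(x1 = 0:1, x2 = 0:1)
  expect_equal(predict(f_bin$model, states), predict(f_sq$model, states),
               tolerance = 1e-6)
})

test_that("model JSON round trip is bit-exact", {
  fm <- feature_map(2, 2, binary_inputs = TRUE)
  set.seed(9)
  model <- mne_model(fm, rnorm(4) * 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_mne_model(model, path)
  back <- read_mne_model(path)
  expect_identical(unname(back$coefficients), unname(model$coefficients))
  expect_equal(back$feature_map$monomials, fm$monomials)
})

test_that("fit JSON carries convergence diagnostics", {
  fit <- fit_mne(gate_dataset(named_gate("AND")), order = 1,
                 binary_inputs = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_mne_fit(fit, path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(payload$converged)
  expect_equal(payload$coefficients, unname(fit$model$coefficients))
  expect_equal(payload$options$l2_penalty, fit$control$l2_penalty)
})
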