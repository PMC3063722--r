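test_that("spike binning uses half-open bins and clips multi-spike bins", {
  y <- bin_spikes(c(0.006, 0.013), duration = 0.02)
  expect_equal(as.integer(y), c(0, 1, 0, 1, 0))
  expect_equal(attr(y, "clipped"), 0)
  expect_warning(y2 <- bin_spikes(c(0.001, 0.002), duration = 0.008),
                 "clipped")
  expect_equal(as.integer(y2), c(1, 0))
  expect_equal(attr(y2, "clipped"), 1)
  expect_equal(as.integer(bin_spikes(numeric(0), duration = 0.02)),
               rep(0L, 5))
  expect_error(bin_spikes(c(0.5), duration = 0.02), "within")
})

test_that("lagged inputs are aligned, oldest first", {
  lag <- build_lagged_inputs(0:9, window_bins = 3)
  expect_equal(nrow(lag), 8)
  expect_equal(unname(lag[1, ]), c(0, 1, 2))
  expect_equal(unname(lag[8, ]), c(7, 8, 9))
  expect_equal(attr(lag, "trim"), 2)
  one <- build_lagged_inputs(rnorm(50), window_bins = 50)
  expect_equal(nrow(one), 1)
  expect_error(build_lagged_inputs(rnorm(10), window_bins = 11), "shorter")
  const <- build_lagged_inputs(rep(2, 6), window_bins = 3)
  expect_true(all(const == 2))
})

test_that("a delta stimulus aligns with the filter peak", {
  # the input for response bin t is the window ending at and including t:
  # with a filter selecting the most recent sample, the projection must peak
  # exactly at the bin where the delta occurred
  w <- 10
  stim <- rep(0, 40); stim[25] <- 1
  lag <- build_lagged_inputs(stim, w)
  pick_now <- matrix(0, w, 2); pick_now[w, 1] <- 1; pick_now[1, 2] <- 1
  s <- project_and_normalize(lag, pick_now)
  expect_equal(which.max(abs(s$s1)) + attr(lag, "trim"), 25)
  # the second filter sees the delta only w-1 bins later
  expect_equal(which.max(abs(s$s2)) + attr(lag, "trim"), 25 + w - 1)
})

test_that("projection normalizes each dimension to [-1, 1]", {
  set.seed(8)
  lag <- build_lagged_inputs(rnorm(500), 50)
  fl <- generate_filters(50)
  s <- project_and_normalize(lag, fl)
  expect_equal(max(abs(s$s1)), 1)
  expect_equal(max(abs(s$s2)), 1)
  expect_true(all(abs(s$s1) <= 1) && all(abs(s$s2) <= 1))
  # orthonormal filters on white noise give uncorrelated projections
  lag_big <- build_lagged_inputs(rnorm(20000), 50)
  s_big <- project_and_normalize(lag_big, fl)
  expect_lt(abs(cor(s_big$s1, s_big$s2)), 0.05)
  bad <- fl; bad[, 2] <- 0
  expect_error(project_and_normalize(lag, bad), "nonzero")
})

test_that("2-D response binning distinguishes empty from silent cells", {
  brf <- bin_response_2d(c(1, 1, -1), c(1, 1, -1), c(1, 0, 0), n_bins = 14)
  expect_equal(sum(brf$occupancy), 3)
  top <- dplyr::filter(brf, bin1 == 14, bin2 == 14)
  expect_equal(top$occupancy, 2)
  expect_equal(top$probability, 0.5)         # (1,1) lands in the last bin
  bottom <- dplyr::filter(brf, bin1 == 1, bin2 == 1)
  expect_equal(bottom$probability, 0)        # sampled, no spikes
  expect_true(all(is.na(
    dplyr::filter(brf, !(bin1 %in% c(1, 14)))$probability)))
  expect_true(all(brf$spikes <= brf$occupancy))
  expect_warning(bin_response_2d(c(0, 1.5), c(0, 0), c(0, 1)), "clipped")
})

test_that("single-cell occupancy reproduces the mean response", {
  y <- c(1, 0, 1, 1)
  brf <- bin_response_2d(rep(0.01, 4), rep(0.01, 4), y)
  cell <- dplyr::filter(brf, occupancy > 0)
  expect_equal(nrow(cell), 1)
  expect_equal(cell$probability, mean(y))
})

test_that("reduced-model information is monotone in the constraint set", {
  sim <- sim_20k()
  f1 <- fit_mne(sim$data, order = 1)
  f2d <- fit_mne(sim$data, order = 2, cross_terms = FALSE)
  f2 <- fit_mne(sim$data, order = 2)
  i1 <- model_information(f1, sim$data)
  i2d <- model_information(f2d, sim$data)
  i2 <- model_information(f2, sim$data)
  expect_lte(i1, i2d + 1e-6)
  expect_lte(i2d, i2 + 1e-6)
})

test_that("responses independent of the inputs carry no information", {
  sim <- sim_20k()
  y_ind <- withr::with_seed(99, rbinom(nrow(sim$data), 1, 0.2))
  d <- response_dataset(data.frame(s1 = sim$data$s1, s2 = sim$data$s2,
                                   y = y_ind))
  res <- fit_reduced_models(d)
  expect_true(all(res$reports$percent < 5))
})

test_that("unconstrained-moment predictions pair model and data", {
  sim <- sim_20k()
  fit <- fit_mne(sim$data, order = 1)
  cmp <- predict_unconstrained_moments(fit, sim$data)
  expect_true(all(c("term", "degree", "predicted", "observed") %in%
                    names(cmp)))
  # constrained rows agree to fit tolerance
  con <- dplyr::filter(cmp, constrained)
  expect_equal(con$predicted, con$observed, tolerance = 1e-4)
  # requesting constrained monomials explicitly warns
  expect_warning(
    predict_unconstrained_moments(fit, sim$data, fm = feature_map(2, 1)),
    "trivially")
  # the constant-1/2 model predicts half the ensemble monomial mean
  m0 <- mne_model(feature_map(2, 2), rep(0, 6))
  cmp0 <- predict_unconstrained_moments(m0, sim$data,
                                        fm = feature_map(2, 1)) |>
    suppressWarnings()
  ens_means <- colMeans(feature_matrix(feature_map(2, 1),
                                       as.matrix(sim$data[c("s1", "s2")])))
  expect_equal(cmp0$predicted, unname(0.5 * ens_means), tolerance = 1e-12)
})

test_that("the cross-term never loses information on any dataset", {
  sim <- sim_20k()
  cc <- suppressWarnings(compare_cross_term(sim$data))
  expect_gte(cc$gain_bits, -1e-9)
  expect_equal(nrow(cc$reports), 2)
  expect_type(cc$mixed_coefficient, "double")
})
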