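test_that("entropies take their closed-form values in bits", {
  ens <- input_ensemble(expand.grid(x1 = 0:1, x2 = 0:1))
  fm <- feature_map(2, 1, binary_inputs = TRUE)
  expect_equal(noise_entropy(mne_model(fm, c(0, 0, 0)), ens), 1)
  # deterministic tables carry exactly zero noise entropy
  expect_identical(noise_entropy(c(0, 1, 1, 0)), 0)
  expect_equal(noise_entropy(rep(0.25, 4)), 0.8112781, tolerance = 1e-7)
  expect_equal(response_entropy(0.5), 1)
  expect_identical(response_entropy(0), 0)
  expect_equal(response_entropy(0.25), 0.8112781, tolerance = 1e-7)
})

test_that("model information separates XOR orders", {
  xor <- gate_dataset(named_gate("XOR"))
  f1 <- fit_mne(xor, order = 1, binary_inputs = TRUE)
  f2 <- fit_mne(xor, order = 2, binary_inputs = TRUE)
  expect_lt(abs(model_information(f1, xor)), 1e-9)
  expect_equal(model_information(f2, xor), 1, tolerance = 1e-3)
  fm <- feature_map(2, 1, binary_inputs = TRUE)
  expect_equal(model_information(mne_model(fm, c(2, 0, 0)), xor), 0)
})

test_that("plug-in mutual information is exact on exact tables", {
  xor <- gate_dataset(named_gate("XOR"))
  st <- interaction(xor$x1, xor$x2)
  expect_equal(empirical_information(xor$y, st, xor$.weight), 1)
  and <- gate_dataset(named_gate("AND"))
  expect_equal(empirical_information(and$y, interaction(and$x1, and$x2),
                                     and$.weight),
               0.8112781, tolerance = 1e-7)
  # response independent of the state
  expect_equal(empirical_information(c(0, 1, 0, 1), c("a", "a", "b", "b")), 0)
  expect_warning(z <- empirical_information(c(0, 1), c("a", "a")), "states")
  expect_identical(z, 0)
})

test_that("information ratios clip, error and report as documented", {
  expect_equal(info_ratio(0, 1), 0)
  expect_equal(info_ratio(1, 1), 1)
  expect_warning(r <- info_ratio(1.01, 1), "clipping")
  expect_equal(r, 1)
  expect_error(info_ratio(0.5, 0), "reference")
  expect_warning(r0 <- info_ratio(1e-12, 0), "undefined")
  expect_true(is.na(r0))
})

test_that("order scans stop at the first sufficient order", {
  xor_scan <- scan_orders(gate_dataset(named_gate("XOR")), max_order = 2,
                          threshold = 90)
  expect_equal(attr(xor_scan, "selected_order"), 2)
  expect_equal(nrow(xor_scan), 2)
  and_scan <- scan_orders(gate_dataset(named_gate("AND")), max_order = 2,
                          threshold = 90)
  expect_equal(attr(and_scan, "selected_order"), 1)
  expect_equal(nrow(and_scan), 1)
  zero_scan <- scan_orders(gate_dataset(named_gate("XOR")), max_order = 2,
                           threshold = 0)
  expect_equal(attr(zero_scan, "selected_order"), 1)
})

test_that("the MinMI chain orders informations on exact ensembles", {
  # 0 <= I(order 1) <= I(order 2) <= I_empirical <= H2(rate)
  for (g in enumerate_gates(2)) {
    d <- gate_dataset(g)
    if (length(unique(d$y)) < 2) next
    st <- interaction(d$x1, d$x2)
    i_emp <- empirical_information(d$y, st, d$.weight)
    i1 <- model_information(fit_mne(d, order = 1, binary_inputs = TRUE), d)
    i2 <- model_information(fit_mne(d, order = 2, binary_inputs = TRUE), d)
    rate <- sum(d$.weight * d$y)
    tol <- 1e-6
    expect_gte(i1, -1e-9)
    expect_lte(i1, i2 + tol)
    expect_lte(i2, i_emp + tol)
    expect_lte(i_emp, h2(rate) + 1e-12)
  }
})

test_that("full-order models capture all information on binary tables", {
  # spot check on a fixed sample; the exhaustive 3-input sweep is in the
  # acceptance suite
  for (gi in c(7, 23, 106, 151, 201)) {
    g <- enumerate_gates(3)[[gi]]
    d <- gate_dataset(g)
    if (length(unique(d$y)) < 2) next
    rep3 <- info_report(fit_mne(d, order = 3, binary_inputs = TRUE,
                                control = tight_ctl), d)
    expect_gt(rep3$percent, 99.5)
  }
})

test_that("report CSV writer produces a readable table", {
  scan <- scan_orders(gate_dataset(named_gate("XOR")), max_order = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(scan, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(scan))
  expect_true(all(c("order", "percent", "converged") %in% names(back)))
})
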