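#' Bin spike times into a binary response sequence
#'
#' Divides `[0, duration)` into half-open bins of width `dt` and sets
#' `y_t = 1` if at least one spike falls in bin t. At 4 ms resolution
#' (the default elsewhere in the package) primate retinal and geniculate
#' responses are effectively binary; bins that nevertheless contain more
#' than one spike are clipped to 1 and counted in the `clipped` attribute
#' with a warning.
#'
#' @param spike_times nondecreasing spike times in seconds.
#' @param duration recording duration in seconds.
#' @param dt bin width in seconds (default 0.004).
#' @return integer 0/1 vector of length `ceiling(duration / dt)` with
#'   attribute `clipped` (number of multi-spike bins).
#' @export
#' @examples
#' bin_spikes(c(0.006, 0.013), duration = 0.02)
bin_spikes <- function(spike_times, duration, dt = 0.004) {
  stopifnot(dt > 0, duration > 0)
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) abort("spike times must be nondecreasing")
  if (any(spike_times < 0 | spike_times > duration)) {
    abort("spike times must lie within [0, duration]")
  }
  n_bins <- ceiling(duration / dt)
  idx <- pmin(floor(spike_times / dt), n_bins - 1) + 1
  counts <- tabulate(idx, nbins = n_bins)
  clipped <- sum(counts > 1)
  if (clipped > 0) {
    warn(sprintf("%d bin(s) contained more than one spike; clipped to 1",
                 clipped))
  }
  structure(as.integer(counts > 0), clipped = clipped)
}

#' Build lagged stimulus input vectors
#'
#' The input associated with response bin t is the window of `window_bins`
#' stimulus bins ending at and including bin t (most recent sample last).
#' The first `window_bins - 1` bins have incomplete history and are dropped;
#' trim the response series with the `trim` attribute to keep alignment.
#'
#' @param stimulus numeric stimulus series, one value per time bin.
#' @param window_bins window length in bins (default 50, i.e. 200 ms at
#'   4 ms resolution).
#' @return numeric matrix, one row per retained time bin, `window_bins`
#'   columns ordered oldest to newest, with attribute `trim` (= number of
#'   dropped leading bins, `window_bins - 1`).
#' @export
#' @examples
#' build_lagged_inputs(0:9, window_bins = 3)[1, ]  # 0 1 2
build_lagged_inputs <- function(stimulus, window_bins = 50) {
  window_bins <- check_count(window_bins, "window_bins")
  stimulus <- as.numeric(stimulus)
  n <- length(stimulus)
  if (n < window_bins) {
    abort("stimulus is shorter than the requested window")
  }
  idx <- outer(seq_len(n - window_bins + 1L) - 1L, seq_len(window_bins), "+")
  out <- matrix(stimulus[idx], nrow = n - window_bins + 1L)
  colnames(out) <- sprintf("lag%d", rev(seq_len(window_bins)) - 1L)
  attr(out, "trim") <- window_bins - 1L
  out
}

# drop the leading bins of a response series to match build_lagged_inputs
trim_response <- function(y, lagged) {
  trim <- attr(lagged, "trim")
  if (length(y) != nrow(lagged) + trim) {
    abort("response length does not match the stimulus the window was built from")
  }
  y[(trim + 1L):length(y)]
}

#' Project stimulus histories onto two temporal filters and normalize
#'
#' Computes the dot product of each lagged stimulus vector with each filter
#' (the convolution of the stimulus with the two receptive-field dimensions)
#' and rescales each projection by its maximum absolute value so the reduced
#' inputs `s1`, `s2` lie in \[-1, 1\] and attain +/-1 somewhere.
#'
#' @param lagged matrix from [build_lagged_inputs()].
#' @param filters a 2-column matrix or data frame, one filter per column,
#'   rows matching the window length.
#' @return a tibble with columns `s1`, `s2`; the scale factors used are in
#'   attribute `scales`.
#' @export
project_and_normalize <- function(lagged, filters) {
  filters <- as_input_matrix(filters)
  if (ncol(filters) == 1L) filters <- t(filters)
  if (nrow(filters) != ncol(lagged)) {
    if (ncol(filters) == ncol(lagged)) filters <- t(filters)
    else abort("filter length does not match the window length")
  }
  if (ncol(filters) != 2L) abort("exactly two filters are required")
  nrm <- sqrt(colSums(filters^2))
  if (any(nrm == 0)) abort("filters must have nonzero norm")
  proj <- lagged %*% filters
  scales <- apply(abs(proj), 2L, max)
  if (any(scales == 0)) scales[scales == 0] <- 1
  out <- tibble(s1 = proj[, 1] / scales[1], s2 = proj[, 2] / scales[2])
  attr(out, "scales") <- scales
  out
}

#' Discretize the 2-D reduced input space and bin the response function
#'
#' Lays a uniform grid of `n_bins x n_bins` cells over \[-1, 1\]^2 (half-open
#' bins, last bin closed) and tabulates per cell the occupancy, the spike
#' count, and the spike probability. Cells never visited have probability
#' `NA` — an *unsampled input*, distinct from a sampled cell where no spike
#' occurred (probability 0). Values outside \[-1, 1\] are clipped into the
#' edge bins and counted in the `clipped` attribute.
#'
#' @param s1,s2 reduced inputs in \[-1, 1\].
#' @param y binary responses.
#' @param n_bins bins per dimension (default 14).
#' @return a tibble of class `mne_brf` with columns `bin1`, `bin2` (1-based
#'   indices), `s1_mid`, `s2_mid` (bin centers), `occupancy`, `spikes`,
#'   `probability`, and attributes `n_bins`, `clipped`, `state` (the per-
#'   observation cell id, usable as the discretization for
#'   [empirical_information()]).
#' @export
bin_response_2d <- function(s1, s2, y, n_bins = 14) {
  n_bins <- check_count(n_bins, "n_bins")
  stopifnot(length(s1) == length(s2), length(s1) == length(y))
  if (!all(y %in% c(0, 1))) abort("responses must be binary (0/1)")
  clipped <- sum(abs(s1) > 1) + sum(abs(s2) > 1)
  if (clipped > 0) {
    warn(sprintf("%d reduced-input value(s) outside [-1, 1]; clipped", clipped))
  }
  b1 <- bin_index(pmin(pmax(s1, -1), 1), n_bins)
  b2 <- bin_index(pmin(pmax(s2, -1), 1), n_bins)
  state <- (b1 - 1L) * n_bins + b2
  occupancy <- tabulate(state, nbins = n_bins^2)
  spikes <- tabulate(state[y == 1], nbins = n_bins^2)
  grid <- tidyr::expand_grid(bin1 = seq_len(n_bins), bin2 = seq_len(n_bins))
  mids <- -1 + (seq_len(n_bins) - 0.5) * 2 / n_bins
  out <- dplyr::mutate(grid,
                       s1_mid = mids[.data$bin1],
                       s2_mid = mids[.data$bin2],
                       occupancy = occupancy[(.data$bin1 - 1L) * n_bins + .data$bin2],
                       spikes = spikes[(.data$bin1 - 1L) * n_bins + .data$bin2],
                       probability = ifelse(.data$occupancy > 0,
                                            .data$spikes / .data$occupancy,
                                            NA_real_))
  attr(out, "n_bins") <- n_bins
  attr(out, "clipped") <- clipped
  attr(out, "state") <- state
  class(out) <- c("mne_brf", class(out))
  out
}

# half-open uniform bins on [-1, 1], last bin closed
bin_index <- function(v, n_bins) {
  idx <- floor((v + 1) / 2 * n_bins) + 1L
  pmin(as.integer(idx), n_bins)
}

#' Fit first- and second-order MNE models in the reduced input space
#'
#' Fits MNE models of the requested orders on the continuous reduced inputs
#' `(s1, s2)`; the empirical reference information is the plug-in mutual
#' information on the `n_bins x n_bins` discretization of the input plane
#' (binning is for the reference and display only — the fits themselves use
#' the continuous inputs).
#'
#' @param data a data frame with columns `s1`, `s2` and binary `y` (e.g.
#'   from [simulate_neuron()] or assembled with [project_and_normalize()]).
#' @param orders interaction orders to fit (default `1:2`).
#' @param cross_terms include the mixed second-order term `s1 s2`?
#' @param n_bins bins per dimension for the empirical reference.
#' @param control an [mne_control()].
#' @return a list of class `mne_reduced_fit` with elements `reports` (tibble,
#'   one [info_report()] row per order), `fits` (list of `mne_fit`), and
#'   `brf` (the [bin_response_2d()] table).
#' @export
fit_reduced_models <- function(data, orders = 1:2, cross_terms = TRUE,
                               n_bins = 14, control = mne_control()) {
  data <- as_mne_data(data)
  if (!all(c("s1", "s2") %in% input_cols(data))) {
    abort("`data` must have reduced-input columns `s1` and `s2`")
  }
  brf <- bin_response_2d(data$s1, data$s2, data$y, n_bins = n_bins)
  states <- attr(brf, "state")
  fits <- lapply(orders, function(k) {
    fit_mne(data, order = k, binary_inputs = FALSE,
            cross_terms = cross_terms, control = control)
  })
  reports <- dplyr::bind_rows(
    lapply(fits, info_report, data = data, states = states))
  structure(list(reports = reports, fits = fits, brf = brf),
            class = "mne_reduced_fit")
}

#' @export
print.mne_reduced_fit <- function(x, ...) {
  cat("<mne_reduced_fit>\n")
  print(dplyr::select(x$reports, "order", "model_information_bits",
                      "reference_information_bits", "percent", "converged"))
  invisible(x)
}

#' Predicted versus observed unconstrained moments
#'
#' A fitted MNE model matches its constrained moments by construction; a
#' sharper diagnostic is how well it predicts moments it was *not*
#' constrained on (e.g. third-order moments for a second-order model). This
#' pairs the model-implied `<y f(x)>` with the empirical value for each
#' requested monomial, for scatter diagnostics; requesting a monomial inside
#' the model's own constraint set triggers a warning (the comparison is
#' trivially exact).
#'
#' @param model an [mne_model()] or `mne_fit`.
#' @param data the dataset (inputs, `y`, optional `.weight`).
#' @param fm a [feature_map()] listing the monomials to compare; default is
#'   all monomials up to degree `order + 1` of the model's map.
#' @return a tibble with columns `term`, `degree`, `predicted`, `observed`,
#'   `constrained`.
#' @export
predict_unconstrained_moments <- function(model, data, fm = NULL) {
  if (inherits(model, "mne_fit")) model <- model$model
  stopifnot(inherits(model, "mne_model"))
  data <- as_mne_data(data)
  mfm <- model$feature_map
  explicit <- !is.null(fm)
  fm <- fm %||% feature_map(mfm$n_inputs, mfm$order + 1L,
                            binary_inputs = mfm$binary_inputs)
  pred <- model_moments(model, data, fm = fm)
  obs <- empirical_moments(data, fm)
  constrained <- names(fm$monomials) %in% names(mfm$monomials)
  if (explicit && any(constrained)) {
    warn("some requested monomials are in the model's constraint set; their comparison is trivially exact")
  }
  tibble(term = pred$term,
         degree = vapply(fm$monomials, length, integer(1)),
         predicted = pred$value,
         observed = obs$value,
         constrained = constrained)
}

#' Compare second-order models with and without the mixed term
#'
#' The mixed second-order coefficient rotates the conic-section contours of
#' the 2-D response function away from the filter axes. This fits the two
#' second-order models that differ only in that term and reports both
#' information ratios together with the fitted mixed coefficient; because
#' the models are nested, the information gain from the cross term is never
#' negative beyond numerical tolerance.
#'
#' @inheritParams fit_reduced_models
#' @return a list with `reports` (two-row tibble, `cross_terms` column),
#'   `gain_bits` (information gain from the mixed term), `mixed_coefficient`
#'   and the two fits.
#' @export
compare_cross_term <- function(data, n_bins = 14, control = mne_control()) {
  with_cross <- fit_reduced_models(data, orders = 2, cross_terms = TRUE,
                                   n_bins = n_bins, control = control)
  without <- fit_reduced_models(data, orders = 2, cross_terms = FALSE,
                                n_bins = n_bins, control = control)
  reports <- dplyr::bind_rows(
    dplyr::mutate(with_cross$reports, cross_terms = TRUE),
    dplyr::mutate(without$reports, cross_terms = FALSE)
  )
  list(reports = reports,
       gain_bits = with_cross$reports$model_information_bits -
         without$reports$model_information_bits,
       mixed_coefficient = unname(with_cross$fits[[1]]$model$coefficients["x1:x2"]),
       fit_with = with_cross$fits[[1]],
       fit_without = without$fits[[1]])
}
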