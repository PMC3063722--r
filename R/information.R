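#' Noise entropy, response entropy and model information
#'
#' The mutual information between inputs and a binary output decomposes as
#' response entropy minus noise entropy. The noise entropy
#' `sum_x P(x) H2(P(y=1|x))` measures output variability to repeated inputs
#' (0 bits for a deterministic system); the response entropy of a binary
#' output is `H2(mean rate)`, fixed entirely by the mean output. A model's
#' information is therefore `H2(rate) - noise entropy`, and — because the
#' MNE solution maximizes noise entropy at fixed rate — it is the *minimum*
#' information consistent with the moment constraints.
#'
#' @param object an [mne_model()], an `mne_fit`, a `maxent_table` from
#'   [maxent_oracle()], or a numeric vector of per-state conditional
#'   probabilities.
#' @param ensemble an [input_ensemble()] / data frame of inputs with optional
#'   `.weight` column. Not needed for a `maxent_table`; for a numeric
#'   `object` it may be a vector of state weights (uniform if `NULL`).
#' @return entropy / information in bits.
#' @export
#' @examples
#' xor <- gate_dataset(named_gate("XOR"))
#' fit2 <- fit_mne(xor, order = 2, binary_inputs = TRUE)
#' noise_entropy(fit2, xor)      # ~0 bits: XOR is deterministic at order 2
#' model_information(fit2, xor)  # ~1 bit
noise_entropy <- function(object, ensemble = NULL) {
  pw <- cond_probs(object, ensemble)
  sum(pw$w * h2(pw$p))
}

cond_probs <- function(object, ensemble) {
  if (inherits(object, "mne_fit")) object <- object$model
  if (inherits(object, "mne_model")) {
    if (is.null(ensemble)) abort("an ensemble is required for a model")
    list(p = predict(object, ensemble), w = ens_weights(ensemble))
  } else if (inherits(object, "maxent_table")) {
    list(p = object$p, w = object$.weight)
  } else if (is.numeric(object)) {
    w <- if (is.null(ensemble)) rep(1 / length(object), length(object))
         else normalize_weights(ensemble, length(object))
    list(p = object, w = w)
  } else {
    abort("unsupported object for entropy computation")
  }
}

#' @rdname noise_entropy
#' @param mean_output the mean output rate (probability of output 1).
#' @export
response_entropy <- function(mean_output) {
  h2(mean_output)
}

#' @rdname noise_entropy
#' @export
model_information <- function(object, ensemble = NULL) {
  pw <- cond_probs(object, ensemble)
  rate <- sum(pw$w * pw$p)
  h2(rate) - sum(pw$w * h2(pw$p))
}

#' Plug-in mutual information between a discrete state and a binary output
#'
#' The maximum-likelihood (plug-in) estimate of I(state; y) in bits from
#' observed (weighted) counts. For exact ensembles, such as logic-gate truth
#' tables with their state probabilities, the plug-in value is the exact
#' mutual information; for sampled data it is the usual empirical reference
#' against which model information is expressed as a ratio.
#'
#' @param y binary outputs (0/1).
#' @param states a vector assigning each observation to a discrete input
#'   state (any type coercible to factor).
#' @param weights optional observation weights (normalized internally).
#' @return mutual information in bits. Fewer than 2 distinct states yields 0
#'   with a warning.
#' @export
empirical_information <- function(y, states, weights = NULL) {
  stopifnot(length(y) == length(states))
  if (!all(y %in% c(0, 1))) abort("responses must be binary (0/1)")
  w <- normalize_weights(weights, length(y))
  s <- as.factor(states)
  if (nlevels(s) < 2L) {
    warn("fewer than 2 distinct input states: information is 0")
    return(0)
  }
  ws <- rowsum(w, s)[, 1]                     # P(s)
  wy <- rowsum(w * y, s)[, 1]                 # P(s, y = 1)
  rate <- sum(w * y)
  p_cond <- ifelse(ws > 0, wy / ws, 0)
  h2(rate) - sum(ws * h2(p_cond))
}

#' Information ratio of a model relative to an empirical reference
#'
#' The fraction of the empirically measured mutual information captured by
#' the model's constraints. Values slightly above 1 from numerical noise are
#' clipped to 1 with a warning; a zero reference with genuinely positive
#' model information signals inconsistent inputs and is an error.
#'
#' @param model_info model information, bits.
#' @param reference_info empirical (reference) information, bits.
#' @return the ratio as a fraction in \[0, 1\] (multiply by 100 for percent).
#' @export
info_ratio <- function(model_info, reference_info) {
  stopifnot(reference_info >= 0)
  if (reference_info == 0) {
    if (model_info > 1e-9) {
      abort("model information is positive but the reference is 0 bits")
    }
    warn("reference information is 0 bits: ratio undefined, returning NA")
    return(NA_real_)
  }
  r <- model_info / reference_info
  if (r > 1) {
    if (r > 1 + 1e-6) {
      warn(sprintf("ratio %.6f > 1 (numerical noise); clipping to 1", r))
    }
    r <- 1
  }
  max(r, 0)
}

#' Information report for a fitted model
#'
#' Assembles the entropies, model information, empirical reference
#' information and their ratio into a one-row tibble.
#'
#' @param fit an `mne_fit`.
#' @param data the dataset the fit should be scored on (see
#'   [response_dataset()]).
#' @param states optional discrete state assignment for the empirical
#'   reference; defaults to the exact input states (appropriate for discrete
#'   ensembles such as gates). For continuous inputs supply binned states,
#'   e.g. from [bin_response_2d()].
#' @return a tibble with columns `order`, `constraint_count`,
#'   `noise_entropy_bits`, `response_entropy_bits`, `model_information_bits`,
#'   `reference_information_bits`, `ratio`, `percent`, `converged`.
#' @export
info_report <- function(fit, data, states = NULL) {
  stopifnot(inherits(fit, "mne_fit"))
  data <- as_mne_data(data)
  w <- ens_weights(data)
  states <- states %||% interaction(data[input_cols(data)], drop = TRUE)
  ref <- empirical_information(data$y, states, w)
  p <- predict(fit$model, data)
  rate <- sum(w * p)
  noise <- sum(w * h2(p))
  info <- h2(rate) - noise
  ratio <- info_ratio(info, ref)
  tibble(order = fit$model$feature_map$order,
         constraint_count = length(fit$model$coefficients),
         noise_entropy_bits = noise,
         response_entropy_bits = h2(rate),
         model_information_bits = info,
         reference_information_bits = ref,
         ratio = ratio,
         percent = 100 * ratio,
         converged = fit$converged)
}

#' Incremental constraint selection across interaction orders
#'
#' Implements the constraint-selection loop: fit the order-1 MNE model,
#' compute the percentage of the empirical mutual information it captures,
#' and augment the constraint set (raise the order) until the percentage
#' reaches `threshold`. All orders up to the stopping point are reported;
#' ratios are non-decreasing in order up to numerical tolerance because the
#' constraint sets are nested.
#'
#' @inheritParams fit_mne
#' @param max_order largest interaction order to consider.
#' @param threshold stopping threshold, in percent.
#' @param states optional state assignment for the empirical reference (see
#'   [info_report()]).
#' @return a tibble of class `mne_scan`, one [info_report()] row per fitted
#'   order, with the chosen order in attribute `selected_order` (NA if no
#'   order reached the threshold) and the fits in attribute `fits`.
#' @export
#' @examples
#' scan_orders(gate_dataset(named_gate("XOR")), max_order = 2,
#'             binary_inputs = TRUE)
scan_orders <- function(data, max_order = 2, threshold = 90,
                        response = "y", binary_inputs = NULL,
                        cross_terms = TRUE, states = NULL,
                        control = mne_control()) {
  max_order <- check_count(max_order, "max_order")
  data <- as_mne_data(data, response)
  X <- ens_inputs(data)
  if (is.null(binary_inputs)) binary_inputs <- all(X %in% c(0, 1))
  reports <- list()
  fits <- list()
  selected <- NA_integer_
  for (k in seq_len(max_order)) {
    fit <- fit_mne(data, order = k, binary_inputs = binary_inputs,
                   cross_terms = cross_terms, control = control)
    reports[[k]] <- info_report(fit, data, states = states)
    fits[[k]] <- fit
    if (!is.na(reports[[k]]$percent) && reports[[k]]$percent >= threshold) {
      selected <- k
      break
    }
  }
  out <- dplyr::bind_rows(reports)
  attr(out, "selected_order") <- selected
  attr(out, "fits") <- fits
  class(out) <- c("mne_scan", class(out))
  out
}

#' Write an order-by-order information report to CSV
#'
#' @param reports a tibble of reports (e.g. from [scan_orders()]).
#' @param path file path.
#' @export
write_report_csv <- function(reports, path) {
  utils::write.csv(as.data.frame(reports), path, row.names = FALSE)
  invisible(path)
}
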