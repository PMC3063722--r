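#' Discrete input ensembles and paired response datasets
#'
#' An input ensemble is a set of D-dimensional input vectors with probability
#' weights: either an exact ensemble (e.g. the four states of a two-input
#' gate, each with weight 1/4) or an empirical sample carrying uniform
#' weights 1/T. A response dataset pairs each input with a binary output.
#' Both are stored as tibbles — one row per input, input columns plus a
#' `.weight` column, and for datasets a response column `y` — so they compose
#' with dplyr and the pipe.
#'
#' @param data a data frame or matrix of inputs (one row per input vector);
#'   for `response_dataset()` it must also contain the response column.
#' @param weights optional nonnegative weights, one per row; they are
#'   normalized to sum to 1. The default is uniform `1/nrow(data)`.
#' @return a tibble of class `mne_ensemble` (or `mne_data`).
#' @export
#' @examples
#' input_ensemble(expand.grid(x1 = 0:1, x2 = 0:1))
input_ensemble <- function(data, weights = NULL) {
  if (is.matrix(data)) data <- as_tibble(as.data.frame(data), .name_repair = "minimal")
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a nonempty data frame or matrix of inputs")
  }
  data <- as_tibble(data)
  data$.weight <- normalize_weights(weights, nrow(data))
  class(data) <- c("mne_ensemble", class(data))
  data
}

#' @rdname input_ensemble
#' @param response name of the binary response column (default `"y"`).
#' @export
response_dataset <- function(data, response = "y", weights = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("`data` must be a nonempty data frame")
  }
  if (!response %in% names(data)) {
    abort(sprintf("response column `%s` not found", response))
  }
  y <- data[[response]]
  if (!all(y %in% c(0, 1))) abort("responses must be binary (0/1)")
  out <- as_tibble(data)
  names(out)[names(out) == response] <- "y"
  out$y <- as.numeric(y)
  out$.weight <- if (is.null(weights) && ".weight" %in% names(data)) {
    normalize_weights(data$.weight, nrow(data))
  } else {
    normalize_weights(weights, nrow(data))
  }
  class(out) <- c("mne_data", "mne_ensemble", class(out))
  out
}

normalize_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1 / n, n))
  if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0)) {
    abort("`weights` must be nonnegative and finite, one per row")
  }
  s <- sum(weights)
  if (s <= 0) abort("`weights` must not all be zero")
  weights / s
}

input_cols <- function(data) {
  setdiff(names(data), c("y", ".weight"))
}

ens_inputs <- function(data, n_inputs = NULL) {
  as_input_matrix(data[input_cols(data)], n_inputs)
}

ens_weights <- function(data) {
  if (".weight" %in% names(data)) data$.weight else rep(1 / nrow(data), nrow(data))
}

as_mne_data <- function(data, response = "y") {
  if (inherits(data, "mne_data")) data else response_dataset(data, response)
}
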