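#' Maximum-noise-entropy (MNE) model objects
#'
#' An MNE model for a binary output pairs a [feature_map()] with one Lagrange
#' multiplier per monomial constraint. The spike (output) probability is the
#' logistic function
#'
#' \deqn{P(y = 1 \mid x) = \frac{1}{1 + \exp(a + \sum_i h_i x_i +
#'   \sum_{i \le j} J_{ij} x_i x_j + \cdots)}}{P(y=1|x) = 1 / (1 + exp(z))}
#'
#' where the exponent `z` is the linear combination of the monomial features
#' with the stored coefficients. This sign convention — probability
#' *decreasing* in `z` — is fixed throughout the package and recorded in
#' serialized models; fitted coefficients are convention-dependent and must
#' be negated before comparison with software using `1/(1 + exp(-z))`.
#'
#' @param fm a [feature_map()].
#' @param coefficients numeric vector of Lagrange multipliers, one per
#'   monomial, all finite.
#' @return an object of class `mne_model`.
#' @export
#' @examples
#' fm <- feature_map(2, 2, binary_inputs = TRUE)
#' m <- mne_model(fm, c(0, 0, 0, 0))
#' predict(m, expand.grid(x1 = 0:1, x2 = 0:1))  # constant 1/2
mne_model <- function(fm, coefficients) {
  stopifnot(inherits(fm, "feature_map"))
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != n_features(fm)) {
    abort(sprintf("need %d coefficients (one per monomial), got %d",
                  n_features(fm), length(coefficients)))
  }
  if (any(!is.finite(coefficients))) abort("coefficients must be finite")
  structure(
    list(feature_map = fm,
         coefficients = setNames(coefficients, names(fm$monomials)),
         convention = "P(y=1|x) = 1/(1+exp(a + sum_mu lambda_mu f_mu(x)))"),
    class = "mne_model"
  )
}

#' @export
print.mne_model <- function(x, ...) {
  fm <- x$feature_map
  cat(sprintf("<mne_model> order %d, %d inputs, %d constraints\n",
              fm$order, fm$n_inputs, n_features(fm)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict spike probabilities from an MNE model
#'
#' @param object an [mne_model()].
#' @param newdata data frame or matrix of inputs, one row per observation
#'   (extra columns named `y` or `.weight` are ignored).
#' @param ... unused.
#' @return numeric vector of probabilities `P(y = 1 | x)` in (0, 1).
#' @export
predict.mne_model <- function(object, newdata, ...) {
  if (inherits(newdata, "maxent_table")) {
    newdata <- newdata[setdiff(names(newdata), "p")]
  }
  X <- if (is.data.frame(newdata)) {
    ens_inputs(newdata, object$feature_map$n_inputs)
  } else {
    as_input_matrix(newdata, object$feature_map$n_inputs)
  }
  z <- drop(feature_matrix(object$feature_map, X) %*% object$coefficients)
  1 / (1 + exp(z))
}

#' Model-implied output moments
#'
#' Computes the model's expectation `<y f(x)> = sum_x P(x) P(y=1|x) f(x)` for
#' every monomial of a feature map, by direct expectation over the ensemble.
#' At a converged fit these match the empirical moments (the moment-matching
#' conditions that define the maximum-noise-entropy solution).
#'
#' @param model an [mne_model()].
#' @param ensemble an [input_ensemble()] or any data frame of inputs
#'   (uniform weights assumed if no `.weight` column).
#' @param fm optional [feature_map()] whose monomials to evaluate; defaults
#'   to the model's own map. Passing a larger map evaluates moments the model
#'   was *not* constrained on (see [predict_unconstrained_moments()]).
#' @return a tibble of class `mne_moments` with columns `term` and `value`.
#' @export
model_moments <- function(model, ensemble, fm = NULL) {
  stopifnot(inherits(model, "mne_model"))
  fm <- fm %||% model$feature_map
  X <- ens_inputs(ensemble, fm$n_inputs)
  w <- ens_weights(ensemble)
  p <- predict(model, X)
  vals <- drop(crossprod(feature_matrix(fm, X), w * p))
  new_moments(fm, vals)
}

new_moments <- function(fm, values) {
  out <- tibble(term = names(fm$monomials), value = as.numeric(values))
  attr(out, "feature_map") <- fm
  class(out) <- c("mne_moments", class(out))
  out
}

moments_fm <- function(moments) {
  fm <- attr(moments, "feature_map")
  if (is.null(fm)) abort("moment vector carries no feature map")
  fm
}

#' Serialize and restore MNE models as JSON
#'
#' The JSON records the sign convention, the feature map (dimension, order,
#' input encoding, monomial index lists) and the coefficients at full
#' precision, so a round trip reproduces the coefficients bit-exactly.
#'
#' @param model an [mne_model()].
#' @param path file path to write to / read from.
#' @return `write_mne_model()` returns `path` invisibly; `read_mne_model()`
#'   returns the restored [mne_model()].
#' @export
write_mne_model <- function(model, path) {
  stopifnot(inherits(model, "mne_model"))
  fm <- model$feature_map
  payload <- list(
    convention = model$convention,
    n_inputs = fm$n_inputs,
    order = fm$order,
    binary_inputs = fm$binary_inputs,
    cross_terms = fm$cross_terms,
    monomials = unname(lapply(fm$monomials, as.integer)),
    coefficients = unname(model$coefficients)
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mne_model
#' @export
read_mne_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fm <- feature_map(payload$n_inputs, payload$order,
                    binary_inputs = isTRUE(payload$binary_inputs),
                    cross_terms = isTRUE(payload$cross_terms))
  stored <- lapply(payload$monomials, as.integer)
  if (!identical(unname(lapply(fm$monomials, as.integer)), stored)) {
    abort("stored monomials do not match the canonical feature map")
  }
  mne_model(fm, payload$coefficients)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
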