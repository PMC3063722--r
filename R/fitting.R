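#' Fitting control parameters
#'
#' @param tolerance convergence tolerance: maximum absolute mismatch between
#'   empirical and model moments (which equals the likelihood gradient) at
#'   which a fit is declared converged.
#' @param max_iterations iteration cap for the optimizer.
#' @param l2_penalty ridge penalty on the non-constant coefficients. The
#'   default is tiny: it only tames the divergence of coefficients for
#'   deterministic systems (logic gates), where the unpenalized optimum is at
#'   infinity.
#' @param coefficient_cap box bound on the absolute value of every
#'   coefficient, for the same reason.
#' @param seed integer seed used by any randomized routine downstream (the
#'   default fitting path is deterministic and does not consume it).
#' @return a list of class `mne_control`.
#' @export
mne_control <- function(tolerance = 1e-6, max_iterations = 1000L,
                        l2_penalty = 1e-8, coefficient_cap = 50,
                        seed = 1L) {
  stopifnot(tolerance > 0, coefficient_cap > 0, l2_penalty >= 0,
            max_iterations >= 1)
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 l2_penalty = l2_penalty,
                 coefficient_cap = coefficient_cap,
                 seed = as.integer(seed)),
            class = "mne_control")
}

#' Empirical output moments of a dataset
#'
#' The weighted averages `<y f(x)>` for every monomial of a feature map: the
#' first entry is the mean output rate, the degree-1 entries are the
#' (unnormalized) spike-triggered average, the degree-2 entries the
#' spike-triggered second moments. These are the constraints an MNE fit
#' matches.
#'
#' @param data a data frame with input columns and a binary response column
#'   (see [response_dataset()]); exact ensembles carry a `.weight` column.
#' @param fm a [feature_map()].
#' @param response name of the response column.
#' @return a tibble of class `mne_moments` with columns `term`, `value`.
#' @export
#' @examples
#' xor <- gate_dataset(named_gate("XOR"))
#' empirical_moments(xor, feature_map(2, 1, binary_inputs = TRUE))
empirical_moments <- function(data, fm, response = "y") {
  data <- as_mne_data(data, response)
  X <- ens_inputs(data, fm$n_inputs)
  w <- ens_weights(data)
  vals <- drop(crossprod(feature_matrix(fm, X), w * data$y))
  new_moments(fm, vals)
}

#' Fit a maximum-noise-entropy model by moment matching
#'
#' Finds the Lagrange multipliers such that the model moments `<y f(x)>`
#' equal the empirical ones for every monomial in the feature map. For a
#' binary output this moment-matching problem is equivalent to maximizing
#' the average log-likelihood of the logistic model: the gradient of the
#' objective with respect to each coefficient is exactly the moment
#' mismatch, so the fit is a smooth convex optimization solved here
#' with L-BFGS-B from the all-zero start (the constant-1/2 model). The
#' default path is fully deterministic.
#'
#' Deterministic systems (e.g. exact logic gates) drive coefficients toward
#' infinity; the `coefficient_cap` box and the tiny ridge penalty in
#' [mne_control()] keep the fit finite while the information captured
#' converges to its limit.
#'
#' @inheritParams empirical_moments
#' @param order interaction order to fit (used when `fm` is not given).
#' @param binary_inputs,cross_terms passed to [feature_map()] when `fm` is
#'   not given.
#' @param fm optionally, an explicit [feature_map()] overriding `order`.
#' @param control an [mne_control()].
#' @return an object of class `mne_fit`: a list with elements `model`
#'   ([mne_model()]), `converged`, `final_mismatch`, `n_iterations`,
#'   `moments` (tibble of empirical vs fitted moments), `mean_output`,
#'   `control` and `log`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
#' @examples
#' and <- gate_dataset(named_gate("AND"))
#' fit <- fit_mne(and, order = 1, binary_inputs = TRUE)
#' glance(fit)
fit_mne <- function(data, order = 2, response = "y", binary_inputs = FALSE,
                    cross_terms = TRUE, fm = NULL, control = mne_control()) {
  data <- as_mne_data(data, response)
  fm <- fm %||% feature_map(length(input_cols(data)), order,
                            binary_inputs = binary_inputs,
                            cross_terms = cross_terms)
  X <- ens_inputs(data, fm$n_inputs)
  w <- ens_weights(data)
  y <- data$y
  if (!all(y %in% c(0, 1))) abort("responses must be binary (0/1)")
  Fmat <- feature_matrix(fm, X)
  emp <- drop(crossprod(Fmat, w * y))
  rate <- emp[[1]]

  if (rate <= 0 || rate >= 1) {
    warn(sprintf(
      "mean output is %g: returning the degenerate constant model", rate))
    cap <- control$coefficient_cap
    theta <- c(if (rate <= 0) cap else -cap, rep(0, n_features(fm) - 1L))
    model <- mne_model(fm, theta)
    mm <- model_moments(model, data)
    return(new_mne_fit(model, emp, mm$value, TRUE, 0L, control,
                       "degenerate constant model"))
  }

  l2 <- control$l2_penalty
  pen_mask <- c(0, rep(1, n_features(fm) - 1L))  # no penalty on the constant
  # negative average log-likelihood (natural log) plus ridge penalty;
  # gradient wrt theta is (empirical - model) moments + l2 * theta
  objective <- function(theta) {
    z <- drop(Fmat %*% theta)
    # -[y log p + (1-y) log(1-p)] with p = 1/(1+e^z) equals y*z + log(1+e^-z)
    nll <- sum(w * (y * z + log1p(exp(-abs(z))) + pmax(-z, 0)))
    nll + 0.5 * l2 * sum(pen_mask * theta^2)
  }
  gradient <- function(theta) {
    p <- 1 / (1 + exp(drop(Fmat %*% theta)))
    drop(crossprod(Fmat, w * (y - p))) + l2 * pen_mask * theta
  }
  cap <- control$coefficient_cap
  opt <- optim(rep(0, n_features(fm)), objective, gradient,
               method = "L-BFGS-B", lower = -cap, upper = cap,
               control = list(maxit = control$max_iterations,
                              factr = 10, pgtol = control$tolerance / 100))
  model <- mne_model(fm, opt$par)
  mod_m <- model_moments(model, data)$value
  mismatch <- max(abs(emp - mod_m))
  converged <- mismatch <= control$tolerance
  new_mne_fit(model, emp, mod_m, converged, opt$counts[["function"]],
              control, opt$message %||% "")
}

new_mne_fit <- function(model, emp, mod_m, converged, n_iter, control, msg) {
  moments <- tibble(term = names(model$coefficients),
                    empirical = as.numeric(emp),
                    fitted = as.numeric(mod_m))
  structure(
    list(model = model, converged = converged,
         final_mismatch = max(abs(emp - mod_m)),
         n_iterations = as.integer(n_iter),
         moments = moments, mean_output = emp[[1]],
         control = control, log = msg),
    class = "mne_fit"
  )
}

#' @export
print.mne_fit <- function(x, ...) {
  cat(sprintf("<mne_fit> %s, moment mismatch %.2e after %d evaluations\n",
              if (x$converged) "converged" else "NOT converged",
              x$final_mismatch, x$n_iterations))
  print(x$model)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MNE fit
#'
#' One row per constraint with the coefficient (Lagrange multiplier), the
#' empirical moment and the fitted model moment.
#'
#' @param x an `mne_fit`.
#' @param ... unused.
#' @method tidy mne_fit
#' @export
tidy.mne_fit <- function(x, ...) {
  dplyr::mutate(x$moments,
                estimate = unname(x$model$coefficients),
                .after = "term")
}

#' @rdname tidy.mne_fit
#' @method glance mne_fit
#' @export
glance.mne_fit <- function(x, ...) {
  tibble(converged = x$converged,
         final_mismatch = x$final_mismatch,
         n_iterations = x$n_iterations,
         mean_output = x$mean_output,
         n_constraints = length(x$model$coefficients),
         order = x$model$feature_map$order)
}

#' Serialize a fit (model plus diagnostics) as JSON
#'
#' Extends the model JSON of [write_mne_model()] with the convergence flag,
#' final moment mismatch, iteration count and fitting options.
#'
#' @param fit an `mne_fit`.
#' @param path file path.
#' @export
write_mne_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mne_fit"))
  fm <- fit$model$feature_map
  payload <- list(
    convention = fit$model$convention,
    n_inputs = fm$n_inputs, order = fm$order,
    binary_inputs = fm$binary_inputs, cross_terms = fm$cross_terms,
    monomials = unname(lapply(fm$monomials, as.integer)),
    coefficients = unname(fit$model$coefficients),
    converged = fit$converged,
    final_mismatch = fit$final_mismatch,
    n_iterations = fit$n_iterations,
    options = unclass(fit$control)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
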