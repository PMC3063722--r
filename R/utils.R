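#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats optim predict rnorm runif setNames
NULL

# probability floor used inside logarithms so entropies of near-deterministic
# models stay finite; probabilities exactly 0 or 1 contribute 0 by convention
PROB_EPS <- 1e-12

clamp01 <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Binary entropy in bits
#'
#' `h2(p)` is the entropy of a Bernoulli(p) variable in bits. Probabilities
#' exactly 0 or 1 give exactly 0 bits; interior probabilities are floored at
#' 1e-12 inside the logarithms.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return numeric vector of entropies in bits.
#' @export
#' @examples
#' h2(c(0, 0.25, 0.5, 1))
h2 <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE)) {
    abort("probabilities must lie in [0, 1]")
  }
  p <- pmin(pmax(p, 0), 1)
  out <- numeric(length(p))
  interior <- !is.na(p) & p > 0 & p < 1
  q <- clamp01(p[interior])
  out[interior] <- -q * log2(q) - (1 - q) * log2(1 - q)
  out[is.na(p)] <- NA_real_
  out
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# resolve a data frame / matrix of inputs into a plain numeric matrix
as_input_matrix <- function(x, n_inputs = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (!is.null(n_inputs) && ncol(x) != n_inputs) {
    abort(sprintf("inputs have %d columns but the feature map expects %d",
                  ncol(x), n_inputs))
  }
  if (any(!is.finite(x))) abort("inputs must be finite")
  x
}
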