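#' Build the monomial feature map of an interaction-order model
#'
#' A maximum-noise-entropy (MNE) model of interaction order `K` constrains the
#' moments `<y f(x)>` for every monomial feature `f` of degree up to `K`. This
#' constructor enumerates those monomials in a fixed canonical order so that
#' serialized models are comparable across runs:
#'
#' * the constant feature (the mean-output constraint) is always first;
#' * then all degree-1 monomials `x_i`, ascending;
#' * then, within each degree, monomials with fewer distinct indices first
#'   (e.g. squares `x_i^2` before mixed pairs `x_i x_j`), each sub-block in
#'   lexicographic index order.
#'
#' For binary (0/1) inputs, powers are idempotent (`x_i^2 = x_i`), so any
#' monomial with a repeated index is redundant and is excluded when
#' `binary_inputs = TRUE`. Setting `cross_terms = FALSE` drops the mixed
#' second-degree monomials `x_i x_j` (i != j) only, leaving squares in place;
#' this is the diagonal second-order model used to assess the importance of
#' the mixed covariance term.
#'
#' @param n_inputs number of input dimensions (D >= 1).
#' @param order maximum interaction order K (>= 1).
#' @param binary_inputs if `TRUE`, inputs are declared 0/1 and repeated-index
#'   monomials are excluded as redundant.
#' @param cross_terms if `FALSE`, mixed second-degree monomials are dropped.
#' @return an object of class `feature_map`: a list with `n_inputs`, `order`,
#'   `binary_inputs`, `cross_terms` and `monomials` (a named list of 1-based
#'   index vectors; `integer(0)` is the constant feature).
#' @export
#' @examples
#' feature_map(2, 2, binary_inputs = TRUE)   # 1, x1, x2, x1:x2
#' feature_map(2, 2, cross_terms = FALSE)    # 1, x1, x2, x1^2, x2^2
feature_map <- function(n_inputs, order, binary_inputs = FALSE,
                        cross_terms = TRUE) {
  n_inputs <- check_count(n_inputs, "n_inputs")
  order <- check_count(order, "order")
  monomials <- list(integer(0))
  for (k in seq_len(order)) {
    block <- if (binary_inputs) {
      if (k > n_inputs) list() else
        apply(utils::combn(n_inputs, k), 2L, identity, simplify = FALSE)
    } else {
      multisets(n_inputs, k)
    }
    if (k == 2L && !cross_terms) {
      block <- Filter(function(m) length(unique(m)) == 1L, block)
    }
    if (k >= 2L) {
      n_distinct <- vapply(block, function(m) length(unique(m)), integer(1))
      block <- block[base::order(n_distinct, vapply(block, lex_key, character(1)))]
    }
    monomials <- c(monomials, block)
  }
  names(monomials) <- vapply(monomials, monomial_label, character(1))
  structure(
    list(n_inputs = n_inputs, order = order, binary_inputs = binary_inputs,
         cross_terms = cross_terms, monomials = monomials),
    class = "feature_map"
  )
}

# all nondecreasing index vectors of length k over 1..d, lexicographic
multisets <- function(d, k) {
  if (k == 1L) return(lapply(seq_len(d), identity))
  out <- list()
  for (first in seq_len(d)) {
    for (rest in multisets(d - first + 1L, k - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest + first - 1L)
    }
  }
  out
}

lex_key <- function(m) paste(sprintf("%04d", m), collapse = ",")

monomial_label <- function(m) {
  if (length(m) == 0L) return("1")
  tab <- table(m)
  paste(ifelse(tab > 1L,
               sprintf("x%s^%d", names(tab), tab),
               sprintf("x%s", names(tab))),
        collapse = ":")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> D = %d, order = %d, %s inputs%s\n",
              x$n_inputs, x$order,
              if (x$binary_inputs) "binary" else "continuous",
              if (x$cross_terms) "" else ", no cross terms"))
  cat("features:", paste(names(x$monomials), collapse = ", "), "\n")
  invisible(x)
}

n_features <- function(fm) length(fm$monomials)

#' Evaluate monomial features
#'
#' `eval_features()` evaluates every monomial of a feature map at a single
#' input vector; `feature_matrix()` does the same for each row of a matrix or
#' data frame of inputs, returning one column per monomial (the constant
#' feature evaluates to 1 everywhere).
#'
#' @param fm a [feature_map()].
#' @param x a numeric vector of length `fm$n_inputs`.
#' @return `eval_features()`: a named numeric vector, one entry per monomial.
#' @export
#' @examples
#' fm <- feature_map(2, 2)
#' eval_features(fm, c(0.5, -1))
eval_features <- function(fm, x) {
  stopifnot(inherits(fm, "feature_map"))
  if (length(x) != fm$n_inputs) {
    abort(sprintf("input has length %d but the feature map expects %d",
                  length(x), fm$n_inputs))
  }
  drop(feature_matrix(fm, matrix(as.numeric(x), nrow = 1L)))
}

#' @rdname eval_features
#' @param X numeric matrix or data frame, one row per observation, with
#'   `fm$n_inputs` columns.
#' @return `feature_matrix()`: a numeric matrix, rows matching `X`, one named
#'   column per monomial.
#' @export
feature_matrix <- function(fm, X) {
  stopifnot(inherits(fm, "feature_map"))
  X <- as_input_matrix(X, fm$n_inputs)
  out <- matrix(1, nrow = nrow(X), ncol = n_features(fm),
                dimnames = list(NULL, names(fm$monomials)))
  for (j in seq_along(fm$monomials)) {
    for (i in fm$monomials[[j]]) out[, j] <- out[, j] * X[, i]
  }
  out
}
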