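#' Boolean truth gates as exactly solvable test systems
#'
#' A truth gate maps each binary input state to a probability of output 1
#' (deterministic gates use 0/1). Under a uniform input distribution these
#' small systems have exactly computable mutual information, which makes
#' them ideal for checking which interaction orders an MNE model needs: AND
#' and OR are captured completely at first order, XOR only at second order.
#'
#' @param name one of `"AND"`, `"OR"`, `"XOR"`, `"NAND"`, `"NOR"`, `"XNOR"`.
#' @param n_inputs number of inputs (>= 2); the N-input generalizations are
#'   all-of / any-of / parity and their negations.
#' @return a tibble of class `truth_gate`: one row per input state (columns
#'   `x1..xN`) with the output probability `p`.
#' @export
#' @examples
#' named_gate("XOR")
named_gate <- function(name, n_inputs = 2) {
  n_inputs <- check_count(n_inputs, "n_inputs", min = 2L)
  name <- toupper(name)
  states <- gate_states(n_inputs)
  s <- rowSums(states)
  p <- switch(name,
    AND  = as.numeric(s == n_inputs),
    OR   = as.numeric(s > 0),
    XOR  = as.numeric(s %% 2 == 1),
    NAND = as.numeric(s < n_inputs),
    NOR  = as.numeric(s == 0),
    XNOR = as.numeric(s %% 2 == 0),
    abort(sprintf("unknown gate name `%s`", name))
  )
  truth_gate(states, p)
}

gate_states <- function(n_inputs) {
  states <- expand.grid(rep(list(0:1), n_inputs))[, n_inputs:1, drop = FALSE]
  names(states) <- paste0("x", seq_len(n_inputs))
  as_tibble(states[do.call(base::order, states), , drop = FALSE])
}

#' @rdname named_gate
#' @param states data frame / matrix of all `2^N` binary input states.
#' @param p output probability for each state, in \[0, 1\].
#' @export
truth_gate <- function(states, p) {
  states <- as_tibble(as.data.frame(states))
  n <- ncol(states)
  if (!all(as.matrix(states) %in% c(0, 1))) abort("states must be binary")
  if (nrow(states) != 2^n || anyDuplicated(states)) {
    abort(sprintf("need all %d distinct states of %d inputs", 2^n, n))
  }
  if (length(p) != nrow(states) || any(p < 0 | p > 1)) {
    abort("`p` must give one probability in [0, 1] per state")
  }
  names(states) <- paste0("x", seq_len(n))
  out <- states[do.call(base::order, states), , drop = FALSE]
  out$p <- as.numeric(p)[do.call(base::order, states)]
  class(out) <- c("truth_gate", class(out))
  out
}

#' Expand a truth gate into an exact response dataset
#'
#' Every input state appears with weight `2^-N` (uniform input
#' distribution). Deterministic states contribute one row with the output
#' they dictate; stochastic states expand into two rows (y = 1 and y = 0)
#' whose weights split the state probability by the output probability.
#'
#' @param gate a [truth_gate()].
#' @return a [response_dataset()] tibble with exact weights.
#' @export
#' @examples
#' gate_dataset(named_gate("AND"))
gate_dataset <- function(gate) {
  stopifnot(inherits(gate, "truth_gate"))
  n <- sum(startsWith(names(gate), "x"))
  w_state <- 1 / nrow(gate)
  rows <- purrr::pmap(gate, function(p, ...) {
    state <- tibble(...)
    if (p %in% c(0, 1)) {
      dplyr::mutate(state, y = p, .weight = w_state)
    } else {
      dplyr::bind_rows(
        dplyr::mutate(state, y = 1, .weight = w_state * p),
        dplyr::mutate(state, y = 0, .weight = w_state * (1 - p))
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  response_dataset(out, weights = out$.weight)
}

#' Enumerate all deterministic truth gates on N inputs
#'
#' Yields all `2^(2^N)` deterministic truth tables exactly once, in a fixed
#' order (the gate index read as a binary output pattern over the canonical
#' state order). Guarded at N <= 4.
#'
#' @param n_inputs number of inputs (2..4).
#' @return a list of [truth_gate()] objects.
#' @export
#' @examples
#' length(enumerate_gates(2))  # 16
enumerate_gates <- function(n_inputs) {
  n_inputs <- check_count(n_inputs, "n_inputs", min = 1L)
  if (n_inputs > 4L) abort("enumeration is guarded at n_inputs <= 4")
  states <- gate_states(n_inputs)
  n_states <- nrow(states)
  lapply(seq_len(2^n_states) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_states)]
    truth_gate(states, bits)
  })
}

#' Re-encode gate inputs from 0/1 to -1/+1
#'
#' The package's moments are written for the 0/1 encoding (so `<y x_i>` is
#' the spike-triggered average). This utility re-encodes a dataset's binary
#' inputs to the symmetric -1/+1 convention used in spin models; fitted
#' coefficients are not comparable across encodings without an affine map.
#'
#' @param data a dataset or ensemble with binary 0/1 input columns.
#' @return the same tibble with inputs mapped to -1/+1.
#' @export
recode_pm1 <- function(data) {
  cols <- input_cols(data)
  X <- as.matrix(data[cols])
  if (!all(X %in% c(0, 1))) abort("inputs must be 0/1 to re-encode")
  data[cols] <- 2 * X - 1
  data
}

#' Read and write truth tables as plain text
#'
#' One line per state: the input bits, space-separated, followed by the
#' output probability.
#'
#' @param gate a [truth_gate()].
#' @param path file path.
#' @export
write_truth_table <- function(gate, path) {
  stopifnot(inherits(gate, "truth_gate"))
  utils::write.table(as.data.frame(gate), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  truth_gate(tab[, -ncol(tab), drop = FALSE], tab[[ncol(tab)]])
}
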