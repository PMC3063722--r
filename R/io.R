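#' Read analysis inputs from plain-text files
#'
#' `read_stimulus()` reads a one-value-per-line stimulus trace;
#' `read_spike_times()` reads spike times (one per line, seconds);
#' `read_filters()` reads a two-column whitespace/comma-delimited filter
#' file, one row per time lag (oldest first, matching the lagged-input
#' columns).
#'
#' @param path file path.
#' @param dt stimulus bin width in seconds.
#' @return `read_stimulus()`: numeric vector with attribute `dt`;
#'   `read_spike_times()`: numeric vector; `read_filters()`: a matrix with
#'   two columns.
#' @export
read_stimulus <- function(path, dt = 0.004) {
  v <- scan(path, what = double(), sep = if (grepl("\\.csv$", path)) "," else "",
            quiet = TRUE)
  structure(as.numeric(v), dt = dt)
}

#' @rdname read_stimulus
#' @export
read_spike_times <- function(path) {
  v <- scan(path, what = double(), quiet = TRUE)
  if (is.unsorted(v)) abort("spike times must be nondecreasing")
  v
}

#' @rdname read_stimulus
#' @export
read_filters <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           sep = if (grepl("\\.csv$", path)) "," else "")
  m <- as.matrix(tab)
  if (ncol(m) != 2L) abort("filter file must have exactly two columns")
  storage.mode(m) <- "double"
  colnames(m) <- c("f1", "f2")
  m
}

#' Write a binned response function to CSV
#'
#' One row per grid cell: bin indices, bin centers, occupancy, spike count
#' and spike probability (empty for unsampled cells).
#'
#' @param brf a [bin_response_2d()] table.
#' @param path file path.
#' @export
write_brf_csv <- function(brf, path) {
  stopifnot(inherits(brf, "mne_brf"))
  utils::write.csv(as.data.frame(brf), path, row.names = FALSE, na = "")
  invisible(path)
}
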