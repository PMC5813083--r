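#' Construct a set of stimulus-locked epochs
#'
#' An `epoch_set` holds multi-trial ROI time series: a numeric array indexed
#' `(trial, roi, sample)` together with the ROI labels, the sampling rate and
#' the time of the first sample relative to stimulus onset. It is the
#' universal input of the connectivity functions.
#'
#' @param data Numeric 3-d array indexed `(trial, roi, sample)`. All values
#'   must be finite.
#' @param roi_labels Character vector of unique ROI names, one per slice of
#'   the second array dimension (e.g. `c("lPAC", "rPAC", "lSAC", "rSAC")`).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Time of the first sample relative to stimulus onset, in seconds.
#'
#' @return An object of class `epoch_set`.
#' @examples
#' x <- array(rnorm(2 * 3 * 8), dim = c(2, 3, 8))
#' ep <- epoch_set(x, c("a", "b", "c"), fs = 256, t0 = -0.2)
#' ep
#' @export
epoch_set <- function(data, roi_labels, fs, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop("`data` must be a numeric 3-d array indexed (trial, roi, sample).",
         call. = FALSE)
  }
  if (dim(data)[1] < 1L) {
    stop("`data` must contain at least one trial.", call. = FALSE)
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stop("`data` contains non-finite values.", call. = FALSE)
  }
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != dim(data)[2] || anyDuplicated(roi_labels)) {
    stop("`roi_labels` must be unique and match dim(data)[2].", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive finite scalar (Hz).", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("`t0` must be a finite scalar (seconds).", call. = FALSE)
  }
  dimnames(data) <- list(NULL, roi_labels, NULL)
  structure(
    list(data = data, roi_labels = roi_labels, fs = fs, t0 = t0),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d ROIs x %d samples @ %g Hz (t0 = %g s)\n",
    d[1], d[2], d[3], x$fs, x$t0
  ))
  cat("ROIs:", paste(x$roi_labels, collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1]
n_rois <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Time axis of an epoch set
#'
#' @param epochs An [epoch_set()].
#' @return Numeric vector of sample times in seconds relative to stimulus
#'   onset.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$t0 + (seq_len(n_samples(epochs)) - 1L) / epochs$fs
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.epoch_set <- function(x, ...) {
  tt <- epoch_times(x)
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    roi = rep(rep(x$roi_labels, each = d[1]), times = d[3]),
    time = rep(tt, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Extract a stimulus-locked time window
#'
#' Selects the half-open interval `[start, stop)` from the epoch time axis.
#' Sample indices are obtained by rounding `(t - t0) * fs`, so a 200 ms
#' window of 2048 ms epochs sampled at 256 Hz with `t0 = -0.2` starts at
#' sample index 179 (0-based) and contains 51 samples.
#'
#' @param epochs An [epoch_set()].
#' @param start,stop Window bounds in seconds relative to stimulus onset;
#'   `start < stop` and the window must lie within the epoch.
#' @return An [epoch_set()] restricted to the window, with updated `t0`.
#' @examples
#' ep <- epoch_set(array(rnorm(1 * 1 * 525), c(1, 1, 525)), "roi",
#'                 fs = 256, t0 = -0.2)
#' extract_window(ep, 0.5, 0.7)
#' @export
extract_window <- function(epochs, start, stop) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.numeric(start) || !is.numeric(stop) || length(start) != 1L ||
      length(stop) != 1L || !is.finite(start) || !is.finite(stop)) {
    stop("`start` and `stop` must be finite scalars (seconds).", call. = FALSE)
  }
  i0 <- round((start - epochs$t0) * epochs$fs)
  i1 <- round((stop - epochs$t0) * epochs$fs)
  ns <- n_samples(epochs)
  if (i1 <= i0) {
    stop(sprintf("empty window: [%g, %g) selects no samples.", start, stop),
         call. = FALSE)
  }
  if (i0 < 0 || i1 > ns) {
    stop(sprintf(
      "window [%g, %g) falls outside the epoch time axis [%g, %g).",
      start, stop, epochs$t0, epochs$t0 + ns / epochs$fs
    ), call. = FALSE)
  }
  if (i0 == 0 && i1 == ns) return(epochs)
  epoch_set(
    epochs$data[, , (i0 + 1L):i1, drop = FALSE],
    epochs$roi_labels,
    fs = epochs$fs,
    t0 = epochs$t0 + i0 / epochs$fs
  )
}

#' Apply an instantaneous (zero-lag) linear mixing
#'
#' Mixes the ROI series sample-wise with a square invertible matrix,
#' emulating volume conduction: the output at ROI `i` is
#' `sum_j M[i, j] * x_j` at every sample, with no temporal filtering.
#'
#' @param epochs An [epoch_set()].
#' @param matrix Square numeric mixing matrix with dimension equal to the
#'   ROI count; must be invertible.
#' @return An [epoch_set()] with mixed signals (labels unchanged).
#' @export
apply_instantaneous_mixing <- function(epochs, matrix) {
  stopifnot(inherits(epochs, "epoch_set"))
  r <- n_rois(epochs)
  if (!is.matrix(matrix) || !is.numeric(matrix) ||
      nrow(matrix) != r || ncol(matrix) != r) {
    stop("`matrix` must be a square numeric matrix of dimension ", r, ".",
         call. = FALSE)
  }
  if (rcond_of(matrix) < 1e-12) {
    stop("mixing matrix is singular (or numerically so).", call. = FALSE)
  }
  d <- dim(epochs$data)
  # (roi) x (trial * sample) layout so the mixing is one matrix product
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = r)
  mixed <- matrix %*% flat
  out <- aperm(array(mixed, dim = c(r, d[1], d[3])), c(2, 1, 3))
  epoch_set(out, epochs$roi_labels, fs = epochs$fs, t0 = epochs$t0)
}

rcond_of <- function(m) {
  tryCatch(rcond(m), error = function(e) 0)
}
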