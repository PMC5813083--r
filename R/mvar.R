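#' Construct a multivariate autoregressive (MVAR) model
#'
#' An `mvar_model` stores the lag coefficient matrices `A_k` and the
#' innovation covariance `S_eps` of the model
#' `x(t) = sum_k A_k x(t - k) + eps(t)`. `A_k[i, j]` is the influence of ROI
#' `j` at lag `k` on ROI `i`.
#'
#' @param coeffs 3-d numeric array `(roi, roi, lag)` of coefficient
#'   matrices, or a list of `roi x roi` matrices (one per lag).
#' @param noise_cov Innovation covariance matrix (`roi x roi`), symmetric
#'   with strictly positive diagonal.
#' @param fs Sampling rate in Hz.
#' @param roi_labels Optional ROI names; defaults to `roi1, roi2, ...`.
#'
#' @return An object of class `mvar_model` with fields `order`, `coeffs`,
#'   `noise_cov`, `fs`, `roi_labels`.
#' @examples
#' m <- mvar_model(list(matrix(c(0.5, 0.8, 0, 0.5), 2, 2)), diag(2), fs = 256)
#' is_stable(m)
#' @export
mvar_model <- function(coeffs, noise_cov, fs, roi_labels = NULL) {
  if (is.list(coeffs)) {
    r <- nrow(coeffs[[1]])
    coeffs <- array(unlist(coeffs), dim = c(r, r, length(coeffs)))
  } else if (is.matrix(coeffs)) {
    coeffs <- array(coeffs, dim = c(dim(coeffs), 1L))   # order-1 shorthand
  }
  if (!is.array(coeffs) || length(dim(coeffs)) != 3L ||
      dim(coeffs)[1] != dim(coeffs)[2]) {
    stop("`coeffs` must be a (roi, roi, lag) array or list of square matrices.",
         call. = FALSE)
  }
  if (dim(coeffs)[3] < 1L) stop("model order must be >= 1.", call. = FALSE)
  if (anyNA(coeffs) || !all(is.finite(coeffs))) {
    stop("`coeffs` contains non-finite values.", call. = FALSE)
  }
  r <- dim(coeffs)[1]
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != r || ncol(noise_cov) != r) {
    stop("`noise_cov` must be ", r, " x ", r, ".", call. = FALSE)
  }
  if (max(abs(noise_cov - t(noise_cov))) > 1e-8 * max(1, max(abs(noise_cov)))) {
    stop("`noise_cov` is not symmetric within tolerance.", call. = FALSE)
  }
  if (any(diag(noise_cov) <= 0)) {
    stop("`noise_cov` must have a strictly positive diagonal.", call. = FALSE)
  }
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(r))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != r || anyDuplicated(roi_labels)) {
    stop("`roi_labels` must be unique and of length ", r, ".", call. = FALSE)
  }
  dimnames(coeffs) <- list(roi_labels, roi_labels, NULL)
  dimnames(noise_cov) <- list(roi_labels, roi_labels)
  structure(
    list(order = dim(coeffs)[3], coeffs = coeffs, noise_cov = noise_cov,
         fs = fs, roi_labels = roi_labels),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d ROIs @ %g Hz, spectral radius %.3f\n",
              x$order, length(x$roi_labels), x$fs, spectral_radius(x)))
  invisible(x)
}

#' Fit an MVAR model to multi-trial epochs
#'
#' Joint ordinary-least-squares estimation across trials: each trial
#' contributes the regression rows whose full lag window lies inside that
#' trial, so no design row ever mixes samples from two trials. The
#' innovation covariance is the covariance of the pooled residuals (with a
#' degrees-of-freedom correction for the fitted coefficients).
#'
#' @param epochs An [epoch_set()] with more than `order` samples per trial.
#' @param order Model order `p >= 1` (number of lags). Default 8, a
#'   high-order choice that gives fine spectral resolution for gamma-band
#'   analysis of short windows.
#' @param demean Subtract the per-trial, per-ROI mean before fitting
#'   (default `TRUE`). Band-passed source signals are zero-mean in
#'   expectation, but per-trial demeaning removes residual offsets.
#'
#' @return An [mvar_model()] with extra fields `nobs` (pooled regression
#'   rows) and `n_trials`.
#' @details A warning (not an error) is issued when the pooled number of
#'   regression rows is below `10 * roi_count * order`, and when the fitted
#'   model is not stable. A rank-deficient design (e.g. duplicated ROI
#'   series) raises an error naming the offending ROI/lag columns.
#' @export
fit_mvar <- function(epochs, order = 8, demean = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  p <- as.integer(order)
  if (length(p) != 1L || is.na(p) || p < 1L) {
    stop("`order` must be an integer >= 1.", call. = FALSE)
  }
  ns <- n_samples(epochs)
  r <- n_rois(epochs)
  nt <- n_trials(epochs)
  if (ns <= p) {
    stop(sprintf("trials have %d samples; need more than order = %d.", ns, p),
         call. = FALSE)
  }
  rows <- nt * (ns - p)
  if (rows < 10 * r * p) {
    warning(sprintf(
      "only %d regression rows for %d coefficients per equation; estimates may be unstable.",
      rows, r * p
    ), call. = FALSE)
  }

  dm <- lagged_design(epochs$data, p, demean)
  X <- dm$X
  Y <- dm$Y

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- qx$pivot[(qx$rank + 1L):ncol(X)]
    lag_of <- (bad - 1L) %/% r + 1L
    roi_of <- epochs$roi_labels[(bad - 1L) %% r + 1L]
    stop(sprintf(
      "singular MVAR design: collinear regressors %s.",
      paste(sprintf("%s@lag%d", roi_of, lag_of), collapse = ", ")
    ), call. = FALSE)
  }
  B <- qr.coef(qx, Y)                      # (r*p) x r, column i = equation i
  resid <- Y - X %*% B
  df <- max(1L, nrow(X) - ncol(X))
  S <- crossprod(resid) / df
  S <- (S + t(S)) / 2

  A <- array(0, dim = c(r, r, p))
  for (k in seq_len(p)) {
    # design column (k-1)*r + j is roi j at lag k; B[col, i] feeds A_k[i, j]
    A[, , k] <- t(B[((k - 1L) * r + 1L):(k * r), , drop = FALSE])
  }

  m <- mvar_model(A, S, fs = epochs$fs, roi_labels = epochs$roi_labels)
  m$nobs <- nrow(X)
  m$n_trials <- nt
  if (!is_stable(m)) {
    warning(sprintf("fitted MVAR model is unstable (spectral radius %.3f).",
                    spectral_radius(m)), call. = FALSE)
  }
  m
}

# Stacked per-trial lagged design; rows never straddle trial boundaries.
# One embed() call over the trial-concatenated series, then the rows whose
# lag window crosses a trial boundary are dropped.
lagged_design <- function(data, p, demean) {
  d <- dim(data)
  nt <- d[1]; r <- d[2]; ns <- d[3]
  if (demean) {
    mu <- rowMeans(data, dims = 2)             # trial x roi means
    data <- data - array(mu, dim = c(nt, r, ns))
  }
  # concatenate trials along time: (nt * ns) x r, trial t occupies rows
  # (t-1)*ns + 1 .. t*ns
  flat <- matrix(aperm(data, c(3, 1, 2)), nrow = nt * ns)
  emb <- stats::embed(flat, p + 1L)            # row k covers samples k..k+p
  k <- seq_len(nt * ns - p)
  keep <- ((k - 1L) %/% ns) == ((k + p - 1L) %/% ns)
  emb <- emb[keep, , drop = FALSE]
  list(X = emb[, -seq_len(r), drop = FALSE], Y = emb[, seq_len(r), drop = FALSE])
}

#' Companion-matrix spectral radius of an MVAR model
#'
#' @param model An [mvar_model()].
#' @return The largest eigenvalue modulus of the `(roi * p)`-dimensional
#'   companion matrix; the model is stationary iff this is `< 1`.
#' @export
spectral_radius <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  r <- length(model$roi_labels)
  p <- model$order
  C <- matrix(0, r * p, r * p)
  for (k in seq_len(p)) C[1:r, ((k - 1) * r + 1):(k * r)] <- model$coeffs[, , k]
  if (p > 1) {
    C[(r + 1):(r * p), 1:(r * (p - 1))] <- diag(r * (p - 1))
  }
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Is an MVAR model stable (stationary)?
#'
#' @param model An [mvar_model()].
#' @return `TRUE` iff the companion spectral radius is `< 1`, with the
#'   radius attached as attribute `"radius"`.
#' @export
is_stable <- function(model) {
  rho <- spectral_radius(model)
  structure(rho < 1, radius = rho)
}

#' Spectral transfer structure of an MVAR model
#'
#' Evaluates `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)` on a frequency
#' grid. `Abar` carries the model's frequency-domain coupling structure; the
#' isolated effective coherence is built from its entries.
#'
#' @param model An [mvar_model()].
#' @param freqs Frequencies in Hz, within `[0, fs/2]`.
#' @return An object of class `spectral_transfer`: list with `freqs` and the
#'   complex array `abar` indexed `(freq, roi, roi)`.
#' @export
spectral_transfer <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  freqs <- as.numeric(freqs)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > model$fs / 2)) {
    stop("`freqs` must lie within [0, fs/2] = [0, ", model$fs / 2, "] Hz.",
         call. = FALSE)
  }
  r <- length(model$roi_labels)
  p <- model$order
  ab <- array(0 + 0i, dim = c(length(freqs), r, r))
  eye <- diag(r)
  for (fi in seq_along(freqs)) {
    ph <- exp(-1i * 2 * pi * freqs[fi] * seq_len(p) / model$fs)
    m <- eye + 0i
    for (k in seq_len(p)) m <- m - model$coeffs[, , k] * ph[k]
    ab[fi, , ] <- m
  }
  structure(
    list(freqs = freqs, abar = ab, roi_labels = model$roi_labels, fs = model$fs),
    class = "spectral_transfer"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of an MVAR model
#'
#' @param x An [mvar_model()].
#' @param ... Unused.
#' @return A tibble with columns `target`, `source`, `lag`, `estimate`.
#' @export
tidy.mvar_model <- function(x, ...) {
  r <- length(x$roi_labels)
  tibble::tibble(
    target = rep(x$roi_labels, times = r * x$order),
    source = rep(rep(x$roi_labels, each = r), times = x$order),
    lag = rep(seq_len(x$order), each = r * r),
    estimate = as.vector(x$coeffs)
  )
}

#' One-row summary of an MVAR model
#'
#' @param x An [mvar_model()].
#' @param ... Unused.
#' @return A tibble with order, ROI count, spectral radius, stability and
#'   (for fitted models) the pooled row count.
#' @export
glance.mvar_model <- function(x, ...) {
  tibble::tibble(
    order = x$order,
    n_roi = length(x$roi_labels),
    fs = x$fs,
    spectral_radius = spectral_radius(x),
    stable = spectral_radius(x) < 1,
    nobs = if (is.null(x$nobs)) NA_integer_ else x$nobs
  )
}
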