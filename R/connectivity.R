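#' Complex coherency from unit-modulus Fourier coefficients
#'
#' For every trial the discrete Fourier transform of each ROI is taken over
#' the full epoch, each complex coefficient is normalized to unit modulus
#' (so only its phase is retained), and the cross-spectral outer products
#' are averaged across trials and scaled to coherency form. The frequency
#' grid is the native DFT grid of the epoch length (about 5 Hz spacing for a
#' 200 ms window at 256 Hz).
#'
#' @param epochs An [epoch_set()] with at least two trials.
#' @param hann Apply a Hann taper before the DFT (default `FALSE`; the
#'   untapered transform is the most literal reading of unit-modulus
#'   normalization).
#' @param demean Subtract the per-trial, per-ROI mean first (default `TRUE`).
#' @return An object of class `coherency`: list with `freqs` (Hz) and the
#'   complex array `values` indexed `(freq, roi, roi)`, Hermitian with unit
#'   diagonal at every frequency.
#' @seealso [lagged_phase_synchronization()]
#' @export
coherency <- function(epochs, hann = FALSE, demean = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_trials(epochs)
  if (nt < 2L) {
    stop("coherency is undefined from a single trial (need >= 2).",
         call. = FALSE)
  }
  r <- n_rois(epochs)
  ns <- n_samples(epochs)
  nf <- floor(ns / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * epochs$fs / ns

  # samples x (roi * trial): one FFT call for the whole set
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = ns)
  if (demean) flat <- sweep(flat, 2L, colMeans(flat))
  if (hann) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns - 1) / (ns - 1))
    flat <- flat * w
  }
  Fc <- stats::mvfft(flat)[seq_len(nf), , drop = FALSE]
  mod <- Mod(Fc)
  Z <- Fc / mod
  Z[mod == 0] <- 0 + 0i          # undefined phase contributes nothing
  dim(Z) <- c(nf, r, nt)

  vals <- array(0 + 0i, dim = c(nf, r, r))
  for (fi in seq_len(nf)) {
    zf <- matrix(Z[fi, , ], nrow = r)
    S <- zf %*% Conj(t(zf)) / nt
    d <- Re(diag(S))
    scale <- sqrt(pmax(d, 1e-300))
    vals[fi, , ] <- S / outer(scale, scale)
  }
  structure(
    list(freqs = freqs, values = vals, n_trials = nt,
         roi_labels = epochs$roi_labels, fs = epochs$fs),
    class = "coherency"
  )
}

#' @export
print.coherency <- function(x, ...) {
  cat(sprintf("<coherency> %d ROIs, %d frequencies (0-%g Hz), %d trials\n",
              length(x$roi_labels), length(x$freqs), max(x$freqs), x$n_trials))
  invisible(x)
}

new_spectral_connectivity <- function(df, kind, roi_labels, fs) {
  out <- tibble::new_tibble(df, kind = kind, roi_labels = roi_labels, fs = fs,
                            class = "spectral_connectivity")
  out
}

#' @export
print.spectral_connectivity <- function(x, ...) {
  cat(sprintf("<spectral_connectivity: %s>\n", attr(x, "kind")))
  NextMethod()
}

#' Lagged phase synchronization (LPS)
#'
#' Applies `phi^2 = Im(f)^2 / (1 - Re(f)^2)` entrywise to a coherency
#' object. The real (instantaneous, zero-lag) part of the coherency is
#' partialled out, so connectivity produced by instantaneous linear mixing —
#' volume conduction in EEG source analysis — does not inflate the measure.
#'
#' Entries with `Re(f)^2` within `tol` of 1 (perfect instantaneous
#' coherence, e.g. an ROI paired with a copy of itself) are set to 0 with a
#' warning rather than dividing by (near) zero.
#'
#' @param coh A [coherency()] object.
#' @param tol Guard tolerance on `1 - Re(f)^2` (default `1e-10`).
#' @return A `spectral_connectivity` tibble of kind `"lps"` with columns
#'   `freq`, `source`, `target`, `value`; values lie in `[0, 1]` and the
#'   measure is symmetric (both orderings of each pair are reported with
#'   equal value).
#' @export
lagged_phase_synchronization <- function(coh, tol = 1e-10) {
  stopifnot(inherits(coh, "coherency"))
  r <- length(coh$roi_labels)
  nf <- length(coh$freqs)
  pairs <- which(outer(seq_len(r), seq_len(r), "!="), arr.ind = TRUE)
  rows <- vector("list", nrow(pairs))
  n_guard <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    f <- coh$values[, i, j]
    den <- 1 - Re(f)^2
    guard <- den < tol
    n_guard <- n_guard + sum(guard)
    v <- Im(f)^2 / pmax(den, 1e-12)
    v[guard] <- 0
    rows[[k]] <- tibble::tibble(
      freq = coh$freqs,
      source = coh$roi_labels[j],
      target = coh$roi_labels[i],
      value = v
    )
  }
  if (n_guard > 0) {
    warning(sprintf(
      "%d entries had (near-)perfect instantaneous coherence; LPS set to 0 there.",
      n_guard
    ), call. = FALSE)
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$freq, .data$target)
  new_spectral_connectivity(out, "lps", coh$roi_labels, coh$fs)
}

#' Isolated effective coherence (iCoh)
#'
#' Directed, Granger-sense coupling from a fitted MVAR model. For each
#' ordered pair (source `j`, target `i`) an isolated model is formed: every
#' cross-ROI lag coefficient except the `j -> i` entries is set to zero,
#' all self-connections (diagonal lag coefficients) are retained, and the
#' innovation covariance is reduced to its diagonal. On that model
#'
#' `kappa_{i<-j}(f) = (|Abar_ij(f)|^2 / s_ii) /
#'                    (|Abar_ij(f)|^2 / s_ii + |Abar_jj(f)|^2 / s_jj)`
#'
#' where `s_ii`, `s_jj` are the innovation variances. Values lie in
#' `[0, 1]` by construction.
#'
#' @param model An [mvar_model()] (a warning is issued if unstable).
#' @param freqs Frequency grid in Hz; default `1, 2, ..., floor(fs/2)`
#'   (1 Hz resolution, matching a high-order AR spectrum).
#' @param pairs Ordered pairs to evaluate: a two-column matrix/data frame or
#'   list of `c(source, target)` label pairs. Default: all ordered pairs.
#' @return A `spectral_connectivity` tibble of kind `"icoh"` with columns
#'   `freq`, `source`, `target`, `value`; entry (source `j`, target `i`)
#'   holds `kappa_{i<-j}`.
#' @export
isolated_effective_coherence <- function(model, freqs = NULL, pairs = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  if (is.null(freqs)) freqs <- seq_len(floor(model$fs / 2))
  freqs <- as.numeric(freqs)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > model$fs / 2)) {
    stop("`freqs` must lie within [0, fs/2].", call. = FALSE)
  }
  labs <- model$roi_labels
  if (is.null(pairs)) {
    r <- length(labs)
    idx <- which(outer(seq_len(r), seq_len(r), "!="), arr.ind = TRUE)
    pairs <- cbind(labs[idx[, 2]], labs[idx[, 1]])    # source, target
  } else {
    pairs <- normalize_pairs(pairs, labs)
  }
  if (!is_stable(model)) {
    warning(sprintf("MVAR model is unstable (spectral radius %.3f); iCoh may be unreliable.",
                    spectral_radius(model)), call. = FALSE)
  }
  s <- diag(model$noise_cov)
  if (any(s <= 0)) {
    stop("degenerate model: zero innovation variance.", call. = FALSE)
  }
  ph <- exp(-1i * 2 * pi * outer(freqs, seq_len(model$order)) / model$fs)

  np <- nrow(pairs)
  nf <- length(freqs)
  vals <- matrix(0, nf, np)
  for (k in seq_len(np)) {
    j <- match(pairs[k, 1], labs)      # source
    i <- match(pairs[k, 2], labs)      # target
    if (is.na(i) || is.na(j)) {
      stop("unknown ROI label in `pairs`.", call. = FALSE)
    }
    if (i == j) stop("iCoh requires source != target.", call. = FALSE)
    # isolation keeps only j->i cross terms and all self terms; for this
    # pair only Abar[i, j] and Abar[j, j] enter the statistic
    a_ij <- -as.vector(ph %*% model$coeffs[i, j, ])
    a_jj <- 1 - as.vector(ph %*% model$coeffs[j, j, ])
    num <- Mod(a_ij)^2 / s[i]
    den <- num + Mod(a_jj)^2 / s[j]
    vals[, k] <- num / pmax(den, 1e-12)
  }
  out <- tibble::tibble(
    freq = rep(freqs, times = np),
    source = rep(pairs[, 1], each = nf),
    target = rep(pairs[, 2], each = nf),
    value = as.vector(vals)
  )
  new_spectral_connectivity(out, "icoh", labs, model$fs)
}

normalize_pairs <- function(pairs, labs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) {
    stop("`pairs` must have two columns: source, target.", call. = FALSE)
  }
  storage.mode(pairs) <- "character"
  pairs
}

#' Average a connectivity spectrum over a frequency band
#'
#' Arithmetic mean over grid frequencies `f` with `lo <= f <= hi`, both
#' edges inclusive. The default band is the gamma range 30-100 Hz.
#'
#' @param conn A `spectral_connectivity` tibble (or any tibble with columns
#'   `freq`, `source`, `target`, `value`).
#' @param lo,hi Band edges in Hz.
#' @return A tibble with one row per `(source, target)` and the
#'   band-averaged `value`.
#' @export
band_average <- function(conn, lo = 30, hi = 100) {
  stopifnot(is.data.frame(conn),
            all(c("freq", "source", "target", "value") %in% names(conn)))
  in_band <- conn$freq >= lo & conn$freq <= hi
  if (!any(in_band)) {
    stop(sprintf("band [%g, %g] Hz does not intersect the frequency grid.",
                 lo, hi), call. = FALSE)
  }
  sub <- conn[in_band, c("source", "target", "value")]
  key <- paste(sub$source, sub$target, sep = "\r")
  first <- !duplicated(key)
  means <- rowsum(sub$value, key, reorder = FALSE) /
    as.vector(table(factor(key, levels = unique(key))))
  out <- tibble::tibble(source = sub$source[first], target = sub$target[first],
                        value = as.vector(means))
  if (!is.null(attr(conn, "kind"))) attr(out, "kind") <- attr(conn, "kind")
  out
}

#' Connectivity matrix at one frequency
#'
#' @param conn A `spectral_connectivity` tibble.
#' @param freq One frequency from the grid.
#' @return A `roi x roi` matrix (target rows, source columns); the diagonal
#'   is `NA` (self-connectivity is not defined for these measures).
#' @export
connectivity_matrix <- function(conn, freq) {
  labs <- attr(conn, "roi_labels")
  stopifnot(!is.null(labs))
  sub <- conn[conn$freq == freq, , drop = FALSE]
  if (nrow(sub) == 0) stop("`freq` is not on the grid.", call. = FALSE)
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  m[cbind(match(sub$target, labs), match(sub$source, labs))] <- sub$value
  m
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a connectivity spectrum
#'
#' One line per ordered ROI pair, value against frequency.
#'
#' @param object A `spectral_connectivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_connectivity <- function(object, ...) {
  kind <- attr(object, "kind")
  lab <- if (identical(kind, "icoh")) {
    expression(kappa[i %<-% j])
  } else {
    expression(phi^2)
  }
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$freq, y = .data$value,
                 colour = paste(.data$source, "→", .data$target))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = lab, colour = "pair") +
    ggplot2::theme_minimal()
}
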