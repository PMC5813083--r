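# Independent oracles and small fixture builders. Oracles deliberately use
# explicit loops and share no code with the package internals.

white_epochs <- function(n_trials, n_roi, n_samples, fs = 256, t0 = 0,
                         seed = 1, sd = 1) {
  withr::with_seed(seed, {
    epoch_set(array(rnorm(n_trials * n_roi * n_samples, sd = sd),
                    dim = c(n_trials, n_roi, n_samples)),
              paste0("roi", seq_len(n_roi)), fs = fs, t0 = t0)
  })
}

# Naive Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs), scalar loops only.
naive_abar <- function(coeffs, fs, f) {
  r <- dim(coeffs)[1]
  p <- dim(coeffs)[3]
  m <- matrix(0 + 0i, r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    acc <- if (i == j) 1 + 0i else 0 + 0i
    for (k in seq_len(p)) {
      acc <- acc - coeffs[i, j, k] * exp(-1i * 2 * pi * f * k / fs)
    }
    m[i, j] <- acc
  }
  m
}

# Naive iCoh: explicitly builds the isolated model (zero all cross lag
# coefficients except j -> i, keep every self term, diagonalize the noise
# covariance), then evaluates the ratio from its naive Abar.
naive_icoh <- function(model, target, source, freqs) {
  labs <- model$roi_labels
  i <- match(target, labs)
  j <- match(source, labs)
  iso <- model$coeffs
  r <- length(labs)
  for (a in seq_len(r)) for (b in seq_len(r)) {
    if (a != b && !(a == i && b == j)) iso[a, b, ] <- 0
  }
  s <- diag(diag(model$noise_cov), r)
  out <- numeric(length(freqs))
  for (fi in seq_along(freqs)) {
    ab <- naive_abar(iso, model$fs, freqs[fi])
    num <- (1 / s[i, i]) * Mod(ab[i, j])^2
    den <- num + (1 / s[j, j]) * Mod(ab[j, j])^2
    out[fi] <- num / den
  }
  out
}

# Random stable MVAR model: draw coefficients, then shrink until the
# companion spectral radius is comfortably below 1.
random_stable_model <- function(n_roi, order, seed, fs = 256,
                                target_radius = 0.9) {
  withr::with_seed(seed, {
    A <- array(rnorm(n_roi * n_roi * order, sd = 0.4),
               dim = c(n_roi, n_roi, order))
    v <- abs(rnorm(n_roi, 1, 0.2)) + 0.2
    m <- mvar_model(A, diag(v), fs = fs)
    rho <- spectral_radius(m)
    if (rho >= target_radius) {
      scale <- target_radius / rho
      for (k in seq_len(order)) A[, , k] <- A[, , k] * scale^k
      m <- mvar_model(A, diag(v), fs = fs)
    }
    m
  })
}

# Hand-built coherency object with a given complex off-diagonal value for a
# 2-ROI system at a single frequency.
coherency_fixture <- function(f_xy, freq = 40, fs = 256) {
  vals <- array(0 + 0i, dim = c(1, 2, 2))
  vals[1, 1, 1] <- 1
  vals[1, 2, 2] <- 1
  vals[1, 1, 2] <- f_xy
  vals[1, 2, 1] <- Conj(f_xy)
  structure(
    list(freqs = freq, values = vals, n_trials = 2L,
         roi_labels = c("x", "y"), fs = fs),
    class = "coherency"
  )
}

# Two-ROI, two-condition in-memory study with white-noise epochs;
# used for pipeline plumbing tests where connectivity content is irrelevant.
toy_study <- function(n_subjects = 4, n_trials = c(LE = 12, RE = 12),
                      n_samples = 64, fs = 256, seed = 1) {
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  epochs <- list()
  k <- 0
  for (s in subjects) {
    epochs[[s]] <- list()
    for (cn in names(n_trials)) {
      k <- k + 1
      epochs[[s]][[cn]] <- white_epochs(n_trials[[cn]], 4, n_samples, fs,
                                        t0 = 0.5, seed = seed * 1000 + k)
      epochs[[s]][[cn]]$roi_labels <- c("lPAC", "rPAC", "lSAC", "rSAC")
      dimnames(epochs[[s]][[cn]]$data)[[2]] <- c("lPAC", "rPAC", "lSAC", "rSAC")
    }
  }
  manifest <- tidyr::expand_grid(subject = subjects,
                                 condition = names(n_trials))
  manifest$path <- NA_character_
  behavior <- simulate_behavior(n_subjects, seed = seed)
  structure(list(epochs = epochs, behavior = behavior, manifest = manifest,
                 config = NULL, seed = seed),
            class = "study_data")
}

# Null two-condition study over the SAC pair only, with all subject x
# condition datasets drawn in one batched MVAR simulation (the per-subject
# models are identical under the null, so the split is distributionally
# exact and much faster than per-subject simulation).
null_study <- function(n_subjects, seed, n_trials = 82, n_samples = 51) {
  cfg <- sim_config(
    roi_labels = c("lSAC", "rSAC"),
    coupling = tibble::tibble(source = c("lSAC", "rSAC"),
                              target = c("rSAC", "lSAC"),
                              strength = 0.05, condition = NA_character_)
  )
  model <- generator_model(cfg, NULL)
  big <- simulate_mvar(model, n_trials = n_subjects * 2 * n_trials,
                       n_samples = n_samples, seed = seed, t0 = 0.5)
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  epochs <- list()
  k <- 0
  for (s in subjects) {
    epochs[[s]] <- list()
    for (cn in c("LE", "RE")) {
      idx <- (k * n_trials + 1):((k + 1) * n_trials)
      k <- k + 1
      epochs[[s]][[cn]] <- epoch_set(big$data[idx, , , drop = FALSE],
                                     cfg$roi_labels, fs = cfg$fs, t0 = 0.5)
    }
  }
  manifest <- tidyr::expand_grid(subject = subjects,
                                 condition = c("LE", "RE"))
  manifest$path <- NA_character_
  structure(list(epochs = epochs, behavior = NULL, manifest = manifest,
                 config = cfg, seed = seed),
            class = "study_data")
}

sac_only_config <- function() {
  pipeline_config(measures = "icoh",
                  lps_pairs = list(c("lSAC", "rSAC")),
                  icoh_pairs = list(SAC = c("lSAC", "rSAC")),
                  heterotopic = FALSE)
}
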