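#' Configuration for the synthetic ROI signal generator
#'
#' Describes the generative model for source-level auditory ROI signals:
#' each ROI is a stochastically driven damped AR(2) oscillator (a narrow-band
#' gamma rhythm), and directed coupling is injected as lag-1 cross
#' coefficients, optionally only in one stimulus/report condition. Keeping
#' the generator inside the MVAR family makes the ground-truth coupling
#' exact, so fitted coefficients and directed connectivity can be checked
#' against it.
#'
#' @param roi_labels ROI names; default the four auditory ROIs
#'   `lPAC, rPAC, lSAC, rSAC` (left/right primary and secondary auditory
#'   cortex).
#' @param fs Sampling rate in Hz (default 256).
#' @param epoch_len Epoch length in seconds (default 0.2, the analysis
#'   window length).
#' @param t0 Time of the first sample relative to stimulus onset (default
#'   0.5 s, so the default epoch *is* the 500-700 ms analysis window).
#' @param n_trials Trials per condition (default 82, a realistic balanced
#'   per-condition trial count for this paradigm).
#' @param osc_freq Oscillator center frequency in Hz (default 40, inside
#'   the 30-100 Hz gamma band).
#' @param pole_modulus AR(2) pole modulus (default 0.95; larger is more
#'   narrow-band).
#' @param noise_sd Innovation standard deviation, scalar or per ROI
#'   (default 1).
#' @param coupling Tibble of directed edges with columns `source`, `target`,
#'   `strength` (lag-1 coefficient) and `condition` (`NA` = present in all
#'   conditions, otherwise the condition name). See [default_coupling()].
#' @param mixing Optional instantaneous mixing matrix applied to the
#'   generated signals (volume-conduction emulation); `NULL` = none.
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(roi_labels = c("lPAC", "rPAC", "lSAC", "rSAC"),
                       fs = 256,
                       epoch_len = 0.2,
                       t0 = 0.5,
                       n_trials = 82,
                       osc_freq = 40,
                       pole_modulus = 0.95,
                       noise_sd = 1,
                       coupling = default_coupling(),
                       mixing = NULL,
                       seed = 1L) {
  roi_labels <- as.character(roi_labels)
  stopifnot(length(roi_labels) >= 1, !anyDuplicated(roi_labels),
            fs > 0, epoch_len > 0, n_trials >= 1,
            osc_freq > 0, osc_freq < fs / 2,
            pole_modulus > 0, pole_modulus < 1)
  noise_sd <- rep_len(as.numeric(noise_sd), length(roi_labels))
  stopifnot(all(noise_sd > 0))
  coupling <- tibble::as_tibble(coupling)
  if (nrow(coupling) > 0) {
    stopifnot(all(c("source", "target", "strength", "condition") %in%
                    names(coupling)),
              all(coupling$source %in% roi_labels),
              all(coupling$target %in% roi_labels),
              all(coupling$source != coupling$target))
  }
  if (!is.null(mixing)) {
    stopifnot(is.matrix(mixing),
              nrow(mixing) == length(roi_labels),
              ncol(mixing) == length(roi_labels))
  }
  structure(
    list(roi_labels = roi_labels, fs = fs, epoch_len = epoch_len, t0 = t0,
         n_trials = as.integer(n_trials), osc_freq = osc_freq,
         pole_modulus = pole_modulus, noise_sd = noise_sd,
         coupling = coupling, mixing = mixing, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default directed coupling scheme for the two-condition study
#'
#' Weak bidirectional homotopic coupling between left and right PAC and
#' between left and right SAC in both conditions, plus a right-to-left SAC
#' coupling boost present only during left-ear (LE) reports — the
#' callosal-relay pattern the group pipeline is designed to detect.
#'
#' @param base Baseline homotopic lag-1 coupling strength (default 0.05).
#' @param le_boost Additional rSAC -> lSAC strength in the LE condition
#'   (default 0.08).
#' @return A coupling tibble for [sim_config()].
#' @export
default_coupling <- function(base = 0.05, le_boost = 0.08) {
  tibble::tibble(
    source    = c("lPAC", "rPAC", "lSAC", "rSAC", "rSAC"),
    target    = c("rPAC", "lPAC", "rSAC", "lSAC", "lSAC"),
    strength  = c(base, base, base, base, le_boost),
    condition = c(NA, NA, NA, NA, "LE")
  )
}

#' Generative MVAR model implied by a simulation config
#'
#' Order-2 model: the diagonal carries the damped oscillator
#' (`a1 = 2 rho cos(2 pi f0 / fs)`, `a2 = -rho^2`), condition-matching
#' coupling edges add lag-1 cross coefficients, and the innovation
#' covariance is diagonal.
#'
#' @param config A [sim_config()].
#' @param condition Condition name (`NULL` applies only unconditional
#'   edges).
#' @return An [mvar_model()].
#' @export
generator_model <- function(config, condition = NULL) {
  stopifnot(inherits(config, "sim_config"))
  r <- length(config$roi_labels)
  theta <- 2 * pi * config$osc_freq / config$fs
  rho <- config$pole_modulus
  A <- array(0, dim = c(r, r, 2))
  diag(A[, , 1]) <- 2 * rho * cos(theta)
  diag(A[, , 2]) <- -rho^2
  cp <- config$coupling
  if (nrow(cp) > 0) {
    keep <- is.na(cp$condition) |
      (!is.null(condition) & cp$condition %in% condition)
    for (k in which(keep)) {
      i <- match(cp$target[k], config$roi_labels)
      j <- match(cp$source[k], config$roi_labels)
      A[i, j, 1] <- A[i, j, 1] + cp$strength[k]
    }
  }
  mvar_model(A, diag(config$noise_sd^2, r), fs = config$fs,
             roi_labels = config$roi_labels)
}

#' Simulate epochs from an MVAR model
#'
#' Draws each trial independently with Gaussian innovations; a burn-in of
#' `burn_in` samples (default `40 * order`, safely past transients for pole
#' moduli up to ~0.97) is discarded from every trial.
#'
#' @param model A stable [mvar_model()]; an unstable model is a hard error.
#' @param n_trials,n_samples Trials and retained samples per trial.
#' @param seed Integer seed (the draw is a pure function of it).
#' @param burn_in Discarded leading samples per trial.
#' @param t0 `t0` for the returned [epoch_set()].
#' @return An [epoch_set()].
#' @export
simulate_mvar <- function(model, n_trials, n_samples, seed,
                          burn_in = 40L * model$order, t0 = 0) {
  stopifnot(inherits(model, "mvar_model"), n_trials >= 1, n_samples >= 1)
  rho <- spectral_radius(model)
  if (rho >= 1) {
    stop(sprintf("requested generative model is unstable (spectral radius %.3f).",
                 rho), call. = FALSE)
  }
  r <- length(model$roi_labels)
  p <- model$order
  total <- burn_in + n_samples
  L <- chol(model$noise_cov)
  At <- lapply(seq_len(p), function(k) t(model$coeffs[, , k]))
  X <- withr::with_seed(seed, {
    eps <- array(stats::rnorm(n_trials * total * r), dim = c(n_trials, r, total))
    X <- array(0, dim = c(n_trials, r, total))
    for (s in seq_len(total)) {
      acc <- eps[, , s, drop = TRUE] %*% L
      if (r == 1L) acc <- matrix(eps[, 1, s], ncol = 1L) %*% L
      for (k in seq_len(min(p, s - 1L))) {
        xk <- X[, , s - k, drop = TRUE]
        if (r == 1L) xk <- matrix(X[, 1, s - k], ncol = 1L)
        acc <- acc + xk %*% At[[k]]
      }
      X[, , s] <- acc
    }
    X
  })
  epoch_set(X[, , (burn_in + 1L):total, drop = FALSE], model$roi_labels,
            fs = model$fs, t0 = t0)
}

#' Simulate one condition's epochs from a simulation config
#'
#' Builds the condition-specific generative model, verifies stability (hard
#' error naming the spectral radius otherwise), simulates the trials and
#' applies the instantaneous mixing matrix if one is configured.
#'
#' @param config A [sim_config()].
#' @param condition Condition name (e.g. `"LE"` or `"RE"`); `NULL` uses only
#'   unconditional coupling edges.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An [epoch_set()].
#' @export
simulate_epochs <- function(config, condition = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  model <- generator_model(config, condition)
  ep <- simulate_mvar(
    model,
    n_trials = config$n_trials,
    n_samples = round(config$epoch_len * config$fs),
    seed = seed,
    t0 = config$t0
  )
  if (!is.null(config$mixing)) {
    ep <- apply_instantaneous_mixing(ep, config$mixing)
  }
  ep
}

#' Default behavioral report probabilities
#'
#' RE/LE/error report probabilities for the dichotic listening task,
#' proportional to typical group mean counts of 134.81 right-ear, 80.00
#' left-ear and 25.69 error reports out of 240 trials (a clear right-ear
#' advantage).
#'
#' @return Named numeric vector `c(RE, LE, ERR)` summing to 1.
#' @export
behavioral_probs <- function() {
  m <- c(RE = 134.81, LE = 80.00, ERR = 25.69)
  m / sum(m)
}

#' Simulate per-subject behavioral report counts
#'
#' Each subject's (RE, LE, ERR) counts are one multinomial draw over the
#' task's trials.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param total Trials per subject (default 240).
#' @param probs Probability vector `c(RE, LE, ERR)`; default
#'   [behavioral_probs()].
#' @param seed Integer seed.
#' @return A tibble with columns `subject`, `RE`, `LE`, `ERR`, `total`.
#' @export
simulate_behavior <- function(n_subjects, total = 240,
                              probs = behavioral_probs(), seed = 1L) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1.", call. = FALSE)
  probs <- as.numeric(probs)
  if (length(probs) != 3L || any(probs < 0) || any(!is.finite(probs)) ||
      abs(sum(probs) - 1) > 1e-8) {
    stop("`probs` must be a length-3 probability vector summing to 1.",
         call. = FALSE)
  }
  counts <- withr::with_seed(seed, stats::rmultinom(n_subjects, total, probs))
  tibble::tibble(
    subject = sprintf("S%03d", seq_len(n_subjects)),
    RE = counts[1, ],
    LE = counts[2, ],
    ERR = counts[3, ],
    total = as.integer(total)
  )
}

#' Simulate a full two-condition study
#'
#' Generates, for each subject, left-ear-report (LE) and right-ear-report
#' (RE) condition epochs with subject-specific coupling strengths (each
#' edge's strength is drawn from a normal with the configured mean and
#' `coupling_sd`), plus behavioral report counts. Neural and behavioral
#' effects are statistically independent. With `dir` set, epochs, behavior
#' and a JSON manifest are written to disk; otherwise everything is kept in
#' memory.
#'
#' @param n_subjects Number of subjects (>= 2; default 33).
#' @param config A [sim_config()] template.
#' @param coupling_sd Between-subject SD of every coupling strength
#'   (default 0.05).
#' @param seed Integer seed for the whole study.
#' @param conditions Condition names (default `c("LE", "RE")`).
#' @param dir Optional output directory; created if missing.
#' @return An object of class `study_data`: list with `epochs` (nested list
#'   `[[subject]][[condition]]`, `NULL` when written to disk), `behavior`
#'   tibble, `manifest` tibble (`subject`, `condition`, `path`), `config`,
#'   `seed` and, when written, `manifest_path`.
#' @export
simulate_study <- function(n_subjects = 33, config = sim_config(),
                           coupling_sd = 0.05, seed = 1L,
                           conditions = c("LE", "RE"), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_subjects < 2) stop("`n_subjects` must be >= 2.", call. = FALSE)
  n_edges <- nrow(config$coupling)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                             n_subjects * (length(conditions) + 1L) + 1L))
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  behavior <- simulate_behavior(n_subjects, seed = seeds[length(seeds)])

  write_out <- !is.null(dir)
  if (write_out) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  epochs <- if (write_out) NULL else
    stats::setNames(vector("list", n_subjects), subjects)
  manifest <- vector("list", n_subjects * length(conditions))
  row <- 0L
  for (s in seq_len(n_subjects)) {
    base <- (s - 1L) * (length(conditions) + 1L)
    cfg_s <- config
    if (n_edges > 0 && coupling_sd > 0) {
      # redraw (seeded, deterministic) until both condition models are
      # stable; the subject-level distribution is truncated to the stable
      # region of the MVAR family
      cfg_s$coupling$strength <- withr::with_seed(seeds[base + 1L], {
        for (try in 1:50) {
          s_try <- stats::rnorm(n_edges, config$coupling$strength, coupling_sd)
          cfg_try <- config
          cfg_try$coupling$strength <- s_try
          ok <- all(vapply(conditions, function(cn) {
            spectral_radius(generator_model(cfg_try, cn)) < 1
          }, logical(1)))
          if (ok) break
        }
        if (!ok) stop("could not draw a stable subject-level model in 50 attempts.",
                      call. = FALSE)
        s_try
      })
    }
    if (!write_out) epochs[[s]] <- list()
    for (ci in seq_along(conditions)) {
      ep <- simulate_epochs(cfg_s, conditions[ci], seed = seeds[base + 1L + ci])
      row <- row + 1L
      if (write_out) {
        path <- file.path(dir, sprintf("%s_%s.feather", subjects[s],
                                       conditions[ci]))
        write_epochs(ep, path)
        manifest[[row]] <- tibble::tibble(subject = subjects[s],
                                          condition = conditions[ci],
                                          path = basename(path))
      } else {
        epochs[[s]][[conditions[ci]]] <- ep
        manifest[[row]] <- tibble::tibble(subject = subjects[s],
                                          condition = conditions[ci],
                                          path = NA_character_)
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  out <- structure(
    list(epochs = epochs, behavior = behavior, manifest = manifest,
         config = config, seed = as.integer(seed)),
    class = "study_data"
  )
  if (write_out) {
    write_behavior(behavior, file.path(dir, "behavior.tsv"))
    out$manifest_path <- write_manifest(manifest, "behavior.tsv",
                                        file.path(dir, "manifest.json"))
  }
  out
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> %d subjects x %d conditions (%s)\n",
              length(unique(x$manifest$subject)),
              length(unique(x$manifest$condition)),
              if (is.null(x$epochs)) "on disk" else "in memory"))
  invisible(x)
}
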