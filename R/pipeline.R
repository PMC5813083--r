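#' Analysis pipeline configuration
#'
#' Defaults reproduce the study design the package targets: a 200 ms
#' analysis window starting 500 ms post-stimulus, gamma-band averaging over
#' 30-100 Hz (inclusive edges), MVAR order 8, and the four auditory ROIs.
#'
#' @param window Analysis window `c(start, stop)` in seconds post-stimulus
#'   (half-open, default `c(0.5, 0.7)`).
#' @param band Frequency band `c(lo, hi)` in Hz for averaging (default
#'   `c(30, 100)`).
#' @param ar_order MVAR model order for iCoh (default 8).
#' @param alpha Significance level (default 0.05).
#' @param lps_pairs List of unordered ROI pairs for the functional
#'   (LPS) analysis; default homotopic SAC and PAC pairs.
#' @param icoh_pairs Named list of homotopic ROI pairs for the directed
#'   (iCoh) analysis; each gets a 2x2 Condition x Direction ANOVA.
#' @param heterotopic Also compute iCoh for the crossed PAC/SAC pairs
#'   (e.g. rPAC -> lSAC) in the per-subject tables (default `TRUE`).
#' @param icoh_fit `"joint"` (default) fits one MVAR per subject and
#'   condition across all trials; `"per_trial"` fits per trial and averages
#'   the iCoh spectra.
#' @param hann Hann-taper the coherency DFT (default `FALSE`).
#' @param measures Which measures to compute (default both).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = c(0.5, 0.7),
                            band = c(30, 100),
                            ar_order = 8,
                            alpha = 0.05,
                            lps_pairs = list(c("lSAC", "rSAC"),
                                             c("lPAC", "rPAC")),
                            icoh_pairs = list(SAC = c("lSAC", "rSAC"),
                                              PAC = c("lPAC", "rPAC")),
                            heterotopic = TRUE,
                            icoh_fit = c("joint", "per_trial"),
                            hann = FALSE,
                            measures = c("lps", "icoh")) {
  stopifnot(length(window) == 2, window[1] < window[2],
            length(band) == 2, band[1] <= band[2],
            ar_order >= 1, alpha > 0, alpha < 1)
  icoh_fit <- match.arg(icoh_fit)
  measures <- match.arg(measures, several.ok = TRUE)
  structure(
    list(window = window, band = band, ar_order = as.integer(ar_order),
         alpha = alpha, lps_pairs = lps_pairs, icoh_pairs = icoh_pairs,
         heterotopic = isTRUE(heterotopic), icoh_fit = icoh_fit,
         hann = isTRUE(hann), measures = measures),
    class = "pipeline_config"
  )
}

hemisphere <- function(label) {
  h <- tolower(substr(label, 1, 1))
  ifelse(h %in% c("l", "r"), h, NA_character_)
}

direction_label <- function(source, target) {
  hs <- hemisphere(source); ht <- hemisphere(target)
  dplyr::case_when(
    !is.na(hs) & !is.na(ht) & hs == "r" & ht == "l" ~ "R->L",
    !is.na(hs) & !is.na(ht) & hs == "l" & ht == "r" ~ "L->R",
    TRUE ~ paste0(source, "->", target)
  )
}

#' Band-averaged connectivity for one subject and condition
#'
#' Applies the analysis window, then computes the configured measures:
#' LPS from the trial-averaged unit-modulus coherency for each unordered
#' pair, and iCoh from a fitted MVAR model on a 1 Hz grid for every
#' directed pair (homotopic both ways, plus the crossed PAC/SAC pairs when
#' `heterotopic` is set), each averaged over the configured band.
#'
#' @param epochs An [epoch_set()].
#' @param config A [pipeline_config()].
#' @return A tibble with columns `measure`, `source`, `target`, `direction`,
#'   `value` (LPS rows carry the pair in alphabetical order and direction
#'   `"sym"`).
#' @export
subject_connectivity <- function(epochs, config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(config, "pipeline_config"))
  ep <- extract_window(epochs, config$window[1], config$window[2])
  out <- list()

  if ("lps" %in% config$measures) {
    coh <- coherency(ep, hann = config$hann)
    lps <- lagged_phase_synchronization(coh)
    ba <- band_average(lps, config$band[1], config$band[2])
    keep <- purrr::map_dfr(config$lps_pairs, function(pr) {
      if (!all(pr %in% ep$roi_labels)) return(NULL)
      pr <- sort(pr)
      v <- ba$value[ba$source == pr[1] & ba$target == pr[2]]
      tibble::tibble(measure = "lps", source = pr[1], target = pr[2],
                     direction = "sym", value = v)
    })
    out$lps <- keep
  }

  if ("icoh" %in% config$measures) {
    prs <- icoh_pair_table(config, ep$roi_labels)
    if (nrow(prs) > 0) {
      freqs <- seq_len(floor(ep$fs / 2))
      if (config$icoh_fit == "joint") {
        model <- fit_mvar(ep, order = config$ar_order)
        ic <- isolated_effective_coherence(model, freqs, as.matrix(prs))
        ba <- band_average(ic, config$band[1], config$band[2])
      } else {
        per <- lapply(seq_len(n_trials(ep)), function(t) {
          e1 <- epoch_set(ep$data[t, , , drop = FALSE], ep$roi_labels,
                          ep$fs, ep$t0)
          m <- suppressWarnings(fit_mvar(e1, order = config$ar_order))
          isolated_effective_coherence(m, freqs, as.matrix(prs))
        })
        all <- dplyr::bind_rows(per)
        ba <- band_average(all, config$band[1], config$band[2])
      }
      ba$measure <- "icoh"
      ba$direction <- direction_label(ba$source, ba$target)
      out$icoh <- ba[c("measure", "source", "target", "direction", "value")]
    }
  }
  dplyr::bind_rows(out)
}

icoh_pair_table <- function(config, roi_labels) {
  prs <- list()
  for (pr in config$icoh_pairs) {
    if (all(pr %in% roi_labels)) {
      prs <- c(prs, list(c(pr[1], pr[2])), list(c(pr[2], pr[1])))
    }
  }
  if (config$heterotopic && length(config$icoh_pairs) >= 2) {
    sets <- config$icoh_pairs
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a == b) next
        for (x in sets[[a]]) for (y in sets[[b]]) {
          hx <- hemisphere(x); hy <- hemisphere(y)
          if (!is.na(hx) && !is.na(hy) && hx != hy &&
              all(c(x, y) %in% roi_labels)) {
            prs <- c(prs, list(c(x, y)))
          }
        }
      }
    }
  }
  if (length(prs) == 0) return(tibble::tibble(source = character(),
                                              target = character()))
  m <- unique(do.call(rbind, prs))
  tibble::tibble(source = m[, 1], target = m[, 2])
}

#' Run the full group analysis
#'
#' End-to-end study analysis: per subject and condition the trial counts
#' are balanced (seeded random subsampling to the smaller count), the
#' analysis window is applied, LPS and iCoh are band-averaged; then group
#' statistics are computed — paired Wilcoxon (LE vs RE) per LPS pair, a
#' 2x2 Condition x Direction repeated-measures ANOVA per homotopic iCoh
#' pair, the four Holm-corrected post-hoc Wilcoxon contrasts per pair, and
#' the behavioral laterality analysis (LI and a paired RE-vs-LE Wilcoxon).
#'
#' @param study A `study_data` object from [simulate_study()], or the path
#'   to a study manifest JSON (see [read_study()]).
#' @param config A [pipeline_config()].
#' @param seed Integer seed controlling trial subsampling.
#' @return An object of class `study_result`; see [tidy.study_result()] and
#'   [glance.study_result()].
#' @export
run_study <- function(study, config = pipeline_config(), seed = 1L) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "study_data"), inherits(config, "pipeline_config"))

  manifest <- study$manifest
  conditions <- sort(unique(manifest$condition))  # LE before RE
  if (length(conditions) != 2L) {
    stop("the group analysis requires exactly two conditions.", call. = FALSE)
  }
  tab <- table(manifest$subject)
  complete <- names(tab)[tab == 2L]
  dropped <- setdiff(unique(manifest$subject), complete)
  if (length(dropped) > 0) {
    message(length(dropped), " subject(s) excluded (missing a condition): ",
            paste(dropped, collapse = ", "))
  }
  if (length(complete) < 3L) {
    stop("fewer than 3 subjects with both conditions; aborting.", call. = FALSE)
  }
  subjects <- sort(complete)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                             length(subjects)))

  res <- vector("list", length(subjects) * 2L)
  row <- 0L
  for (s in seq_along(subjects)) {
    eps <- lapply(conditions, function(cn) get_epochs(study, subjects[s], cn))
    names(eps) <- conditions
    n_min <- min(vapply(eps, n_trials, integer(1)))
    eps <- lapply(eps, balance_trials, n_min = n_min, seed = seeds[s])
    for (cn in conditions) {
      row <- row + 1L
      sc <- subject_connectivity(eps[[cn]], config)
      sc$subject <- subjects[s]
      sc$condition <- cn
      res[[row]] <- sc
    }
  }
  subject_results <- dplyr::bind_rows(res)[
    c("subject", "condition", "measure", "source", "target", "direction",
      "value")
  ]

  # --- behavioral laterality -------------------------------------------
  laterality <- NULL
  if (!is.null(study$behavior) && nrow(study$behavior) > 0) {
    beh <- study$behavior[study$behavior$subject %in% subjects, ]
    per <- dplyr::mutate(beh, LI = laterality_index(.data$RE, .data$LE))
    laterality <- list(
      per_subject = per,
      summary = tibble::tibble(
        n = nrow(per), mean_li = mean(per$LI), sd_li = stats::sd(per$LI),
        n_positive = sum(per$LI > 0), n_negative = sum(per$LI < 0)
      ),
      rea_test = safe_wilcoxon(per$RE, per$LE)
    )
  }

  # --- LPS group tests (LE vs RE per unordered pair) -------------------
  lps_tests <- NULL
  lps <- subject_results[subject_results$measure == "lps", ]
  if (nrow(lps) > 0) {
    lps_tests <- lps |>
      dplyr::mutate(pair = paste0(.data$source, "-", .data$target)) |>
      tidyr::pivot_wider(id_cols = c("subject", "pair"),
                         names_from = "condition", values_from = "value") |>
      dplyr::group_by(.data$pair) |>
      dplyr::group_modify(function(d, g) {
        w <- safe_wilcoxon(d[[conditions[1]]], d[[conditions[2]]])
        w$median_a <- stats::median(d[[conditions[1]]])
        w$median_b <- stats::median(d[[conditions[2]]])
        w
      }) |>
      dplyr::ungroup() |>
      dplyr::rename(!!paste0("median_", conditions[1]) := "median_a",
                    !!paste0("median_", conditions[2]) := "median_b")
  }

  # --- iCoh ANOVAs + Holm post-hocs per homotopic pair -----------------
  anova_tab <- NULL
  posthoc <- NULL
  ic <- subject_results[subject_results$measure == "icoh" &
                          subject_results$direction %in% c("R->L", "L->R"), ]
  if (nrow(ic) > 0) {
    homot <- purrr::imap_dfr(config$icoh_pairs, function(pr, nm) {
      d <- ic[ic$source %in% pr & ic$target %in% pr, ]
      if (nrow(d) == 0) return(NULL)
      d$pair <- nm
      d
    })
    anova_tab <- homot |>
      dplyr::group_by(.data$pair) |>
      dplyr::group_modify(~ rm_anova_2x2(.x)) |>
      dplyr::ungroup()
    posthoc <- homot |>
      dplyr::group_by(.data$pair) |>
      dplyr::group_modify(~ posthoc_contrasts(.x, conditions)) |>
      dplyr::ungroup()
  }

  structure(
    list(subject_results = subject_results, laterality = laterality,
         lps_tests = lps_tests, anova = anova_tab, posthoc = posthoc,
         dropped_subjects = dropped, conditions = conditions,
         config = config, seed = as.integer(seed),
         log = list(seed = as.integer(seed), config_hash = rlang::hash(config),
                    n_subjects = length(subjects),
                    n_dropped = length(dropped),
                    timestamp = format(Sys.time(), tz = "UTC"))),
    class = "study_result"
  )
}

get_epochs <- function(study, subject, condition) {
  if (!is.null(study$epochs)) {
    ep <- study$epochs[[subject]][[condition]]
    if (is.null(ep)) stop("missing epochs for ", subject, "/", condition,
                          call. = FALSE)
    return(ep)
  }
  m <- study$manifest
  path <- m$path[m$subject == subject & m$condition == condition]
  if (length(path) != 1L || is.na(path)) {
    stop("missing epochs for ", subject, "/", condition, call. = FALSE)
  }
  if (!is.null(study$root)) path <- file.path(study$root, path)
  read_epochs(path)
}

balance_trials <- function(epochs, n_min, seed) {
  nt <- n_trials(epochs)
  if (nt == n_min) return(epochs)
  keep <- sort(withr::with_seed(seed, sample.int(nt, n_min)))
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$roi_labels,
            epochs$fs, epochs$t0)
}

# The four post-hoc contrasts reported per homotopic pair, Holm-corrected
# as a family of four.
posthoc_contrasts <- function(d, conditions) {
  wide <- tidyr::pivot_wider(d, id_cols = "subject",
                             names_from = c("condition", "direction"),
                             values_from = "value")
  cn1 <- conditions[1]; cn2 <- conditions[2]
  contrasts <- list(
    list(name = paste0(cn1, ": R->L vs L->R"),
         a = paste0(cn1, "_R->L"), b = paste0(cn1, "_L->R")),
    list(name = paste0(cn2, ": R->L vs L->R"),
         a = paste0(cn2, "_R->L"), b = paste0(cn2, "_L->R")),
    list(name = paste0("R->L: ", cn1, " vs ", cn2),
         a = paste0(cn1, "_R->L"), b = paste0(cn2, "_R->L")),
    list(name = paste0("L->R: ", cn1, " vs ", cn2),
         a = paste0(cn1, "_L->R"), b = paste0(cn2, "_L->R"))
  )
  out <- purrr::map_dfr(contrasts, function(ct) {
    w <- safe_wilcoxon(wide[[ct$a]], wide[[ct$b]])
    w$contrast <- ct$name
    w
  })
  out$p_holm <- ifelse(is.na(out$p), NA_real_,
                       holm_adjust(ifelse(is.na(out$p), 1, out$p)))
  out[c("contrast", "n_pairs", "statistic", "z", "p", "p_holm", "r")]
}

# Wilcoxon tests need >= 5 pairs; for smaller groups the group-level test
# is reported as NA rather than aborting the whole study analysis.
safe_wilcoxon <- function(a, b) {
  if (sum(is.finite(a) & is.finite(b)) < 5L) {
    message("fewer than 5 pairs; Wilcoxon test reported as NA.")
    return(tibble::tibble(n_pairs = length(a), n_nonzero = NA_integer_,
                          statistic = NA_real_, z = NA_real_, p = NA_real_,
                          r = NA_real_))
  }
  wilcoxon_paired(a, b)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subjects, conditions %s\n",
              x$log$n_subjects, paste(x$conditions, collapse = "/")))
  if (!is.null(x$laterality)) {
    cat(sprintf("  LI: mean %.2f (sd %.2f), REA test z = %.2f, p = %.3g\n",
                x$laterality$summary$mean_li, x$laterality$summary$sd_li,
                x$laterality$rea_test$z, x$laterality$rea_test$p))
  }
  if (!is.null(x$anova)) {
    inter <- x$anova[x$anova$effect == "condition:direction", ]
    for (i in seq_len(nrow(inter))) {
      cat(sprintf("  %s Condition x Direction: F(%d,%d) = %.3f, p = %.3g, eta2p = %.2f\n",
                  inter$pair[i], inter$df1[i], inter$df2[i],
                  inter$statistic[i], inter$p[i], inter$eta_sq_partial[i]))
    }
  }
  invisible(x)
}

#' Tidy the group statistics of a study result
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return A long tibble of all inferential results with columns `analysis`,
#'   `pair`, `term`, `statistic`, `df1`, `df2`, `z`, `p`, `p_holm`,
#'   `effect_size`.
#' @export
tidy.study_result <- function(x, ...) {
  out <- list()
  if (!is.null(x$laterality)) {
    w <- x$laterality$rea_test
    out$rea <- tibble::tibble(
      analysis = "behavior", pair = "RE vs LE", term = "wilcoxon",
      statistic = w$statistic, df1 = NA_real_, df2 = NA_real_, z = w$z,
      p = w$p, p_holm = NA_real_, effect_size = w$r
    )
  }
  if (!is.null(x$lps_tests)) {
    out$lps <- tibble::tibble(
      analysis = "lps", pair = x$lps_tests$pair, term = "wilcoxon",
      statistic = x$lps_tests$statistic, df1 = NA_real_, df2 = NA_real_,
      z = x$lps_tests$z, p = x$lps_tests$p, p_holm = NA_real_,
      effect_size = x$lps_tests$r
    )
  }
  if (!is.null(x$anova)) {
    out$anova <- tibble::tibble(
      analysis = "icoh_anova", pair = x$anova$pair, term = x$anova$effect,
      statistic = x$anova$statistic, df1 = x$anova$df1, df2 = x$anova$df2,
      z = NA_real_, p = x$anova$p, p_holm = NA_real_,
      effect_size = x$anova$eta_sq_partial
    )
  }
  if (!is.null(x$posthoc)) {
    out$posthoc <- tibble::tibble(
      analysis = "icoh_posthoc", pair = x$posthoc$pair,
      term = x$posthoc$contrast, statistic = x$posthoc$statistic,
      df1 = NA_real_, df2 = NA_real_, z = x$posthoc$z, p = x$posthoc$p,
      p_holm = x$posthoc$p_holm, effect_size = x$posthoc$r
    )
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a study result
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return A tibble with subject counts, the behavioral laterality summary
#'   and the SAC Condition x Direction interaction.
#' @export
glance.study_result <- function(x, ...) {
  g <- tibble::tibble(n_subjects = x$log$n_subjects,
                      n_dropped = x$log$n_dropped)
  if (!is.null(x$laterality)) {
    g$mean_li <- x$laterality$summary$mean_li
    g$sd_li <- x$laterality$summary$sd_li
    g$rea_p <- x$laterality$rea_test$p
  }
  if (!is.null(x$anova)) {
    inter <- x$anova[x$anova$effect == "condition:direction", ]
    first <- inter[1, ]
    g$interaction_pair <- first$pair
    g$interaction_F <- first$statistic
    g$interaction_p <- first$p
    g$interaction_eta_sq <- first$eta_sq_partial
  }
  g
}

#' Plot per-subject band-averaged connectivity of a study
#'
#' Boxplots of the per-subject band-averaged values by condition (and
#' direction for iCoh), faceted by measure and ROI pair.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, ...) {
  d <- object$subject_results
  d$pair <- paste0(d$source, "-", d$target)
  d$group <- ifelse(d$measure == "lps", d$condition,
                    paste(d$condition, d$direction))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ measure + pair, scales = "free") +
    ggplot2::labs(x = NULL, y = "band-averaged connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
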