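#' Behavioral laterality index
#'
#' `LI = 100 * (RE - LE) / (RE + LE)`, where RE and LE are the numbers of
#' correct right-ear and left-ear reports. The scale runs from -100 to 100;
#' positive values indicate a right-ear advantage (REA), negative a
#' left-ear advantage.
#'
#' @param re,le Correct right-ear / left-ear report counts (vectorized).
#' @return Numeric LI values in `[-100, 100]`.
#' @examples
#' laterality_index(134.81, 80.00)
#' @export
laterality_index <- function(re, le) {
  if (length(re) != length(le)) {
    stop("`re` and `le` must have equal length.", call. = FALSE)
  }
  if (any(re < 0 | le < 0, na.rm = TRUE)) {
    stop("report counts must be non-negative.", call. = FALSE)
  }
  if (any(re + le == 0, na.rm = TRUE)) {
    stop("LI is undefined when RE + LE = 0.", call. = FALSE)
  }
  100 * (re - le) / (re + le)
}

#' Paired Wilcoxon signed-rank test with Z and effect size r
#'
#' Signed-rank test on paired differences using the normal approximation
#' with the standard tie correction; zero differences are dropped before
#' ranking. The effect size follows the `r = |Z| / sqrt(n_pairs)`
#' convention, with `n_pairs` the number of complete pairs supplied (before
#' zero differences are removed).
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A one-row tibble: `n_pairs`, `n_nonzero`, `statistic` (sum of
#'   positive-difference ranks), `z`, `p` (two-sided), `r`.
#' @examples
#' wilcoxon_paired(c(1, 2, 3, 5, 8, 9), c(0, 1, 1, 2, 2, 3))
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length.", call. = FALSE)
  }
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; test is degenerate.",
            call. = FALSE)
    return(tibble::tibble(n_pairs = n_pairs, n_nonzero = 0L,
                          statistic = NA_real_, z = 0, p = 1, r = 0))
  }
  if (n_pairs < 5L) {
    stop("need at least 5 pairs for the signed-rank test.", call. = FALSE)
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    warning("zero variance in signed ranks; test is degenerate.",
            call. = FALSE)
    return(tibble::tibble(n_pairs = n_pairs, n_nonzero = n,
                          statistic = W, z = 0, p = 1, r = 0))
  }
  z <- (W - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(n_pairs = n_pairs, n_nonzero = n, statistic = W,
                 z = z, p = min(p, 1),
                 r = wilcoxon_effect_size_r(z, n_pairs))
}

#' Wilcoxon effect size r
#'
#' The `r = |Z| / sqrt(n)` convention for reporting signed-rank effect
#' sizes, with `n` the number of pairs entering the test.
#'
#' @param z Normal-approximation Z statistic.
#' @param n Number of pairs.
#' @return The effect size r.
#' @examples
#' wilcoxon_effect_size_r(3.181, 33)
#' @export
wilcoxon_effect_size_r <- function(z, n) {
  stopifnot(n > 0)
  abs(z) / sqrt(n)
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA (e.g. Condition x Direction), fit
#' with `stats::aov` and an `Error(subject/(condition*direction))` stratum
#' structure. With two levels per factor sphericity holds trivially
#' (a Greenhouse-Geisser epsilon of 1), and each F equals the squared
#' paired t of the corresponding within-subject contrast. Effect sizes are
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' Subjects with incomplete cells are dropped listwise (with a message).
#'
#' @param data Data frame with columns `subject`, `condition`, `direction`
#'   (two levels each of the latter two) and `value` — one value per cell.
#' @return A tibble with one row per effect (`condition`, `direction`,
#'   `condition:direction`): `df1`, `df2`, `statistic` (F), `p`,
#'   `eta_sq_partial`. A zero-variance error stratum yields `statistic =
#'   Inf`, `p = 0` and a warning.
#' @export
rm_anova_2x2 <- function(data) {
  req <- c("subject", "condition", "direction", "value")
  stopifnot(is.data.frame(data), all(req %in% names(data)))
  df <- tibble::as_tibble(data[req])
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$condition)) != 2L || length(unique(df$direction)) != 2L) {
    stop("`condition` and `direction` must each have exactly two levels.",
         call. = FALSE)
  }
  cells <- dplyr::count(df, .data$subject)
  if (any(cells$n != 4L)) {
    bad <- cells$subject[cells$n != 4L]
    message(length(bad), " subject(s) dropped for incomplete cells.")
    df <- df[!df$subject %in% bad, ]
  }
  n_sub <- length(unique(df$subject))
  if (n_sub < 3L) stop("need at least 3 complete subjects.", call. = FALSE)
  df$subject <- factor(df$subject)
  df$condition <- factor(df$condition)
  df$direction <- factor(df$direction)

  fit <- stats::aov(
    value ~ condition * direction + Error(subject / (condition * direction)),
    data = df
  )
  sm <- summary(fit)
  effects <- c("condition", "direction", "condition:direction")
  out <- purrr::map_dfr(effects, function(eff) {
    tab <- find_stratum(sm, eff)
    rn <- trimws(rownames(tab))
    ss_eff <- tab[rn == eff, "Sum Sq"]
    ss_err <- tab[rn == "Residuals", "Sum Sq"]
    df1 <- tab[rn == eff, "Df"]
    df2 <- tab[rn == "Residuals", "Df"]
    if (length(ss_err) != 1L) {
      stop("no residual stratum for effect '", eff,
           "'; is there exactly one value per cell?", call. = FALSE)
    }
    if (ss_err <= 1e-12 * max(ss_eff, 1e-300)) {
      warning(sprintf("zero error variance for effect '%s'; F is infinite.",
                      eff), call. = FALSE)
      Fv <- Inf; pv <- 0
    } else {
      Fv <- (ss_eff / df1) / (ss_err / df2)
      pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    tibble::tibble(effect = eff, df1 = df1, df2 = df2, statistic = Fv,
                   p = pv, eta_sq_partial = ss_eff / (ss_eff + ss_err))
  })
  out
}

find_stratum <- function(sm, eff) {
  for (st in sm) {
    tab <- if (is.list(st)) st[[1]] else st
    if (eff %in% trimws(rownames(tab))) return(as.matrix(tab))
  }
  stop("effect '", eff, "' not found in ANOVA strata.", call. = FALSE)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Step-down Holm (sequentially rejective Bonferroni) adjusted p-values,
#' capped at 1 and monotone in the raw p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}
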