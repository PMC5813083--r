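test_that("laterality index follows 100 * (RE - LE) / (RE + LE)", {
  expect_equal(laterality_index(120, 120), 0)
  expect_equal(laterality_index(192, 0), 100)
  expect_equal(laterality_index(0, 192), -100)
  expect_equal(laterality_index(134.81, 80.00), 25.515, tolerance = 1e-3)
  expect_equal(laterality_index(c(10, 20), c(20, 10)), c(-100 / 3, 100 / 3))
  expect_error(laterality_index(0, 0), "undefined")
  expect_error(laterality_index(-1, 5), "non-negative")
})

test_that("wilcoxon_paired matches the normal-approximation reference", {
  withr::with_seed(14, {
    for (i in 1:10) {
      a <- rnorm(25)
      b <- rnorm(25, 0.3)
      if (i %% 2 == 0) b <- round(b, 1)  # induce ties
      ours <- wilcoxon_paired(a, b)
      ref <- suppressWarnings(
        wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
      )
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$r, abs(ours$z) / sqrt(25))
    }
  })
})

test_that("a uniformly shifted sample attains the extreme signed-rank p", {
  a <- rnorm(20)
  ours <- wilcoxon_paired(a, a + 1)
  expect_equal(ours$statistic, 0)          # all differences negative
  # exact enumeration oracle: the extreme two-sided p for n = 20 is
  # 2 * P(W <= 0) = 2 / 2^20 under the signed-rank null distribution
  p_exact <- 2 * psignrank(0, 20)
  expect_equal(p_exact, 2 / 2^20)
  expect_lt(ours$p, 1e-4)                  # normal approximation, extreme tail
})

test_that("degenerate paired inputs are handled explicitly", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_warning(out <- wilcoxon_paired(a, a), "zero")
  expect_equal(out$p, 1)
  expect_equal(out$r, 0)
  expect_error(wilcoxon_paired(1:3, 2:4), "at least 5")
})

test_that("effect size convention reproduces the printed group value", {
  expect_equal(round(wilcoxon_effect_size_r(3.181, 33), 2), 0.55)
})

test_that("rm_anova_2x2 equals squared paired t tests on each contrast", {
  withr::with_seed(8, {
    n <- 14
    d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:n),
                            condition = c("LE", "RE"),
                            direction = c("L->R", "R->L"))
    d$value <- rnorm(nrow(d), 0.1) +
      0.3 * (d$condition == "LE" & d$direction == "R->L")
    out <- rm_anova_2x2(d)

    wide <- tidyr::pivot_wider(d, names_from = c(condition, direction),
                               values_from = value)
    cond <- (wide$`LE_L->R` + wide$`LE_R->L`) -
      (wide$`RE_L->R` + wide$`RE_R->L`)
    dir <- (wide$`LE_R->L` + wide$`RE_R->L`) -
      (wide$`LE_L->R` + wide$`RE_L->R`)
    inter <- (wide$`LE_R->L` - wide$`LE_L->R`) -
      (wide$`RE_R->L` - wide$`RE_L->R`)
    for (row in list(list("condition", cond), list("direction", dir),
                     list("condition:direction", inter))) {
      tt <- t.test(row[[2]])
      got <- out[out$effect == row[[1]], ]
      expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(got$p, tt$p.value, tolerance = 1e-10)
      expect_equal(got$df1, 1)
      expect_equal(got$df2, n - 1)
      # partial eta^2 from the t statistic: t^2 / (t^2 + df)
      expect_equal(got$eta_sq_partial,
                   unname(tt$statistic)^2 / (unname(tt$statistic)^2 + n - 1),
                   tolerance = 1e-10)
    }
  })
})

test_that("rm_anova_2x2 flags zero-variance designs and drops incomplete subjects", {
  d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:6),
                          condition = c("LE", "RE"),
                          direction = c("L->R", "R->L"))
  d$value <- 1 + 0.5 * (d$condition == "LE" & d$direction == "R->L")
  expect_warning(out <- rm_anova_2x2(d), "infinite")
  expect_true(is.infinite(out$statistic[out$effect == "condition:direction"]))
  expect_equal(out$p[out$effect == "condition:direction"], 0)

  withr::with_seed(3, {
    d2 <- tidyr::expand_grid(subject = sprintf("S%02d", 1:6),
                             condition = c("LE", "RE"),
                             direction = c("L->R", "R->L"))
    d2$value <- rnorm(nrow(d2))
    d2 <- d2[-1, ]                        # S01 incomplete
    expect_message(out2 <- rm_anova_2x2(d2), "dropped")
    expect_equal(unique(out2$df2), 4)     # 5 remaining subjects
  })

  expect_error(
    rm_anova_2x2(tibble::tibble(subject = c("a", "a", "a", "a"),
                                condition = c("LE", "LE", "RE", "RE"),
                                direction = c("x", "y", "x", "y"),
                                value = 1:4)),
    "at least 3"
  )
})

test_that("holm_adjust reproduces the hand-worked step-down values", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.06, 0.06, 0.06))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("holm_adjust is permutation-equivariant and monotone", {
  withr::with_seed(5, {
    p <- runif(9)
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    perm <- sample(9)
    expect_equal(holm_adjust(p[perm]), adj[perm])
    o <- order(p)
    expect_true(all(diff(adj[o]) >= 0))
  })
})
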