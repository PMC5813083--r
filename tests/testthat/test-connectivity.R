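test_that("coherency is Hermitian with unit diagonal and detects identity", {
  ep <- white_epochs(30, 2, 64, seed = 4)
  # duplicate roi1: perfectly coherent pair at every frequency
  dup <- epoch_set(array(ep$data[, c(1, 1), ], c(30, 2, 64)),
                   c("x", "x_copy"), fs = 256)
  co <- coherency(dup)
  expect_equal(Mod(co$values[, 1, 2]), rep(1, length(co$freqs)),
               tolerance = 1e-12)
  for (fi in seq_along(co$freqs)) {
    expect_equal(co$values[fi, , ], Conj(t(co$values[fi, , ])),
                 tolerance = 1e-12)
    expect_equal(diag(co$values[fi, , ]), c(1, 1) + 0i, tolerance = 1e-12)
  }
  expect_true(all(Mod(co$values) <= 1 + 1e-12))
})

test_that("a pure delay keeps unit coherence magnitude with nonzero phase", {
  ep <- white_epochs(20, 1, 64, seed = 6)
  dat <- array(0, c(20, 2, 64))
  dat[, 1, ] <- ep$data[, 1, ]
  dat[, 2, ] <- ep$data[, 1, c(64, 1:63)]            # circular 1-sample delay
  both <- epoch_set(dat, c("x", "x_delayed"), fs = 256)
  co <- coherency(both, demean = FALSE)
  f <- co$values[, 1, 2]
  expect_equal(Mod(f), rep(1, length(f)), tolerance = 1e-10)
  inner <- co$freqs > 0 & co$freqs < 128
  expect_true(all(abs(Arg(f[inner])) > 1e-3))
})

test_that("independent white noise stays below the trial-count null bound", {
  ep <- white_epochs(1000, 2, 50, seed = 8)
  co <- coherency(ep)
  bound <- sqrt(-log(0.05) / 1000)      # ~0.055 per-entry 95% null bound
  expect_lt(median(Mod(co$values[, 1, 2])), bound)
  expect_lt(max(Mod(co$values[, 1, 2])), 2 * bound)
})

test_that("coherency requires at least two trials", {
  ep <- white_epochs(1, 2, 32, seed = 2)
  expect_error(coherency(ep), "single trial")
})

test_that("lagged phase synchronization applies Im^2 / (1 - Re^2)", {
  expect_equal(lagged_phase_synchronization(coherency_fixture(0 + 0i))$value,
               rep(0, 2))
  expect_equal(lagged_phase_synchronization(coherency_fixture(0.6i))$value,
               rep(0.36, 2))
  # purely instantaneous coherence is excluded entirely
  expect_equal(lagged_phase_synchronization(coherency_fixture(0.5 + 0i))$value,
               rep(0, 2))
  # mixed case: direct evaluation of the formula
  f <- 0.3 + 0.4i
  expect_equal(lagged_phase_synchronization(coherency_fixture(f))$value,
               rep(0.4^2 / (1 - 0.3^2), 2))
})

test_that("LPS guards perfect instantaneous coherence with a warning", {
  expect_warning(
    out <- lagged_phase_synchronization(coherency_fixture(1 + 0i)),
    "instantaneous"
  )
  expect_equal(out$value, rep(0, 2))
})

test_that("LPS output is exactly symmetric and within [0, 1]", {
  ep <- simulate_epochs(sim_config(), "LE", seed = 31)
  lps <- lagged_phase_synchronization(coherency(ep))
  m <- connectivity_matrix(lps, lps$freq[5])
  off <- !diag(nrow(m))
  expect_identical(m[off], t(m)[off])
  expect_true(all(lps$value >= 0 & lps$value <= 1))
})

test_that("iCoh matches the bivariate closed form", {
  m <- mvar_model(list(matrix(c(0, 1, 0, 0), 2, 2)), diag(2), fs = 256,
                  c("src", "tgt"))
  ic <- isolated_effective_coherence(m)
  fwd <- ic$value[ic$source == "src" & ic$target == "tgt"]
  rev <- ic$value[ic$source == "tgt" & ic$target == "src"]
  expect_equal(fwd, rep(0.5, 128))       # c^2 / (c^2 + 1) with c = 1
  expect_equal(rev, rep(0, 128))

  # general coupling strength c at zero self-dynamics: kappa = c^2/(c^2+1)
  for (c_val in c(0.3, 0.7, 2)) {
    m2 <- mvar_model(list(matrix(c(0, c_val, 0, 0), 2, 2)), diag(2), 256)
    ic2 <- isolated_effective_coherence(m2, freqs = c(10, 50))
    expect_equal(ic2$value[ic2$source == "roi1" & ic2$target == "roi2"],
                 rep(c_val^2 / (c_val^2 + 1), 2))
  }
})

test_that("iCoh of a diagonal (uncoupled) model is zero everywhere", {
  A <- array(0, c(3, 3, 2))
  diag(A[, , 1]) <- 0.8
  diag(A[, , 2]) <- -0.5
  m <- mvar_model(A, diag(c(1, 2, 0.5)), fs = 256)
  ic <- isolated_effective_coherence(m)
  expect_true(all(ic$value == 0))
})

test_that("iCoh lies in [0, 1] and matches the naive oracle on random models", {
  freqs <- c(1, 17.3, 40, 77, 128)
  for (s in 1:40) {
    m <- random_stable_model(3, 2, seed = 900 + s)
    ic <- isolated_effective_coherence(m, freqs = freqs)
    expect_true(all(ic$value >= 0 & ic$value <= 1))
    for (pair in list(c(1, 2), c(3, 1))) {
      src <- m$roi_labels[pair[1]]; tgt <- m$roi_labels[pair[2]]
      got <- ic$value[ic$source == src & ic$target == tgt]
      expect_equal(got, naive_icoh(m, tgt, src, freqs), tolerance = 1e-10)
    }
  }
})

test_that("iCoh input validation", {
  m <- random_stable_model(2, 1, seed = 1)
  expect_error(isolated_effective_coherence(m, pairs = list(c("roi1", "roi1"))),
               "source != target")
  expect_error(isolated_effective_coherence(m, freqs = 500), "fs/2")
  m_un <- mvar_model(list(matrix(c(1.05, 0.2, 0, 1.05), 2, 2)), diag(2), 256)
  expect_warning(isolated_effective_coherence(m_un, freqs = 10), "unstable")
})

test_that("band_average takes the inclusive arithmetic mean over the band", {
  grid <- tibble::tibble(
    freq = c(30, 65, 100, 110),
    source = "a", target = "b",
    value = c(0.2, 0.4, 0.6, 9)
  )
  expect_equal(band_average(grid, 30, 100)$value, 0.4)

  const <- tibble::tibble(freq = seq(30, 100, 5), source = "a", target = "b",
                          value = 0.5)
  expect_equal(band_average(const, 30, 100)$value, 0.5)

  expect_error(band_average(grid, 200, 300), "does not intersect")

  # band edges are inclusive on both sides
  edges <- tibble::tibble(freq = c(29.9, 30, 100, 100.1), source = "a",
                          target = "b", value = c(100, 0.1, 0.3, 100))
  expect_equal(band_average(edges, 30, 100)$value, 0.2)
})

test_that("band-averaged closed-form iCoh stays at the closed-form value", {
  m <- mvar_model(list(matrix(c(0, 1, 0, 0), 2, 2)), diag(2), fs = 256)
  ic <- isolated_effective_coherence(m)
  ba <- band_average(ic, 30, 100)
  expect_equal(ba$value[ba$source == "roi1" & ba$target == "roi2"], 0.5)
})
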