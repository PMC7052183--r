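test_that("every estimator matches its brute-force oracle on random short series", {
  for (i in 1:50) {
    x <- withr::with_seed(2000 + i, {
      n <- sample(20:40, 1)
      if (i %% 3 == 0) cumsum(rnorm(n)) else rnorm(n)
    })
    expect_equal(renyi_entropy(x, 2), oracle_renyi(x, 2), tolerance = 1e-12)
    expect_equal(fuzzy_entropy(x, 2, 0.15, 2), oracle_fuzzy(x, 2, 0.15, 2),
                 tolerance = 1e-12)
    expect_equal(dispersion_entropy(x, 2, 6, 1), oracle_disen(x, 2, 6, 1),
                 tolerance = 1e-12)
    expect_equal(rdis_entropy(x, 2, 8, 2), oracle_rdis(x, 2, 8, 2),
                 tolerance = 1e-12)
    expect_equal(impe(x, 3, 2), oracle_impe(x, 3, 2), tolerance = 1e-12)
    base <- baseline_entropies(x, 2, 0.15)
    expect_equal(base$ApEn, oracle_apen(x, 2, 0.15), tolerance = 1e-12)
    expect_equal(base$SamEn, oracle_samen(x, 2, 0.15), tolerance = 1e-12)
  }
})

test_that("analytic identities hold", {
  expect_equal(fuzzy_entropy(rep(5, 30)), 0)
  expect_equal(dispersion_entropy(rep(5, 30)), 0)
  expect_equal(rdis_entropy(rep(5, 30)), 0)
  expect_equal(impe(1:60, 3, 2), 0)
  expect_equal(impe(1:60, 4, 3), 0)

  # exactly two equal-power spectral bins at q = 2 give 1 bit
  n <- 64
  x2 <- cos(2 * pi * 8 * (0:(n - 1)) / n) + cos(2 * pi * 16 * (0:(n - 1)) / n)
  expect_equal(renyi_entropy(x2, 2), 1, tolerance = 1e-9)
  # bin-aligned pure sine concentrates the spectrum: ~0 bits
  expect_lte(renyi_entropy(sin(2 * pi * 8 * (0:255) / 256), 2), 0.05)

  # distances uniform over all M bins give exactly 1
  expect_equal(rdis_entropy(c(0, 1, 3, 99), a = 1, M = 3, q = 2), 1)

  # IMPE at scale 1 is plain permutation entropy
  x <- withr::with_seed(3, runif(300))
  expect_equal(impe(x, 3, 1), permutation_entropy(x, 3), tolerance = 1e-15)
  expect_equal(impe(x, 3, 2), oracle_impe(x, 3, 2), tolerance = 1e-12)
})

test_that("entropy bounds hold across random signals", {
  for (i in 1:20) {
    x <- withr::with_seed(300 + i, rnorm(sample(50:200, 1)))
    expect_lte(dispersion_entropy(x, 2, 6), 2 * log(6) + 1e-12)
    rd <- rdis_entropy(x, 2, 64, 2)
    expect_gte(rd, 0); expect_lte(rd, 1)
    expect_lte(impe(x, 3, 2), log(factorial(3)) + 1e-12)
    expect_lte(renyi_entropy(x, 2), log2(length(x) %/% 2) + 1e-12)
    expect_gte(fuzzy_entropy(x), -1e-12)
  }
})

test_that("CDF- and rank-based estimators are invariant to positive affine maps", {
  for (i in 1:10) {
    x <- withr::with_seed(400 + i, rnorm(150))
    y <- 3.7 * x + 11
    expect_equal(dispersion_entropy(y, 2, 6), dispersion_entropy(x, 2, 6),
                 tolerance = 1e-12)
    expect_equal(rdis_entropy(y, 2, 64, 2), rdis_entropy(x, 2, 64, 2),
                 tolerance = 1e-12)
    expect_equal(impe(y, 3, 2), impe(x, 3, 2), tolerance = 1e-12)
  }
})

test_that("constant series yield zero baselines and SamEn flags empty matches", {
  b <- baseline_entropies(rep(2, 30))
  expect_equal(b$ApEn, 0)
  expect_equal(b$SamEn, 0)
  # an alternating small/large series whose templates never match within r
  x <- c(0, 10, 1, 20, 2, 30, 3.5, 40, 0.5, 50, 2.2, 60)
  b2 <- baseline_entropies(x, 2, 0.15)
  expect_true(is.na(b2$SamEn))
  expect_false(b2$SamEn_defined)
})

test_that("length-stability study reproduces the short-series behaviour", {
  lengths <- seq(100, 500, by = 50)
  tab <- length_stability_study(rr_iid, lengths, reps = 5, seed = 21)
  expect_equal(sum(tab$n_undefined), 0)
  for (est in unique(tab$estimator)) {
    m <- tab$mean[tab$estimator == est]
    expect_lte(sd(m) / mean(m), 0.25)
  }

  short <- length_stability_study(rr_iid, c(50, 100),
                                  estimators = c("SamEn"), reps = 10,
                                  seed = 22)
  expect_gte(short$n_undefined[short$length == 50], 1)

  again <- length_stability_study(rr_iid, c(50, 100),
                                  estimators = c("SamEn"), reps = 10,
                                  seed = 22)
  expect_identical(tabulate(short$n_undefined), tabulate(again$n_undefined))
  expect_identical(short, again)
})
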