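# Truncated-normal selection theory. Expected values below were computed
# with an independent oracle: numerical integration of the standard-normal
# density (threshold by root-finding on the integrated tail mass, moments of
# the truncated distribution by quadrature to 1e-13 relative tolerance).

test_that("intensity and truncation point match the integration oracle", {
  cases <- list(
    #      p        t               i               k
    list(0.700, -0.5244005127, 0.4967037346, 0.5071862930),
    list(0.500,  0.0000000000, 0.7978845608, 0.6366197724),
    list(0.125,  1.1503493804, 1.6468282414, 0.8176154095),
    list(0.050,  1.6448536270, 2.0627128075, 0.8619234835),
    list(0.010,  2.3263478740, 2.6652142203, 0.9031514050)
  )
  for (cs in cases) {
    st <- selection_intensity(cs[[1]])
    expect_equal(st$t, cs[[2]], tolerance = 1e-9)
    expect_equal(st$i, cs[[3]], tolerance = 1e-9)
    expect_equal(variance_reduction(st$i, st$t), cs[[4]], tolerance = 1e-9)
  }
})

test_that("no selection gives zero intensity and variance reduction", {
  st <- selection_intensity(1)
  expect_identical(st$i, 0)
  expect_identical(st$t, -Inf)
  expect_identical(variance_reduction(st$i, st$t), 0)
})

test_that("invalid proportions are rejected", {
  expect_error(selection_intensity(0), "proportion")
  expect_error(selection_intensity(-0.1), "proportion")
  expect_error(selection_intensity(1.2), "proportion")
  expect_error(build_regime(c(0.5, 0.5, 0.5, 0)), "proportion")
})

test_that("build_regime orders paths and zeroes unselected paths", {
  rg <- build_regime(c(0.05, 0.125, 0.01, 0.70))
  expect_identical(rg$path, PATHS)
  expect_gt(rg$i[1], rg$i[2])   # SS selected harder than SD
  expect_gt(rg$i[2], rg$i[4])   # and than DD
  expect_gt(rg$k[1], rg$k[2])
  rg2 <- build_regime(c(0.01, 0.05, 0.01, 0.70))
  expect_equal(rg2$i[1], rg2$i[3])  # equal proportions, equal intensity
  rg3 <- build_regime(c(1, 1, 1, 1))
  expect_identical(rg3$i, rep(0, 4))
  expect_identical(rg3$k, rep(0, 4))
})

test_that("intensity and variance reduction decrease in the proportion", {
  p <- seq(0.01, 0.999, length.out = 60)
  i <- vapply(p, function(p) selection_intensity(p)$i, 0)
  k <- vapply(p, function(p) {
    st <- selection_intensity(p); variance_reduction(st$i, st$t)
  }, 0)
  expect_true(all(diff(i) < 0))
  expect_true(all(diff(k) < 0))
  expect_lt(selection_intensity(0.9999)$i, 0.001)
  expect_true(all(k >= 0 & k < 1))
})

test_that("analytic intensity and k agree with Monte-Carlo truncation", {
  set.seed(1)
  z <- rnorm(1e6)
  for (p in c(0.30, 0.05)) {
    st <- selection_intensity(p)
    kept <- z[z > st$t]
    n <- length(kept)
    se_i <- sd(kept) / sqrt(n)
    expect_lt(abs(mean(kept) - st$i), 3 * se_i)
    k_hat <- 1 - var(kept)
    se_k <- sd((kept - mean(kept))^2) / sqrt(n)
    expect_lt(abs(k_hat - variance_reduction(st$i, st$t)), 3 * se_k)
  }
})
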