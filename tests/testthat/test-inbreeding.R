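# deltaF assembly, effective population size, shares, and the family-size
# correction.

test_that("no-selection closed form and algebraic reductions", {
  expect_equal(delta_f_no_selection(c(20, 50, 100, 7000)),
               (1 / 32) * (1 / 20 + 3 / 50 + 1 / 100 + 3 / 7000))
  for (c in c(10, 25, 400))
    expect_equal(delta_f_no_selection(rep(c, 4)), 1 / (4 * c))
  expect_error(delta_f_no_selection(c(0, 1, 1, 1)))
})

test_that("unselected chain equals the closed form to machine precision", {
  set.seed(42)
  for (j in 1:200) {
    N <- sort(sample(2:500, 2))            # N_SS <= N_SD
    Nd <- sort(sample(2:5000, 2))          # N_DS <= N_DD
    N <- c(N[1], N[2], Nd[1], Nd[2])
    scn <- breeding_scenario(N, c(1, 1, 1, 1))
    rpt <- suppressWarnings(predict_inbreeding(scn, gen_h03_5()))
    expect_equal(rpt$deltaF_selection, delta_f_no_selection(N),
                 tolerance = 1e-12)
  }
})

test_that("effective population size inverts deltaF", {
  expect_equal(effective_population_size(0.005), 100)
  expect_equal(round(effective_population_size(
    delta_f_no_selection(c(20, 50, 100, 7000))), 1), 132.9)
  expect_error(effective_population_size(0), "positive")
})

test_that("deltaF decreases when any parent number increases", {
  ge <- gen_h03_5()
  N0 <- c(20, 50, 100, 7000)
  base <- suppressWarnings(
    predict_inbreeding(breeding_scenario(N0, c(0.05, 0.125, 0.01, 0.70)), ge))
  for (x in 1:4) {
    N1 <- N0; N1[x] <- N1[x] * 2
    more <- suppressWarnings(
      predict_inbreeding(breeding_scenario(N1, c(0.05, 0.125, 0.01, 0.70)), ge))
    expect_lt(more$deltaF_selection, base$deltaF_selection)
    expect_lt(more$deltaF_no_selection, base$deltaF_no_selection)
  }
})

test_that("scaling all parent numbers scales deltaF inversely", {
  ge <- gen_h03_5()
  N0 <- c(20, 50, 100, 7000)
  p <- c(0.05, 0.125, 0.01, 0.70)
  base <- predict_inbreeding(breeding_scenario(N0, p), ge)
  for (c in c(2, 3)) {
    sc <- predict_inbreeding(breeding_scenario(c * N0, p), ge)
    expect_equal(sc$deltaF_no_selection, base$deltaF_no_selection / c)
    expect_equal(sc$deltaF_selection, base$deltaF_selection / c,
                 tolerance = 0.05)
  }
})

test_that("accounting shares are an exact partition of deltaF", {
  for (ge in list(gen_h03_5(), gen_idx_5())) {
    rpt <- predict_inbreeding(scn_mid(), ge)
    sh <- rpt$accounting_shares
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    expect_equal(attr(sh, "residual"), 0, tolerance = 1e-12)
    expect_true(all(sh > 0))
    expect_gt(sh[["SS"]], sh[["SD"]])  # elite male path dominates
    expect_lt(sh[["DD"]], 0.01)
  }
  # at beta = 0 and equal N the shared cross moments make the paths
  # symmetric: the partition assigns a quarter to each
  scn <- breeding_scenario(rep(100, 4), c(1, 1, 1, 1))
  rpt <- predict_inbreeding(scn, gen_h03_5())
  expect_equal(as.numeric(rpt$accounting_shares), rep(0.25, 4))
})

test_that("family-size correction is small, negative, and vanishes with q", {
  rpt <- predict_inbreeding(scn_small(), gen_h03_5())
  expect_lt(rpt$correction_aggregate, 0)
  expect_lt(abs(rpt$correction_aggregate), rpt$deltaF_selection / 10)
  expect_equal(rpt$deltaF_corrected,
               rpt$deltaF_selection + rpt$correction_aggregate)
  expect_true(all(rpt$delta_corrections <= 0))
  # shrinking all retained proportions drives the correction to zero
  ge <- gen_h03_5()
  mags <- vapply(c(1e-2, 1e-3, 1e-4), function(q) {
    scn <- breeding_scenario(c(20, 50, 100, 7000), rep(q, 4))
    abs(predict_inbreeding(scn, ge)$correction_aggregate)
  }, 0)
  expect_true(all(diff(mags) < 0))
  expect_lt(mags[3], 1e-6)
})

test_that("headline deltaF respects the correction flag", {
  rpt0 <- predict_inbreeding(scn_small(), gen_h03_5())
  rpt1 <- predict_inbreeding(scn_small(), gen_h03_5(), with_correction = TRUE)
  expect_equal(rpt0$deltaF, rpt0$deltaF_selection)
  expect_equal(rpt1$deltaF, rpt1$deltaF_corrected)
  expect_equal(rpt1$Ne, 1 / (2 * rpt1$deltaF_corrected))
})

test_that("few selected parents with large families trigger a warning", {
  scn <- breeding_scenario(c(10, 25, 50, 3500), c(0.05, 0.125, 0.01, 0.70))
  expect_warning(predict_inbreeding(scn, gen_h03_5()), "fewer than 20")
  expect_silent(invisible(predict_inbreeding(scn_small(), gen_h03_5())))
})
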