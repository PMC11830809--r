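test_that("left-rectangle integration matches closed forms", {
  # constant 10 mA for 6 days
  tr <- flat_trace(10e-3)
  expect_equal(integrate_current(tr), 10e-3 * 6 * 86400)

  # two samples, left value held over the interval
  tr2 <- current_trace("t", c(0, 3600), c(-1e-3, -2e-3), 1)
  expect_equal(integrate_current(tr2, 0, 3600), 3.6)

  # window outside the span
  expect_error(integrate_current(tr2, 0, 7200), "outside trace span")
})

test_that("left-rectangle rule is exact on piecewise-constant currents", {
  # breakpoints sampled exactly: analytic integral = sum of segment areas
  t <- c(0, 100, 250, 600, 1000)
  i <- c(2e-3, 5e-4, 3e-3, 1e-3, 1e-3)
  tr <- current_trace("pw", t, -i, 1)
  analytic <- sum(i[-5] * diff(t))
  expect_identical(integrate_current(tr), analytic)
})

test_that("integration is additive over adjacent windows", {
  tr <- toy_bundle(seed = 3, noise_scale = 1)$trace
  a <- min(tr$time_s); c <- max(tr$time_s)
  for (b in c(5000, 86400, 400000)) {
    expect_equal(integrate_current(tr, a, b) + integrate_current(tr, b, c),
                 integrate_current(tr, a, c))
  }
})

test_that("refined sampling of a smooth ramp converges to the trapezoid oracle", {
  # linear ramp 0 -> 1 mA over 3600 s sampled every second
  t <- 0:3600
  i <- t / 3600 * 1e-3
  tr <- current_trace("ramp", t, -i, 1)
  trapezoid <- sum((i[-1] + i[-length(i)]) / 2 * diff(t))
  expect_lt(abs(integrate_current(tr) - trapezoid) / trapezoid, 1e-3)
})

test_that("baseline j1h interpolates at exactly one hour", {
  # bracketing samples at 3000 s (1 mA) and 4200 s (2 mA), area 2.25 cm2
  tr <- current_trace("b", c(0, 3000, 4200, 7200),
                      -c(1e-3, 1e-3, 2e-3, 2e-3), 2.25)
  expect_equal(baseline_j1h(tr), 1.5e-3 / 2.25)

  # sample exactly at 3600 s
  tr2 <- current_trace("b2", c(0, 3600, 7200), -c(1, 2, 3) * 1e-3, 2.25)
  expect_equal(baseline_j1h(tr2), 2e-3 / 2.25)

  expect_error(baseline_j1h(current_trace("s", c(0, 1800), c(-1, -1), 1)),
               "3600")
})

test_that("biocoulombs accrue only the excess over the 1 h baseline", {
  # flat trace: no excess anywhere
  expect_equal(biocoulombs(flat_trace()), 0)

  # baseline 0.1 mA then 0.6 mA for the final 5 days: 0.5 mA * 432000 s
  tr <- step_trace(1e-4, 6e-4, step_at_s = 86400)
  expect_equal(biocoulombs(tr), 0.5e-3 * 5 * 86400)

  # decaying trace never exceeds the baseline
  t <- seq(0, 6 * 86400, by = 3600)
  tr_dec <- current_trace("dec", t, -1e-3 * exp(-t / 2e5), 1)
  expect_equal(biocoulombs(tr_dec), 0)
})

test_that("biocoulombs and fold statistics are sign-convention invariant", {
  tr_neg <- step_trace()
  tr_mag <- current_trace(tr_neg$reactor_id, tr_neg$time_s,
                          abs(tr_neg$current_A), tr_neg$area_cm2,
                          polarity = "magnitude")
  expect_equal(biocoulombs(tr_neg), biocoulombs(tr_mag))
  expect_equal(fold_increase(tr_neg)$ratio, fold_increase(tr_mag)$ratio)
  expect_equal(integrate_current(tr_neg), integrate_current(tr_mag))
})

test_that("fold increase is j_max over j_1h with the earliest attaining time", {
  tr <- flat_trace(dt_s = 1800)
  fi <- fold_increase(tr)
  expect_equal(fi$ratio, 1.0)
  expect_equal(fi$t_at_max_s, 5400) # first sample after 3600 s

  # monotone decay: ratio < 1
  t <- seq(0, 6 * 86400, by = 3600)
  tr_dec <- current_trace("dec", t, -1e-3 * exp(-t / 2e5), 1)
  expect_lt(fold_increase(tr_dec)$ratio, 1)

  # zero baseline -> ratio reported missing, not infinite
  tr0 <- current_trace("z", c(0, 3600, 7200), c(0, 0, -1e-3), 1)
  expect_true(is.na(fold_increase(tr0)$ratio))
})

test_that("coulomb-to-H2 conversion follows Q/(2FV)", {
  expect_equal(coulombs_to_h2_mM(0, 0.25), 0)
  expect_equal(coulombs_to_h2_mM(2 * FARADAY * 0.25 / 1000, 0.25), 1.0)
  expect_equal(coulombs_to_h2_mM(FARADAY, 1), 500)
  expect_error(coulombs_to_h2_mM(10, 0), "volume")
})

test_that("trace summary bundles the per-reactor statistics consistently", {
  tr <- step_trace()
  ts <- trace_summary(tr)
  expect_equal(ts$biocoulombs_C, biocoulombs(tr))
  expect_equal(ts$total_coulombs_C, integrate_current(tr))
  expect_gte(ts$total_coulombs_C, ts$biocoulombs_C)
  expect_equal(ts$fold_increase, 6)
})
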