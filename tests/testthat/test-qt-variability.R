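test_that("each marker matches hand-computed values on tiny series", {
  expect_equal(qtvar(rep(420, 10)), 0)
  expect_equal(qtvar(c(400, 420, 440)), 400) # sum dev^2 = 800, / 2
  expect_equal(sdqt(c(400, 420, 440)), 20)
  expect_equal(stvqt(rep(400, 5)), 0)
  expect_equal(stvqt(c(400, 410, 400)), 10 / sqrt(2))
  expect_equal(qtvn(c(380, 400, 420)), qtvar(c(380, 400, 420)) / 400^2)
  expect_equal(rmssdqt(c(400, 420)), 20)
  expect_equal(rmssdqt(c(400, 410, 430)), sqrt((100 + 400) / 2))
  expect_error(qtvar(420), "at least 2")
  expect_error(rmssdqt(c(400, -1)), "positive")
})

test_that("QTVI is the log ratio of normalized variances", {
  qt <- c(400, 420, 410, 430, 405)
  # HR series scaled so normalized variances are equal -> QTVI = 0
  hr <- qt * 70 / mean(qt)
  expect_equal(qtvi_hr(qt, hr), 0, tolerance = 1e-12)
  # inflating QT variance tenfold about its mean adds exactly 1
  qt10 <- mean(qt) + (qt - mean(qt)) * sqrt(10)
  expect_equal(qtvi_hr(qt10, hr), 1, tolerance = 1e-12)
  expect_error(qtvi_hr(qt, rep(70, 5)), "variance is zero")
})

test_that("all six markers agree with an independent brute-force loop to 1e-9 relative", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    qt <- 420 + rnorm(n, 0, 15)
    hr <- 70 + rnorm(n, 0, 4)
    panel <- qtv_panel(qt, hr)
    expect_equal(panel$QTvar, oracle_qtvar(qt), tolerance = 1e-9)
    expect_equal(panel$SDqt, oracle_sdqt(qt), tolerance = 1e-9)
    expect_equal(panel$STVqt, oracle_stvqt(qt), tolerance = 1e-9)
    expect_equal(panel$QTVN, oracle_qtvn(qt), tolerance = 1e-9)
    expect_equal(panel$QTVI, oracle_qtvi(qt, hr), tolerance = 1e-9)
    expect_equal(panel$RMSSDqt, oracle_rmssdqt(qt), tolerance = 1e-9)
  }
})

test_that("marker invariances hold: SD^2 = variance, time reversal, constant shift", {
  set.seed(7)
  qt <- 400 + rnorm(50, 0, 12)
  expect_equal(sdqt(qt)^2, qtvar(qt), tolerance = 1e-12)
  for (f in list(qtvar, sdqt, stvqt, qtvn, rmssdqt)) {
    expect_equal(f(qt), f(rev(qt)), tolerance = 1e-12)
  }
  for (f in list(stvqt, rmssdqt)) {
    expect_equal(f(qt), f(qt + 55), tolerance = 1e-9)
  }
  # quadratic mean of |diff| >= arithmetic mean of |diff|
  d <- abs(diff(qt))
  expect_gte(rmssdqt(qt) * sqrt(length(d) / (length(qt) - 1)), mean(d))
})

test_that("white-noise QT series obey the RMSSD/SD -> sqrt(2) limit", {
  s <- gen_qt_series(1e5, 420, 20, lag1_corr = 0, seed = 31)
  expect_equal(rmssdqt(s$qt_ms) / sdqt(s$qt_ms), sqrt(2), tolerance = 0.02)
  expect_gt(sdqt(s$qt_ms), 19.8)
  expect_lt(sdqt(s$qt_ms), 20.2)
})

test_that("the panel is consistent and degenerate QTVI is flagged, not fatal", {
  s <- gen_qt_series(200, 420, 18, 0.3, hr = list(hrm_bpm = 72, sd_bpm = 3),
                     seed = 12)
  panel <- qtv_panel(s$qt_ms, s$hr_bpm)
  expect_equal(panel$SDqt^2, panel$QTvar, tolerance = 1e-12)
  const <- qtv_panel(rep(420, 10), 70 + rnorm(10))
  expect_equal(const$QTvar, 0)
  expect_equal(const$STVqt, 0)
  expect_equal(const$RMSSDqt, 0)
  expect_identical(const$QTVI, -Inf)
  expect_identical(attr(const, "qtvi_flag"), "degenerate")
  expect_error(qtv_panel(rep(420, 10), 70 + rnorm(10), na_qtvi = FALSE),
               "degenerate")
})

test_that("the fixed-30-beat STVqt denominator mode scales as documented", {
  qt <- 400 + sin(seq_len(40))
  expect_equal(stvqt(qt, "fixed30"), stvqt(qt, "diffs") * 39 / 30,
               tolerance = 1e-12)
})
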