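square <- function(n = 40) matrix(0L, n, n)

test_that("area fractions have the documented trivial endpoints", {
  m <- square()
  icd <- m; icd[10:30, 5:8] <- 1L
  # cx43 identical to the ICD mask -> 100%
  expect_equal(cx43_icd_fraction(icd, icd), 100)
  # disjoint -> 0%
  far <- m; far[35:38, 35:38] <- 1L
  expect_equal(cx43_icd_fraction(far, icd), 0)
  expect_error(cx43_icd_fraction(far, m), "empty")

  lat <- m; lat[1:2, 10:30] <- 1L
  # all Cx43 at the ICD -> lateralization 0
  expect_equal(lateralization_ratio(icd, lat, icd), 0)
  # equal lateral and ICD areas -> 100
  cx <- m; cx[10:13, 5:8] <- 1L; cx[1:2, 10:17] <- 1L
  expect_equal(lateralization_ratio(cx, lat, icd),
               100 * sum(cx & lat) / sum(cx & icd))
  expect_error(lateralization_ratio(far, lat, icd), "no Cx43")

  tissue <- m; tissue[, ] <- 1L
  psr <- m; psr[1:10, ] <- 1L # 25% of a 40x40 frame
  expect_equal(fibrosis_fraction(psr, tissue), 25)
  expect_equal(fibrosis_fraction(m, tissue), 0)
  expect_error(fibrosis_fraction(psr, m), "empty")
})

test_that("mask_set enforces shape and binarity", {
  good <- mask_set(list(tissue = square() + 1L, psr = square()))
  expect_s3_class(good, "mask_set")
  expect_error(mask_set(list(a = square(), b = matrix(0L, 10, 10))),
               "identical shape")
  bad <- square(); bad[1, 1] <- 2L
  expect_error(mask_set(list(a = bad)), "binary")
})

test_that("the mask generator realizes its truth fractions and round-trips", {
  ms <- gen_masks(mask_spec(seed = 21))
  truth <- attr(ms, "truth")
  q <- quantify_masks(ms)
  expect_equal(q$cx43_icd_pct, truth$icd_fraction_pct, tolerance = 1e-9)
  expect_lt(abs(q$cx43_icd_pct - 37), 1)
  expect_equal(q$lateralization_pct, truth$lateral_ratio_pct,
               tolerance = 1e-9)
  expect_lt(abs(q$lateralization_pct - 150), 3)
  expect_equal(q$fibrosis_pct, truth$fibrosis_pct, tolerance = 1e-9)
  expect_lt(abs(q$fibrosis_pct - 8), 0.5)

  # trivial programmed endpoints
  ms0 <- gen_masks(mask_spec(lateral_ratio_truth = 0, fibrosis_truth = 0,
                             seed = 22))
  q0 <- quantify_masks(ms0)
  expect_equal(q0$lateralization_pct, 0)
  expect_equal(q0$fibrosis_pct, 0)
  expect_equal(sum(ms0$masks$cx43 & !ms0$masks$ncadh), 0)
})

test_that("fractions are rotation invariant and fibrosis grows under dilation", {
  ms <- gen_masks(mask_spec(seed = 23))
  rot <- lapply(ms$masks, function(m) t(m[nrow(m):1, ])) # 90-degree rotation
  q1 <- quantify_masks(ms)
  q2 <- quantify_masks(mask_set(rot, ms$pixel_size_um))
  expect_equal(q1, q2, tolerance = 1e-12)

  psr <- ms$masks$psr
  f0 <- fibrosis_fraction(psr, ms$masks$tissue)
  f1 <- fibrosis_fraction(dilate1(psr), ms$masks$tissue)
  expect_gte(f1, f0)
})

test_that("per-animal averaging over sections behaves as a mean", {
  secs <- lapply(1:3, function(s) gen_masks(mask_spec(seed = 30 + s)))
  avg <- quantify_animal(secs)
  each <- do.call(rbind, lapply(secs, quantify_masks))
  expect_equal(avg$fibrosis_pct, mean(each$fibrosis_pct))
  expect_identical(avg$n_sections, 3L)
})

test_that("the Otsu helper splits a clean bimodal image", {
  img <- matrix(c(rep(0.1, 500), rep(0.9, 500)) +
                  runif(1000, -0.02, 0.02), 40, 25)
  m <- otsu_mask(img)
  expect_equal(sum(m), 500)
})
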