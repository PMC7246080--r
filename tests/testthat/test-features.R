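test_that("pubic-bone landmarks S and I follow the corner criteria", {
  bone <- contour(c(0, 10, 15, 2), c(0, 5, -35, -40))
  fp <- locate_feature_points(bone)
  expect_equal(fp$S, c(a = 0, s = 0))
  expect_equal(fp$I, c(a = 2, s = -40))
  # axis-aligned square: S = posterior-superior, I = posterior-inferior
  sq <- rect_contour(1, 5, -3, 2)
  fp <- locate_feature_points(sq)
  expect_equal(fp$S, c(a = 1, s = 2))
  expect_equal(fp$I, c(a = 1, s = -3))
  # translation equivariance
  fp2 <- locate_feature_points(translate_contour(bone, 4.5, -1.25))
  expect_equal(fp2$S, c(a = 4.5, s = -1.25))
  expect_equal(fp2$I, c(a = 6.5, s = -41.25))
  expect_error(locate_feature_points(matrix(1, 2, 2)), "degenerate")
})

test_that("distances on the rectangle fixture match closed-form values", {
  d <- measure_distances(rectangle_anatomy())
  expect_equal(d[["d1"]], sqrt(10^2 + 45^2), tolerance = 1e-9)
  expect_equal(d[["d2"]], 45, tolerance = 1e-9)
  expect_equal(d[["d3"]], 30, tolerance = 1e-9)
  expect_equal(d[["d4"]], 15, tolerance = 1e-9)
  expect_equal(d[["d5"]], 32, tolerance = 1e-9)
  expect_equal(d[["d6"]], 15, tolerance = 1e-9)
  expect_equal(d[["d7"]], 0, tolerance = 1e-9)
})

test_that("distances are invariant under whole-anatomy translation", {
  anat <- rectangle_anatomy()
  d0 <- measure_distances(anat)
  d1 <- measure_distances(translate_anatomy(anat, 17.3, -8.6))
  expect_equal(d1, d0, tolerance = 1e-9)
  # and the same for a generated anatomy
  b <- make_patient_baseline(generator_params(), "P", 12)
  expect_equal(measure_distances(translate_anatomy(b, -3.21, 5.57)),
               measure_distances(b), tolerance = 1e-9)
})

test_that("widening the rectum posteriorly changes only the diameters", {
  anat <- rectangle_anatomy()
  d0 <- measure_distances(anat)
  anat$rectum <- rect_contour(-50, -30, -60, 10)  # posterior wall -45 -> -50
  d1 <- measure_distances(anat)
  expect_equal(d1[["d3"]], d0[["d3"]])
  expect_equal(d1[["d5"]], d0[["d5"]])
  expect_equal(d1[["d4"]], d0[["d4"]] + 5)
  expect_equal(d1[["d6"]], d0[["d6"]] + 5)
  expect_equal(d1[["d7"]], d0[["d7"]])
})

test_that("moving the rectal anterior wall anteriorly shrinks d3", {
  anat <- rectangle_anatomy()
  d3 <- vapply(c(0, 2, 5, 9), function(push) {
    a <- anat
    a$rectum <- rect_contour(-45, -30 + push, -60, 10)
    measure_distances(a)[["d3"]]
  }, numeric(1))
  expect_true(all(diff(d3) < 0))
})

test_that("unmeasurable configurations raise named errors, never NaN", {
  anat <- rectangle_anatomy()
  anat$bladder <- rect_contour(20, 30, 5, 45)     # SI line misses bladder
  expect_error(measure_distances(anat), "distance 2.*misses the bladder")
  anat <- rectangle_anatomy()
  anat$rectum <- rect_contour(-45, -30, -20, 10)  # I line below the rectum
  expect_error(measure_distances(anat), "distance 5")
  anat <- rectangle_anatomy()
  anat$rectum <- rect_contour(5, 20, -60, 10)     # wall anterior to S
  expect_error(measure_distances(anat), "distance 3.*not posterior")
})

test_that("prostate center is the bounding-box midpoint", {
  expect_equal(prostate_center(rect_contour(-25, -5, -35, -5)),
               c(a = -15, s = -20))
  circ <- superellipse_contour(c(4, -7), 13, 13, m = 2, n = 64)
  expect_equal(prostate_center(circ), c(a = 4, s = -7), tolerance = 1e-9)
  expect_equal(prostate_center(translate_contour(circ, 2, 3)),
               c(a = 6, s = -4), tolerance = 1e-9)
})

test_that("feature vector arithmetic and the f7 identity", {
  anat <- rectangle_anatomy()
  d <- measure_distances(anat)
  cop <- prostate_center(anat$prostate)
  f <- compute_features(d, d, cop, cop)
  expect_equal(unname(f), rep(0, 9))
  d2 <- d
  d2[["d3"]] <- 35
  f <- compute_features(d, d2, cop, cop)
  expect_equal(unname(f), c(0, 0, 5, 0, 0, 0, 0, 0, 0))
  d3 <- d
  d3[["d4"]] <- d[["d4"]] + 2
  d3[["d6"]] <- d[["d6"]] + 4
  d3[["d7"]] <- d3[["d6"]] - d3[["d4"]]
  f <- compute_features(d, d3, cop, cop)
  expect_equal(f[["f4"]], 2)
  expect_equal(f[["f6"]], 4)
  expect_equal(f[["f7"]], f[["f6"]] - f[["f4"]])
})

test_that("extracted cohort features keep f7 = f6 - f4 exactly", {
  co <- simulate_cohort(generator_params(), 3, 8, seed = 21)
  ft <- extract_features(co, seed = 22)
  expect_equal(ft$f7, ft$f6 - ft$f4, tolerance = 1e-12)
  expect_equal(nrow(ft), 24)
  # COP displacement tracks the true shift when click noise is off
  ft0 <- extract_features(co, click_sd = 0, cop_click_sd = 0, seed = 1)
  expect_equal(ft0$f8, ft0$si, tolerance = 1e-9)
  expect_equal(ft0$f9, ft0$ap, tolerance = 1e-9)
})
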