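test_that("identical seeds reproduce cohorts bit-identically", {
  p <- generator_params()
  b1 <- make_patient_baseline(p, "P01", 42)
  b2 <- make_patient_baseline(p, "P01", 42)
  expect_identical(b1, b2)
  co1 <- simulate_cohort(p, 2, 3, seed = 9)
  co2 <- simulate_cohort(p, 2, 3, seed = 9)
  expect_identical(co1, co2)
  co3 <- simulate_cohort(p, 2, 3, seed = 10)
  expect_false(identical(cohort_shifts(co1), cohort_shifts(co3)))
})

test_that("baselines satisfy the anatomical invariants across seeds", {
  p <- generator_params()
  for (seed in 1:100) {
    b <- make_patient_baseline(p, "P", seed)
    expect_silent(validate_anatomy(b))
    S <- locate_feature_points(b$bone)$S
    expect_lt(polygon_centroid(b$rectum)[1], S[["a"]])
  }
})

test_that("zero-variance generator reproduces the baseline exactly", {
  p0 <- zero_variance_params()
  b <- make_patient_baseline(p0, "P01", 5)
  fr <- sample_fraction(b, p0, 1, seed = 77)
  expect_equal(unname(fr$reference_shift), c(0, 0, 0))
  for (nm in c("bladder", "rectum", "prostate", "ctv", "bone")) {
    expect_equal(unclass(fr$pretreatment[[nm]]), unclass(b[[nm]]),
                 tolerance = 1e-12)
  }
  co <- simulate_cohort(p0, 3, 4, seed = 2)
  sh <- cohort_shifts(co)
  expect_equal(max(abs(as.matrix(sh[, c("lr", "si", "ap")]))), 0)
})

test_that("reference shift equals the recoverable CTV translation", {
  p <- generator_params()
  b <- make_patient_baseline(p, "P01", 3)
  cen0 <- polygon_centroid(b$ctv)
  for (seed in 1:20) {
    fr <- sample_fraction(b, p, 1, seed)
    cen1 <- polygon_centroid(fr$pretreatment$ctv)
    expect_equal(cen1[["a"]] - cen0[["a"]], fr$reference_shift[["ap"]],
                 tolerance = 1e-9)
    expect_equal(cen1[["s"]] - cen0[["s"]], fr$reference_shift[["si"]],
                 tolerance = 1e-9)
  }
})

test_that("cohort bookkeeping: counts, ids and fraction indexing", {
  co <- simulate_cohort(generator_params(), 3, 5, seed = 1)
  sh <- cohort_shifts(co)
  expect_equal(nrow(sh), 15)
  expect_equal(sort(unique(sh$patient_id)), c("P01", "P02", "P03"))
  expect_equal(sh$fraction[sh$patient_id == "P02"], 1:5)
  expect_error(simulate_cohort(generator_params(), 1, 5), "2 patients")
  expect_error(simulate_cohort(generator_params(), 2, 0), "1 fraction")
})

test_that("pooled shift statistics sit at the clinical scale", {
  co <- simulate_cohort(generator_params(), 10, 38, seed = 3)
  sh <- cohort_shifts(co)
  expect_gt(mean(abs(sh$si)), 0.5)
  expect_lt(mean(abs(sh$si)), 1.5)
  expect_gt(mean(abs(sh$ap)), 0.8)
  expect_lt(mean(abs(sh$ap)), 2.0)
  # LR is negligible by construction
  expect_lt(mean(abs(sh$lr)), 0.3)
  expect_lt(sd(sh$lr), 0.5)
})

test_that("rasterization fills polygons at pixel centers", {
  p <- generator_params(gas_prob = 0)
  b <- make_patient_baseline(p, "P01", 8)
  ext <- anatomy_extent(b)
  i1 <- rasterize(b, 1, include_gas = TRUE, extent = ext)
  i2 <- rasterize(b, 1, include_gas = FALSE, extent = ext)
  expect_identical(i1$pixels, i2$pixels)  # no gas region present
  # gas flag changes only gas pixels
  bg <- add_gas_pocket(b)
  i3 <- rasterize(bg, 1, include_gas = FALSE, extent = ext)
  expect_identical(i3$pixels, i1$pixels)
  i4 <- rasterize(bg, 1, include_gas = TRUE, extent = ext)
  expect_gt(sum(i4$pixels == 0), 50)
  expect_error(rasterize(b, pixel_size_mm = 0), "pixel_size")
})

test_that("rasterization is translation-equivariant on the pixel grid", {
  p <- generator_params(gas_prob = 0)
  b <- make_patient_baseline(p, "P01", 4)
  ext <- anatomy_extent(b)
  i0 <- rasterize(b, 1, extent = ext)
  bt <- translate_anatomy(b, 3, -2)  # exactly 3 and -2 pixels
  it <- rasterize(bt, 1, extent = ext)
  nr <- nrow(i0$pixels); nc <- ncol(i0$pixels)
  # interior comparison: it[r, c] == i0[r + 2, c - 3]
  expect_equal(it$pixels[3:(nr - 3), 4:nc],
               i0$pixels[(3 + 2):(nr - 1), (4 - 3):(nc - 3)])
})

test_that("rasterized area matches polygon area within 5% at 1 mm pixels", {
  circ <- superellipse_contour(c(0, 0), 20, 20, m = 2, n = 128)
  anat <- sagittal_anatomy(bladder = circ, rectum = circ, prostate = circ,
                           ctv = circ, bone = circ, validate = FALSE)
  img <- rasterize(anat, 1, extent = c(-30, 30, -30, 30),
                   intensities = c(background = 0, bladder = 0, rectum = 0,
                                   ctv = 0, prostate = 1, bone = 1, gas = 0))
  filled <- sum(img$pixels == 1)
  expect_lt(abs(filled * 1 - polygon_area(circ)) / polygon_area(circ), 0.05)
})
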