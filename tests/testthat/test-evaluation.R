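test_that("Spearman rho and exact small-sample p-values", {
  r <- spearman_rho(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$rho, -1)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(spearman_rho(1:5, 1:5)$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)
  # against the reference implementation on a larger sample
  set.seed(3)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r <- spearman_rho(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_error(spearman_rho(1:2, 1:2), "lengths >= 3")
})

test_that("feature ranking keys, tie-breaking and null behavior", {
  ft <- synthetic_feature_table(noise_sd = 0.3, seed = 5)
  rk <- rank_features(ft)
  expect_equal(rk$order[1], 3)
  expect_lt(rk$rho_si[3], 0)    # anterior wall motion: negative correlate
  expect_equal(rk$subsets[[2]], rk$order[1:2])
  # duplicated feature: equal keys, lower index first
  ft2 <- ft
  ft2$f5 <- ft2$f3
  rk2 <- rank_features(ft2)
  expect_equal(rk2$key[5], rk2$key[3], tolerance = 1e-12)
  expect_lt(which(rk2$order == 3), which(rk2$order == 5))
  # independent shifts: no feature reaches a strong mean correlation
  set.seed(11)
  for (s in 1:3) {
    ftn <- synthetic_feature_table(n_patients = 10, n_per_patient = 38,
                                   coef = 0, noise_sd = 1, seed = 100 + s)
    expect_lt(max(rank_features(ftn)$key), 0.2)
  }
  expect_error(rank_features(ft[1:2, ]), "3 fractions")
})

test_that("LCV predicts every fraction of every patient exactly once", {
  ft <- synthetic_feature_table(n_patients = 2, n_per_patient = 10,
                                seed = 2)
  res <- run_lcv(ft, "svr", 1, seed = 1)
  expect_equal(nrow(res), 2 * 10 * 2)  # fractions x directions
  counts <- table(res$patient_id, res$direction)
  expect_true(all(counts == 10))
  expect_true(all(res$residual >= 0))
  expect_equal(res$residual, abs(res$reference - res$predicted))
  expect_error(run_lcv(ft[ft$patient_id == "P01", ], "svr", 1),
               "2 patients")
})

test_that("noiseless linear shift is recovered through the LCV loop", {
  ft <- synthetic_feature_table(n_patients = 4, n_per_patient = 15,
                                coef = -0.4, noise_sd = 0, seed = 3)
  res <- run_lcv(ft, "svr", 1, hyper = 0.01, seed = 1)
  expect_lt(mean(res$residual), 0.1)
})

test_that("validation run demands disjoint patients and recovers signal", {
  tr <- synthetic_feature_table(n_patients = 4, n_per_patient = 15,
                                coef = -0.4, noise_sd = 0, seed = 4)
  va <- synthetic_feature_table(n_patients = 3, n_per_patient = 8,
                                coef = -0.4, noise_sd = 0, seed = 5)
  va$patient_id <- sub("P", "V", va$patient_id)
  res <- run_validation(tr, va, "svr", 1, hyper = 0.01, seed = 1)
  expect_equal(nrow(res), 3 * 8 * 2)
  expect_lt(mean(res$residual), 0.1)
  expect_error(run_validation(tr, tr, "svr", 1), "overlap")
})

test_that("residual summaries report mean, sample SD and max", {
  s <- residual_summary(c(1, 1, 1))
  expect_equal(s$mean_abs, 1)
  expect_equal(s$sd, 0)
  expect_equal(s$max, 1)
  s <- residual_summary(c(0, 2))
  expect_equal(s$mean_abs, 1)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)  # sample SD
  expect_equal(residual_summary(c(0, 2), sd_type = "population")$sd, 1)
  expect_error(residual_summary(numeric(0)), "no residuals")
  # direction split
  rt <- data.frame(direction = c("si", "si", "ap", "ap"),
                   residual = c(1, 3, 2, 2))
  s <- residual_summary(rt)
  expect_equal(s$mean_abs[s$direction == "si"], 2)
  expect_equal(s$mean_abs[s$direction == "pooled"], 2)
  expect_equal(s$n[s$direction == "pooled"], 4)
})

test_that("Steel-Dwass agrees with exact rank-sum enumeration at k = 2", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  ex <- steel_dwass(g, method = "exact")
  expect_equal(ex$p[1, 2], 0.1, tolerance = 1e-12)
  # independent route: exact Wilcoxon enumeration
  expect_equal(ex$p[1, 2],
               wilcox.test(g[[1]], g[[2]], exact = TRUE)$p.value,
               tolerance = 1e-12)
  # identical groups: zero statistic, p ~ 1
  same <- steel_dwass(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_gte(same$p[1, 2], 0.99)
  expect_equal(same$statistic[1, 2], 0)
  # clearly separated triples are detected
  g3 <- list(rnorm(30), rnorm(30) + 5, rnorm(30) + 10)
  sd3 <- steel_dwass(g3)
  expect_lt(max(sd3$p[upper.tri(sd3$p)]), 0.01)
  expect_error(steel_dwass(list(1:3)), "2 groups")
  expect_error(steel_dwass(list(1, 1:3)), "n >= 2")
})

test_that("variance F test matches the closed-form F(2,2) example", {
  r <- f_test_variance(c(-1, 0, 1), c(-2, 0, 2))
  expect_equal(r$F, 0.25)
  expect_equal(r$p, 0.4, tolerance = 1e-12)  # F(2,2) cdf is x/(1+x)
  expect_equal(f_test_variance(1:5, 1:5)$p, 1)
  # cross-check against the reference implementation
  set.seed(8)
  a <- rnorm(40); b <- rnorm(35, sd = 1.7)
  expect_equal(f_test_variance(a, b)$p, var.test(a, b)$p.value,
               tolerance = 1e-12)
})

test_that("Cohen's kappa on discretized shifts", {
  x <- c(-1.2, 0.4, 2.1, 0.9, -0.1)
  expect_equal(cohens_kappa(x, x), 1)
  expect_equal(cohens_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1), 1), 0)
  set.seed(4)
  a <- sample(0:3, 2000, replace = TRUE)
  b <- sample(0:3, 2000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.08)
  # bin width matters: sub-mm disagreements vanish at 1 mm bins but not at
  # fine ones
  expect_equal(cohens_kappa(c(0.9, 2.1), c(1.3, 1.7), bin_width_mm = 1), 1)
  expect_lte(cohens_kappa(c(0.9, 2.1), c(1.3, 1.7), bin_width_mm = 0.25), 0)
  expect_error(cohens_kappa(1:3, 1:4), "length")
})

test_that("Dice coefficient of overlapping contours", {
  sq <- rect_contour(0, 1, 0, 1)
  expect_equal(dice_coefficient(sq, sq), 1)
  expect_equal(dice_coefficient(sq, translate_contour(sq, 0.5, 0)), 0.5)
  expect_equal(dice_coefficient(sq, translate_contour(sq, 3, 3)), 0)
  circ <- superellipse_contour(c(0, 0), 10, 10, m = 2, n = 128)
  expect_equal(dice_coefficient(circ, circ), 1, tolerance = 1e-12)
})
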