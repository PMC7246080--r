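# Fixtures built in code: rectangle-organ anatomies with closed-form
# distances, and small synthetic feature tables with known structure.

rect_contour <- function(a1, a2, s1, s2) {
  contour(c(a1, a2, a2, a1), c(s1, s1, s2, s2))
}

# Bone with landmarks S = (0, 0), I = (2, -40); rectangle organs whose
# d1..d7 have closed-form values (see test-features.R).
rectangle_anatomy <- function() {
  bone <- contour(c(0, 10, 15, 2), c(0, 5, -35, -40))
  sagittal_anatomy(
    bladder = rect_contour(-10, 30, 5, 45),
    rectum = rect_contour(-45, -30, -60, 10),
    prostate = rect_contour(-25, -5, -35, -5),
    ctv = rect_contour(-27, -3, -37, -3),
    bone = bone
  )
}

# Feature table with shift = coef * f3 + noise; the other features carry
# independent variation. Used where cohort-level geometry is irrelevant.
synthetic_feature_table <- function(n_patients = 4L, n_per_patient = 20L,
                                    coef = -0.4, noise_sd = 0.5,
                                    seed = 1L) {
  set.seed(seed)
  n <- n_patients * n_per_patient
  f <- matrix(rnorm(n * 9, sd = 3), n, 9)
  f[, 7] <- f[, 6] - f[, 4]
  si <- coef * f[, 3] + rnorm(n, sd = noise_sd)
  ap <- 1.2 * coef * f[, 3] + rnorm(n, sd = noise_sd)
  out <- data.frame(patient_id = rep(sprintf("P%02d", seq_len(n_patients)),
                                     each = n_per_patient),
                    fraction = rep(seq_len(n_per_patient), n_patients))
  out[paste0("f", 1:9)] <- as.data.frame(f)
  out$lr <- 0
  out$si <- si
  out$ap <- ap
  out
}

# Common extent covering a planning anatomy with room for shifts + search.
anatomy_extent <- function(anatomy, margin = 25) {
  allv <- do.call(rbind, lapply(c("bladder", "rectum", "prostate", "ctv",
                                  "bone"),
                                function(nm) unclass(anatomy[[nm]])))
  c(min(allv[, 1]) - margin, max(allv[, 1]) + margin,
    min(allv[, 2]) - margin, max(allv[, 2]) + margin)
}
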