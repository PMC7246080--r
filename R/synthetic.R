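# Synthetic sagittal pelvic-anatomy simulator.
#
# Each patient gets a randomized baseline ("planning") anatomy. Each
# treatment fraction redraws three latent states: u (upper-rectal filling),
# v (lower-rectal filling) and w (bladder filling). The rectal anterior wall
# is displaced anteriorly by wall_gain * u (upper) / * v (lower) with the
# posterior wall following at a fraction of that displacement (filling both
# displaces and distends the rectum); the bladder is scaled by w; and the
# prostate + CTV are rigidly translated by the ground-truth shift
#   si = alpha_u * u + alpha_w * w + noise
#   ap = beta_u * u + beta_v * v + beta_w * w + noise
# so that target motion is driven by the same latent states the anatomical
# features measure, along the anterior-superior / posterior-inferior
# diagonal that pelvic organ filling produces. Left-right motion is pure
# small noise.

#' Generator parameters for the synthetic cohort simulator
#'
#' Defaults are calibrated so that pooled cohorts reproduce the clinically
#' reported shift scale (mean |SI| about 0.9 mm, mean |AP| about 1.3 mm,
#' negligible LR) and so that feature 3 (upper rectal wall position) is the
#' strongest single correlate of both shift components.
#'
#' @param sigma_u,sigma_v,sigma_w SDs of the unitless latent filling states.
#' @param alpha Length-2 named vector `c(u=, w=)`: SI-shift coupling, mm per
#'   latent unit.
#' @param beta Length-3 named vector `c(u=, v=, w=)`: AP-shift coupling.
#' @param eps_si,eps_ap,eps_lr Shift noise SDs, mm.
#' @param wall_gain_upper,wall_gain_lower Anterior rectal-wall displacement,
#'   mm per latent unit.
#' @param posterior_follow Fraction of the anterior-wall displacement that
#'   the posterior wall follows (0 = pure distension, 1 = pure translation).
#' @param bladder_scale_gain Relative bladder scaling per latent unit.
#' @param click_sd Measurement (click) noise SD for bone/wall points, mm.
#' @param cop_click_sd Click noise SD for the prostate center; larger than
#'   `click_sd` because the prostate boundary is poorly visible on CBCT.
#' @param gas_prob Per-fraction probability of a rectal gas pocket in the
#'   pretreatment anatomy.
#' @param organs Baseline organ geometry, see [default_organ_geometry()].
#' @param max_regen Maximum redraws when a deformation degenerates.
#' @return A classed parameter list.
#' @export
generator_params <- function(sigma_u = 1, sigma_v = 1, sigma_w = 1,
                             alpha = c(u = 1.05, w = 0.30),
                             beta = c(u = 1.45, v = 0.35, w = 0.35),
                             eps_si = 0.30, eps_ap = 0.45, eps_lr = 0.12,
                             wall_gain_upper = 3.0, wall_gain_lower = 3.0,
                             posterior_follow = 0.6,
                             bladder_scale_gain = 0.05,
                             click_sd = 0.5, cop_click_sd = 1.5,
                             gas_prob = 0.1,
                             organs = default_organ_geometry(),
                             max_regen = 10L) {
  p <- list(sigma_u = sigma_u, sigma_v = sigma_v, sigma_w = sigma_w,
            alpha = alpha, beta = beta,
            eps_si = eps_si, eps_ap = eps_ap, eps_lr = eps_lr,
            wall_gain_upper = wall_gain_upper,
            wall_gain_lower = wall_gain_lower,
            posterior_follow = posterior_follow,
            bladder_scale_gain = bladder_scale_gain,
            click_sd = click_sd, cop_click_sd = cop_click_sd,
            gas_prob = gas_prob, organs = organs,
            max_regen = as.integer(max_regen))
  sds <- c(sigma_u, sigma_v, sigma_w, eps_si, eps_ap, eps_lr,
           click_sd, cop_click_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("generator SDs must be finite and >= 0")
  }
  if (length(alpha) != 2L || length(beta) != 3L) {
    stop("alpha must have 2 components (u, w) and beta 3 (u, v, w)")
  }
  if (gas_prob < 0 || gas_prob > 1) stop("gas_prob must be in [0, 1]")
  if (posterior_follow < 0 || posterior_follow > 1) {
    stop("posterior_follow must be in [0, 1]")
  }
  class(p) <- "generator_params"
  p
}

#' All-noise-off generator parameters
#'
#' Zero latent SDs, zero shift noise and zero click noise: every pretreatment
#' anatomy equals its baseline and every reference shift is exactly (0,0,0).
#' @param ... Overrides passed on to [generator_params()].
#' @export
zero_variance_params <- function(...) {
  generator_params(sigma_u = 0, sigma_v = 0, sigma_w = 0,
                   eps_si = 0, eps_ap = 0, eps_lr = 0,
                   click_sd = 0, cop_click_sd = 0, gas_prob = 0, ...)
}

#' Baseline organ geometry and per-patient jitter ranges
#'
#' Centers/semi-axes in mm in the bone-registered sagittal frame (isocenter
#' at the prostate). The rectum is a high-exponent superellipse (rounded
#' tube) posterior to the target; the bladder sits anterior-superior; the
#' pubic bone is a convex quadrilateral anterior-inferior.
#' @export
default_organ_geometry <- function() {
  list(
    prostate = list(center = c(0, 0), r = c(20, 20), m = 2, n = 48L,
                    center_jitter = 1.5, r_jitter = 0.08),
    ctv = list(offset = c(-4, 4), r = c(32, 32), m = 2, n = 64L,
               r_jitter = 0.05),
    bladder = list(center = c(18, 45), r = c(35, 30), m = 2.5, n = 64L,
                   center_jitter = 4, r_jitter = 0.15),
    rectum = list(center = c(-38, -10), r = c(12, 40), m = 4, n = 64L,
                  center_jitter = c(3, 5), r_jitter = c(0.15, 0.10)),
    bone = list(vertices = cbind(a = c(32, 52, 50, 30),
                                 s = c(-4, 2, -28, -26)),
                center_jitter = 2)
  )
}

runif1 <- function(half) stats::runif(1L, -half, half)

#' Generate a patient's planning (baseline) anatomy
#'
#' Organ sizes and positions are drawn uniformly inside the jitter ranges of
#' `params$organs`; deterministic given `seed`.
#'
#' @param params A [generator_params()] object.
#' @param patient_id Identifier stored on the anatomy.
#' @param seed Integer seed.
#' @return A `sagittal_anatomy` with the sampled geometry attached.
#' @export
make_patient_baseline <- function(params, patient_id = "P01", seed = 1L) {
  if (!inherits(params, "generator_params")) {
    stop("`params` must come from generator_params()")
  }
  og <- params$organs
  with_seed(seed, {
    pc <- og$prostate$center +
      c(runif1(og$prostate$center_jitter), runif1(og$prostate$center_jitter))
    pr <- og$prostate$r *
      (1 + c(runif1(og$prostate$r_jitter), runif1(og$prostate$r_jitter)))
    cc <- pc + og$ctv$offset
    cr <- og$ctv$r * (1 + c(runif1(og$ctv$r_jitter), runif1(og$ctv$r_jitter)))
    bc <- og$bladder$center +
      c(runif1(og$bladder$center_jitter), runif1(og$bladder$center_jitter))
    br <- og$bladder$r *
      (1 + c(runif1(og$bladder$r_jitter), runif1(og$bladder$r_jitter)))
    rj <- og$rectum
    rc <- rj$center + c(runif1(rj$center_jitter[1L]),
                        runif1(rj$center_jitter[length(rj$center_jitter)]))
    rr <- rj$r * (1 + c(runif1(rj$r_jitter[1L]),
                        runif1(rj$r_jitter[length(rj$r_jitter)])))
    bshift <- c(runif1(og$bone$center_jitter), runif1(og$bone$center_jitter))
    bone <- contour(og$bone$vertices[, 1L] + bshift[1L],
                    og$bone$vertices[, 2L] + bshift[2L])
    geom <- list(prostate = list(center = pc, r = pr, m = og$prostate$m,
                                 n = og$prostate$n),
                 ctv = list(center = cc, r = cr, m = og$ctv$m, n = og$ctv$n),
                 bladder = list(center = bc, r = br, m = og$bladder$m,
                                n = og$bladder$n),
                 rectum = list(center = rc, r = rr, m = rj$m, n = rj$n))
    anat <- sagittal_anatomy(
      bladder = superellipse_contour(bc, br[1L], br[2L], og$bladder$m,
                                     og$bladder$n),
      rectum = superellipse_contour(rc, rr[1L], rr[2L], rj$m, rj$n),
      prostate = superellipse_contour(pc, pr[1L], pr[2L], og$prostate$m,
                                      og$prostate$n),
      ctv = superellipse_contour(cc, cr[1L], cr[2L], og$ctv$m, og$ctv$n),
      bone = bone
    )
    attr(anat, "geom") <- geom
    attr(anat, "patient_id") <- patient_id
    anat
  })
}

# SI weight of the upper-rectal latent: 1 above the transition band, 0 below.
upper_weight <- function(s) pmin(pmax((s + 18) / 6, 0), 1)

deform_rectum <- function(rectum, geom, params, u, v) {
  a <- rectum[, 1L]; s <- rectum[, 2L]
  ac <- geom$rectum$center[1L]; ra <- geom$rectum$r[1L]
  wu <- upper_weight(s)
  disp <- params$wall_gain_upper * u * wu + params$wall_gain_lower * v * (1 - wu)
  follow <- params$posterior_follow +
    (1 - params$posterior_follow) * pmin(pmax((a - (ac - ra)) / (2 * ra), 0), 1)
  out <- rectum
  out[, 1L] <- a + disp * follow
  out
}

#' Sample one treatment fraction for a patient
#'
#' Draws the latent filling states, deforms the baseline anatomy and rigidly
#' translates the prostate + CTV by the ground-truth shift; the recorded
#' `reference_shift` equals that translation exactly.
#'
#' @param baseline Output of [make_patient_baseline()].
#' @param params A [generator_params()] object.
#' @param fraction_index Integer fraction number.
#' @param seed Integer seed.
#' @return A `fraction_record`: list with `patient_id`, `fraction_index`,
#'   `pretreatment` anatomy, `reference_shift` (`lr`, `si`, `ap`, mm) and
#'   `latent` (`u`, `v`, `w`).
#' @export
sample_fraction <- function(baseline, params, fraction_index = 1L, seed = 1L) {
  geom <- attr(baseline, "geom")
  if (is.null(geom)) stop("`baseline` must come from make_patient_baseline()")
  for (attempt in seq_len(params$max_regen)) {
    sub <- derive_seed(seed, attempt - 1L)
    rec <- with_seed(sub, {
      u <- stats::rnorm(1L, 0, params$sigma_u)
      v <- stats::rnorm(1L, 0, params$sigma_v)
      w <- stats::rnorm(1L, 0, params$sigma_w)
      si <- params$alpha[["u"]] * u + params$alpha[["w"]] * w +
        stats::rnorm(1L, 0, params$eps_si)
      ap <- params$beta[["u"]] * u + params$beta[["v"]] * v +
        params$beta[["w"]] * w + stats::rnorm(1L, 0, params$eps_ap)
      lr <- stats::rnorm(1L, 0, params$eps_lr)
      rectum <- deform_rectum(baseline$rectum, geom, params, u, v)
      if (!is_simple_polygon(rectum)) return(NULL)
      bl <- geom$bladder
      scale <- 1 + params$bladder_scale_gain * w
      if (scale <= 0.1) return(NULL)
      bladder <- superellipse_contour(bl$center, bl$r[1L] * scale,
                                      bl$r[2L] * scale, bl$m, bl$n)
      anat <- sagittal_anatomy(
        bladder = bladder,
        rectum = as_contour(rectum),
        prostate = translate_contour(baseline$prostate, ap, si),
        ctv = translate_contour(baseline$ctv, ap, si),
        bone = baseline$bone,
        validate = FALSE
      )
      if (params$gas_prob > 0 && stats::runif(1L) < params$gas_prob) {
        anat <- add_gas_pocket(anat)
      }
      validate_anatomy(anat)
      list(patient_id = attr(baseline, "patient_id"),
           fraction_index = as.integer(fraction_index),
           pretreatment = anat,
           reference_shift = c(lr = lr, si = si, ap = ap),
           latent = c(u = u, v = v, w = w),
           gas = !is.null(anat$gas))
    })
    if (!is.null(rec)) {
      if (attempt > 1L) {
        message("fraction ", fraction_index, ": regenerated ", attempt - 1L,
                " degenerate draw(s)")
      }
      class(rec) <- "fraction_record"
      return(rec)
    }
  }
  stop("could not generate a valid fraction in ", params$max_regen, " draws")
}

#' Insert a rectal gas pocket
#'
#' Adds an elliptical low-density pocket in the upper rectum. The pocket only
#' affects rasterized images; contours and hence geometric features are
#' unchanged.
#'
#' @param anatomy A `sagittal_anatomy`.
#' @param frac_width,frac_height Pocket semi-axes as fractions of the rectum
#'   half-extent. The pocket distends the upper rectal lumen against the
#'   anterior wall (where it borders the target region).
#' @export
add_gas_pocket <- function(anatomy, frac_width = 0.8, frac_height = 0.35) {
  r <- anatomy$rectum
  amin <- min(r[, 1L]); amax <- max(r[, 1L])
  smin <- min(r[, 2L]); smax <- max(r[, 2L])
  hw <- (amax - amin) / 2; hh <- (smax - smin) / 2
  center <- c(amax - frac_width * hw, (smin + smax) / 2 + 0.5 * hh)
  anatomy$gas <- superellipse_contour(center, frac_width * hw,
                                      frac_height * hh, m = 2, n = 32L)
  anatomy
}

#' Simulate a cohort of patients with paired planning/pretreatment anatomies
#'
#' @param params A [generator_params()] object.
#' @param n_patients Number of patients (>= 2).
#' @param n_fractions_per_patient Fractions per patient (>= 1).
#' @param seed Master seed; patient and fraction substreams are derived from
#'   it, so cohorts are bit-identical across runs.
#' @return A `ctv_cohort`: `params`, `seed` and `patients`, each patient a
#'   list of `patient_id`, `planning` anatomy and `fractions`.
#' @export
simulate_cohort <- function(params, n_patients = 10L,
                            n_fractions_per_patient = 38L, seed = 1L) {
  if (n_patients < 2L) stop("a cohort needs at least 2 patients")
  if (n_fractions_per_patient < 1L) stop("need at least 1 fraction per patient")
  patients <- lapply(seq_len(n_patients), function(p) {
    pid <- sprintf("P%02d", p)
    baseline <- make_patient_baseline(params, pid, derive_seed(seed, p, 0L))
    fractions <- lapply(seq_len(n_fractions_per_patient), function(i) {
      sample_fraction(baseline, params, i, derive_seed(seed, p, i))
    })
    list(patient_id = pid, planning = baseline, fractions = fractions)
  })
  structure(list(params = params, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 n_fractions_per_patient = as.integer(n_fractions_per_patient),
                 patients = patients),
            class = "ctv_cohort")
}

#' @export
print.ctv_cohort <- function(x, ...) {
  nf <- sum(vapply(x$patients, function(p) length(p$fractions), integer(1)))
  cat(sprintf("<ctv_cohort> %d patients, %d fractions (seed %d)\n",
              length(x$patients), nf, x$seed))
  invisible(x)
}

#' Reference shifts of a cohort as a data frame
#' @param cohort A `ctv_cohort`.
#' @return Data frame with `patient_id`, `fraction`, `lr`, `si`, `ap` (mm).
#' @export
cohort_shifts <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    do.call(rbind, lapply(p$fractions, function(f) {
      data.frame(patient_id = f$patient_id, fraction = f$fraction_index,
                 lr = f$reference_shift[["lr"]],
                 si = f$reference_shift[["si"]],
                 ap = f$reference_shift[["ap"]])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_intensities <- function() {
  c(background = 40, bladder = 30, rectum = 50, ctv = 45, prostate = 48,
    bone = 100, gas = 0)
}

#' Rasterize an anatomy into a grayscale image
#'
#' Pixel-center point-in-polygon fill: each organ is painted with a constant
#' intensity over a soft-tissue background (paint order bladder, rectum,
#' CTV, prostate, bone, gas), emulating the low-contrast appearance the
#' grey-value comparator works on.
#'
#' @param anatomy A `sagittal_anatomy`.
#' @param pixel_size_mm Pixel pitch, mm (> 0).
#' @param include_gas Paint the gas pocket (if any) with the gas intensity.
#' @param intensities Named intensity vector, see [default_intensities()].
#' @param noise_sd Additive Gaussian intensity noise SD (0 = none).
#' @param seed Seed for the noise draw.
#' @param extent `c(a_min, a_max, s_min, s_max)` in mm; defaults to the
#'   anatomy bounding box plus 10 mm. Pass a common extent to obtain
#'   co-registered image pairs.
#' @return An `image2d`: `pixels` (rows index s ascending, cols a ascending),
#'   `pixel_size`, `origin` (center of pixel \[1,1\]).
#' @export
rasterize <- function(anatomy, pixel_size_mm = 1, include_gas = TRUE,
                      intensities = default_intensities(), noise_sd = 0,
                      seed = 1L, extent = NULL) {
  if (!is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("pixel_size_mm must be > 0")
  }
  if (is.null(extent)) {
    allv <- do.call(rbind, lapply(organ_names(),
                                  function(nm) unclass(anatomy[[nm]])))
    extent <- c(min(allv[, 1L]) - 10, max(allv[, 1L]) + 10,
                min(allv[, 2L]) - 10, max(allv[, 2L]) + 10)
  }
  ax <- seq(extent[1L] + pixel_size_mm / 2, extent[2L], by = pixel_size_mm)
  sx <- seq(extent[3L] + pixel_size_mm / 2, extent[4L], by = pixel_size_mm)
  img <- matrix(intensities[["background"]], nrow = length(sx),
                ncol = length(ax))
  paint <- function(img, poly, value) {
    jr <- which(ax >= min(poly[, 1L]) - pixel_size_mm &
                  ax <= max(poly[, 1L]) + pixel_size_mm)
    ir <- which(sx >= min(poly[, 2L]) - pixel_size_mm &
                  sx <= max(poly[, 2L]) + pixel_size_mm)
    if (!length(jr) || !length(ir)) return(img)
    pts <- cbind(rep(ax[jr], each = length(ir)),
                 rep(sx[ir], times = length(jr)))
    inside <- point_in_polygon(pts, poly)
    idx <- cbind(rep(ir, times = length(jr)), rep(jr, each = length(ir)))
    img[idx[inside, , drop = FALSE]] <- value
    img
  }
  for (nm in c("bladder", "rectum", "ctv", "prostate", "bone")) {
    img <- paint(img, anatomy[[nm]], intensities[[nm]])
  }
  if (include_gas && !is.null(anatomy$gas)) {
    img <- paint(img, anatomy$gas, intensities[["gas"]])
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow = nrow(img)))
  }
  structure(list(pixels = img, pixel_size = pixel_size_mm,
                 origin = c(a = ax[1L], s = sx[1L])),
            class = "image2d")
}
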