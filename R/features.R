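# Bone-relative anatomical features.
#
# Two pubic-bone landmarks anchor every measurement: S (superior-posterior
# edge) and I (inferior-posterior edge). Seven distances d1-d7 are measured
# per image; the nine features of a planning/pretreatment pair are the
# distance differences f_l = d_l(CBCT) - d_l(pCT) for l = 1..7 plus the
# prostate-center displacement along SI (f8) and AP (f9).

#' Locate the pubic-bone feature points S and I
#'
#' S is the bone vertex maximizing `s - a` (most superior-posterior corner),
#' I the vertex maximizing `-s - a` (most inferior-posterior). Ties go to
#' the more superior (S) / inferior (I) vertex, then to the more posterior.
#'
#' @param bone Pubic-bone contour.
#' @return List with `S` and `I`, each a named `c(a, s)` point.
#' @export
locate_feature_points <- function(bone) {
  if (!is.matrix(bone) || nrow(bone) < 3L || !all(is.finite(bone))) {
    stop("degenerate bone contour")
  }
  a <- bone[, 1L]; s <- bone[, 2L]
  pick <- function(key, tie1, tie2) {
    i <- which(key == max(key))
    if (length(i) > 1L) i <- i[tie1[i] == max(tie1[i])]
    if (length(i) > 1L) i <- i[tie2[i] == max(tie2[i])]
    i[1L]
  }
  iS <- pick(s - a, s, -a)
  iI <- pick(-s - a, -s, -a)
  list(S = c(a = a[iS], s = s[iS]), I = c(a = a[iI], s = s[iI]))
}

measurement_error <- function(distance, what) {
  stop(sprintf("distance %s not measurable: %s", distance, what),
       call. = FALSE)
}

#' Measure the seven bone-relative distances on one image
#'
#' All distances are positive magnitudes in their anatomical direction
#' (d2 superior to the bladder top; d3/d5 posterior to the rectal anterior
#' wall); a wall on the wrong side of its landmark raises an error rather
#' than a negative value. With more than two rectal crossings the outermost
#' pair defines the anterior wall and the diameter.
#'
#' @param anatomy A `sagittal_anatomy`.
#' @param points Feature points from [locate_feature_points()]; computed
#'   from `anatomy$bone` when omitted.
#' @return Named numeric vector `d1..d7` (mm); `d7 = d6 - d4` exactly and
#'   may be negative.
#' @export
measure_distances <- function(anatomy, points = NULL) {
  if (is.null(points)) points <- locate_feature_points(anatomy$bone)
  S <- points$S; I <- points$I
  bl <- anatomy$bladder; re <- anatomy$rectum

  # d1: S to the most-posterior bladder vertex, ties to the most superior
  # ("top of the posterior convex"); Euclidean.
  amin <- min(bl[, 1L])
  cand <- which(bl[, 1L] <= amin + 1e-12)
  top <- cand[which.max(bl[cand, 2L])]
  d1 <- unname(sqrt((bl[top, 1L] - S[["a"]])^2 + (bl[top, 2L] - S[["s"]])^2))

  # d2: SI-parallel line through S up to the superior bladder wall.
  si_cross <- line_polygon_intersections(bl, "a", S[["a"]])
  if (!length(si_cross)) {
    measurement_error("2", "SI line through S misses the bladder")
  }
  d2 <- max(si_cross) - S[["s"]]
  if (d2 <= 0) measurement_error("2", "bladder top is not superior to S")

  rect_line <- function(P, dist_wall, dist_diam) {
    cr <- line_polygon_intersections(re, "s", P[["s"]])
    if (length(cr) < 2L) {
      measurement_error(dist_wall, "AP line misses the rectum")
    }
    wall <- P[["a"]] - max(cr)
    if (wall <= 0) {
      measurement_error(dist_wall,
                        "rectal anterior wall is not posterior to the landmark")
    }
    c(wall = wall, diam = max(cr) - min(cr))
  }
  up <- rect_line(S, "3", "4")
  lo <- rect_line(I, "5", "6")

  d <- c(d1 = d1, d2 = d2, d3 = up[["wall"]], d4 = up[["diam"]],
         d5 = lo[["wall"]], d6 = lo[["diam"]])
  c(d, d7 = d[["d6"]] - d[["d4"]])
}

#' Prostate center (COP)
#'
#' Midpoint of the axis-aligned extent along AP and SI (not the area
#' centroid), matching the one-click middle-point convention.
#'
#' @param prostate Prostate contour.
#' @return Named `c(a, s)` point, mm.
#' @export
prostate_center <- function(prostate) {
  c(a = (min(prostate[, 1L]) + max(prostate[, 1L])) / 2,
    s = (min(prostate[, 2L]) + max(prostate[, 2L])) / 2)
}

#' Combine two per-image measurements into the nine-feature vector
#'
#' @param planning_d,pretreatment_d Distance vectors from
#'   [measure_distances()] (planning CT and pretreatment CBCT).
#' @param cop_p,cop_c Prostate centers on the planning and pretreatment
#'   image.
#' @return Named numeric `f1..f9` (mm): `f1..f7` = pretreatment minus
#'   planning distances, `f8`/`f9` = prostate-center difference along SI/AP
#'   (superior/anterior positive).
#' @export
compute_features <- function(planning_d, pretreatment_d, cop_p, cop_c) {
  f <- unname(pretreatment_d[paste0("d", 1:7)] -
                planning_d[paste0("d", 1:7)])
  out <- c(f, cop_c[["s"]] - cop_p[["s"]], cop_c[["a"]] - cop_p[["a"]])
  names(out) <- paste0("f", 1:9)
  out
}

# Click-noise model: one noise draw per clicked point, applied to the
# measured quantity. d1, d2, d3, d5 each involve one clicked organ point;
# d4 and d6 involve two (sd * sqrt(2)); d7 is recomputed from the noisy d4
# and d6; the COP gets its own (larger) per-axis click noise.
perturb_distances <- function(d, click_sd) {
  if (click_sd <= 0) return(d)
  n <- stats::rnorm(6L, 0, click_sd * c(1, 1, 1, sqrt(2), 1, sqrt(2)))
  d[1:6] <- d[1:6] + n
  d[["d7"]] <- d[["d6"]] - d[["d4"]]
  d
}

#' Extract the feature table of a cohort
#'
#' Measures both images of every fraction, applies the click-noise model of
#' the generator parameters (set `click_sd = 0` for exact geometry) and
#' returns one row per fraction.
#'
#' @param cohort A `ctv_cohort` from [simulate_cohort()].
#' @param click_sd,cop_click_sd Measurement noise SDs, mm; default from the
#'   cohort's generator parameters.
#' @param seed Seed for the click-noise draws.
#' @return Data frame with `patient_id`, `fraction`, `f1..f9`, and the
#'   reference shifts `si`, `ap` (plus `lr`), in mm.
#' @export
extract_features <- function(cohort, click_sd = NULL, cop_click_sd = NULL,
                             seed = 1L) {
  click_sd <- click_sd %||% cohort$params$click_sd
  cop_click_sd <- cop_click_sd %||% cohort$params$cop_click_sd
  with_seed(seed, {
    rows <- lapply(cohort$patients, function(p) {
      pts <- locate_feature_points(p$planning$bone)
      do.call(rbind, lapply(p$fractions, function(fr) {
        dp <- perturb_distances(measure_distances(p$planning, pts), click_sd)
        dc <- perturb_distances(
          measure_distances(fr$pretreatment,
                            locate_feature_points(fr$pretreatment$bone)),
          click_sd)
        cp <- prostate_center(p$planning$prostate)
        cc <- prostate_center(fr$pretreatment$prostate)
        if (cop_click_sd > 0) {
          cp <- cp + stats::rnorm(2L, 0, cop_click_sd)
          cc <- cc + stats::rnorm(2L, 0, cop_click_sd)
        }
        f <- compute_features(dp, dc, cp, cc)
        cbind(data.frame(patient_id = fr$patient_id,
                         fraction = fr$fraction_index),
              as.data.frame(as.list(f)),
              data.frame(lr = fr$reference_shift[["lr"]],
                         si = fr$reference_shift[["si"]],
                         ap = fr$reference_shift[["ap"]]))
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

feature_cols <- function() paste0("f", 1:9)
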