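# Intensity-based rigid registration: exhaustive integer-pixel translation
# search maximizing the correlation ratio inside a region of interest,
# followed by quadratic sub-pixel refinement. This is the clinical
# comparator (grey-value match of an IGRT system) for the feature-based
# predictors.

#' Correlation ratio between two intensity samples
#'
#' `eta^2 = 1 - E[Var(moving | reference bin)] / Var(moving)`: how well the
#' moving intensities are explained as a function of the reference
#' intensities. 1 for a deterministic mapping, ~0 for independence.
#'
#' @param ref,mov Numeric vectors of paired intensities.
#' @param n_bins Number of equal-width bins for the reference intensities.
#' @return Correlation ratio in \[0, 1\].
#' @export
correlation_ratio <- function(ref, mov, n_bins = 32L) {
  vt <- stats::var(mov)
  if (!is.finite(vt) || vt < 1e-300) return(1)
  rng <- range(ref)
  cls <- if (rng[2L] - rng[1L] < 1e-12) rep(1L, length(ref)) else {
    pmin(pmax(findInterval(ref, seq(rng[1L], rng[2L],
                                    length.out = n_bins + 1L),
                           all.inside = TRUE), 1L), n_bins)
  }
  nk <- tabulate(cls, n_bins)
  sk <- rowsum_by(mov, cls, n_bins)
  sk2 <- rowsum_by(mov^2, cls, n_bins)
  keep <- nk > 0L
  within <- sum(sk2[keep] - sk[keep]^2 / nk[keep])
  max(0, min(1, 1 - within / (vt * (length(mov) - 1))))
}

rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Estimate a translation by grey-value matching
#'
#' Searches integer-pixel translations within `search_mm` of zero for the
#' offset maximizing the correlation ratio of the two images inside the
#' ROI, then refines each axis by a three-point parabolic fit. Ties go to
#' the smallest translation magnitude.
#'
#' The returned shift follows the anatomy convention: the translation that
#' maps planning-frame structures onto the pretreatment image (si superior-
#' positive, ap anterior-positive, mm).
#'
#' @param reference `image2d` of the planning anatomy.
#' @param moving `image2d` of the pretreatment anatomy (same pixel size and
#'   grid extent).
#' @param roi Contour delimiting the matched region in the reference frame
#'   (clinically: CTV plus a 5 mm margin).
#' @param search_mm Search half-range, mm.
#' @param refine Apply sub-pixel quadratic refinement.
#' @param n_bins Bins for [correlation_ratio()].
#' @return List with `shift` (`c(lr = 0, si, ap)`, mm) and `cr` (the
#'   correlation ratio at the optimum).
#' @export
grey_value_match <- function(reference, moving, roi, search_mm = 15,
                             refine = TRUE, n_bins = 32L) {
  if (abs(reference$pixel_size - moving$pixel_size) > 1e-9) {
    stop("images must share one pixel size")
  }
  if (!all(dim(reference$pixels) == dim(moving$pixels)) ||
      any(abs(reference$origin - moving$origin) > 1e-9)) {
    stop("images must be defined on the same grid")
  }
  px <- reference$pixel_size
  k <- as.integer(floor(search_mm / px))
  nr <- nrow(reference$pixels); nc <- ncol(reference$pixels)
  ac <- reference$origin[["a"]] + (seq_len(nc) - 1L) * px
  sc <- reference$origin[["s"]] + (seq_len(nr) - 1L) * px
  pts <- cbind(rep(ac, each = nr), rep(sc, times = nc))
  inside <- which(point_in_polygon(pts, roi))
  rows <- (inside - 1L) %% nr + 1L
  cols <- (inside - 1L) %/% nr + 1L
  ok <- rows > k & rows <= nr - k & cols > k & cols <= nc - k
  if (!any(ok)) stop("ROI (plus search range) does not fit inside the images")
  rows <- rows[ok]; cols <- cols[ok]
  idx <- (cols - 1L) * nr + rows
  refv <- reference$pixels[idx]
  offs <- expand.grid(di = -k:k, dj = -k:k)
  offs <- offs[order(offs$di^2 + offs$dj^2, abs(offs$di), abs(offs$dj)), ]
  cr_at <- function(di, dj) {
    correlation_ratio(refv, moving$pixels[idx + dj * nr + di], n_bins)
  }
  best <- -Inf; bi <- 0L; bj <- 0L
  crs <- numeric(nrow(offs))
  for (t in seq_len(nrow(offs))) {
    crs[t] <- cr_at(offs$di[t], offs$dj[t])
    if (crs[t] > best + 1e-12) {     # strict: earlier (smaller) offsets win ties
      best <- crs[t]; bi <- offs$di[t]; bj <- offs$dj[t]
    }
  }
  di <- bi; dj <- bj
  sub <- c(0, 0)
  if (refine && best < 1 - 1e-12) {  # a perfect match is already exact
    quad <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (!is.finite(den) || den >= -1e-12) return(0)
      max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
    if (abs(di) < k) {
      sub[1L] <- quad(cr_at(di - 1L, dj), best, cr_at(di + 1L, dj))
    }
    if (abs(dj) < k) {
      sub[2L] <- quad(cr_at(di, dj - 1L), best, cr_at(di, dj + 1L))
    }
  }
  list(shift = c(lr = 0, si = (di + sub[1L]) * px, ap = (dj + sub[2L]) * px),
       cr = best)
}

#' Registration region of interest from an anatomy
#'
#' CTV contour expanded by a margin (default 5 mm), the clinical matching
#' ROI.
#' @param anatomy A `sagittal_anatomy`.
#' @param margin_mm Margin, mm.
#' @export
match_roi <- function(anatomy, margin_mm = 5) {
  expand_contour(anatomy$ctv, margin_mm)
}
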