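# The per-image anatomy container: closed sagittal contours for bladder,
# rectum, prostate, CTV (prostate + seminal-vesicle region) and pubic bone,
# all in one bone-registered frame (mm; a anterior-positive, s
# superior-positive, isocenter origin).

#' Construct a sagittal anatomy
#'
#' @param bladder,rectum,prostate,ctv,bone Contours (see [contour()]).
#' @param gas Optional rectal gas-pocket contour or `NULL`.
#' @param validate Check the anatomical invariants (prostate inside CTV,
#'   rectum posterior to the pubic-bone landmark S).
#' @return An object of class `sagittal_anatomy`.
#' @export
sagittal_anatomy <- function(bladder, rectum, prostate, ctv, bone,
                             gas = NULL, validate = TRUE) {
  obj <- structure(
    list(bladder = bladder, rectum = rectum, prostate = prostate,
         ctv = ctv, bone = bone, gas = gas),
    class = "sagittal_anatomy"
  )
  if (validate) validate_anatomy(obj)
  obj
}

organ_names <- function() c("bladder", "rectum", "prostate", "ctv", "bone")

#' Validate a sagittal anatomy
#'
#' Checks that every organ contour is a valid simple polygon, that the
#' prostate lies inside the CTV and that the rectum centroid is posterior to
#' the superior-posterior pubic-bone landmark S.
#'
#' @param anatomy A `sagittal_anatomy`.
#' @return The anatomy, invisibly; stops on violation.
#' @export
validate_anatomy <- function(anatomy) {
  for (nm in organ_names()) {
    p <- anatomy[[nm]]
    if (is.null(p)) stop("missing organ contour: ", nm)
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
      stop("organ ", nm, " is not a valid contour")
    }
    if (!all(is.finite(p))) stop("organ ", nm, " has non-finite coordinates")
    if (polygon_area(p) < 1e-9) stop("organ ", nm, " has degenerate area")
  }
  if (!all(point_in_polygon(unclass(anatomy$prostate), anatomy$ctv))) {
    stop("prostate contour is not contained in the CTV contour")
  }
  S <- locate_feature_points(anatomy$bone)$S
  if (polygon_centroid(anatomy$rectum)[1L] >= S[1L]) {
    stop("rectum centroid must be posterior to pubic-bone landmark S")
  }
  invisible(anatomy)
}

#' Rigidly translate an entire anatomy
#'
#' All organs (bone included) are moved together; bone-relative features are
#' invariant under this operation.
#'
#' @param anatomy A `sagittal_anatomy`.
#' @param da,ds Translation along AP and SI, mm.
#' @export
translate_anatomy <- function(anatomy, da, ds) {
  for (nm in organ_names()) {
    anatomy[[nm]] <- translate_contour(anatomy[[nm]], da, ds)
  }
  if (!is.null(anatomy$gas)) {
    anatomy$gas <- translate_contour(anatomy$gas, da, ds)
  }
  anatomy
}

#' @export
print.sagittal_anatomy <- function(x, ...) {
  cat("<sagittal_anatomy>\n")
  for (nm in organ_names()) {
    cen <- polygon_centroid(x[[nm]])
    cat(sprintf("  %-9s %2d vertices, area %8.1f mm^2, centroid (%.1f, %.1f)\n",
                nm, nrow(x[[nm]]), polygon_area(x[[nm]]), cen[1L], cen[2L]))
  }
  if (!is.null(x$gas)) cat("  gas pocket present\n")
  invisible(x)
}
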