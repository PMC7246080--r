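# Evaluation protocol: Spearman feature ranking, leave-one-patient-out
# cross-validation (LCV), independent validation, residual summaries and
# the nonparametric comparison statistics used to compare architectures
# with each other and with intensity-based registration.

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks for ties. The two-sided p-value is computed by full
#' permutation enumeration for n <= 9 and by the t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("need equal lengths >= 3")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (!is.finite(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (n <= 9L) {
    perms <- e1071::permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    num <- abs(matrix(ryc[perms], nrow(perms)) %*% rxc)
    p <- mean(num >= abs(sum(rxc * ryc)) - 1e-9)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Rank the nine features by correlation with the reference shifts
#'
#' Features are ordered by descending mean of |rho(f, SI)| and |rho(f, AP)|
#' (Spearman); ties break toward the lower feature index. Also returns the
#' nested subsets (first k features, k = 1..9) used for the feature-count
#' search.
#'
#' @param features Feature table (columns `f1..f9`, `si`, `ap`), e.g. from
#'   [extract_features()], with >= 3 rows.
#' @return List with `order` (feature indices, best first), `key` (mean
#'   absolute rho per feature), `rho_si`, `rho_ap`, and `subsets`.
#' @export
rank_features <- function(features) {
  if (nrow(features) < 3L) stop("need at least 3 fractions to rank features")
  fm <- as.matrix(features[, feature_cols()])
  rho_si <- suppressWarnings(
    as.vector(stats::cor(fm, features$si, method = "spearman")))
  rho_ap <- suppressWarnings(
    as.vector(stats::cor(fm, features$ap, method = "spearman")))
  key <- (abs(rho_si) + abs(rho_ap)) / 2
  key[!is.finite(key)] <- -Inf
  ord <- order(-key, seq_along(key))
  list(order = ord, key = key, rho_si = rho_si, rho_ap = rho_ap,
       subsets = lapply(seq_along(ord), function(k) ord[seq_len(k)]))
}

fit_and_predict <- function(architecture, train, test, feats, hyper, seed) {
  Xtr <- as.matrix(train[, feature_cols()[feats], drop = FALSE])
  Xte <- as.matrix(test[, feature_cols()[feats], drop = FALSE])
  out <- list()
  for (dir in c("si", "ap")) {
    m <- train_regressor(architecture, Xtr, train[[dir]], hyper = hyper,
                         seed = derive_seed(seed, match(dir, c("si", "ap"))))
    out[[dir]] <- stats::predict(m, Xte)
  }
  out
}

residual_rows <- function(test, pred, architecture, n_features) {
  do.call(rbind, lapply(c("si", "ap"), function(dir) {
    data.frame(patient_id = test$patient_id, fraction = test$fraction,
               direction = dir, architecture = architecture,
               n_features = n_features, reference = test[[dir]],
               predicted = pred[[dir]],
               residual = abs(test[[dir]] - pred[[dir]]))
  }))
}

as_feature_table <- function(x, ...) {
  if (inherits(x, "ctv_cohort")) extract_features(x, ...) else x
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient, features are ranked and models fitted (one per shift
#' direction) on all other patients' fractions, then the held-out patient's
#' fractions are predicted; residuals are pooled over patients.
#'
#' By default the feature ranking is recomputed inside every training fold
#' (no information from the held-out patient leaks into the subset choice);
#' `rank_per_fold = FALSE` uses one pooled ranking instead.
#'
#' @param features Feature table (or a `ctv_cohort`, which is extracted
#'   first) with >= 2 patients.
#' @param architecture Architecture name, see [architectures()].
#' @param n_features Number of top-ranked features to use (1..9).
#' @param hyper Optional tuning value, see [train_regressor()].
#' @param rank_per_fold Recompute the feature ranking per fold.
#' @param seed Seed for stochastic trainers.
#' @return A residual table: one row per fraction and direction with
#'   `reference`, `predicted` and `residual` (mm).
#' @export
run_lcv <- function(features, architecture = "svr", n_features = 1L,
                    hyper = NULL, rank_per_fold = TRUE, seed = 1L) {
  features <- as_feature_table(features)
  pats <- unique(features$patient_id)
  if (length(pats) < 2L) stop("LCV needs at least 2 patients")
  pooled_order <- if (!rank_per_fold) rank_features(features)$order
  out <- lapply(seq_along(pats), function(i) {
    test <- features[features$patient_id == pats[i], , drop = FALSE]
    if (nrow(test) == 0L) {
      warning("patient ", pats[i], " has no fractions; skipped")
      return(NULL)
    }
    train <- features[features$patient_id != pats[i], , drop = FALSE]
    ord <- if (rank_per_fold) rank_features(train)$order else pooled_order
    feats <- ord[seq_len(n_features)]
    pred <- fit_and_predict(architecture, train, test, feats, hyper,
                            derive_seed(seed, i))
    residual_rows(test, pred, architecture, n_features)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Independent validation run
#'
#' Ranks features and fits on the full training cohort, then predicts every
#' fraction of a disjoint validation cohort.
#'
#' @param train_features,val_features Feature tables (or cohorts) with
#'   disjoint patient sets.
#' @inheritParams run_lcv
#' @return A residual table as in [run_lcv()].
#' @export
run_validation <- function(train_features, val_features,
                           architecture = "svr", n_features = 1L,
                           hyper = NULL, seed = 1L) {
  train <- as_feature_table(train_features)
  val <- as_feature_table(val_features)
  if (length(intersect(unique(train$patient_id),
                       unique(val$patient_id)))) {
    stop("training and validation patient sets overlap")
  }
  feats <- rank_features(train)$order[seq_len(n_features)]
  pred <- fit_and_predict(architecture, train, val, feats, hyper, seed)
  res <- residual_rows(val, pred, architecture, n_features)
  rownames(res) <- NULL
  res
}

#' Summarize absolute residuals
#'
#' Mean absolute residual with its sample SD (n - 1 denominator) and the
#' maximum, per direction and pooled over both directions.
#'
#' @param residuals A residual table from [run_lcv()]/[run_validation()],
#'   or a bare numeric vector of absolute residuals.
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return Data frame with `direction`, `n`, `mean_abs`, `sd`, `max`.
#' @export
residual_summary <- function(residuals, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  sdev <- function(x) {
    if (length(x) == 1L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  if (is.numeric(residuals)) {
    if (!length(residuals)) stop("no residuals to summarize")
    residuals <- data.frame(direction = "pooled", residual = residuals)
    dirs <- "pooled"
  } else {
    if (!nrow(residuals)) stop("no residuals to summarize")
    dirs <- c(unique(residuals$direction), "pooled")
  }
  do.call(rbind, lapply(dirs, function(d) {
    r <- if (d == "pooled") residuals$residual
         else residuals$residual[residuals$direction == d]
    data.frame(direction = d, n = length(r), mean_abs = mean(r),
               sd = sdev(r), max = max(r))
  }))
}

sd_pair_stat <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  r <- rank(c(xi, xj))
  Ri <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(c(stat = 0, Ri = Ri, E = E))
  c(stat = (Ri - E) / sqrt(V), Ri = Ri, E = E)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' Every pair of groups is compared by a two-sample rank-sum statistic
#' (ranks recomputed within the pair, tie-corrected variance) referred to
#' the studentized-range distribution with k groups (large-sample
#' approximation). For exactly two small groups `method = "exact"`
#' enumerates all labelings of the pooled sample instead.
#'
#' @param groups List of >= 2 numeric vectors (each n >= 2).
#' @param method `"asymptotic"` (default) or `"exact"` (2 groups, pooled
#'   size <= 12).
#' @return List with symmetric matrices `p` and `statistic`.
#' @export
steel_dwass <- function(groups, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs n >= 2")
  }
  nm <- names(groups) %||% paste0("g", seq_len(k))
  P <- S <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(P) <- 1; diag(S) <- 0
  if (method == "exact") {
    if (k != 2L) stop("exact enumeration is implemented for 2 groups only")
    N <- length(groups[[1L]]) + length(groups[[2L]])
    if (N > 12L) stop("exact enumeration limited to pooled n <= 12")
    pooled <- c(groups[[1L]], groups[[2L]])
    r <- rank(pooled)
    n1 <- length(groups[[1L]])
    obs <- sum(r[seq_len(n1)])
    E <- n1 * (N + 1) / 2
    combs <- utils::combn(N, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(sums - E) >= abs(obs - E) - 1e-9)
    st <- sd_pair_stat(groups[[1L]], groups[[2L]])[["stat"]]
    P[1L, 2L] <- P[2L, 1L] <- p
    S[1L, 2L] <- st; S[2L, 1L] <- -st
    return(list(p = P, statistic = S, method = method))
  }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      st <- sd_pair_stat(groups[[i]], groups[[j]])[["stat"]]
      p <- stats::ptukey(abs(st) * sqrt(2), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      P[i, j] <- P[j, i] <- p
      S[i, j] <- st; S[j, i] <- -st
    }
  }
  list(p = P, statistic = S, method = method)
}

#' Two-sided F test for equality of variances
#'
#' `F = var(a) / var(b)` (sample variances); the two-sided p doubles the
#' smaller tail of the F distribution.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @return List with `F`, `df`, and `p`.
#' @export
f_test_variance <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in both samples")
  f <- stats::var(a) / stats::var(b)
  df <- c(length(a) - 1L, length(b) - 1L)
  lo <- stats::pf(f, df[1L], df[2L])
  p <- min(1, 2 * min(lo, 1 - lo))
  list(F = f, df = df, p = p)
}

#' Cohen's kappa between two shift raters
#'
#' Continuous shifts are discretized to `bin_width_mm` bins centered on
#' multiples of the bin width (1 mm default, i.e. rounding to the nearest
#' millimeter), then unweighted kappa is computed on the categories.
#'
#' @param shifts_a,shifts_b Equal-length numeric vectors (mm), or factors /
#'   integer categories (used as-is).
#' @param bin_width_mm Bin width, mm (> 0).
#' @return Kappa (1 = perfect agreement, 0 = chance level).
#' @export
cohens_kappa <- function(shifts_a, shifts_b, bin_width_mm = 1) {
  if (length(shifts_a) != length(shifts_b)) stop("length mismatch")
  if (bin_width_mm <= 0) stop("bin_width_mm must be > 0")
  tocat <- function(x) {
    if (is.factor(x) || is.character(x)) as.character(x)
    else as.character(round(x / bin_width_mm))
  }
  a <- tocat(shifts_a); b <- tocat(shifts_b)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev)) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Dice similarity coefficient of two contours
#'
#' `2 |A intersect B| / (|A| + |B|)` by polygon clipping (at least one of
#' the contours must be convex).
#'
#' @param polyA,polyB Contours.
#' @return DSC in \[0, 1\].
#' @export
dice_coefficient <- function(polyA, polyB) {
  inter <- polygon_intersection_area(polyA, polyB)
  2 * inter / (polygon_area(polyA) + polygon_area(polyB))
}
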