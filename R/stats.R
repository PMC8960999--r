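#' @keywords internal
test_result <- function(name, statistic, df, p_value,
                        tail = c("two-sided", "left", "right"),
                        alpha = 0.05, note = NA_character_) {
  tail <- match.arg(tail)
  data.frame(name = name, statistic = statistic, df = df, p_value = p_value,
             tail = tail, alpha = alpha,
             significant = is.finite(p_value) & p_value < alpha,
             note = note, stringsAsFactors = FALSE)
}

# zero variance up to floating-point noise relative to the mean magnitude
degenerate_sd <- function(x) {
  stats::sd(x) <= 1e-10 * max(1, abs(mean(x)))
}

#' Per-axis and Euclidean displacement between two coordinates
#'
#' @param coordinate,reference world points (mm), ML/AP/SI order.
#' @return A list of class `displacement`: `d_ml`, `d_ap`, `d_si` (absolute
#'   per-axis distances) and `ed` (Euclidean distance), all in mm.
#' @export
displacement <- function(coordinate, reference) {
  d <- abs(as.numeric(coordinate) - as.numeric(reference))
  structure(list(d_ml = d[1], d_ap = d[2], d_si = d[3],
                 ed = sqrt(sum(d^2))), class = "displacement")
}

centroid_matrix <- function(centroids) {
  m <- do.call(rbind, lapply(centroids, as.numeric))
  colnames(m) <- c("ml", "ap", "si")
  m
}

#' Cohort dispersion summary
#'
#' Summarises a set of centroids against a reference coordinate (the cohort
#' mean or an atlas target) with the root-mean-square Euclidean distance, the
#' maximum Euclidean distance, and the maximum absolute displacement along
#' each axis.
#'
#' @param centroids list (or n x 3 matrix) of world coordinates.
#' @param reference world coordinate; defaults to the centroid mean.
#' @return A list of class `dispersion_summary`.
#' @export
cohort_dispersion <- function(centroids, reference = NULL) {
  m <- if (is.matrix(centroids)) centroids else centroid_matrix(centroids)
  if (nrow(m) < 2L) stop("dispersion needs at least 2 centroids")
  if (is.null(reference)) reference <- colMeans(m)
  d <- sweep(m, 2, as.numeric(reference))
  ed <- sqrt(rowSums(d^2))
  structure(list(rms_ed = sqrt(mean(ed^2)), max_ed = max(ed),
                 max_abs_ml = max(abs(d[, 1])), max_abs_ap = max(abs(d[, 2])),
                 max_abs_si = max(abs(d[, 3])), n = nrow(m),
                 reference = as.numeric(reference)),
            class = "dispersion_summary")
}

#' Paired hemispheric position tests
#'
#' Paired t-tests comparing left and right centroid positions per axis, using
#' absolute values on the ML axis (so the comparison is laterality rather than
#' sign) and signed values on AP and SI. Degenerate zero-variance differences
#' are reported as exact mean differences with `p = 0` when nonzero and
#' `p = 1` when all differences vanish.
#'
#' @param left,right lists (or n x 3 matrices) of paired centroids, subject
#'   order aligned.
#' @param alpha significance level.
#' @return A data.frame with one test per axis.
#' @export
hemispheric_position_test <- function(left, right, alpha = 0.05) {
  L <- if (is.matrix(left)) left else centroid_matrix(left)
  R <- if (is.matrix(right)) right else centroid_matrix(right)
  if (nrow(L) != nrow(R)) stop("left and right cohorts must be paired")
  if (nrow(L) < 3L) stop("paired t-test needs at least 3 pairs")
  L[, 1] <- abs(L[, 1]); R[, 1] <- abs(R[, 1])
  axes <- c(ml = 1L, ap = 2L, si = 3L)
  do.call(rbind, lapply(names(axes), function(ax) {
    dif <- L[, axes[[ax]]] - R[, axes[[ax]]]
    if (degenerate_sd(dif)) {
      return(test_result(paste0("position_", ax), statistic = NA_real_,
                         df = NA_real_, p_value = if (all(dif == 0)) 1 else 0,
                         alpha = alpha,
                         note = sprintf("zero-variance differences; exact mean difference %.6g mm",
                                        mean(dif))))
    }
    tt <- stats::t.test(dif)
    test_result(paste0("position_", ax), unname(tt$statistic),
                unname(tt$parameter), tt$p.value, alpha = alpha)
  }))
}

#' Pitman-Morgan test for equal variances of paired samples
#'
#' For paired samples the usual variance-ratio F-test is invalid because the
#' samples are correlated. The Pitman-Morgan statistic uses the variance ratio
#' `F = s1^2/s2^2` and the Pearson correlation `r` of the pairs:
#' `t = (F - 1) sqrt(n - 2) / (2 sqrt(F (1 - r^2)))` on `n - 2` degrees of
#' freedom. It is equivalent to testing zero correlation between the
#' within-pair sums and differences, and is exact under bivariate normality.
#'
#' @param x,y paired numeric vectors.
#' @param alpha significance level.
#' @param name label for the result row.
#' @return A one-row test data.frame.
#' @export
pitman_morgan_test <- function(x, y, alpha = 0.05, name = "pitman_morgan") {
  if (length(x) != length(y)) stop("samples must be paired")
  n <- length(x)
  if (n < 4L) stop("Pitman-Morgan test needs at least 4 pairs")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0) stop("zero variance in one of the paired samples")
  FF <- v1 / v2
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1)
  if (abs(FF - 1) < 1e-12) {
    tstat <- 0  # equal variances: the numerator vanishes even if r^2 = 1
  } else if (1 - r2 < 1e-12) {
    tstat <- sign(FF - 1) * Inf  # perfectly correlated pairs with unequal spread
  } else {
    tstat <- (FF - 1) * sqrt(n - 2) / (2 * sqrt(FF * (1 - r2)))
  }
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  test_result(name, tstat, n - 2, p, alpha = alpha)
}

#' Per-axis variance comparison between hemispheres
#'
#' Applies [pitman_morgan_test()] to each axis of paired left/right centroids.
#'
#' @inheritParams hemispheric_position_test
#' @return A data.frame with one test per axis.
#' @export
hemispheric_variance_test <- function(left, right, alpha = 0.05) {
  L <- if (is.matrix(left)) left else centroid_matrix(left)
  R <- if (is.matrix(right)) right else centroid_matrix(right)
  if (nrow(L) != nrow(R)) stop("left and right cohorts must be paired")
  do.call(rbind, lapply(c(ml = 1L, ap = 2L, si = 3L), function(a)
    pitman_morgan_test(L[, a], R[, a], alpha = alpha,
                       name = paste0("variance_", c("ml", "ap", "si")[a]))))
}

#' One-sample comparison of centroids against the atlas target
#'
#' Signed per-axis differences (centroid minus atlas) tested against zero with
#' a one-sample t-test. Zero-variance differences are reported as exact
#' offsets.
#'
#' @param centroids list or n x 3 matrix of world coordinates.
#' @param atlas_target world coordinate of the atlas-based target.
#' @param alpha significance level.
#' @return A data.frame with one test per axis.
#' @export
atlas_offset_test <- function(centroids, atlas_target, alpha = 0.05) {
  m <- if (is.matrix(centroids)) centroids else centroid_matrix(centroids)
  if (nrow(m) < 3L) stop("one-sample t-test needs at least 3 centroids")
  d <- sweep(m, 2, as.numeric(atlas_target))
  do.call(rbind, lapply(c(ml = 1L, ap = 2L, si = 3L), function(a) {
    ax <- c("ml", "ap", "si")[a]
    if (degenerate_sd(d[, a])) {
      return(test_result(paste0("atlas_offset_", ax), NA_real_, NA_real_,
                         p_value = if (all(d[, a] == 0)) 1 else 0,
                         alpha = alpha,
                         note = sprintf("zero-variance differences; exact offset %.6g mm",
                                        mean(d[, a]))))
    }
    tt <- stats::t.test(d[, a])
    test_result(paste0("atlas_offset_", ax), unname(tt$statistic),
                unname(tt$parameter), tt$p.value, alpha = alpha)
  }))
}

#' Confound screen: regression F-tests of displacements on confounds
#'
#' Regresses each of the four displacement metrics (absolute AP, ML, SI
#' displacement and Euclidean distance from the cohort mean) on each of the
#' five confounds (two movement surrogates, M1 and cerebellum mask volumes,
#' total intracranial volume) with simple linear regression, reporting the
#' regression F-test p-value for each of the 20 cells. Significance is
#' flagged both at the applied Bonferroni level (`alpha_bonferroni`, default
#' the conventional printed 0.007) and at the nominal `0.05 / 20`.
#'
#' @param confounds data.frame with columns `movement_rms_first_volume`,
#'   `movement_rms_preceding_volume`, `m1_volume`, `cerebellum_volume`,
#'   `tiv`.
#' @param displacements data.frame with columns `d_ap`, `d_ml`, `d_si`, `ed`
#'   (one row per subject, aligned with `confounds`).
#' @param alpha_bonferroni applied corrected significance level.
#' @return A data.frame with one row per confound-metric pair; columns
#'   `significant` (at `alpha_bonferroni`) and `significant_nominal` (at
#'   0.05 divided by the family size).
#' @export
confound_screen <- function(confounds, displacements,
                            alpha_bonferroni = 0.007) {
  conf_names <- c("movement_rms_first_volume", "movement_rms_preceding_volume",
                  "m1_volume", "cerebellum_volume", "tiv")
  metr_names <- c("d_ap", "d_ml", "d_si", "ed")
  if (!all(conf_names %in% names(confounds)))
    stop("confound table must contain the five named confounds")
  if (!all(metr_names %in% names(displacements)))
    stop("displacement table must contain d_ap, d_ml, d_si, ed")
  if (nrow(confounds) != nrow(displacements))
    stop("confound and displacement tables must be row-aligned")
  family <- length(conf_names) * length(metr_names)
  out <- lapply(conf_names, function(cn) lapply(metr_names, function(mn) {
    x <- confounds[[cn]]; y <- displacements[[mn]]
    if (stats::sd(x) == 0) {
      return(test_result(paste(mn, "~", cn), NA_real_, NA_real_, NA_real_,
                         alpha = alpha_bonferroni,
                         note = "constant confound; regression undefined"))
    }
    fit <- stats::lm(y ~ x)
    fs <- summary(fit)$fstatistic
    p <- stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]],
                   lower.tail = FALSE)
    test_result(paste(mn, "~", cn), fs[["value"]], fs[["dendf"]], p,
                alpha = alpha_bonferroni)
  }))
  res <- do.call(rbind, unlist(out, recursive = FALSE))
  res$significant_nominal <- is.finite(res$p_value) &
    res$p_value < 0.05 / family
  res
}

#' Principal directions of centroid variance
#'
#' Eigendecomposition of the 3x3 covariance of centroid coordinates,
#' eigenvalues in descending order, unit eigenvectors with the sign fixed so
#' the first component of non-negligible magnitude is positive.
#'
#' @param centroids list or n x 3 matrix of world coordinates.
#' @return A list with `values` (descending eigenvalues, mm^2) and `vectors`
#'   (3 x 3 matrix, columns are the corresponding unit eigenvectors).
#' @export
principal_directions <- function(centroids) {
  m <- if (is.matrix(centroids)) centroids else centroid_matrix(centroids)
  if (nrow(m) < 4L) stop("principal directions need at least 4 centroids")
  e <- eigen(stats::cov(m), symmetric = TRUE)
  v <- e$vectors
  for (j in 1:3) {
    nz <- which(abs(v[, j]) > 1e-12)[1]
    if (!is.na(nz) && v[nz, j] < 0) v[, j] <- -v[, j]
  }
  list(values = e$values, vectors = v)
}

#' Integrate a Jacobian-determinant field over a region
#'
#' Sums the Jacobian determinant over the mask voxels and multiplies by the
#' voxel volume, yielding the region's volume in subject space (mm^3).
#'
#' @param jacobian numeric array of strictly positive Jacobian determinants.
#' @param mask logical array on the same grid.
#' @param grid a [volume_grid()].
#' @return Volume in mm^3.
#' @export
integrate_jacobian <- function(jacobian, mask, grid) {
  if (!all(dim(jacobian) == grid$dims) || !all(dim(mask) == grid$dims))
    stop("jacobian and mask must match the grid")
  if (!any(mask)) stop("mask is empty")
  vals <- jacobian[mask]
  if (any(vals <= 0))
    stop("non-positive Jacobian determinant inside the mask")
  sum(vals) * voxel_volume(grid)
}

#' Correlation of SCP volume with DTCp maximum PICo
#'
#' Because the pathway decussates, each DTCp traverses the contralateral SCP;
#' the left DTCp's maximum PICo is therefore correlated against the right SCP
#' volume and vice versa (Pearson correlation, two-sided).
#'
#' @param scp_volumes data.frame/list with numeric `L` and `R` per-subject SCP
#'   volumes (mm^3).
#' @param dtcp_max_pico data.frame/list with numeric `L` and `R` per-subject
#'   maximum raw PICo of the combined DTCp.
#' @param alpha significance level.
#' @return A data.frame with one row per pathway; `estimate` holds r.
#' @export
scp_pico_correlation <- function(scp_volumes, dtcp_max_pico, alpha = 0.05) {
  pairing <- list(dtcp_L = c(pico = "L", scp = "R"),
                  dtcp_R = c(pico = "R", scp = "L"))
  do.call(rbind, lapply(names(pairing), function(nm) {
    pk <- dtcp_max_pico[[pairing[[nm]][["pico"]]]]
    sv <- scp_volumes[[pairing[[nm]][["scp"]]]]
    if (stats::sd(pk) == 0 || stats::sd(sv) == 0)
      stop("constant input in SCP-PICo correlation")
    ct <- stats::cor.test(sv, pk)
    res <- test_result(paste0("scp_pico_", nm), unname(ct$statistic),
                       unname(ct$parameter), ct$p.value, alpha = alpha)
    res$estimate <- unname(ct$estimate)
    res
  }))
}

# left-tailed Wilcoxon signed rank with zero differences dropped; exact
# distribution for n <= 25 nonzero differences, normal approximation with
# continuity correction above
wilcoxon_left <- function(d, alternative = "less") {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(statistic = NA_real_, p = NA_real_, n = 0L))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = n <= 25,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n)
}

#' Test-retest versus between-subject displacement comparison
#'
#' Compares within-subject displacements (scan1 vs scan2 centroid) to
#' between-subject displacements (scan1 centroid vs cohort average) per metric
#' (absolute AP, ML, SI and Euclidean distance) with a left-tailed Wilcoxon
#' signed-rank test on the paired differences `within - between`, reflecting
#' the a-priori expectation that test-retest displacements are smaller. Zero
#' differences are dropped. The RMS Euclidean distance of each arm is
#' reported alongside.
#'
#' @param within,between data.frames with columns `d_ap`, `d_ml`, `d_si`,
#'   `ed`; one row per subject, aligned.
#' @param alpha significance level.
#' @return A list with `tests` (data.frame, one row per metric),
#'   `rms_ed_within` and `rms_ed_between`.
#' @export
test_retest_comparison <- function(within, between, alpha = 0.05) {
  metr <- c("d_ap", "d_ml", "d_si", "ed")
  if (!all(metr %in% names(within)) || !all(metr %in% names(between)))
    stop("both tables must contain d_ap, d_ml, d_si, ed")
  if (nrow(within) != nrow(between)) stop("tables must be paired")
  if (nrow(within) < 6L) stop("test-retest comparison needs at least 6 pairs")
  tests <- do.call(rbind, lapply(metr, function(mn) {
    d <- within[[mn]] - between[[mn]]
    if (all(d == 0)) {
      return(test_result(paste0("retest_", mn), NA_real_, NA_real_, 1,
                         tail = "left", alpha = alpha,
                         note = "all paired differences are zero"))
    }
    w <- wilcoxon_left(d)
    test_result(paste0("retest_", mn), w$statistic, w$n, w$p, tail = "left",
                alpha = alpha)
  }))
  list(tests = tests,
       rms_ed_within = sqrt(mean(within$ed^2)),
       rms_ed_between = sqrt(mean(between$ed^2)))
}

#' Hemispheric asymmetry of Vim ROI volumes
#'
#' Two-sided Wilcoxon signed-rank test on paired left/right ROI volumes
#' (chosen to match the reporting of medians), with the per-side medians
#' returned alongside.
#'
#' @param left_volumes,right_volumes paired volumes in mm^3.
#' @param alpha significance level.
#' @return A list with `test` (one-row data.frame), `median_left` and
#'   `median_right`.
#' @export
volume_asymmetry_test <- function(left_volumes, right_volumes, alpha = 0.05) {
  if (length(left_volumes) != length(right_volumes))
    stop("volumes must be paired")
  if (length(left_volumes) < 6L)
    stop("volume asymmetry test needs at least 6 pairs")
  d <- left_volumes - right_volumes
  test <- if (all(d == 0)) {
    test_result("volume_asymmetry", NA_real_, NA_real_, 1, alpha = alpha,
                note = "all paired differences are zero")
  } else {
    w <- wilcoxon_left(d, alternative = "two.sided")
    test_result("volume_asymmetry", w$statistic, w$n, w$p, alpha = alpha)
  }
  list(test = test, median_left = stats::median(left_volumes),
       median_right = stats::median(right_volumes))
}

#' Type-I error calibration of the suite's tests
#'
#' Simulates matching nulls and reports the rejection rate at `alpha` for one
#' of the implemented tests: the paired t-test (`"paired_t"`), the
#' Pitman-Morgan paired-variance test (`"pitman_morgan"`), the simple-
#' regression F-test (`"regression_f"`) or the left-tailed Wilcoxon
#' signed-rank comparison (`"wilcoxon"`). Nulls are bivariate normal pairs
#' with equal means and variances (correlation 0.5 for the paired tests) and
#' independent normals for the regression.
#'
#' @param test which implementation to calibrate.
#' @param n sample (pair) size per replicate.
#' @param reps number of simulated replicates.
#' @param alpha nominal level.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return The empirical rejection rate (proportion of `p < alpha`).
#' @export
type1_calibration <- function(test = c("paired_t", "pitman_morgan",
                                       "regression_f", "wilcoxon"),
                              n = 100, reps = 1000, alpha = 0.05,
                              seed = NULL) {
  test <- match.arg(test)
  if (!is.null(seed)) set.seed(seed)
  rho <- 0.5
  pvals <- vapply(seq_len(reps), function(i) {
    switch(test,
      paired_t = {
        x <- stats::rnorm(n); y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
        stats::t.test(x - y)$p.value
      },
      pitman_morgan = {
        x <- stats::rnorm(n); y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
        pitman_morgan_test(x, y)$p_value
      },
      regression_f = {
        x <- stats::rnorm(n); y <- stats::rnorm(n)
        fit <- summary(stats::lm(y ~ x))$fstatistic
        stats::pf(fit[["value"]], fit[["numdf"]], fit[["dendf"]],
                  lower.tail = FALSE)
      },
      wilcoxon = {
        d <- stats::rnorm(n)  # symmetric null differences
        wilcoxon_left(d)$p
      })
  }, numeric(1))
  mean(pvals < alpha)
}
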