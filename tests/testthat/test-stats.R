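test_that("displacement metrics reproduce per-axis and Euclidean distances", {
  d <- displacement(c(3, 4, 0), c(0, 0, 0))
  expect_equal(d$ed, 5)
  expect_equal(c(d$d_ml, d$d_ap, d$d_si), c(3, 4, 0))
  z <- displacement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(z, use.names = FALSE), rep(0, 4))
  set.seed(1)
  for (i in 1:5) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    d <- displacement(a, b)
    expect_equal(d$ed, sqrt(sum((a - b)^2)))
    expect_gte(d$ed, max(d$d_ml, d$d_ap, d$d_si))
  }
})

test_that("cohort dispersion summarises RMS and maxima and is translation invariant", {
  ref <- c(0, 0, 0)
  pts <- rbind(c(0, 0, 0), c(2, 0, 0))
  ds <- cohort_dispersion(pts, ref)
  expect_equal(ds$rms_ed, sqrt(2))
  expect_equal(ds$max_ed, 2)
  same <- matrix(rep(c(1, 2, 3), 4), ncol = 3, byrow = TRUE)
  ds0 <- cohort_dispersion(same, c(1, 2, 3))
  expect_equal(ds0$rms_ed + ds0$max_ed + ds0$max_abs_ml, 0)
  # rms_ed ~ sigma * sqrt(3) for isotropic Gaussian scatter
  set.seed(2)
  sig <- 1.3
  m <- matrix(stats::rnorm(3000 * 3, 0, sig), ncol = 3)
  expect_lt(abs(cohort_dispersion(m, c(0, 0, 0))$rms_ed - sig * sqrt(3)),
            3 * sig * sqrt(3) / sqrt(2 * 3000))
  # rigid translation of points and reference leaves the summary unchanged
  t0 <- cohort_dispersion(m, c(0, 0, 0))
  t1 <- cohort_dispersion(sweep(m, 2, c(5, -3, 7), "+"), c(5, -3, 7))
  expect_equal(t0$rms_ed, t1$rms_ed)
  expect_equal(t0$max_ed, t1$max_ed)
  expect_error(cohort_dispersion(m[1, , drop = FALSE]), "at least 2")
})

test_that("hemispheric position tests use |ML| and handle degenerate inputs", {
  set.seed(3)
  L <- matrix(stats::rnorm(30), ncol = 3)
  res_same <- hemispheric_position_test(L, L)
  expect_true(all(res_same$p_value == 1))
  # a pure sign flip of ML is no laterality difference at all
  Rflip <- L; Rflip[, 1] <- -Rflip[, 1]
  expect_equal(hemispheric_position_test(L, Rflip)[1, "p_value"], 1)
  # deterministic offset: exact-difference report
  Roff <- L; Roff[, 2] <- Roff[, 2] + 1
  res_off <- hemispheric_position_test(L, Roff)
  expect_equal(res_off$p_value[res_off$name == "position_ap"], 0)
  # power against the closed-form paired-t oracle
  n <- 30; delta <- 0.6; sdd <- 1
  expected_power <- stats::power.t.test(n = n, delta = delta, sd = sdd,
                                        type = "one.sample")$power
  reps <- 400
  rej <- 0
  for (i in seq_len(reps)) {
    base <- matrix(stats::rnorm(3 * n), ncol = 3)
    Lr <- base; Rr <- base + matrix(stats::rnorm(3 * n, 0, sdd), ncol = 3)
    Rr[, 2] <- Rr[, 2] + delta
    Lr[, 1] <- Lr[, 1] + 20; Rr[, 1] <- Rr[, 1] + 20  # keep |ML| linear
    res <- hemispheric_position_test(Lr, Rr)
    rej <- rej + (res$p_value[res$name == "position_ap"] < 0.05)
  }
  se <- sqrt(expected_power * (1 - expected_power) / reps)
  expect_lt(abs(rej / reps - expected_power), 4 * se)
})

test_that("the Pitman-Morgan statistic matches its defining formula and degenerates safely", {
  set.seed(4)
  x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20)
  res <- pitman_morgan_test(x, y)
  FF <- stats::var(x) / stats::var(y); r <- stats::cor(x, y); n <- 20
  expect_equal(res$statistic,
               (FF - 1) * sqrt(n - 2) / (2 * sqrt(FF * (1 - r^2))))
  expect_equal(res$df, n - 2)
  # identical samples shifted by a constant: F = 1, t = 0, p = 1
  shifted <- pitman_morgan_test(x, x + 3)
  expect_equal(shifted$statistic, 0)
  expect_equal(shifted$p_value, 1)
  expect_error(pitman_morgan_test(rep(1, 10), stats::rnorm(10)),
               "zero variance")
  expect_error(pitman_morgan_test(x[1:3], y[1:3]), "at least 4")
})

test_that("Pitman-Morgan p-values agree with a permutation oracle", {
  # Equal paired variances are equivalent to zero correlation between the
  # within-pair sums s = x + y and differences d = x - y. The oracle permutes
  # d against s (10,000 draws) and measures the exceedance of |cor(s, d)|,
  # never touching the package's formula.
  set.seed(5)
  nperm <- 10000
  n <- 30
  worst <- 0
  for (case in 1:30) {
    rho <- stats::runif(1, -0.6, 0.6)
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    s <- x + y; d <- x - y
    robs <- abs(stats::cor(s, d))
    Dp <- t(replicate(nperm, sample(d)))
    cross <- as.numeric(Dp %*% s)
    r_perm <- (cross - n * mean(d) * mean(s)) /
      ((n - 1) * stats::sd(d) * stats::sd(s))
    p_perm <- mean(abs(r_perm) >= robs - 1e-12)
    p_mine <- pitman_morgan_test(x, y)$p_value
    worst <- max(worst, abs(p_perm - p_mine))
  }
  expect_lt(worst, 0.01)
})

test_that("Pitman-Morgan detects unequal paired variances", {
  set.seed(6)
  reps <- 400
  rej <- vapply(seq_len(reps), function(i) {
    n <- 100
    x <- stats::rnorm(n)
    y <- 0.5 * x + sqrt(1 - 0.25) * stats::rnorm(n)
    c(null = pitman_morgan_test(x, y)$p_value < 0.05,
      alt = pitman_morgan_test(x * sqrt(2), y)$p_value < 0.05)
  }, logical(2))
  expect_gt(mean(rej["alt", ]), mean(rej["null", ]))
  expect_gt(mean(rej["alt", ]), 0.5)
})

test_that("atlas offset tests match a hand-computed one-sample t", {
  set.seed(7)
  m <- matrix(stats::rnorm(60, 0, 1), ncol = 3)
  target <- c(0.3, -0.2, 0.5)
  res <- atlas_offset_test(m, target)
  for (a in 1:3) {
    d <- m[, a] - target[a]
    tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    p <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
    expect_equal(res$statistic[a], tstat)
    expect_equal(res$p_value[a], p)
  }
  # symmetric centroids: t ~ 0 by construction
  sym <- rbind(c(1, 1, 1), c(-1, -1, -1), c(2, 2, 2), c(-2, -2, -2))
  expect_lt(max(abs(atlas_offset_test(sym, c(0, 0, 0))$statistic)), 1e-10)
  # deterministic offset: degenerate exact report
  det <- matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE)
  resd <- atlas_offset_test(det, c(0, 0, 0))
  expect_equal(resd$p_value[2], 0)
  expect_match(resd$note[2], "exact offset")
})

test_that("the confound screen runs 20 regressions and flags exact relations", {
  set.seed(8)
  n <- 40
  conf <- data.frame(movement_rms_first_volume = stats::rlnorm(n),
                     movement_rms_preceding_volume = stats::rlnorm(n),
                     m1_volume = stats::rnorm(n, 15000, 1500),
                     cerebellum_volume = stats::rnorm(n, 140000, 12000),
                     tiv = stats::rnorm(n, 1.4e6, 1e5))
  disp <- data.frame(d_ap = stats::runif(n), d_ml = stats::runif(n),
                     d_si = stats::runif(n), ed = stats::runif(n))
  res <- confound_screen(conf, disp)
  expect_equal(nrow(res), 20L)
  expect_equal(res$alpha[1], 0.007)
  # an exact linear relation is detected
  disp2 <- disp; disp2$ed <- 2 * conf$tiv
  res2 <- suppressWarnings(confound_screen(conf, disp2))  # perfect-fit warning
  expect_true(res2$significant[res2$name == "ed ~ tiv"])
  expect_true(res2$significant_nominal[res2$name == "ed ~ tiv"])
  # a constant confound yields a note, not a failure
  conf3 <- conf; conf3$tiv <- 1.4e6
  res3 <- confound_screen(conf3, disp)
  expect_equal(sum(is.na(res3$p_value)), 4L)
  expect_match(res3$note[res3$name == "ed ~ tiv"], "constant confound")
})

test_that("regression F p-values are uniform under the null", {
  set.seed(9)
  n <- 40
  ps <- replicate(300, {
    conf <- data.frame(movement_rms_first_volume = stats::rlnorm(n),
                       movement_rms_preceding_volume = stats::rlnorm(n),
                       m1_volume = stats::rnorm(n), cerebellum_volume = stats::rnorm(n),
                       tiv = stats::rnorm(n))
    disp <- data.frame(d_ap = stats::rnorm(n), d_ml = stats::rnorm(n),
                       d_si = stats::rnorm(n), ed = stats::rnorm(n))
    confound_screen(conf, disp)$p_value[1]
  })
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 300))
})

test_that("principal directions recover generating axes and fix signs", {
  onx <- cbind(stats::rnorm(50), 0, 0)
  pd <- principal_directions(onx)
  expect_equal(abs(pd$vectors[, 1]), c(1, 0, 0))
  expect_gte(pd$vectors[1, 1], 0)  # sign convention
  expect_equal(pd$values[2:3], c(0, 0))
  # anisotropic Gaussian with known rotated axes, n = 500: axes within 5 deg
  set.seed(10)
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  z <- cbind(stats::rnorm(500, 0, 3), stats::rnorm(500, 0, 2),
             stats::rnorm(500, 0, 1))
  pts <- z %*% t(R)
  pd2 <- principal_directions(pts)
  for (j in 1:3) {
    ang <- acos(min(1, abs(sum(pd2$vectors[, j] * R[, j])))) * 180 / pi
    expect_lt(ang, 5)
  }
  expect_true(all(diff(pd2$values) <= 0))
  # isotropic cloud: eigenvalues comparable
  iso <- matrix(stats::rnorm(3000), ncol = 3)
  ev <- principal_directions(iso)$values
  expect_lt(ev[1] / ev[3], 1.5)
})

test_that("Jacobian integration equals the brute-force masked sum times voxel volume", {
  grid <- volume_grid(c(10L, 10L, 10L), voxel_size = 1.25)
  jac <- array(1, c(10, 10, 10))
  mask <- array(FALSE, c(10, 10, 10)); mask[1:4, 1:5, 1:5] <- TRUE  # 100 voxels
  expect_equal(integrate_jacobian(jac, mask, grid), 195.3125)
  expect_equal(integrate_jacobian(jac * 2, mask, grid), 2 * 195.3125)
  set.seed(11)
  jr <- array(stats::rexp(1000) + 0.1, c(10, 10, 10))
  expect_equal(integrate_jacobian(jr, mask, grid),
               sum(jr[mask]) * 1.25^3)
  jbad <- jac; jbad[2, 2, 2] <- -1
  expect_error(integrate_jacobian(jbad, mask, grid), "non-positive")
  expect_error(integrate_jacobian(jac, array(FALSE, c(10, 10, 10)), grid),
               "empty")
})

test_that("SCP-PICo correlation uses the contralateral pairing", {
  set.seed(12)
  scp <- list(L = stats::rnorm(30, 50, 5), R = stats::rnorm(30, 50, 5))
  # left DTCp max PICo is an exact function of the RIGHT SCP volume
  pico <- list(L = 0.01 * scp$R + 0.2, R = stats::rnorm(30, 0.3, 0.05))
  res <- scp_pico_correlation(scp, pico)
  expect_equal(res$estimate[res$name == "scp_pico_dtcp_L"], 1)
  expect_lt(abs(res$estimate[res$name == "scp_pico_dtcp_R"]), 0.7)
  # independent inputs: r near 0 on both sides over simulations
  set.seed(13)
  rs <- replicate(200, {
    s <- list(L = stats::rnorm(30), R = stats::rnorm(30))
    p <- list(L = stats::rnorm(30), R = stats::rnorm(30))
    scp_pico_correlation(s, p)$p_value
  })
  expect_lt(abs(mean(rs < 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / 400))
  expect_error(scp_pico_correlation(list(L = rep(1, 10), R = rep(1, 10)),
                                    list(L = rep(1, 10), R = rep(1, 10))),
               "constant")
})

test_that("test-retest comparison favours the within arm exactly when it is smaller", {
  n <- 10
  tbl <- function(v) data.frame(d_ap = v, d_ml = v, d_si = v, ed = v)
  # uniformly smaller within: minimal attainable left-tail p = 1/2^n
  within <- tbl(seq_len(n) / n)
  between <- tbl(seq_len(n) / n + seq_len(n))  # distinct gaps: exact Wilcoxon
  res <- test_retest_comparison(within, between)
  expect_equal(res$tests$p_value,
               rep(stats::psignrank(0, n), 4))
  expect_equal(res$rms_ed_within, sqrt(mean((seq_len(n) / n)^2)))
  # identical arms: degenerate no-evidence report
  res0 <- test_retest_comparison(within, within)
  expect_true(all(res0$tests$p_value == 1))
  expect_match(res0$tests$note[1], "zero")
  # same-distribution arms: p is not systematically small
  set.seed(14)
  ps <- replicate(200, {
    a <- tbl(abs(stats::rnorm(20))); b <- tbl(abs(stats::rnorm(20)))
    test_retest_comparison(a, b)$tests$p_value[4]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / 200))
  expect_error(test_retest_comparison(tbl(1:3), tbl(1:3)), "at least 6")
})

test_that("volume asymmetry testing reports medians and exact-distribution p-values", {
  lv <- c(100, 110, 120, 130, 140, 150, 160, 170, 180, 190)
  res_same <- volume_asymmetry_test(lv, lv)
  expect_equal(res_same$test$p_value, 1)
  res <- volume_asymmetry_test(lv, lv * 1.5)
  expect_equal(res$test$p_value, 2 * stats::psignrank(0, 10))
  expect_equal(res$median_left, stats::median(lv))
  expect_equal(res$median_right, stats::median(lv * 1.5))
  set.seed(15)
  rate <- mean(replicate(300, {
    a <- stats::rlnorm(20, log(120), 0.3); b <- stats::rlnorm(20, log(120), 0.3)
    volume_asymmetry_test(a, b)$test$p_value < 0.05
  }))
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 300))
})
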