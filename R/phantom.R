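#' Configuration for the synthetic fibre phantom
#'
#' Builds the parameter list controlling phantom geometry, fibre properties,
#' inter-subject variability and confound distributions. The phantom emulates
#' the dentato-thalamo-cortical pathway (DTCp): for each hemisphere a
#' cubic-spline tube runs from a primary motor cortex (M1) patch down through
#' the ipsilateral thalamus, narrows to the superior cerebellar peduncle (SCP)
#' waist, decussates (crosses the midline) once, and ends in the contralateral
#' cerebellum. Fibre orientations are tangent to the tube skeleton; no
#' diffusion signal is simulated.
#'
#' All coordinates are world mm with the origin at the mid-commissural point,
#' +x right (ML), +y anterior (AP), +z superior (SI).
#'
#' @param dims grid dimensions in voxels (>= 40 per axis).
#' @param voxel_size isotropic voxel edge in mm.
#' @param tube_radius_mm main tract tube radius (mm).
#' @param scp_width_vox SCP waist diameter in voxels (>= 1).
#' @param scp_width_sd_vox between-subject SD of the SCP waist diameter.
#' @param dispersion_deg angular dispersion (SD of the polar angle, degrees)
#'   of the fibre populations.
#' @param fibre_fraction volume fraction assigned to each tract population.
#' @param jitter_sd per-axis SD (mm, order ML/AP/SI) of the between-subject
#'   positional jitter applied to each hemisphere's pathway.
#' @param hemi_offset_left,hemi_offset_right mean positional offset (mm) added
#'   to the respective hemisphere's jitter, for simulating systematic
#'   hemispheric asymmetry.
#' @param retest_sd per-axis SD (mm) of within-subject scan-to-scan noise used
#'   by [sample_test_retest_pair()].
#' @param confound_coupling correlation in (-1, 1) between the M1-volume
#'   confound and the left-hemisphere ML jitter; 0 keeps all confounds
#'   independent of centroid position.
#' @param scp_jacobian_bump multiplicative value of the Jacobian-determinant
#'   field inside the SCP masks (1 elsewhere).
#' @param vim_canonical canonical left Vim centre (world mm); the right centre
#'   is its mirror image.
#' @return A named list of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(64L, 64L, 64L),
                           voxel_size = 1.25,
                           tube_radius_mm = 2.5,
                           scp_width_vox = 2,
                           scp_width_sd_vox = 0,
                           dispersion_deg = 8,
                           fibre_fraction = 0.45,
                           jitter_sd = c(1.2, 1.3, 1.5),
                           hemi_offset_left = c(0, 0, 0),
                           hemi_offset_right = c(0, 0, 0),
                           retest_sd = c(0.5, 0.5, 0.5),
                           confound_coupling = 0,
                           scp_jacobian_bump = 1.2,
                           vim_canonical = c(-13.75, -6.25, 2.5)) {
  cfg <- list(
    dims = as.integer(dims), voxel_size = voxel_size,
    tube_radius_mm = tube_radius_mm,
    scp_width_vox = scp_width_vox, scp_width_sd_vox = scp_width_sd_vox,
    dispersion_deg = dispersion_deg, fibre_fraction = fibre_fraction,
    jitter_sd = rep_len(jitter_sd, 3L),
    hemi_offset_left = rep_len(hemi_offset_left, 3L),
    hemi_offset_right = rep_len(hemi_offset_right, 3L),
    retest_sd = rep_len(retest_sd, 3L),
    confound_coupling = confound_coupling,
    scp_jacobian_bump = scp_jacobian_bump,
    vim_canonical = vim_canonical,
    # fixed canonical anatomy (left pathway; right is the x-mirror)
    m1_centre = c(-20, -8, 30), m1_radius = 2.5,
    cerebellum_centre = c(17, -18, -28), cerebellum_radius = 3.5,
    thalamus_half = c(5, 5, 5),
    scp_band_z = c(-23, -19), scp_taper_z = c(-25, -17),
    ac = c(0, 12, 0), pc = c(0, -12, 0),
    # confound distributions: movement surrogates log-normal, volumes normal
    confound_dists = list(
      movement_rms_first_volume    = list(kind = "lognormal", meanlog = log(0.50), sdlog = 0.35),
      movement_rms_preceding_volume = list(kind = "lognormal", meanlog = log(0.12), sdlog = 0.35),
      m1_volume         = list(kind = "normal", mean = 15000,  sd = 1500),
      cerebellum_volume = list(kind = "normal", mean = 140000, sd = 12000),
      tiv               = list(kind = "normal", mean = 1.42e6, sd = 0.14e6)))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$dims < 40L))
    stop("phantom configuration error: grid must be at least 40 voxels per axis")
  if (cfg$tube_radius_mm < cfg$voxel_size)
    stop("phantom configuration error: tube radius must be at least one voxel")
  if (cfg$scp_width_vox < 1)
    stop("phantom configuration error: SCP width must be at least one voxel")
  invisible(cfg)
}

# Canonical skeleton control points for one pathway, before jitter.
# `side` is the hemisphere of the M1/thalamus end ("L" places M1 at x < 0).
pathway_controls <- function(cfg, side) {
  v <- cfg$vim_canonical
  u <- c(-0.1, -0.06, -0.99); u <- u / sqrt(sum(u^2))  # thalamic transit direction
  pts <- rbind(
    cfg$m1_centre,
    c(-17, -7, 18),
    v - 6.5 * u,
    v,
    v + 6.5 * u,
    c(-10, -9, -10),
    c(-4, -12.5, -15),
    c(2, -14.5, -19),
    c(9, -16.5, -23),
    cfg$cerebellum_centre)
  if (side == "R") pts[, 1] <- -pts[, 1]
  pts
}

# Densify control points with a natural cubic spline over chord length;
# returns points, unit tangents and per-point tube radii (SCP taper applied).
densify_skeleton <- function(cfg, pts, scp_width_vox, spacing = 0.4) {
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  to <- seq(0, max(tt), by = spacing)
  dense <- sapply(1:3, function(a)
    stats::spline(tt, pts[, a], xout = to, method = "natural")$y)
  tan <- apply(dense, 2, function(v) c(v[2] - v[1], diff(v, lag = 2) / 2,
                                       v[length(v)] - v[length(v) - 1]))
  tan <- tan / sqrt(rowSums(tan^2))
  r_scp <- scp_width_vox * cfg$voxel_size / 2
  radii <- taper_radius(dense[, 3], cfg$tube_radius_mm, r_scp,
                        cfg$scp_band_z, cfg$scp_taper_z)
  list(points = dense, tangents = tan, radii = radii)
}

# tube radius as a function of z: r_main outside the taper zone, r_scp inside
# the SCP band, linear in between
taper_radius <- function(z, r_main, r_scp, band, taper) {
  w <- numeric(length(z))
  w[z >= band[1] & z <= band[2]] <- 1
  lo <- z > taper[1] & z < band[1]
  w[lo] <- (z[lo] - taper[1]) / (band[1] - taper[1])
  hi <- z > band[2] & z < taper[2]
  w[hi] <- (taper[2] - z[hi]) / (taper[2] - band[2])
  r_main * (1 - w) + r_scp * w
}

# Union-of-balls tube rasterization. Returns, for every voxel, the squared
# distance to the nearest skeleton sample within radius and that sample's
# index (0 = outside tube).
rasterize_tube <- function(grid, sk) {
  dims <- grid$dims
  nvox <- prod(dims)
  best <- rep(Inf, nvox)
  nearest <- integer(nvox)
  vox <- world_to_voxel(grid, sk$points)
  rvox <- sk$radii / min(grid$voxel_size)
  for (s in seq_len(nrow(sk$points))) {
    c0 <- vox[s, ]
    lo <- pmax(ceiling(c0 - rvox[s] - 0.5), 0)
    hi <- pmin(floor(c0 + rvox[s] + 0.5), dims - 1L)
    if (any(lo > hi))
      stop("phantom geometry error: tract tube leaves the grid")
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    w <- voxel_to_world(grid, g)
    d2 <- (w[, 1] - sk$points[s, 1])^2 + (w[, 2] - sk$points[s, 2])^2 +
      (w[, 3] - sk$points[s, 3])^2
    lin <- g[, 1] + 1L + dims[1] * (g[, 2] + dims[2] * g[, 3])
    upd <- d2 <= sk$radii[s]^2 & d2 < best[lin]
    best[lin[upd]] <- d2[upd]
    nearest[lin[upd]] <- s
  }
  list(dist2 = best, nearest = nearest)
}

#' Build one synthetic DTCp phantom
#'
#' Generates the voxel grid, multi-fibre orientation field, binary masks,
#' AC/PC landmarks, Jacobian-determinant field and ground truth for a single
#' subject. With `subject = NULL` a subject is drawn from the configured
#' between-subject distributions using `seed`; pass an element of
#' [sample_subject_params()] to build a specific subject.
#'
#' Mask naming: suffixes `_L`/`_R` on `m1`, `thalamus` and the exclusion masks
#' refer to the pathway hemisphere (the side of its M1/thalamus end);
#' `cerebellum_L/R` and `scp_L/R` are anatomical sides, so the left pathway
#' terminates in `cerebellum_R` and traverses `scp_R`.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed used when `subject` is drawn here; `NULL` leaves
#'   the RNG stream untouched.
#' @param subject optional per-subject parameter list from
#'   [sample_subject_params()].
#' @return A list of class `cdvim_phantom` with elements `grid`, `field`
#'   (a [fibre_field()]), `masks`, `landmarks`, `jacobian` and `truth`.
#' @export
build_phantom <- function(config = phantom_config(), seed = NULL,
                          subject = NULL) {
  validate_phantom_config(config)
  if (is.null(subject)) {
    if (!is.null(seed)) set.seed(seed)
    subject <- sample_subject_params(config, 1L)[[1L]]
  }
  grid <- volume_grid(config$dims, voxel_size = config$voxel_size)
  dims <- grid$dims
  nvox <- prod(dims)

  wc <- voxel_to_world(grid, arrayInd(seq_len(nvox), dims) - 1)  # all voxel centres
  box_mask <- function(centre, half) {
    m <- abs(wc[, 1] - centre[1]) <= half[1] &
      abs(wc[, 2] - centre[2]) <= half[2] &
      abs(wc[, 3] - centre[3]) <= half[3]
    array(m, dims)
  }
  ball_mask <- function(centre, r) {
    m <- (wc[, 1] - centre[1])^2 + (wc[, 2] - centre[2])^2 +
      (wc[, 3] - centre[3])^2 <= r^2
    array(m, dims)
  }
  region_mask <- function(xlo = -Inf, xhi = Inf, zlo = -Inf, zhi = Inf) {
    array(wc[, 1] >= xlo & wc[, 1] <= xhi & wc[, 3] >= zlo & wc[, 3] <= zhi,
          dims)
  }

  K <- 2L
  dirs <- array(0, c(dims, 3L, K))
  frac <- array(0, c(dims, K))
  disp <- array(0, c(dims, K))
  npop <- integer(nvox)
  masks <- list()
  truth_sk <- list()

  for (side in c("L", "R")) {
    jit <- subject$jitter[[side]]
    ctrl <- sweep(pathway_controls(config, side), 2, jit, "+")
    width <- subject$scp_width[[side_flip(side)]]  # SCP is contralateral
    sk <- densify_skeleton(config, ctrl, width)
    ras <- rasterize_tube(grid, sk)
    inside <- which(ras$nearest > 0L)
    truth_sk[[side]] <- sk$points

    # fibre population: tangent of the nearest skeleton sample
    slot <- npop[inside] + 1L
    if (any(slot > K)) {
      over <- inside[slot > K]
      slot[slot > K] <- K  # overwrite is impossible with two pathways; guard anyway
      inside <- inside
    }
    tans <- sk$tangents[ras$nearest[inside], , drop = FALSE]
    for (a in 1:3)
      dirs[inside + (a - 1L + (slot - 1L) * 3L) * nvox] <- tans[, a]
    frac[inside + (slot - 1L) * nvox] <- config$fibre_fraction
    disp[inside + (slot - 1L) * nvox] <- config$dispersion_deg
    npop[inside] <- pmin(npop[inside] + 1L, K)

    vim <- mirror_if(config$vim_canonical, side) + jit
    masks[[paste0("m1_", side)]] <-
      ball_mask(mirror_if(config$m1_centre, side) + jit, config$m1_radius)
    masks[[paste0("thalamus_", side)]] <- box_mask(vim, config$thalamus_half)
    masks[[paste0("cerebellum_", side_flip(side))]] <-
      ball_mask(mirror_if(config$cerebellum_centre, side) + jit,
                config$cerebellum_radius)
    scp_vox <- ras$nearest > 0L &
      sk$points[pmax(ras$nearest, 1L), 3] >= config$scp_band_z[1] &
      sk$points[pmax(ras$nearest, 1L), 3] <= config$scp_band_z[2]
    masks[[paste0("scp_", side_flip(side))]] <- array(scp_vox, dims)

    sgn <- if (side == "L") 1 else -1
    masks[[paste0("exclusion_contralateral_cerebrum_", side)]] <-
      region_mask(xlo = if (sgn > 0) 5 else -Inf,
                  xhi = if (sgn > 0) Inf else -5, zlo = 5)
    masks[[paste0("exclusion_ipsilateral_cerebellum_", side)]] <-
      region_mask(xlo = if (sgn > 0) -Inf else 5,
                  xhi = if (sgn > 0) -5 else Inf, zhi = -20)
  }

  csf <- array(abs(wc[, 1]) <= 7 & wc[, 2] >= 6 & wc[, 2] <= 18 &
                 wc[, 3] >= 0 & wc[, 3] <= 12, dims)
  csf[npop > 0L] <- FALSE  # never let the termination mask touch the tract
  masks$csf_termination <- csf

  for (nm in c("thalamus_L", "thalamus_R", "scp_L", "scp_R", "m1_L", "m1_R",
               "cerebellum_L", "cerebellum_R"))
    if (!any(masks[[nm]]))
      stop("phantom geometry error: mask '", nm, "' is empty")

  jac <- array(1, dims)
  jac[masks$scp_L | masks$scp_R] <- config$scp_jacobian_bump

  truth <- list(
    true_vim_centroid = list(
      L = config$vim_canonical + subject$jitter$L,
      R = mirror_if(config$vim_canonical, "R") + subject$jitter$R),
    tract_skeleton = truth_sk,
    scp_width = subject$scp_width,
    jitter_applied = subject$jitter,
    confounds = subject$confounds)

  structure(list(
    grid = grid,
    field = fibre_field(grid, dirs, frac, disp),
    masks = masks,
    landmarks = landmarks(config$ac, config$pc),
    jacobian = jac,
    truth = truth,
    config = config), class = "cdvim_phantom")
}

mirror_if <- function(p, side) { if (side == "R") p[1] <- -p[1]; p }
side_flip <- function(side) if (side == "L") "R" else "L"

#' AC/PC landmark pair
#'
#' @param ac,pc world coordinates (mm) of the anterior and posterior
#'   commissure.
#' @return A list of class `landmarks`.
#' @export
landmarks <- function(ac, pc) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  if (length(ac) != 3L || length(pc) != 3L) stop("landmarks must be 3-D points")
  if (all(ac == pc)) stop("AC and PC landmarks coincide")
  structure(list(ac = ac, pc = pc), class = "landmarks")
}

#' Draw per-subject phantom parameters
#'
#' Samples the subject-level quantities the phantom varies across a cohort:
#' per-hemisphere positional jitter (Gaussian, per-axis SD `jitter_sd`, mean
#' the hemispheric offsets), SCP waist widths, and the five confounds (two
#' movement surrogates, two ROI volumes, total intracranial volume).
#' Confounds are independent of the jitter unless `confound_coupling` is set,
#' in which case the M1 volume is correlated with the left ML jitter.
#'
#' @param config a [phantom_config()].
#' @param n number of subjects.
#' @param seed optional integer seed; `NULL` continues the current RNG stream.
#' @return A list of `n` per-subject parameter lists with elements `jitter`
#'   (`$L`, `$R`), `scp_width` (`$L`, `$R`, voxels) and `confounds`.
#' @export
sample_subject_params <- function(config, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    jit_L <- stats::rnorm(3, config$hemi_offset_left, config$jitter_sd)
    jit_R <- stats::rnorm(3, config$hemi_offset_right, config$jitter_sd)
    widths <- pmax(stats::rnorm(2, config$scp_width_vox, config$scp_width_sd_vox), 1)
    conf <- lapply(config$confound_dists, function(d)
      switch(d$kind,
             lognormal = stats::rlnorm(1, d$meanlog, d$sdlog),
             normal = stats::rnorm(1, d$mean, d$sd)))
    rho <- config$confound_coupling
    if (rho != 0 && config$jitter_sd[1] > 0) {
      # correlate m1_volume with the (standard normal) left ML jitter z-score
      z_jit <- (jit_L[1] - config$hemi_offset_left[1]) / config$jitter_sd[1]
      d <- config$confound_dists$m1_volume
      z <- (conf$m1_volume - d$mean) / d$sd
      conf$m1_volume <- d$mean + d$sd * (rho * z_jit + sqrt(1 - rho^2) * z)
    }
    list(jitter = list(L = jit_L, R = jit_R),
         scp_width = list(L = widths[1], R = widths[2]),
         confounds = conf)
  })
}

#' Sample a phantom cohort
#'
#' Draws `n` subjects from the configured between-subject distributions and
#' builds their phantoms (or, with `truth_only = TRUE`, returns only the
#' per-subject ground truth, which is sufficient for statistical studies that
#' do not run tractography).
#'
#' @inheritParams sample_subject_params
#' @param truth_only if `TRUE`, skip volume generation and return per-subject
#'   truth lists (`true_vim_centroid`, `scp_width`, `jitter_applied`,
#'   `confounds`) only.
#' @return A list of `n` phantoms (or truth lists).
#' @export
sample_cohort <- function(config, n, seed = NULL, truth_only = FALSE) {
  if (n < 2L) stop("a cohort needs at least 2 subjects")
  params <- sample_subject_params(config, n, seed)
  lapply(params, function(s) {
    if (truth_only) {
      list(true_vim_centroid = list(
        L = config$vim_canonical + s$jitter$L,
        R = mirror_if(config$vim_canonical, "R") + s$jitter$R),
        scp_width = s$scp_width, jitter_applied = s$jitter,
        confounds = s$confounds)
    } else build_phantom(config, subject = s)
  })
}

#' Sample paired test-retest phantoms
#'
#' Each pair shares one subject-level centroid (drawn with the between-subject
#' jitter SD) and perturbs each scan's pathway independently with
#' within-subject noise of per-axis SD `retest_sd`. The regime of interest has
#' within-subject noise smaller than between-subject jitter; a configuration
#' violating that is rejected.
#'
#' @inheritParams sample_cohort
#' @return A list of `n` elements, each with `scan1` and `scan2` (phantoms or
#'   truth lists) plus the subject-level `jitter` and recorded scan noises.
#' @export
sample_test_retest_pair <- function(config, n, seed = NULL, truth_only = FALSE) {
  if (n < 2L) stop("a test-retest cohort needs at least 2 subjects")
  if (any(config$retest_sd > config$jitter_sd))
    stop("within-subject (retest) noise SD must not exceed between-subject jitter SD")
  if (!is.null(seed)) set.seed(seed)
  subjects <- sample_subject_params(config, n)
  lapply(subjects, function(s) {
    noises <- list(stats::rnorm(3, 0, config$retest_sd),
                   stats::rnorm(3, 0, config$retest_sd))
    scans <- lapply(noises, function(eps) {
      s2 <- s
      s2$jitter$L <- s$jitter$L + eps
      s2$jitter$R <- s$jitter$R + eps
      if (truth_only) {
        list(true_vim_centroid = list(
          L = config$vim_canonical + s2$jitter$L,
          R = mirror_if(config$vim_canonical, "R") + s2$jitter$R),
          scp_width = s2$scp_width, jitter_applied = s2$jitter,
          confounds = s2$confounds)
      } else build_phantom(config, subject = s2)
    })
    list(scan1 = scans[[1]], scan2 = scans[[2]],
         subject_jitter = s$jitter, scan_noise = noises)
  })
}
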