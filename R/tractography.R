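#' Streamline tracking parameters
#'
#' @param samples_per_voxel streamlines launched per seed voxel. The reference
#'   protocol value is 5000; the package default of 250 gives voxelwise
#'   visitation fractions that agree with 5000-sample maps within binomial
#'   error at a fraction of the cost (the final map is renormalised, so the
#'   global scale cancels).
#' @param curvature_threshold minimum cosine between consecutive step
#'   directions (0.2 permits bends up to about 78.5 degrees).
#' @param step_size propagation step in mm.
#' @param max_steps maximum steps per half-track.
#' @param fibre_fraction_floor populations with volume fraction below this are
#'   ignored during orientation sampling.
#' @return A list of class `tracking_params`.
#' @export
tracking_params <- function(samples_per_voxel = 250,
                            curvature_threshold = 0.2,
                            step_size = 0.5,
                            max_steps = 2000,
                            fibre_fraction_floor = 0.05) {
  stopifnot(samples_per_voxel >= 1, curvature_threshold >= 0,
            curvature_threshold < 1, step_size > 0, max_steps >= 1,
            fibre_fraction_floor >= 0, fibre_fraction_floor <= 1)
  structure(list(samples_per_voxel = as.integer(samples_per_voxel),
                 curvature_threshold = curvature_threshold,
                 step_size = step_size, max_steps = as.integer(max_steps),
                 fibre_fraction_floor = fibre_fraction_floor),
            class = "tracking_params")
}

as_int_mask <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  m
}

#' Draw a fibre orientation at a world position
#'
#' Samples one direction from the fibre populations at the voxel containing
#' `position`. On a first step (`previous_direction = NULL`) the population is
#' chosen proportionally to the volume fractions; otherwise the population
#' (above the fraction floor) best aligned with the previous direction — the
#' one maximising the absolute dot product of mean directions — is used. The
#' mean is perturbed by a Gaussian polar angle with the population's
#' dispersion and sign-aligned with the previous direction.
#'
#' @param field a [fibre_field()].
#' @param position world coordinate (mm) inside the grid.
#' @param previous_direction unit vector of the previous step, or `NULL`.
#' @param fraction_floor minimum usable volume fraction.
#' @return A unit 3-vector, or `NULL` when no population is above the floor
#'   ("no orientation": the streamline terminates there).
#' @export
sample_orientation <- function(field, position, previous_direction = NULL,
                               fraction_floor = 0.05) {
  vox <- containing_voxel(field$grid, position)
  if (any(vox < 0) || any(vox >= field$grid$dims))
    stop("position lies outside the grid")
  out <- .sample_orientation_cpp(field$dirs, field$frac, field$disp,
                                 field$grid$dims, field$K,
                                 as.integer(vox),
                                 previous_direction, fraction_floor)
  if (!length(out)) NULL else out
}

#' Propagate one bidirectional streamline
#'
#' From `seed_point` the tracker samples an initial direction and propagates
#' two half-tracks (along it and its negation), concatenated into one
#' streamline. Each step moves `step_size` mm along a direction drawn at the
#' voxel containing the current point; a step whose cosine with the previous
#' direction falls below the curvature threshold rejects the streamline, as
#' does entering any exclusion mask. Entering the termination mask stops that
#' half-track. The final status is `accepted` only if the full track visited
#' every waypoint mask.
#'
#' @param seed_point world coordinate (mm) of the seed.
#' @param field a [fibre_field()].
#' @param masks list with optional elements `waypoints` (list of logical
#'   arrays), `exclusions` (list of logical arrays, combined with OR) and
#'   `termination` (logical array).
#' @param params a [tracking_params()].
#' @return A list with `points` (n x 3 matrix of world coordinates in
#'   end-to-end order), `status` (`accepted`, `rejected_curvature`,
#'   `rejected_exclusion`, `rejected_waypoint` or `terminated`) and
#'   `stop_reasons` for the two half-tracks.
#' @export
propagate_streamline <- function(seed_point, field, masks = list(),
                                 params = tracking_params()) {
  grid <- field$grid
  way <- lapply(masks$waypoints %||% list(), as_int_mask)
  excl <- combine_exclusions(masks$exclusions)
  term <- if (!is.null(masks$termination)) as_int_mask(masks$termination)
  .propagate_cpp(field$dirs, field$frac, field$disp, grid$dims, field$K,
                 as.numeric(seed_point), way, excl, term,
                 solve(grid$affine), params$curvature_threshold,
                 params$step_size, params$max_steps,
                 params$fibre_fraction_floor)
}

combine_exclusions <- function(exclusions) {
  if (is.null(exclusions) || !length(exclusions)) return(NULL)
  out <- Reduce(`|`, exclusions)
  as_int_mask(out)
}

#' Probabilistic tractography from a seed region
#'
#' Launches `samples_per_voxel` streamlines from the centre of every voxel in
#' `seed_mask` and returns the raw visitation map: each voxel's value is the
#' fraction of all launched streamlines that were accepted (visited every
#' waypoint without rejection) and passed through that voxel, counted once per
#' streamline. This is the probabilistic index of connectivity (PICo) up to
#' the global normalisation applied later by [reconstruct_dtcp()].
#'
#' @param seed_mask logical array on the field's grid.
#' @param waypoints list of logical waypoint masks a streamline must visit.
#' @param exclusions list of logical exclusion masks (entry rejects).
#' @param termination logical termination mask (entry stops a half-track).
#' @param field a [fibre_field()].
#' @param params a [tracking_params()].
#' @return A [pico_map()] with normalisation `"raw"`; attribute `log` holds
#'   per-status streamline counts and the total launched.
#' @export
track_seed_region <- function(seed_mask, waypoints, exclusions = list(),
                              termination = NULL, field,
                              params = tracking_params()) {
  grid <- field$grid
  seeds <- which(seed_mask)
  if (!length(seeds)) stop("seed mask is empty")
  seeds <- arrayInd(seeds, grid$dims) - 1L
  storage.mode(seeds) <- "integer"
  res <- .track_cpp(field$dirs, field$frac, field$disp, grid$dims, field$K,
                    seeds, lapply(waypoints, as_int_mask),
                    combine_exclusions(exclusions),
                    if (!is.null(termination)) as_int_mask(termination),
                    solve(grid$affine), grid$affine,
                    params$samples_per_voxel, params$curvature_threshold,
                    params$step_size, params$max_steps,
                    params$fibre_fraction_floor)
  pico_map(res$map, grid, normalization = "raw",
           log = list(counts = res$counts, total = res$total))
}

#' Probabilistic index of connectivity map
#'
#' @param data numeric array of non-negative values on `grid`.
#' @param grid a [volume_grid()].
#' @param normalization `"raw"` (visitation fractions) or
#'   `"combined-normalized"` (maximum scaled to 1).
#' @param raw_max for combined maps, the maximum of the summed raw maps before
#'   rescaling (the value the combined map was divided by).
#' @param log optional run log.
#' @return A list of class `pico_map`.
#' @export
pico_map <- function(data, grid, normalization = "raw", raw_max = NULL,
                     log = NULL) {
  if (!all(dim(data) == grid$dims)) stop("map dimensions do not match the grid")
  if (any(data < 0)) stop("PICo values must be non-negative")
  structure(list(data = data, grid = grid, normalization = normalization,
                 raw_max = raw_max, log = log), class = "pico_map")
}

#' @export
print.pico_map <- function(x, ...) {
  cat("pico_map (", x$normalization, "): max ", signif(max(x$data), 4),
      ", ", sum(x$data > 0), " nonzero voxels\n", sep = "")
  invisible(x)
}

#' Combine the two seeded runs into the normalised DTCp map
#'
#' The M1-seeded and cerebellum-seeded maps of the same pathway are summed and
#' divided by the maximum of the sum, normalising the range to 0-1. The raw
#' maximum (the divisor) is retained in `$raw_max`; it is the quantity
#' correlated against SCP volume in the bottleneck analysis.
#'
#' @param map_m1_seeded,map_cerebellum_seeded raw [pico_map()]s on the same
#'   grid.
#' @return A combined-normalised [pico_map()]. If both inputs are identically
#'   zero the zero map is passed through with a warning.
#' @export
reconstruct_dtcp <- function(map_m1_seeded, map_cerebellum_seeded) {
  a <- map_m1_seeded; b <- map_cerebellum_seeded
  if (!same_grid(a$grid, b$grid)) stop("PICo maps are on different grids")
  s <- a$data + b$data
  m <- max(s)
  if (m == 0) {
    warning("both input maps are zero; returning a zero DTCp map")
    return(pico_map(s, a$grid, normalization = "combined-normalized",
                    raw_max = 0))
  }
  pico_map(s / m, a$grid, normalization = "combined-normalized", raw_max = m)
}
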