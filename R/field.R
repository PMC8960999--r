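#' Multi-fibre orientation field
#'
#' Container for up to `K` fibre populations per voxel, each with a mean unit
#' direction, a volume fraction and an angular dispersion (SD of the polar
#' angle about the mean, degrees). This is the quantity a ball-and-sticks
#' model fit would supply; here it is produced directly by the phantom.
#'
#' @param grid a [volume_grid()].
#' @param dirs numeric array `c(dims, 3, K)` of mean directions (unit-norm
#'   wherever the corresponding fraction is positive).
#' @param frac numeric array `c(dims, K)` of volume fractions in `[0, 1]`,
#'   summing to at most 1 per voxel.
#' @param disp numeric array `c(dims, K)` of angular dispersions (degrees,
#'   `>= 0`).
#' @return A list of class `fibre_field`.
#' @export
fibre_field <- function(grid, dirs, frac, disp) {
  dims <- grid$dims
  K <- dim(frac)[4]
  stopifnot(all(dim(frac) == c(dims, K)), all(dim(disp) == c(dims, K)),
            all(dim(dirs) == c(dims, 3L, K)))
  if (any(disp < 0)) stop("angular dispersion must be non-negative")
  fs <- apply(frac, 1:3, sum)
  if (max(fs) > 1 + 1e-9) stop("per-voxel fibre fractions must sum to at most 1")
  nvox <- prod(dims)
  for (k in seq_len(K)) {
    pos <- which(frac[(k - 1L) * nvox + seq_len(nvox)] > 0)
    if (length(pos)) {
      d <- cbind(dirs[pos + (0L + (k - 1L) * 3L) * nvox],
                 dirs[pos + (1L + (k - 1L) * 3L) * nvox],
                 dirs[pos + (2L + (k - 1L) * 3L) * nvox])
      n2 <- rowSums(d^2)
      if (any(abs(n2 - 1) > 1e-6))
        stop("mean fibre directions must be unit-norm where fractions are positive")
    }
  }
  structure(list(grid = grid, dirs = dirs, frac = frac, disp = disp, K = K),
            class = "fibre_field")
}

#' @export
print.fibre_field <- function(x, ...) {
  nvox <- sum(apply(x$frac, 1:3, sum) > 0)
  cat("fibre_field:", x$K, "populations,", nvox, "voxels with fibres\n")
  invisible(x)
}
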