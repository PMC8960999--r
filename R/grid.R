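#' Define a voxel grid with a world affine
#'
#' A `volume_grid` couples integer array dimensions with a 4x4 voxel-to-world
#' affine. World axes follow the neuroimaging RAS convention used throughout
#' the package: +x is right (medio-lateral, ML), +y is anterior
#' (anterior-posterior, AP), +z is superior (superior-inferior, SI). The
#' affine maps 0-based voxel indices to the world coordinates (mm) of voxel
#' centres.
#'
#' @param dims integer vector of length 3, array dimensions in voxels.
#' @param affine 4x4 voxel-to-world matrix (mm). If `NULL`, an isotropic
#'   axis-aligned affine with the given `voxel_size` is built, placing the
#'   world origin at the grid centre.
#' @param voxel_size voxel edge lengths in mm (scalar or length 3); ignored
#'   when `affine` is supplied.
#' @return An object of class `volume_grid` with fields `dims`, `affine`
#'   and `voxel_size`.
#' @export
volume_grid <- function(dims, affine = NULL, voxel_size = 1.25) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three positive integers")
  if (is.null(affine)) {
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dims - 1L) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes derived from `affine` must be positive")
  structure(list(dims = dims, affine = affine, voxel_size = vs),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Convert between voxel and world coordinates
#'
#' Voxel coordinates are 0-based and continuous; integer values address voxel
#' centres. `world_to_voxel` applies the inverse affine; `containing_voxel`
#' additionally rounds to the nearest voxel centre (the voxel whose cube
#' contains the point under the centre convention).
#'
#' @param grid a [volume_grid()].
#' @param xyz numeric matrix (n x 3) or length-3 vector of coordinates.
#' @return An n x 3 matrix of transformed coordinates (integer-valued for
#'   `containing_voxel`).
#' @export
voxel_to_world <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  t(grid$affine %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  t(solve(grid$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
containing_voxel <- function(grid, xyz) {
  round(world_to_voxel(grid, xyz))
}

voxel_volume <- function(grid) prod(grid$voxel_size)

same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) <= tol
}

rbind3 <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  storage.mode(xyz) <- "double"
  xyz
}

# world coordinates (n x 3) of every TRUE voxel in a logical array
mask_world_coords <- function(grid, mask) {
  idx <- which(mask)
  if (!length(idx)) return(matrix(numeric(0), ncol = 3L))
  voxel_to_world(grid, arrayInd(idx, grid$dims) - 1)
}
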