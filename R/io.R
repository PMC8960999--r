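`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write NIfTI-1 scalar volumes
#'
#' Thin wrappers around RNifti restricted to the 3-D finite-valued volumes
#' this package uses. `write_volume` stores data as float64 with the grid
#' affine in the sform, so a write-read round trip preserves the data bitwise
#' and the affine to well under 1e-6.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a list with `data` (numeric array) and
#'   `grid` (a [volume_grid()]).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(img)), "-D: ", path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (!all(is.finite(arr)))
    stop("volume contains non-finite voxels: ", path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = arr, grid = volume_grid(dim(arr), affine = aff))
}

#' @rdname read_volume
#' @param volume numeric or logical 3-D array (logicals are written as 0/1).
#' @param grid a [volume_grid()] supplying the affine.
#' @export
write_volume <- function(volume, grid, path) {
  if (length(dim(volume)) != 3L) stop("only 3-D volumes are written")
  if (!all(dim(volume) == grid$dims)) stop("volume does not match the grid")
  arr <- volume * 1.0
  attributes(arr) <- list(dim = dim(volume))
  if (!all(is.finite(arr))) stop("refusing to write non-finite voxels")
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a phantom to disk
#'
#' Writes every mask and the Jacobian field as NIfTI-1 volumes plus a JSON
#' manifest holding landmarks, ground truth, confounds and the seed.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(phantom$masks))
    write_volume(phantom$masks[[nm]], phantom$grid,
                 file.path(dir, paste0(nm, ".nii.gz")))
  write_volume(phantom$jacobian, phantom$grid,
               file.path(dir, "jacobian.nii.gz"))
  manifest <- list(
    landmarks = list(ac = phantom$landmarks$ac, pc = phantom$landmarks$pc),
    truth = phantom$truth[c("true_vim_centroid", "scp_width",
                            "jitter_applied", "confounds")],
    grid = list(dims = phantom$grid$dims,
                affine = as.vector(phantom$grid$affine)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
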