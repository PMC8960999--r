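#' Mid-commissural point
#'
#' @param lm a [landmarks()] object (AC and PC world coordinates, mm).
#' @return The midpoint of AC and PC.
#' @export
mid_commissural_point <- function(lm) {
  if (all(lm$ac == lm$pc)) stop("AC and PC landmarks coincide")
  (lm$ac + lm$pc) / 2
}

#' Atlas-based stereotactic Vim target
#'
#' Computes the surgical atlas coordinate for the Vim from the AC-PC
#' landmarks:
#' anterior-posterior position `(AC-PC length)/3 - 2` mm anterior to PC along
#' the PC-to-AC direction; medio-lateral position `ml_offset` mm off the
#' midline on each side (12 to 14 mm in routine use, 12.5 mm by default); and
#' superior-inferior position 0 relative to the axial AC-PC plane.
#'
#' For landmarks that are not axis-aligned the target is constructed in the
#' AC-PC local frame: the AP axis runs PC to AC, the SI axis is the component
#' of world +z orthogonal to it within the midsagittal plane, and the lateral
#' axis completes the right-handed frame.
#'
#' @param lm a [landmarks()] object.
#' @param ml_offset lateral offset from the midline in mm; values outside
#'   `[12, 14]` are accepted with a warning.
#' @return A list of class `atlas_target` with `left` and `right` world
#'   coordinates, `mcp` and `acpc_length` (mm).
#' @export
atlas_vim_coordinates <- function(lm, ml_offset = 12.5) {
  acpc <- lm$ac - lm$pc
  L <- sqrt(sum(acpc^2))
  if (L <= 6)
    warning("AC-PC length <= 6 mm: the AP formula places the target behind PC")
  if (ml_offset < 12 || ml_offset > 14)
    warning("ml_offset outside the conventional 12-14 mm range")
  yhat <- acpc / L
  zref <- c(0, 0, 1)
  z0 <- zref - sum(zref * yhat) * yhat
  if (sqrt(sum(z0^2)) < 1e-8) {
    # AC-PC runs along world z; fall back to world +y as the SI reference
    zref <- c(0, 1, 0)
    z0 <- zref - sum(zref * yhat) * yhat
  }
  zhat <- z0 / sqrt(sum(z0^2))
  xhat <- c(yhat[2] * zhat[3] - yhat[3] * zhat[2],
            yhat[3] * zhat[1] - yhat[1] * zhat[3],
            yhat[1] * zhat[2] - yhat[2] * zhat[1])
  ap <- lm$pc + (L / 3 - 2) * yhat
  structure(list(left = ap - ml_offset * xhat,
                 right = ap + ml_offset * xhat,
                 mcp = mid_commissural_point(lm),
                 acpc_length = L,
                 ml_offset = ml_offset), class = "atlas_target")
}

#' @export
print.atlas_target <- function(x, ...) {
  cat(sprintf("atlas_target: AC-PC length %.2f mm\n  left  (%.2f, %.2f, %.2f)\n  right (%.2f, %.2f, %.2f)\n",
              x$acpc_length, x$left[1], x$left[2], x$left[3],
              x$right[1], x$right[2], x$right[3]))
  invisible(x)
}
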