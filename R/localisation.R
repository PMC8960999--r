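#' Restrict a DTCp map to the thalamic mask
#'
#' Zeroes every value outside the mask. An all-zero result inside the mask
#' means the pathway reconstruction reached no thalamic voxel for this
#' subject/hemisphere; that is signalled as a classed error
#' (`cdvim_no_connectivity`) so cohort drivers can exclude the subject and
#' continue.
#'
#' @param dtcp a [pico_map()].
#' @param thalamus_mask logical array on the same grid.
#' @return A [pico_map()] restricted to the mask.
#' @export
intersect_dtcp_thalamus <- function(dtcp, thalamus_mask) {
  if (!all(dim(thalamus_mask) == dtcp$grid$dims))
    stop("thalamus mask does not match the map grid")
  out <- dtcp$data * thalamus_mask
  if (max(out) == 0)
    stop(no_connectivity_error("no connectivity inside the thalamic mask"))
  pico_map(out, dtcp$grid, normalization = dtcp$normalization,
           raw_max = dtcp$raw_max)
}

no_connectivity_error <- function(msg, subject = NULL, hemisphere = NULL) {
  if (!is.null(subject))
    msg <- sprintf("%s (subject %s, hemisphere %s)", msg, subject, hemisphere)
  structure(class = c("cdvim_no_connectivity", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Adaptive threshold at a fraction of the maximum
#'
#' Binarises the intersection map by keeping voxels with value at least
#' `fraction` times the maximum value within the intersection (default 20%).
#' The relative cut-point makes the result invariant to any positive rescaling
#' of the map, and the maximal voxel always survives, so the result is never
#' empty.
#'
#' @param intersection a [pico_map()] restricted to the thalamic mask.
#' @param fraction threshold fraction in (0, 1).
#' @return A logical array (the binary ROI).
#' @export
adaptive_threshold <- function(intersection, fraction = 0.2) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  m <- max(intersection$data)
  if (m == 0) stop("intersection map is identically zero")
  intersection$data >= fraction * m
}

# 26-connected component labelling of a logical 3-D array.
# Returns an integer vector of component labels aligned with `which(roi)`.
label_components_26 <- function(roi) {
  dims <- dim(roi)
  idx <- which(roi)
  n <- length(idx)
  if (!n) return(integer(0))
  pos <- integer(prod(dims))
  pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dims)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s]) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      cur <- coords[queue, , drop = FALSE]
      nxt <- integer(0)
      for (r in seq_len(nrow(nb))) {
        cand <- sweep(cur, 2, nb[r, ], "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
          cand[, 2] >= 1 & cand[, 2] <= dims[2] &
          cand[, 3] >= 1 & cand[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- cand[ok, 1] + dims[1] * (cand[ok, 2] - 1L +
                                          dims[2] * (cand[ok, 3] - 1L))
        p <- pos[lin]
        p <- p[p > 0L]
        p <- p[labels[p] == 0L]
        if (length(p)) {
          labels[p] <- comp
          nxt <- c(nxt, p)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels
}

#' Centroid of the largest connected component in world coordinates
#'
#' Restricts the ROI to its largest 26-connected component (ties broken by the
#' higher mean intersection value, when supplied), averages the 0-based voxel
#' coordinates of that component and maps the average through the affine.
#' With `weighted = TRUE` the voxel average is weighted by the intersection
#' values instead.
#'
#' @param roi logical array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param intersection optional [pico_map()] used for tie-breaking and for the
#'   weighted variant.
#' @param weighted use PICo-weighted averaging over the selected component.
#' @return World coordinate (length-3 numeric, mm).
#' @export
centroid_world <- function(roi, affine, intersection = NULL,
                           weighted = FALSE) {
  idx <- which(roi)
  if (!length(idx)) stop("ROI is empty")
  labels <- label_components_26(roi)
  sizes <- tabulate(labels)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L && !is.null(intersection)) {
    means <- vapply(biggest, function(cc)
      mean(intersection$data[idx[labels == cc]]), numeric(1))
    biggest <- biggest[which.max(means)]
  } else {
    biggest <- biggest[1L]
  }
  sel <- idx[labels == biggest]
  vox <- arrayInd(sel, dim(roi)) - 1L
  w <- if (weighted && !is.null(intersection)) intersection$data[sel]
       else rep(1, length(sel))
  centre <- colSums(vox * w) / sum(w)
  as.numeric(affine %*% c(centre, 1))[1:3]
}

#' Localise the connectivity-defined Vim in one hemisphere
#'
#' Composes the three localisation steps: restrict the normalised DTCp map to
#' the thalamic mask, binarise at `fraction` of the intersection maximum, and
#' take the world-space centroid of the largest 26-connected component. The
#' ROI volume is the thresholded foreground voxel count times the voxel
#' volume; the pre-threshold volume (positive intersection voxels) is also
#' reported.
#'
#' @param dtcp combined-normalised [pico_map()].
#' @param thalamus_mask logical array.
#' @param fraction adaptive threshold fraction (default 0.2).
#' @param hemisphere `"left"` or `"right"`, recorded in the result.
#' @param weighted use PICo-weighted centroid averaging.
#' @return A list of class `vim_result`: `roi`, `roi_volume_mm3`,
#'   `roi_volume_prethreshold_mm3`, `centroid` (world mm), `hemisphere`,
#'   `max_pico_in_intersection`.
#' @export
localise_vim <- function(dtcp, thalamus_mask, fraction = 0.2,
                         hemisphere = c("left", "right"), weighted = FALSE) {
  hemisphere <- match.arg(hemisphere)
  inter <- intersect_dtcp_thalamus(dtcp, thalamus_mask)
  roi <- adaptive_threshold(inter, fraction)
  vv <- voxel_volume(dtcp$grid)
  structure(list(
    roi = roi,
    roi_volume_mm3 = sum(roi) * vv,
    roi_volume_prethreshold_mm3 = sum(inter$data > 0) * vv,
    centroid = centroid_world(roi, dtcp$grid$affine, inter,
                              weighted = weighted),
    hemisphere = hemisphere,
    max_pico_in_intersection = max(inter$data)), class = "vim_result")
}

#' @export
print.vim_result <- function(x, ...) {
  cat(sprintf("vim_result [%s]: centroid (ML %.2f, AP %.2f, SI %.2f) mm, volume %.2f mm^3\n",
              x$hemisphere, x$centroid[1], x$centroid[2], x$centroid[3],
              x$roi_volume_mm3))
  invisible(x)
}
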