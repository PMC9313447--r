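#' Mirror a mask or volume about the mid-plane of one axis
#'
#' Index reflection `x -> W + 1 - x` about the mid-plane of `axis`; for the
#' first (left-right) axis of a symmetric brain grid this swaps the
#' hemispheres. The dimension must be even so the plane is unique. The
#' operation is an involution and preserves voxel counts.
#'
#' @param mask 3D array (logical, integer or numeric).
#' @param axis axis to reflect (default 1, the left-right axis).
#' @return array of the same type and dimensions.
#' @export
mirror_mask <- function(mask, axis = 1L) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3) stopf("mask must be a 3D array")
  if (d[axis] %% 2 != 0) {
    stopf("dimension %d along axis %d is odd: no unique symmetry plane", d[axis], axis)
  }
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
}

# one 6-connected dilation step of `mask`, clipped to `within`
.dilate_within <- function(mask, within) {
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      dst <- src
      if (dir == 1L) {
        src[[ax]] <- seq_len(d[ax] - 1L); dst[[ax]] <- 2:d[ax]
      } else {
        src[[ax]] <- 2:d[ax]; dst[[ax]] <- seq_len(d[ax] - 1L)
      }
      shifted <- do.call(`[<-`, c(list(shifted), dst,
                                  list(do.call(`[`, c(list(mask), src, list(drop = FALSE))))))
      out <- out | shifted
    }
  }
  out & within
}

#' Build the 20 bilateral region-of-interest masks of one patient
#'
#' For each of the 10 vascular territories on the abnormal hemisphere, the
#' abnormal ROI is the territory intersected with the lesion (infarct union
#' hypoperfusion); territories the lesion does not reach fall back to their
#' full abnormal-side territory mask, so every patient always contributes
#' 20 non-empty ROIs (the fixed per-patient feature count depends on it).
#' ROIs smaller than `min_voxels` are padded by one 6-connected
#' morphological dilation step inside their territory, because
#' co-occurrence and mesh features degenerate on near-empty masks. The
#' normal-side ROI of each territory is the mirror image of the abnormal
#' ROI about the midsagittal plane.
#'
#' @param atlas a `territory_atlas`.
#' @param infarct,hypoperfusion logical lesion masks on the atlas grid.
#' @param abnormal_side `"left"` or `"right"`: hemisphere holding the
#'   lesion.
#' @param min_voxels minimum ROI size before dilation padding (default 8).
#' @return object of class `roi_set`: named list of 20 logical masks,
#'   ordered `a, m1..m5, p, l, c, i` with the abnormal block before the
#'   normal block; names are `<territory>_<abnormal|normal>`.
#' @export
build_roi_set <- function(atlas, infarct, hypoperfusion, abnormal_side,
                          min_voxels = 8L) {
  abnormal_side <- match.arg(abnormal_side, c("left", "right"))
  d <- dim(atlas$labels)
  stopifnot(identical(dim(infarct), d), identical(dim(hypoperfusion), d))
  side_labels <- atlas$code_map[[abnormal_side]]
  hemi <- array(atlas$labels %in% side_labels, d)
  if (!any(hemi)) stopf("abnormal hemisphere is empty")
  lesion <- infarct | hypoperfusion
  if (any(lesion) && !any(lesion & hemi)) {
    stopf("lesion lies entirely in the declared normal hemisphere (side inconsistency)")
  }

  codes <- territory_codes()
  abn <- vector("list", 10)
  for (k in seq_len(10)) {
    terr <- atlas$labels == side_labels[k]
    roi <- terr & lesion
    if (!any(roi)) roi <- terr  # fallback: full territory ("normal brain area")
    if (sum(roi) < min_voxels) roi <- .dilate_within(roi, terr)
    abn[[k]] <- roi
  }
  nrm <- lapply(abn, mirror_mask, axis = 1L)
  masks <- c(abn, nrm)
  names(masks) <- c(paste0(codes, "_abnormal"), paste0(codes, "_normal"))
  structure(masks, class = "roi_set", abnormal_side = abnormal_side)
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", length(x), "masks, voxel counts",
      paste(range(vapply(x, sum, 0L)), collapse = "-"), "\n")
  invisible(x)
}

#' Serialize an ROI set as one labeled volume plus a name table
#'
#' Codes 1..20 in the canonical ROI order. Overlapping ROIs (possible when
#' territories fall back to their full masks while others use lesion
#' intersections) are resolved by later-ROI-wins, which only matters for
#' visualisation; analysis always uses the individual masks.
#'
#' @param roi_set an `roi_set`.
#' @return list with `labels` (integer array) and `names` (data.frame
#'   code/name).
#' @export
roi_set_labels <- function(roi_set) {
  d <- dim(roi_set[[1]])
  lab <- array(0L, d)
  for (k in seq_along(roi_set)) lab[roi_set[[k]]] <- k
  list(labels = lab,
       names = data.frame(code = seq_along(roi_set), name = names(roi_set),
                          stringsAsFactors = FALSE))
}
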