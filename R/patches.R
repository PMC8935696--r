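# Overlapping-patch extraction and overlap-averaged reassembly for the
# patch-based segmentation network.

patch_starts_1d <- function(lo, hi, patch, stride) {
  len <- hi - lo + 1L
  if (patch > len) stop("extract_patches: patch larger than the region")
  s <- seq(lo, hi - patch + 1L, by = stride)
  if (s[length(s)] + patch - 1L < hi) s <- c(s, hi - patch + 1L)
  unique(s)
}

#' Extract overlapping patches tiling a region of interest
#'
#' Patches tile the bounding box of `roi_mask` (whole volume when NULL);
#' the final start along each axis is clamped so the box is fully covered.
#' The returned placement index is sufficient to reassemble per-voxel
#' predictions by averaging overlaps.
#'
#' @param volume a [volume_image] or 3D array.
#' @param roi_mask logical array or NULL.
#' @param patch_size scalar or length-3 patch edge, voxels.
#' @param stride scalar or length-3 stride, voxels (must be <= patch_size).
#' @return list of class `patch_set`: `patches` (list of 3D arrays),
#'   `starts` (n x 3 matrix of 1-based corners), `patch_size`, `dim`.
#' @export
extract_patches <- function(volume, roi_mask = NULL, patch_size, stride) {
  arr <- if (inherits(volume, "volume_image")) volume$data else as.array(volume)
  patch_size <- rep(as.integer(patch_size), length.out = 3L)
  stride <- rep(as.integer(stride), length.out = 3L)
  if (any(stride > patch_size))
    stop("extract_patches: stride must not exceed patch_size")
  if (any(patch_size > dim(arr)))
    stop("extract_patches: patch larger than the volume")
  if (is.null(roi_mask)) {
    lo <- c(1L, 1L, 1L); hi <- dim(arr)
  } else {
    if (!any(roi_mask)) stop("extract_patches: empty ROI")
    w <- which(roi_mask, arr.ind = TRUE)
    lo <- apply(w, 2, min); hi <- apply(w, 2, max)
    # widen the box if narrower than one patch
    for (a in 1:3) {
      short <- patch_size[a] - (hi[a] - lo[a] + 1L)
      if (short > 0L) {
        lo[a] <- max(1L, lo[a] - ceiling(short / 2))
        hi[a] <- min(dim(arr)[a], lo[a] + patch_size[a] - 1L)
        lo[a] <- hi[a] - patch_size[a] + 1L
      }
    }
  }
  sx <- patch_starts_1d(lo[1], hi[1], patch_size[1], stride[1])
  sy <- patch_starts_1d(lo[2], hi[2], patch_size[2], stride[2])
  sz <- patch_starts_1d(lo[3], hi[3], patch_size[3], stride[3])
  starts <- as.matrix(expand.grid(x = sx, y = sy, z = sz))
  patches <- lapply(seq_len(nrow(starts)), function(i) {
    s <- starts[i, ]
    arr[s[1]:(s[1] + patch_size[1] - 1L),
        s[2]:(s[2] + patch_size[2] - 1L),
        s[3]:(s[3] + patch_size[3] - 1L), drop = FALSE]
  })
  structure(list(patches = patches, starts = starts,
                 patch_size = patch_size, dim = dim(arr)),
            class = "patch_set")
}

#' Reassemble per-patch values by averaging overlaps
#'
#' @param values list of 3D arrays, one per patch (same order as
#'   `patch_set$patches`).
#' @param patch_set the placement index from [extract_patches].
#' @return 3D array on the original grid; voxels covered by no patch are NA.
#' @export
reassemble_patches <- function(values, patch_set) {
  acc <- array(0, patch_set$dim)
  cnt <- array(0, patch_set$dim)
  ps <- patch_set$patch_size
  for (i in seq_along(values)) {
    s <- patch_set$starts[i, ]
    ix <- s[1]:(s[1] + ps[1] - 1L)
    iy <- s[2]:(s[2] + ps[2] - 1L)
    iz <- s[3]:(s[3] + ps[3] - 1L)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + values[[i]]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}
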