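# Intracranial and tissue volumetry from T1-like volumes: brain-mask
# extraction (threshold + morphological closing + largest component) and
# 3-class EM intensity classification. No spatial (Markov-random-field)
# prior is used: plain EM suffices on phantom-grade contrast.

shift_array <- function(arr, d, axis) {
  n <- dim(arr)
  idx <- lapply(n, seq_len)
  src <- idx
  src[[axis]] <- pmin(pmax(idx[[axis]] - d, 1L), n[axis])
  do.call(`[`, c(list(arr), src))
}

# 6-neighbourhood binary dilation/erosion by `iter` voxels.
binary_dilate <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    out <- mask
    for (a in 1:3) out <- out | shift_array(mask, 1L, a) | shift_array(mask, -1L, a)
    mask <- out
  }
  mask
}

binary_erode <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    out <- mask
    for (a in 1:3) out <- out & shift_array(mask, 1L, a) & shift_array(mask, -1L, a)
    mask <- out
  }
  mask
}

#' @rdname binary_dilate
#' @keywords internal
binary_close <- function(mask, iter = 1L) binary_erode(binary_dilate(mask, iter), iter)

#' Estimate the intracranial volume from a T1-like volume
#'
#' Foreground threshold (Otsu over the intensity histogram by default),
#' morphological closing, largest connected component. The reported volume
#' is voxel count x voxel volume.
#'
#' @param t1 a [volume_image].
#' @param threshold optional raw-intensity threshold overriding Otsu.
#' @param closing_iter closing radius in voxels.
#' @return list of class `icv_estimate`: `mask` (logical array), `icv_cm3`.
#' @export
estimate_icv <- function(t1, threshold = NULL, closing_iter = 2L) {
  stopifnot(inherits(t1, "volume_image"))
  img <- t1$data
  if (max(img) <= min(img))
    stop("estimate_icv: empty brain mask (constant image)")
  if (is.null(threshold)) {
    # Otsu splits the dominant tissue modes; half of it reliably separates
    # air from the darkest tissue class (standard brain-extraction heuristic)
    rng <- range(img)
    norm <- (img - rng[1]) / diff(rng)
    ot <- rng[1] + diff(rng) * EBImage::otsu(matrix(norm, nrow = dim(img)[1]),
                                             range = c(0, 1))
    threshold <- 0.5 * ot
  }
  fg <- img > threshold
  if (!any(fg)) stop("estimate_icv: empty brain mask (no voxel above threshold)")
  fg <- binary_close(fg, closing_iter)
  lab <- .label_components(fg, dim(fg))
  keep <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == keep
  structure(list(mask = mask,
                 icv_cm3 = sum(mask) * voxel_volume_mm3(t1) / 1000),
            class = "icv_estimate")
}

#' Segment CSF, gray matter and white matter within a brain mask
#'
#' Fits a 3-component univariate Gaussian mixture to the in-mask intensities
#' by EM and assigns every in-mask voxel its MAP component, so class volumes
#' sum exactly to the mask volume. Components are ordered by mean and mapped
#' CSF < GM < WM for T1-like contrast (CSF darkest); the mapping is inverted
#' for T2-like inputs. An empty class after MAP assignment is flagged with a
#' warning (attribute `empty_classes`).
#'
#' @param t1 a [volume_image] (`modality` `"T1"` or `"T2"`).
#' @param brain_mask logical array (e.g. from [estimate_icv]).
#' @param ... passed to [fit_gmm].
#' @return list of class `tissue_segmentation`: `labels` ([label_map] with
#'   csf = 1, gm = 2, wm = 3), `volumes` (list `icv_cm3, csf_cm3, gm_cm3,
#'   wm_cm3`), `fit` (the `gmm_fit`).
#' @export
segment_tissues <- function(t1, brain_mask, ...) {
  stopifnot(inherits(t1, "volume_image"))
  if (!any(brain_mask)) stop("segment_tissues: empty brain mask")
  x <- t1$data[brain_mask]
  fit <- fit_gmm(x, k = 3L, ...)
  post <- gmm_posterior(fit, x)
  comp <- max.col(post, ties.method = "first")  # mean-ascending components
  t1_like <- !identical(t1$modality, "T2")
  class_of <- if (t1_like) c(1L, 2L, 3L) else c(3L, 2L, 1L)  # csf, gm, wm codes
  lab <- array(0L, dim(t1$data))
  lab[brain_mask] <- class_of[comp]
  vv <- voxel_volume_mm3(t1) / 1000
  vols <- list(icv_cm3 = sum(brain_mask) * vv,
               csf_cm3 = sum(lab == 1L) * vv,
               gm_cm3 = sum(lab == 2L) * vv,
               wm_cm3 = sum(lab == 3L) * vv)
  res <- structure(list(labels = label_map(lab, t1$voxel_size_mm,
                                           c(background = 0L, csf = 1L,
                                             gm = 2L, wm = 3L)),
                        volumes = vols, fit = fit),
                   class = "tissue_segmentation")
  empty <- which(tabulate(class_of[comp], 3L) == 0L)
  if (length(empty)) {
    warning("segment_tissues: empty class(es) after MAP assignment: ",
            paste(c("csf", "gm", "wm")[empty], collapse = ", "))
    attr(res, "empty_classes") <- empty
  }
  res
}
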