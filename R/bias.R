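# Multiplicative bias-field correction: iteratively alternates a hard
# intensity classification with a low-order polynomial fit to the
# log-residual, in the spirit of N4-style correctors but restricted to the
# smooth polynomial family the phantom generator itself uses.

poly_basis3 <- function(gx, gy, gz, order = 2) {
  B <- cbind(1, gx, gy, gz)
  if (order >= 2)
    B <- cbind(B, gx * gy, gx * gz, gy * gz, gx^2, gy^2, gz^2)
  B
}

#' Correct smooth multiplicative intensity inhomogeneity
#'
#' Estimates a smooth multiplicative field by iterating (i) a k-class hard
#' classification of the current corrected intensities (quantile-seeded
#' k-means, deterministic) and (ii) a least-squares fit of a low-order 3D
#' polynomial to the log-intensity residual about the class centres. The
#' field is normalised to unit mean inside the mask and divided out; the
#' in-mask output mean equals the input mean.
#'
#' @param volume a positive-valued [volume_image].
#' @param mask logical array of head voxels (default: voxels above 5% of the
#'   99.9th intensity percentile).
#' @param order polynomial order (1 or 2; default 2).
#' @param n_classes intensity classes used for the piecewise-constant tissue
#'   model (default 6).
#' @param max_iter,tol iteration cap and relative field-update tolerance.
#' @return corrected `volume_image`; the estimated field is attached as
#'   attribute `bias_field`.
#' @export
correct_bias <- function(volume, mask = NULL, order = 2, n_classes = 6,
                         max_iter = 10, tol = 1e-3) {
  stopifnot(inherits(volume, "volume_image"))
  img <- volume$data
  if (is.null(mask)) {
    ref <- quantile(img, 0.999, names = FALSE)
    mask <- img > 0.05 * ref
  }
  if (!any(mask)) stop("correct_bias: empty head mask")
  if (any(img[mask] <= 0))
    stop("correct_bias: non-positive voxels inside the head mask")
  x <- img[mask]
  if (sd(x) < .Machine$double.eps^0.5 * mean(x)) return(volume)  # constant image

  n <- dim(img)
  gx <- array(seq(-1, 1, length.out = n[1]), n)
  gy <- array(rep(seq(-1, 1, length.out = n[2]), each = n[1]), n)
  gz <- array(rep(seq(-1, 1, length.out = n[3]), each = n[1] * n[2]), n)
  Bm <- poly_basis3(gx[mask], gy[mask], gz[mask], order)
  # estimate the field on bright voxels only: additive noise on dark tissue
  # is large and skewed on the log scale and would bend the fit
  fit_sel <- x > 0.25 * quantile(x, 0.999, names = FALSE)
  if (sum(fit_sel) < 10 * ncol(Bm)) fit_sel <- rep(TRUE, length(x))
  logI <- log(x)
  field_log <- rep(0, length(x))
  for (it in seq_len(max_iter)) {
    corr <- logI - field_log
    ux <- unique(corr)
    ctr <- if (length(ux) <= n_classes) sort(ux)
           else unique(quantile(corr, probs = (seq_len(n_classes) - 0.5) /
                                  n_classes, names = FALSE))
    km <- suppressWarnings(kmeans(corr, centers = matrix(ctr),
                                  iter.max = 50))
    resid <- corr - km$centers[km$cluster]
    beta <- qr.coef(qr(Bm[fit_sel, , drop = FALSE]), resid[fit_sel])
    upd <- drop(Bm %*% beta)
    field_log <- field_log + upd
    if (max(abs(upd)) < tol) break
  }
  field_log <- field_log - mean(field_log)        # unit-geometric-mean field
  field_mask <- exp(field_log)
  out <- img
  out[mask] <- x / field_mask
  out[mask] <- out[mask] * (mean(x) / mean(out[mask]))  # preserve mean
  full_field <- array(1, n)
  full_field[mask] <- field_mask
  res <- volume_image(out, volume$voxel_size_mm, volume$modality)
  attr(res, "bias_field") <- full_field
  res
}
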