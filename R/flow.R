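# Quantification of CSF flow through the aqueduct of Sylvius from gated
# phase-contrast data: aqueduct masking on the time-averaged magnitude,
# phase-to-velocity conversion, directionality-informed aliasing correction,
# the cardiac-cycle flow profile and its five summary metrics.

#' Gated phase-contrast series
#'
#' Per-cardiac-bin magnitude and phase images plus the velocity-encoding
#' parameter. Phase values are radians in (-pi, pi]; velocities beyond
#' +/- venc alias (wrap) across that interval.
#'
#' @param magnitude numeric array (nx, ny, n_bins), arbitrary units, >= 0.
#' @param phase numeric array (nx, ny, n_bins), radians in (-pi, pi].
#' @param venc_cm_s velocity-encoding parameter, cm/s.
#' @param voxel_size_mm in-plane spacing, mm (length 2).
#' @param bin_times_s centre time of each cardiac bin, strictly increasing.
#' @param validate enforce the phase-range invariant (disable only for
#'   diagnostic unwrapped series).
#' @return object of class `phase_contrast_series`.
#' @export
phase_contrast_series <- function(magnitude, phase, venc_cm_s,
                                  voxel_size_mm, bin_times_s,
                                  validate = TRUE) {
  magnitude <- as.array(magnitude); phase <- as.array(phase)
  if (!identical(dim(magnitude), dim(phase)))
    stop("phase_contrast_series: magnitude and phase dimensions differ")
  if (length(dim(phase)) != 3L)
    stop("phase_contrast_series: arrays must be (nx, ny, n_bins)")
  nb <- dim(phase)[3]
  if (nb < 2L) stop("phase_contrast_series: need at least 2 cardiac bins")
  if (length(bin_times_s) != nb || any(diff(bin_times_s) <= 0))
    stop("phase_contrast_series: bin_times_s must be strictly increasing, one per bin")
  if (venc_cm_s <= 0) stop("phase_contrast_series: venc must be positive")
  if (any(magnitude < 0)) stop("phase_contrast_series: magnitude must be >= 0")
  if (validate && (any(phase <= -pi - 1e-12) || any(phase > pi + 1e-12)))
    stop("phase_contrast_series: phase values must lie in (-pi, pi]")
  structure(list(magnitude = magnitude, phase = phase,
                 venc_cm_s = venc_cm_s,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 bin_times_s = as.numeric(bin_times_s), n_bins = nb),
            class = "phase_contrast_series")
}

#' Segment the aqueduct on the time-averaged magnitude
#'
#' Thresholds the time-averaged magnitude image (Otsu by default) and keeps
#' the connected component whose centroid is nearest the image centre.
#'
#' @param series a [phase_contrast_series].
#' @param threshold optional numeric override of the Otsu threshold, on the
#'   raw magnitude scale.
#' @return list of class `aqueduct_mask`: `mask` (logical nx x ny) and
#'   `area_cm2`.
#' @export
segment_aqueduct <- function(series, threshold = NULL) {
  stopifnot(inherits(series, "phase_contrast_series"))
  avg <- apply(series$magnitude, c(1, 2), mean)
  rng <- range(avg)
  if (diff(rng) <= 0)
    stop("segment_aqueduct: aqueduct not found (constant magnitude image)")
  if (is.null(threshold)) {
    norm <- (avg - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) * EBImage::otsu(norm, range = c(0, 1))
  }
  fg <- avg > threshold
  if (!any(fg)) stop("segment_aqueduct: aqueduct not found (no voxel above threshold)")
  lab <- .label_components(fg, dim(fg))
  ncomp <- max(lab)
  ctr <- (dim(fg) + 1) / 2
  best <- 1L; bestd <- Inf
  for (cc in seq_len(ncomp)) {
    w <- which(lab == cc, arr.ind = TRUE)
    d <- sum((colMeans(w) - ctr)^2)
    if (d < bestd) { bestd <- d; best <- cc }
  }
  mask <- lab == best
  area <- sum(mask) * prod(series$voxel_size_mm) / 100
  structure(list(mask = mask, area_cm2 = area), class = "aqueduct_mask")
}

#' Convert phase to velocity
#'
#' The standard phase-contrast relation v = venc * phi / pi, elementwise.
#'
#' @param series a [phase_contrast_series].
#' @return numeric array of velocities, cm/s, same shape as the phase data.
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "phase_contrast_series"))
  ph <- series$phase
  if (any(ph <= -pi - 1e-12) || any(ph > pi + 1e-12))
    stop("phase_to_velocity: phase values outside (-pi, pi]")
  series$venc_cm_s * ph / pi
}

#' Directionality-informed aliasing correction
#'
#' During systole aqueductal flow is known to be anterograde; a strongly
#' negative mean velocity inside the systolic window is therefore a wrapped
#' super-venc velocity. Within `systolic_bins`, any velocity below
#' -(venc - margin) is replaced by v + 2*venc (single-wrap assumption); all
#' other values pass through. The operation is idempotent. If a corrected
#' value still falls below the anterograde prior bound the result carries a
#' `suspect_double_wrap` attribute.
#'
#' @param velocity per-bin mean velocities, cm/s.
#' @param venc_cm_s velocity-encoding parameter, cm/s.
#' @param systolic_bins integer indices of bins known to be systolic.
#' @param margin_cm_s guard band below venc, cm/s (default 2).
#' @return corrected velocity vector (attribute `suspect_double_wrap` flags
#'   bins that remain implausible).
#' @export
correct_aliasing <- function(velocity, venc_cm_s, systolic_bins,
                             margin_cm_s = 2) {
  v <- as.numeric(velocity)
  cut <- -(venc_cm_s - margin_cm_s)
  hit <- rep(FALSE, length(v))
  hit[systolic_bins] <- v[systolic_bins] < cut
  v[hit] <- v[hit] + 2 * venc_cm_s
  still <- rep(FALSE, length(v))
  still[systolic_bins] <- v[systolic_bins] < cut
  if (any(still)) {
    warning("correct_aliasing: bins ", paste(which(still), collapse = ", "),
            " remain below the anterograde bound after single-wrap ",
            "correction (possible double wrap)")
    attr(v, "suspect_double_wrap") <- which(still)
  }
  v
}

#' Default systolic window for aliasing correction
#'
#' The bin of largest absolute mean velocity and its two cyclic neighbours:
#' with aliasing present the wrapped systolic peak itself is the largest
#' |v| bin.
#' @param velocity per-bin mean velocities.
#' @return integer bin indices.
#' @export
default_systolic_bins <- function(velocity) {
  n <- length(velocity)
  j <- which.max(abs(velocity))
  sort(unique(((c(j - 1L, j, j + 1L) - 1L) %% n) + 1L))
}

#' Per-bin volumetric flow profile
#'
#' @param flow_mL_s signed volumetric flow per cardiac bin, mL/s
#'   (anterograde positive).
#' @param bin_times_s bin centre times, s.
#' @param cycle_duration_s cardiac period; defaults to `n * mean(diff(times))`
#'   (uniform bins).
#' @return object of class `flow_profile`.
#' @export
flow_profile <- function(flow_mL_s, bin_times_s, cycle_duration_s = NULL) {
  if (length(flow_mL_s) != length(bin_times_s))
    stop("flow_profile: flow and bin_times lengths differ")
  if (any(!is.finite(flow_mL_s))) stop("flow_profile: non-finite flow values")
  if (is.null(cycle_duration_s))
    cycle_duration_s <- length(flow_mL_s) * mean(diff(bin_times_s))
  structure(list(flow_mL_s = as.numeric(flow_mL_s),
                 bin_times_s = as.numeric(bin_times_s),
                 cycle_duration_s = cycle_duration_s,
                 n_bins = length(flow_mL_s)),
            class = "flow_profile")
}

#' Compute the cardiac-cycle flow profile through the aqueduct
#'
#' Per bin: Q = mean in-mask velocity (cm/s) x mask area (cm^2), giving
#' mL/s (1 cm^3 = 1 mL). With `correct = TRUE` the directionality-informed
#' aliasing correction is applied to the per-bin mean velocities first.
#'
#' @param series a [phase_contrast_series].
#' @param mask an [aqueduct_mask] (default: segmented from the series).
#' @param correct apply aliasing correction.
#' @param systolic_bins systolic window (default [default_systolic_bins]).
#' @param margin_cm_s aliasing guard band, cm/s.
#' @param flow_sign +1 if positive phase encodes anterograde (cranial-to-
#'   caudal) flow, -1 to flip the scanner convention.
#' @return a [flow_profile].
#' @export
compute_flow_profile <- function(series, mask = segment_aqueduct(series),
                                 correct = TRUE, systolic_bins = NULL,
                                 margin_cm_s = 2, flow_sign = 1) {
  stopifnot(inherits(series, "phase_contrast_series"),
            inherits(mask, "aqueduct_mask"))
  if (!any(mask$mask)) stop("compute_flow_profile: empty aqueduct mask")
  vel <- phase_to_velocity(series) * flow_sign
  vbar <- vapply(seq_len(series$n_bins),
                 function(b) mean(vel[, , b][mask$mask]), numeric(1))
  if (correct) {
    if (is.null(systolic_bins)) systolic_bins <- default_systolic_bins(vbar)
    vbar <- correct_aliasing(vbar, series$venc_cm_s, systolic_bins,
                             margin_cm_s)
  }
  flow_profile(as.numeric(vbar) * mask$area_cm2, series$bin_times_s)
}

#' Five summary metrics of an aqueductal flow profile
#'
#' Rectangle-rule integration over the cardiac bins: anterograde volume
#' sum(max(Q,0)) dt, retrograde volume sum(max(-Q,0)) dt. Net flow is their
#' difference, absolute flow their sum, and the regurgitant fraction the
#' retrograde-to-anterograde ratio (per-cycle volumes by default; peak-flow
#' ratio via `rf_mode = "peak"`).
#'
#' @param profile a [flow_profile].
#' @param rf_mode `"volume"` (default) or `"peak"` regurgitant-fraction
#'   convention.
#' @return list of class `flow_metrics` with `max_anterograde_mL_s`,
#'   `max_retrograde_mL_s` (signed, <= 0 expected), `net_flow_mL`,
#'   `absolute_flow_mL`, `regurgitant_fraction` (NA with a
#'   `rf_reason` attribute when anterograde volume is zero).
#' @export
compute_flow_metrics <- function(profile, rf_mode = c("volume", "peak")) {
  stopifnot(inherits(profile, "flow_profile"))
  rf_mode <- match.arg(rf_mode)
  q <- profile$flow_mL_s
  dt <- profile$cycle_duration_s / profile$n_bins
  vol_a <- sum(pmax(q, 0)) * dt
  vol_r <- sum(pmax(-q, 0)) * dt
  if (rf_mode == "volume") {
    rf <- if (vol_a > 0) vol_r / vol_a else NA_real_
  } else {
    rf <- if (max(q) > 0) -min(pmin(q, 0)) / max(q) else NA_real_
  }
  m <- structure(list(max_anterograde_mL_s = max(q),
                      max_retrograde_mL_s = min(q),
                      net_flow_mL = vol_a - vol_r,
                      absolute_flow_mL = vol_a + vol_r,
                      regurgitant_fraction = rf,
                      anterograde_volume_mL = vol_a,
                      retrograde_volume_mL = vol_r),
                 class = "flow_metrics")
  if (is.na(rf)) attr(m, "rf_reason") <- "anterograde volume is zero"
  m
}

#' @export
print.flow_metrics <- function(x, ...) {
  cat(sprintf(paste0("<flow_metrics> max antero %.4f mL/s, max retro %.4f mL/s,\n",
                     "  net %.4f mL, absolute %.4f mL, regurgitant fraction %s\n"),
              x$max_anterograde_mL_s, x$max_retrograde_mL_s,
              x$net_flow_mL, x$absolute_flow_mL,
              ifelse(is.na(x$regurgitant_fraction), "NA",
                     sprintf("%.3f", x$regurgitant_fraction))))
  invisible(x)
}
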