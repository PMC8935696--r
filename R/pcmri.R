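# Synthetic ECG-gated phase-contrast acquisition through the cerebral
# aqueduct: a biphasic CSF waveform (anterograde systolic lobe, retrograde
# diastolic lobe), retrospectively binned over a multi-minute acquisition,
# encoded as phase with a configurable venc and optional aliasing.

#' Parameters of the synthetic CSF flow waveform and gated acquisition
#'
#' The waveform is biphasic: a positive (anterograde, cranial-to-caudal)
#' half-sine lobe occupying `systolic_fraction` of the cardiac cycle,
#' followed by a negative (retrograde) half-sine lobe over the remainder.
#' Peak values are volumetric flows in mL/s; the voxel velocity is flow
#' divided by the aqueduct cross-sectional area.
#'
#' @param peak_anterograde_mLs peak systolic flow, mL/s (positive).
#' @param peak_retrograde_mLs peak diastolic flow magnitude, mL/s (positive).
#' @param systolic_fraction fraction of the cycle occupied by the anterograde
#'   lobe, in (0, 1).
#' @param aqueduct_area_cm2 nominal aqueduct cross-sectional area, cm^2 (the
#'   generator voxelises this to a whole number of in-plane voxels and uses
#'   the voxelised area as truth).
#' @param cycle_duration_s cardiac period, s.
#' @param n_bins cardiac phase bins (default 12).
#' @param noise_sd_cm_s per-readout velocity noise SD, cm/s.
#' @param scan_duration_s total gated acquisition time, s (default 300, i.e.
#'   five minutes).
#' @param tr_s repetition time between readouts, s.
#' @param rr_jitter_frac fractional SD of beat-to-beat cycle length.
#' @param seed integer seed.
#' @return list of class `waveform_params`.
#' @export
waveform_params <- function(peak_anterograde_mLs = 0.10,
                            peak_retrograde_mLs = 0.12,
                            systolic_fraction = 0.6,
                            aqueduct_area_cm2 = 0.03,
                            cycle_duration_s = 1.0,
                            n_bins = 12L,
                            noise_sd_cm_s = 0.15,
                            scan_duration_s = 300,
                            tr_s = 0.05,
                            rr_jitter_frac = 0.03,
                            seed = 1L) {
  p <- list(peak_anterograde_mLs = peak_anterograde_mLs,
            peak_retrograde_mLs = peak_retrograde_mLs,
            systolic_fraction = systolic_fraction,
            aqueduct_area_cm2 = aqueduct_area_cm2,
            cycle_duration_s = cycle_duration_s,
            n_bins = as.integer(n_bins),
            noise_sd_cm_s = noise_sd_cm_s,
            scan_duration_s = scan_duration_s,
            tr_s = tr_s, rr_jitter_frac = rr_jitter_frac,
            seed = as.integer(seed))
  if (p$peak_anterograde_mLs < 0 || p$peak_retrograde_mLs < 0)
    stop("waveform_params: peak flows must be non-negative")
  if (p$systolic_fraction <= 0 || p$systolic_fraction >= 1)
    stop("waveform_params: systolic_fraction must lie in (0, 1)")
  if (p$n_bins < 2L) stop("waveform_params: n_bins must be >= 2")
  if (p$aqueduct_area_cm2 <= 0) stop("waveform_params: area must be positive")
  class(p) <- "waveform_params"
  p
}

#' Evaluate the noise-free flow waveform
#' @param params a [waveform_params].
#' @param t_s times within the cardiac cycle, s (vector).
#' @return volumetric flow, mL/s (anterograde positive).
#' @export
csf_flow_waveform <- function(params, t_s) {
  Tt <- params$cycle_duration_s
  fs <- params$systolic_fraction
  ph <- (t_s %% Tt) / Tt
  ifelse(ph < fs,
         params$peak_anterograde_mLs * sin(pi * ph / fs),
         -params$peak_retrograde_mLs * sin(pi * (ph - fs) / (1 - fs)))
}

# Wrap phases into (-pi, pi].
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Generate a gated phase-contrast series with ground-truth flow metrics
#'
#' Simulates readouts every `tr_s` seconds over the full acquisition,
#' assigns each to a cardiac bin by its phase within the (jittered) beat,
#' encodes voxel velocities as phase phi = pi * v / venc (wrapped into
#' (-pi, pi] per readout when `apply_wrapping`), and averages readouts within
#' each bin — retrospective gating. Truth metrics are computed from the
#' noise-free waveform sampled at the bin centres, through the same
#' rectangle-rule integration the quantification stage uses.
#'
#' @param params a [waveform_params].
#' @param venc_cm_s velocity-encoding parameter, cm/s (default 12).
#' @param apply_wrapping logical; wrap each readout's phase into (-pi, pi].
#' @param grid_shape in-plane voxels (length 2).
#' @param voxel_size_mm in-plane spacing, mm (length 2).
#' @return list with `series` (a [phase_contrast_series]) and `truth`
#'   (noise-free profile, metrics, aqueduct mask and area).
#' @export
generate_phase_contrast <- function(params, venc_cm_s = 12,
                                    apply_wrapping = TRUE,
                                    grid_shape = c(24L, 24L),
                                    voxel_size_mm = c(0.6, 0.6)) {
  stopifnot(inherits(params, "waveform_params"))
  if (venc_cm_s <= 0) stop("generate_phase_contrast: venc must be positive")
  vox_area_cm2 <- prod(voxel_size_mm) / 100
  n_vox <- max(1L, round(params$aqueduct_area_cm2 / vox_area_cm2))
  area_cm2 <- n_vox * vox_area_cm2
  peak_v <- max(params$peak_anterograde_mLs, params$peak_retrograde_mLs) / area_cm2
  if (apply_wrapping && peak_v >= 2 * venc_cm_s)
    stop("generate_phase_contrast: peak velocity ", signif(peak_v, 4),
         " cm/s >= 2*venc — double wrapping is unrecoverable")

  withr::with_seed(params$seed, {
    nx <- grid_shape[1]; ny <- grid_shape[2]
    # aqueduct disc: the n_vox voxels closest to the in-plane centre
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`)
    disc <- array(FALSE, c(nx, ny))
    disc[order(d2)[seq_len(n_vox)]] <- TRUE

    nb <- params$n_bins
    Tt <- params$cycle_duration_s
    # beat onsets with RR jitter covering the whole acquisition
    n_beats <- ceiling(params$scan_duration_s / Tt) + 2L
    rr <- Tt * pmax(0.5, 1 + params$rr_jitter_frac * rnorm(n_beats))
    onsets <- cumsum(c(0, rr))
    t_read <- seq(0, params$scan_duration_s, by = params$tr_s)
    beat <- findInterval(t_read, onsets)
    phase_in_cycle <- (t_read - onsets[beat]) / rr[beat]
    phase_in_cycle <- pmin(phase_in_cycle, 1 - 1e-9)
    bin_of <- pmin(nb, 1L + floor(phase_in_cycle * nb))

    v_true <- csf_flow_waveform(params, phase_in_cycle * Tt) / area_cm2
    phase <- array(0, c(nx, ny, nb))
    counts <- tabulate(bin_of, nb)
    for (b in seq_len(nb)) {
      sel <- bin_of == b
      m <- sum(sel)
      if (m == 0L) stop("generate_phase_contrast: empty cardiac bin ", b)
      # in-disc voxels: per-readout noise, wrapped per readout, then averaged
      v_samp <- matrix(v_true[sel], nrow = m, ncol = n_vox)
      if (params$noise_sd_cm_s > 0)
        v_samp <- v_samp + rnorm(length(v_samp), 0, params$noise_sd_cm_s)
      ph_samp <- pi * v_samp / venc_cm_s
      # gated averaging acts on complex phasors, so the stored per-bin phase
      # is wrapped into (-pi, pi]; averaging before wrapping is equivalent
      # to the circular mean up to second order in the within-bin spread,
      # and exactly equal to the unwrapped average below venc
      ph_disc <- colMeans(ph_samp)
      if (apply_wrapping) {
        oob <- ph_disc > pi | ph_disc <= -pi
        ph_disc[oob] <- wrap_phase(ph_disc[oob])
      }
      # background voxels: zero velocity; averaged noise at SD/sqrt(m)
      bg <- matrix(0, nx, ny)
      if (params$noise_sd_cm_s > 0)
        bg[] <- pi * rnorm(nx * ny, 0, params$noise_sd_cm_s / sqrt(m)) / venc_cm_s
      bg[disc] <- ph_disc
      phase[, , b] <- bg
    }
    mag <- array(rep(5 + 95 * disc, nb), c(nx, ny, nb)) +
      rnorm(nx * ny * nb, 0, 2)
    mag[mag < 0] <- 0
    bin_times <- (seq_len(nb) - 0.5) * Tt / nb

    series <- phase_contrast_series(magnitude = mag, phase = phase,
                                    venc_cm_s = venc_cm_s,
                                    voxel_size_mm = voxel_size_mm,
                                    bin_times_s = bin_times,
                                    validate = apply_wrapping)
    # analytic truth: per-bin average of the continuous noise-free waveform
    # (the ideal gated acquisition), on a fine cardiac-phase grid
    phg <- (seq_len(4800L) - 0.5) / 4800
    q_fine <- csf_flow_waveform(params, phg * Tt)
    bin_fine <- pmin(nb, 1L + floor(phg * nb))
    q_bin <- as.numeric(tapply(q_fine, bin_fine, mean))
    truth_profile <- flow_profile(q_bin, bin_times, cycle_duration_s = Tt)
    # realized noise-free profile of this acquisition's actual readout
    # times, through the same (circular or linear) bin averaging
    v_real <- as.numeric(tapply(v_true, bin_of, mean))
    if (apply_wrapping) {
      oob <- abs(v_real) > venc_cm_s
      v_real[oob] <- venc_cm_s / pi * wrap_phase(pi * v_real[oob] / venc_cm_s)
    }
    realized_profile <- flow_profile(v_real * area_cm2, bin_times,
                                     cycle_duration_s = Tt)
    list(series = series,
         truth = list(profile = truth_profile,
                      metrics = compute_flow_metrics(truth_profile),
                      profile_realized = realized_profile,
                      mask = disc, area_cm2 = area_cm2,
                      readouts_per_bin = counts))
  })
}
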