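# End-to-end synthetic study runner: generates a cohort of phantoms and
# gated flow series whose geometry and waveforms encode a Gaussian-copula
# cohort draw, runs segmentation / volumetry / flowmetry per subject,
# assembles the measured cohort table and runs the statistical analysis.

derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 10007 + i * 101 + salt * 13) %% 2147483629)
}

# Polynomial rolling hash of a JSON-serialised object, for provenance blocks.
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Default phantom analytic volumes used as the scaling anchors.
.default_phantom_anchors <- function() {
  p <- head_phantom_params()
  a <- phantom_analytic_cm3(p)
  list(icv = a$icv, psd = a$psd, params = p)
}

#' Phantom parameters encoding one cohort row
#'
#' Maps a subject's cohort-scale volumes (ICV ~ 1371 cm^3, PSD ~ 8.4 cm^3)
#' onto the desk-scale phantom: semi-axes scale with the cube root of the
#' ICV ratio, tissue shell radii are solved so the CSF/GM/WM fractions match
#' the row, and the PSD shell thickness is solved from the annulus volume
#' (clamped so the complex stays inside the cranial ellipsoid; extreme PSD
#' draws are mildly truncated).
#'
#' @param row one-row data.frame with `icv_cm3, csf_cm3, gm_cm3, wm_cm3,
#'   psd_cm3`.
#' @param seed phantom seed.
#' @param center_offset_mm rigid offset (default: seeded draw in +/- 2 mm).
#' @param reference_means cohort-scale anchors (ICV and PSD means of the
#'   emulated study).
#' @return a [head_phantom_params].
#' @export
phantom_params_for_row <- function(row, seed,
                                   center_offset_mm = NULL,
                                   reference_means = c(icv = 1371,
                                                       psd = 8.36)) {
  anchors <- .default_phantom_anchors()
  p0 <- anchors$params
  s <- (row$icv_cm3 / reference_means[["icv"]])^(1 / 3)
  axes <- p0$icv_semi_axes_mm * s
  V <- anchors$icv * row$icv_cm3 / reference_means[["icv"]]  # phantom ICV cm^3
  r_v <- p0$ventricle_radius_mm * s
  v_v <- 4 / 3 * pi * r_v^3 / 1000
  tis <- c(row$csf_cm3, row$gm_cm3, row$wm_cm3)
  tis <- tis / sum(tis)                      # fractions of the cavity
  s_g3 <- 1 - max(tis[1] * V - v_v, 0.01 * V) / V
  s_g3 <- min(max(s_g3, 0.5^3), 0.97^3)
  s_w3 <- min(max(s_g3 - tis[2], 0.3^3), s_g3 - 0.05)
  r_sin <- p0$sinus_radius_mm * s
  L <- p0$sinus_length_mm * s
  height_frac <- 0.5
  psd_target <- anchors$psd * row$psd_cm3 / reference_means[["psd"]]
  t_raw <- sqrt(r_sin^2 + psd_target * 1000 / (pi * L)) - r_sin
  # largest thickness keeping the annulus inside the ellipsoid
  worst <- function(t) ((height_frac * axes[3] + r_sin + t) / axes[3])^2 +
    (L / 2 / axes[2])^2 + ((r_sin + t) / axes[1])^2
  t_max <- t_raw
  while (worst(t_max) >= 0.98 && t_max > 0.5) t_max <- t_max - 0.05
  thickness <- max(min(t_raw, t_max), 0.5)
  if (is.null(center_offset_mm))
    center_offset_mm <- withr::with_seed(derive_seed(seed, 1L, 7L),
                                         runif(3, -2, 2))
  head_phantom_params(grid_shape = p0$grid_shape,
                      voxel_size_mm = p0$voxel_size_mm,
                      icv_semi_axes_mm = axes,
                      ventricle_radius_mm = r_v,
                      sinus_radius_mm = r_sin,
                      sinus_length_mm = L,
                      sinus_height_frac = height_frac,
                      psd_thickness_mm = thickness,
                      class_means = p0$class_means,
                      class_sds = p0$class_sds,
                      bias_amplitude = p0$bias_amplitude,
                      center_offset_mm = center_offset_mm,
                      seed = seed,
                      shell_cuts = c(gm = s_g3^(1 / 3), wm = s_w3^(1 / 3)))
}

#' Template volume for phantom registration
#'
#' A noise-free, bias-free default phantom rendered in the requested
#' modality; phantom analyses use it the way clinical pipelines use a
#' standard-space template.
#' @param modality `"T2"` (default) or `"T1"`.
#' @return a [volume_image].
#' @export
phantom_template <- function(modality = "T2") {
  p <- head_phantom_params(class_sds = rep(0, 6), bias_amplitude = 0, seed = 0L)
  ph <- generate_head_phantom(p)
  if (modality == "T2") ph$t2 else ph$t1
}

#' Run the full synthetic study
#'
#' Draws a cohort from the Gaussian copula, renders per-subject phantoms and
#' gated flow series encoding each row, runs every analysis stage
#' (ICV/tissue volumetry on T1, bias correction + registration + U-Net +
#' GMM MAP PSD volumetry on T2, aliasing-corrected flowmetry), assembles the
#' measured cohort table, and fits the three model specifications plus the
#' Spearman panel and the age-group summary.
#'
#' @param n_subjects number of subjects.
#' @param seed global seed; all per-subject seeds derive from it.
#' @param model optional pre-trained `psd_seg_model` (trained on synthetic
#'   pairs when NULL).
#' @param n_train training pairs when training here.
#' @param train_config a [seg_model_config] for training.
#' @param cohort_cfg a [cohort_gen_config]; `n_subjects` and `seed` override
#'   its fields.
#' @param fit_models fit the model specifications and correlation panel
#'   (requires enough subjects for the largest model; disable for bare
#'   image-processing runs).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose progress messages.
#' @return list of class `study_report`: `target_table`, `measured_table`,
#'   `fits` (M1/M2/M3 `fit_result`s on the measured table), `panel`,
#'   `summary`, `model`, `provenance`.
#' @export
run_synthetic_study <- function(n_subjects = 5L, seed = 1L, model = NULL,
                                n_train = 6L,
                                train_config = seg_model_config(),
                                cohort_cfg = cohort_config(),
                                fit_models = TRUE,
                                out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cohort_cfg$n_subjects <- as.integer(n_subjects)
  cohort_cfg$seed <- derive_seed(seed, 0L, 1L)
  target <- generate_cohort(cohort_cfg)
  template <- phantom_template("T2")

  if (is.null(model)) {
    say("training parasagittal segmentation model on %d synthetic pairs",
        n_train)
    model <- train_parasagittal_model(make_training_pairs(n_train, seed),
                                      train_config)
  }
  roi <- dorsal_roi(dim(template$data))

  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    stage <- "phantom generation"
    res <- tryCatch({
      row <- target[i, ]
      pp <- phantom_params_for_row(row, derive_seed(seed, i, 2L))
      ph <- generate_head_phantom(pp)

      stage <- "tissue volumetry"
      icv <- estimate_icv(ph$t1)
      tis <- segment_tissues(ph$t1, icv$mask)

      stage <- "psd segmentation"
      suppressWarnings(check_psd_resolution(ph$t2))
      t2c <- correct_bias(ph$t2)
      reg <- register_to_template(t2c, template)
      psd <- measure_psd_volume(model, t2c, reg, roi_mask = roi)

      stage <- "flow quantification"
      wp <- waveform_params(peak_anterograde_mLs = row$max_anterograde_mL_s,
                            peak_retrograde_mLs = abs(row$max_retrograde_mL_s),
                            seed = derive_seed(seed, i, 3L))
      pc <- generate_phase_contrast(wp)
      am <- segment_aqueduct(pc$series)
      prof <- compute_flow_profile(pc$series, am)
      met <- compute_flow_metrics(prof)

      data.frame(id = row$id, age_years = row$age_years, sex = row$sex,
                 icv_cm3 = icv$icv_cm3, csf_cm3 = tis$volumes$csf_cm3,
                 gm_cm3 = tis$volumes$gm_cm3, wm_cm3 = tis$volumes$wm_cm3,
                 psd_cm3 = psd$psd_volume_cm3,
                 max_anterograde_mL_s = met$max_anterograde_mL_s,
                 max_retrograde_mL_s = met$max_retrograde_mL_s,
                 net_flow_mL = met$net_flow_mL,
                 absolute_flow_mL = met$absolute_flow_mL,
                 regurgitant_fraction = met$regurgitant_fraction)
    }, error = function(e) {
      stop("run_synthetic_study: stage '", stage, "' failed for subject ",
           target$id[i], ": ", conditionMessage(e), call. = FALSE)
    })
    say("subject %d/%d done (PSD %.2f cm3)", i, n_subjects, res$psd_cm3)
    rows[[i]] <- res
  }
  measured <- do.call(rbind, rows)
  class(measured) <- c("cohort_table", "data.frame")

  fits <- NULL; panel <- NULL; summ <- NULL
  if (fit_models) {
  specs <- default_model_specs("psd_cm3")
  # tiny cohorts can yield degenerate covariates (e.g. single-sex draws);
  # drop them from the model rather than aborting the study
  specs <- lapply(specs, function(sp) {
    keep <- vapply(sp$independents, function(v) {
      x <- measured[[v]]
      if (is.character(x) || is.factor(x)) length(unique(x)) > 1L
      else var(as.numeric(x)) > 0
    }, logical(1))
    if (!all(keep))
      message("run_synthetic_study: dropping constant covariate(s) from ",
              sp$name, ": ", paste(sp$independents[!keep], collapse = ", "))
    model_spec(sp$dependent, sp$independents[keep], sp$name)
  })
  fits <- lapply(specs, function(sp) fit_linear_model(measured, sp))
  panel <- spearman_panel(measured)
  summ <- suppressWarnings(summarize_cohort(measured))
  }

  prov <- list(seed = seed,
               package_version = as.character(utils::packageVersion("psdflow")),
               n_subjects = n_subjects,
               config_hash = config_hash(list(cohort = unclass(cohort_cfg)[
                 c("age_range_years", "marginal_means", "marginal_sds",
                   "sex_ratio_female")],
                 train = unclass(train_config))))
  report <- structure(list(target_table = target, measured_table = measured,
                           fits = fits, panel = panel, summary = summ,
                           model = model, provenance = prov),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(target, file.path(out_dir, "cohort_target.csv"))
    write_cohort(measured, file.path(out_dir, "cohort_measured.csv"))
    if (fit_models) {
      co <- do.call(rbind, lapply(names(fits), function(nm) {
        cbind(model = nm, fits[[nm]]$coefficients)
      }))
      write.csv(co, file.path(out_dir, "model_coefficients.csv"),
                row.names = FALSE)
      write.csv(panel, file.path(out_dir, "spearman_panel.csv"),
                row.names = FALSE)
      write.csv(summ$summary, file.path(out_dir, "cohort_summary.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' Native-space PSD volumetry from a registered T2 volume
#'
#' Predicts the parasagittal envelope in template space, transforms the
#' binary mask back to the native grid (nearest-neighbour), and performs the
#' Gaussian-mixture MAP labeling on the native bias-corrected intensities —
#' resampling blurs the thin PSD shell, so the mixture is fit where the
#' contrast is crisp and all volumes are reported in native space.
#'
#' @param model a trained `psd_seg_model`.
#' @param t2_native native-space bias-corrected T2-like [volume_image].
#' @param registration `registration_result` of `t2_native` to the template.
#' @param roi_mask optional template-space ROI restricting patch tiling.
#' @return a `psd_volumetry` (see [to_native_and_measure]).
#' @export
measure_psd_volume <- function(model, t2_native, registration,
                               roi_mask = NULL) {
  stopifnot(inherits(registration, "registration_result"))
  mask_t <- predict_parasagittal_mask(model, registration$resampled,
                                      roi_mask = roi_mask)
  if (isTRUE(attr(mask_t, "empty_mask")))
    stop("measure_psd_volume: empty parasagittal mask")
  tsp <- registration$resampled$voxel_size_mm
  inv <- invert_transform(registration$transform)
  mask_n <- apply_transform(label_map(mask_t * 1L, tsp), inv,
                            dim(t2_native$data), t2_native$voxel_size_mm,
                            nearest = TRUE)$data == 1L
  fit <- fit_gmm_map(t2_native, mask_n)
  labs <- label_psd_venous(fit, t2_native, mask_n)
  out <- to_native_and_measure(labs, NULL, space = "native")
  out$gmm_fit <- fit
  out
}

#' Synthetic training pairs for the segmentation network
#'
#' Mirrors the study's training data, which consisted of template-aligned
#' scans with expert masks: each phantom (noise and bias on, random
#' sub-voxel offset) is bias-corrected and registered to the template, and
#' the truth parasagittal envelope is carried along by the same transform.
#' Training in the deployment domain matters — the interpolation smoothing
#' introduced by resampling is part of what the network must tolerate.
#'
#' @param n number of pairs.
#' @param seed base seed.
#' @param template template volume (default [phantom_template]).
#' @return list of `list(volume, mask)` in template space.
#' @export
make_training_pairs <- function(n, seed = 1L,
                                template = phantom_template("T2")) {
  lapply(seq_len(n), function(i) {
    off <- withr::with_seed(derive_seed(seed, i, 12L), runif(3, -2, 2))
    p <- head_phantom_params(seed = derive_seed(seed, i, 11L),
                             center_offset_mm = off)
    ph <- generate_head_phantom(p)
    reg <- register_to_template(correct_bias(ph$t2), template)
    # soft (trilinear) transfer of the truth envelope, thresholded at 0.5:
    # sub-voxel consistent labels, free of nearest-neighbour jitter
    env <- parasagittal_envelope(ph$truth)
    env_t <- apply_transform(volume_image(env * 1, ph$t2$voxel_size_mm),
                             reg$transform, dim(template$data),
                             template$voxel_size_mm)$data > 0.5
    list(volume = reg$resampled, mask = env_t)
  })
}

# Dorsal band of the template grid where the parasagittal complex lives;
# restricting patch tiling here keeps prediction cheap.
dorsal_roi <- function(dims, z_frac = 0.55) {
  roi <- array(FALSE, dims)
  z0 <- ceiling(z_frac * dims[3])
  roi[, , z0:dims[3]] <- TRUE
  roi
}

# ---- series I/O -------------------------------------------------------------

#' Read / write gated phase-contrast series (NIfTI + JSON protocol sidecar)
#'
#' The magnitude and phase stacks are written as 3D NIfTI volumes (third
#' dimension = cardiac bin); venc, bin times and in-plane voxel size go to a
#' JSON protocol sidecar.
#'
#' @param series a [phase_contrast_series].
#' @param prefix path prefix; writes `<prefix>_mag.nii.gz`,
#'   `<prefix>_phase.nii.gz`, `<prefix>_protocol.json`.
#' @return `read_series()` returns a `phase_contrast_series`.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "phase_contrast_series"))
  sp <- c(series$voxel_size_mm, 1)
  mag <- RNifti::asNifti(series$magnitude); RNifti::pixdim(mag) <- sp
  phs <- RNifti::asNifti(series$phase); RNifti::pixdim(phs) <- sp
  RNifti::writeNifti(mag, paste0(prefix, "_mag.nii.gz"))
  RNifti::writeNifti(phs, paste0(prefix, "_phase.nii.gz"))
  jsonlite::write_json(list(venc_cm_s = series$venc_cm_s,
                            voxel_size_mm = series$voxel_size_mm,
                            bin_times_s = series$bin_times_s),
                       paste0(prefix, "_protocol.json"), digits = NA)
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  proto <- jsonlite::read_json(paste0(prefix, "_protocol.json"),
                               simplifyVector = TRUE)
  req <- c("venc_cm_s", "voxel_size_mm", "bin_times_s")
  miss <- setdiff(req, names(proto))
  if (length(miss))
    stop("read_series: protocol sidecar missing field(s): ",
         paste(miss, collapse = ", "))
  mag <- RNifti::readNifti(paste0(prefix, "_mag.nii.gz"))
  ph <- RNifti::readNifti(paste0(prefix, "_phase.nii.gz"))
  phase_contrast_series(array(as.numeric(mag), dim(mag)),
                        array(as.numeric(ph), dim(ph)),
                        venc_cm_s = proto$venc_cm_s,
                        voxel_size_mm = proto$voxel_size_mm,
                        bin_times_s = proto$bin_times_s)
}
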