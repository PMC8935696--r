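# Synthetic head phantom: schematic geometry (ellipsoidal cranial cavity,
# concentric tissue shells, a central ventricular CSF sphere, a midline dural
# sinus tube capped by an annular PSD shell). Downstream operators depend on
# topology and intensity contrast only, so no attempt is made at anatomical
# realism; every compartment has an analytically known volume.

PHANTOM_LABELS <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L,
                    sinus = 4L, psd = 5L)

#' Parameters of the synthetic head phantom
#'
#' Class intensity means are given per compartment and modality (arbitrary
#' units). On the T2-like modality the PSD shell is markedly hyperintense and
#' the sinus lumen hypointense, mirroring the contrast that makes the
#' parasagittal space separable on T2-weighted MRI; on the T1-like modality
#' CSF is darkest and white matter brightest.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm per-axis spacing (mm).
#' @param icv_semi_axes_mm ellipsoid semi-axes of the intracranial cavity (mm).
#' @param ventricle_radius_mm radius of the central CSF sphere (mm).
#' @param sinus_radius_mm radius of the midline sinus tube (mm).
#' @param sinus_length_mm length of the sinus tube (mm).
#' @param sinus_height_frac sinus axis height as a fraction of the superior
#'   semi-axis.
#' @param psd_thickness_mm thickness of the PSD shell around the sinus (mm).
#' @param class_means 6 x 2 matrix of intensity means, rows
#'   background/csf/gm/wm/sinus/psd, columns T1/T2.
#' @param class_sds length-6 intensity noise SD per compartment.
#' @param bias_amplitude peak-to-trough fraction of the multiplicative bias
#'   field (0 disables it).
#' @param center_offset_mm rigid offset of all structures from the grid
#'   centre (mm), used to exercise registration.
#' @param seed integer seed; the generator is a pure function of seed and
#'   parameters.
#' @param shell_cuts named fractions (of the cranial semi-axes) cutting the
#'   GM and WM shells; CSF occupies the outermost shell and the ventricle.
#' @return A list of class `head_phantom_params`.
#' @export
head_phantom_params <- function(grid_shape = c(64L, 64L, 64L),
                                voxel_size_mm = c(0.78, 0.78, 0.78),
                                icv_semi_axes_mm = c(19, 22, 18),
                                ventricle_radius_mm = 6,
                                sinus_radius_mm = 2.5,
                                sinus_length_mm = 20,
                                sinus_height_frac = 0.55,
                                psd_thickness_mm = 2,
                                class_means = NULL,
                                class_sds = c(2, 5, 5, 5, 5, 5),
                                bias_amplitude = 0.1,
                                center_offset_mm = c(0, 0, 0),
                                seed = 1L,
                                shell_cuts = c(gm = 0.92, wm = 0.72)) {
  if (is.null(class_means)) {
    class_means <- cbind(T1 = c(0, 30, 70, 100, 45, 55),
                         T2 = c(0, 85, 55, 40, 10, 120))
    rownames(class_means) <- names(PHANTOM_LABELS)
  }
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_size_mm = as.numeric(voxel_size_mm),
            icv_semi_axes_mm = as.numeric(icv_semi_axes_mm),
            ventricle_radius_mm = ventricle_radius_mm,
            sinus_radius_mm = sinus_radius_mm,
            sinus_length_mm = sinus_length_mm,
            sinus_height_frac = sinus_height_frac,
            psd_thickness_mm = psd_thickness_mm,
            class_means = class_means, class_sds = as.numeric(class_sds),
            bias_amplitude = bias_amplitude,
            center_offset_mm = as.numeric(center_offset_mm),
            seed = as.integer(seed),
            shell_cuts = shell_cuts)
  class(p) <- "head_phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  geom <- c(p$voxel_size_mm, p$icv_semi_axes_mm, p$ventricle_radius_mm,
            p$sinus_radius_mm, p$sinus_length_mm, p$psd_thickness_mm)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("phantom parameters: all geometric parameters must be strictly positive")
  if (p$class_means["psd", "T2"] <= p$class_means["sinus", "T2"])
    stop("phantom parameters: PSD must be hyperintense to the sinus on T2")
  ax <- p$icv_semi_axes_mm
  ext <- p$grid_shape * p$voxel_size_mm / 2
  off <- abs(p$center_offset_mm)
  if (any(ax + off >= ext))
    stop("phantom parameters: intracranial ellipsoid exceeds the grid")
  # the PSD annulus must sit inside the cranial ellipsoid
  r_out <- p$sinus_radius_mm + p$psd_thickness_mm
  z0 <- p$sinus_height_frac * ax[3]
  yh <- p$sinus_length_mm / 2
  worst <- ((z0 + r_out) / ax[3])^2 + (yh / ax[2])^2 + (r_out / ax[1])^2
  if (worst >= 1)
    stop("phantom parameters: sinus/PSD complex extends outside the ",
         "intracranial ellipsoid (reduce radius, length or height fraction)")
  if (p$ventricle_radius_mm >= 0.6 * min(ax))
    stop("phantom parameters: ventricle too large for the cranial cavity")
  sc <- p$shell_cuts
  if (!(sc[["wm"]] > 0 && sc[["wm"]] < sc[["gm"]] && sc[["gm"]] < 1))
    stop("phantom parameters: shell_cuts must satisfy 0 < wm < gm < 1")
  invisible(p)
}

# Analytic compartment volumes (cm^3) of the constructed solids.
phantom_analytic_cm3 <- function(p) {
  ax <- p$icv_semi_axes_mm
  r <- p$sinus_radius_mm; t <- p$psd_thickness_mm; L <- p$sinus_length_mm
  list(icv = 4 / 3 * pi * prod(ax) / 1000,
       ventricle = 4 / 3 * pi * p$ventricle_radius_mm^3 / 1000,
       sinus = pi * r^2 * L / 1000,
       psd = pi * ((r + t)^2 - r^2) * L / 1000)
}

# Low-order random quadratic bias field with exact peak-to-trough amplitude.
phantom_bias_field <- function(gx, gy, gz, amplitude) {
  if (amplitude <= 0) return(1)
  cf <- rnorm(9)
  P <- cf[1] * gx + cf[2] * gy + cf[3] * gz + cf[4] * gx * gy +
    cf[5] * gx * gz + cf[6] * gy * gz + cf[7] * gx^2 + cf[8] * gy^2 +
    cf[9] * gz^2
  rng <- range(P)
  if (diff(rng) < .Machine$double.eps) return(1)
  1 + amplitude * ((P - mean(rng)) / diff(rng))
}

#' Generate a co-registered T1-like / T2-like phantom pair with ground truth
#'
#' Builds the compartment label map, then renders each modality as
#' class mean x multiplicative bias field + Gaussian noise. Identical seeds
#' yield bit-identical output.
#'
#' @param params a [head_phantom_params] object.
#' @return list with elements `t1`, `t2` ([volume_image]) and `truth`
#'   ([label_map], with an `analytic_cm3` attribute holding the exact
#'   compartment volumes).
#' @export
generate_head_phantom <- function(params) {
  p <- validate_phantom_params(params)
  withr::with_seed(p$seed, {
    n <- p$grid_shape; sp <- p$voxel_size_mm
    # centred world coordinates, mm, relative to the structure centre
    wx <- ((seq_len(n[1]) - (n[1] + 1) / 2) * sp[1]) - p$center_offset_mm[1]
    wy <- ((seq_len(n[2]) - (n[2] + 1) / 2) * sp[2]) - p$center_offset_mm[2]
    wz <- ((seq_len(n[3]) - (n[3] + 1) / 2) * sp[3]) - p$center_offset_mm[3]
    X <- array(wx, n)
    Y <- array(rep(wy, each = n[1]), n)
    Z <- array(rep(wz, each = n[1] * n[2]), n)
    ax <- p$icv_semi_axes_mm
    rho2 <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2
    lab <- array(PHANTOM_LABELS[["background"]], n)
    lab[rho2 <= 1] <- PHANTOM_LABELS[["csf"]]          # outer CSF shell
    lab[rho2 <= p$shell_cuts[["gm"]]^2] <- PHANTOM_LABELS[["gm"]]
    lab[rho2 <= p$shell_cuts[["wm"]]^2] <- PHANTOM_LABELS[["wm"]]
    vent <- X^2 + Y^2 + Z^2 <= p$ventricle_radius_mm^2
    lab[vent] <- PHANTOM_LABELS[["csf"]]
    # sinus tube along y at the vertex, PSD annular shell around it
    z0 <- p$sinus_height_frac * ax[3]
    rad2 <- X^2 + (Z - z0)^2
    span <- abs(Y) <= p$sinus_length_mm / 2
    r <- p$sinus_radius_mm; rt <- r + p$psd_thickness_mm
    lab[span & rad2 <= rt^2] <- PHANTOM_LABELS[["psd"]]
    lab[span & rad2 <= r^2] <- PHANTOM_LABELS[["sinus"]]

    gx <- X / ax[1]; gy <- Y / ax[2]; gz <- Z / ax[3]
    bias <- phantom_bias_field(gx, gy, gz, p$bias_amplitude)
    render <- function(modality) {
      mu <- p$class_means[, modality][lab + 1L]
      sdv <- p$class_sds[lab + 1L]
      img <- mu * bias
      if (any(sdv > 0)) img <- img + rnorm(length(img), 0, sdv)
      volume_image(array(img, n), sp, modality)
    }
    t1 <- render("T1"); t2 <- render("T2")
    truth <- label_map(lab, sp, PHANTOM_LABELS)
    attr(truth, "analytic_cm3") <- phantom_analytic_cm3(p)
    attr(truth, "bias_field") <- bias
    list(t1 = t1, t2 = t2, truth = truth)
  })
}

#' Truth parasagittal envelope of a phantom
#'
#' The envelope the segmentation network is trained to predict: the union of
#' the PSD shell and the sinus lumen.
#' @param truth phantom truth [label_map].
#' @return logical 3D array.
#' @export
parasagittal_envelope <- function(truth) {
  truth$data == PHANTOM_LABELS[["psd"]] | truth$data == PHANTOM_LABELS[["sinus"]]
}
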