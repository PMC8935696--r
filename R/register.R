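# Template alignment. Phantom cohorts are generated near-aligned, so an
# axis-aligned affine (translation + per-axis scale) optimised against a
# normalised-cross-correlation objective is used; full diffeomorphic
# registration is deliberately out of scope (see the methods vignette).

#' Affine spatial transform (template world -> native world)
#'
#' World coordinates are mm, centred on each volume. The transform maps a
#' template-space world point w to the native-space point A w + t.
#'
#' @param A 3x3 matrix.
#' @param t length-3 translation, mm.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  structure(list(A = A, t = as.numeric(t)), class = "affine_transform")
}

#' @rdname affine_transform
#' @param x an `affine_transform`.
#' @export
invert_transform <- function(x) {
  Ai <- solve(x$A)
  affine_transform(Ai, -Ai %*% x$t)
}

#' Resample a volume through an affine transform
#'
#' Pulls `volume` (native space) onto a destination grid: for each
#' destination voxel the transform gives the native-space point to sample.
#'
#' @param volume source [volume_image] (native space).
#' @param transform an [affine_transform] mapping destination world to source
#'   world.
#' @param dst_dim,dst_spacing destination grid (default: source grid).
#' @param nearest nearest-neighbour interpolation (label maps) instead of
#'   trilinear.
#' @param fill value outside the source field of view.
#' @return resampled `volume_image`.
#' @export
apply_transform <- function(volume, transform, dst_dim = NULL,
                            dst_spacing = NULL, nearest = FALSE, fill = 0) {
  stopifnot(inherits(volume, "volume_image"),
            inherits(transform, "affine_transform"))
  if (is.null(dst_dim)) dst_dim <- dim(volume$data)
  if (is.null(dst_spacing)) dst_spacing <- volume$voxel_size_mm
  out <- .resample_affine(as.numeric(volume$data), volume$voxel_size_mm,
                          dim(volume$data), as.integer(dst_dim),
                          as.numeric(dst_spacing), transform$A,
                          as.numeric(transform$t), nearest, fill)
  volume_image(out, dst_spacing, volume$modality)
}

ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Register a volume to a template
#'
#' Optimises translation and per-axis log-scale of an axis-aligned affine by
#' Nelder-Mead on the negative normalised cross-correlation, evaluated on a
#' 2x-decimated template grid, then resamples the input onto the full
#' template grid.
#'
#' @param volume native-space [volume_image].
#' @param template template [volume_image].
#' @param max_iter Nelder-Mead iteration budget.
#' @param min_ncc convergence guard: final NCC below this raises an error.
#' @return list of class `registration_result`: `transform` (template ->
#'   native [affine_transform]), `resampled` (input in template space) and
#'   `ncc` (final similarity).
#' @export
register_to_template <- function(volume, template, max_iter = 400,
                                 min_ncc = 0.6) {
  stopifnot(inherits(volume, "volume_image"),
            inherits(template, "volume_image"))
  tdim <- dim(template$data); tsp <- template$voxel_size_mm
  cdim <- pmax(8L, as.integer(tdim %/% 2L))
  csp <- tsp * tdim / cdim
  tmpl_coarse <- .resample_affine(as.numeric(template$data), tsp, tdim,
                                  cdim, csp, diag(3), c(0, 0, 0), FALSE, 0)
  obj <- function(par) {
    tr <- affine_transform(diag(exp(par[4:6])), par[1:3])
    mov <- .resample_affine(as.numeric(volume$data), volume$voxel_size_mm,
                            dim(volume$data), cdim, csp, tr$A, tr$t, FALSE, 0)
    -ncc(mov, tmpl_coarse)
  }
  # initialise the translation from the intensity centroids
  centroid <- function(v) {
    arr <- pmax(v$data - stats::median(v$data), 0)
    n <- dim(arr); sp <- v$voxel_size_mm
    w <- sum(arr)
    c(sum(arr * ((slice.index(arr, 1) - (n[1] + 1) / 2) * sp[1])),
      sum(arr * ((slice.index(arr, 2) - (n[2] + 1) / 2) * sp[2])),
      sum(arr * ((slice.index(arr, 3) - (n[3] + 1) / 2) * sp[3]))) / w
  }
  t0 <- centroid(volume) - centroid(template)
  fit <- optim(c(t0, 0, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = max_iter, reltol = 1e-9,
                              parscale = c(2, 2, 2, 0.05, 0.05, 0.05)))
  final_ncc <- -fit$value
  if (final_ncc < min_ncc)
    stop("register_to_template: optimizer failed to converge ",
         sprintf("(final NCC = %.3f < %.2f)", final_ncc, min_ncc))
  tr <- affine_transform(diag(exp(fit$par[4:6])), fit$par[1:3])
  res <- apply_transform(volume, tr, tdim, tsp)
  structure(list(transform = tr, resampled = res, ncc = final_ncc),
            class = "registration_result")
}
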