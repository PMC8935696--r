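#' @useDynLib psdflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor kmeans lm optim pchisq pnorm pt quantile rbinom
#'   rnorm runif sd setNames vcov kruskal.test p.adjust cor.test qnorm
#' @importFrom utils head read.csv write.csv combn
NULL

#' 3D scalar image with voxel geometry
#'
#' `volume_image` is the carrier of all anatomical data in the package: a
#' numeric 3D array plus per-axis voxel spacing in millimetres and a modality
#' tag (`"T1"`, `"T2"`, `"label"`, ...). World coordinates are taken to be
#' centred on the volume, axis-aligned, in mm.
#'
#' @param data numeric 3D array of voxel values.
#' @param voxel_size_mm numeric length-3, per-axis spacing in mm.
#' @param modality character scalar tag.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_mm = c(1, 1, 1), modality = "generic") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume_image: `data` must be a 3D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("volume_image: `voxel_size_mm` must be 3 positive finite values")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 modality = as.character(modality)[1]),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, %s voxels @ %s mm, range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Integer-coded label map on a volume grid
#'
#' Labels share the grid of a [volume_image]. The coding dictionary maps
#' label names to integer codes (0 is always background).
#'
#' @param data integer 3D array of label codes.
#' @param voxel_size_mm per-axis spacing, mm.
#' @param dictionary named integer vector mapping label names to codes.
#' @return An object of class `label_map` (also a `volume_image`).
#' @export
label_map <- function(data, voxel_size_mm = c(1, 1, 1),
                      dictionary = integer()) {
  v <- volume_image(array(as.integer(data), dim = dim(as.array(data))),
                    voxel_size_mm, modality = "label")
  v$dictionary <- dictionary
  class(v) <- c("label_map", "volume_image")
  v
}

#' Voxel volume of an image grid
#' @param x a `volume_image` or numeric length-3 spacing.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) {
  sp <- if (inherits(x, "volume_image")) x$voxel_size_mm else as.numeric(x)
  prod(sp)
}

#' Volume of a label class in cm^3
#' @param lab a `label_map` (or integer array).
#' @param code integer code(s) to count.
#' @param voxel_size_mm spacing, used when `lab` is a bare array.
#' @export
label_volume_cm3 <- function(lab, code, voxel_size_mm = NULL) {
  if (inherits(lab, "volume_image")) {
    arr <- lab$data; sp <- lab$voxel_size_mm
  } else {
    arr <- lab; sp <- voxel_size_mm
    if (is.null(sp)) stop("voxel_size_mm required for a bare array")
  }
  sum(arr %in% code) * prod(sp) / 1000
}

# ---- NIfTI I/O (RNifti) -----------------------------------------------------

#' Read / write volumes as NIfTI
#'
#' Round-trips voxel data and grid spacing through `.nii.gz` via RNifti.
#' `read_volume()` restores a [volume_image]; label maps are written as the
#' underlying integer array (dictionary stored in a JSON sidecar when given).
#'
#' @param vol a `volume_image`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param modality modality tag to attach on read.
#' @return `read_volume()` returns a `volume_image`; `write_volume()` the path,
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  if (!is.null(vol$dictionary) && length(vol$dictionary))
    jsonlite::write_json(as.list(vol$dictionary),
                         paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, modality = "generic") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volume_image(array(as.numeric(img), dim = dim(img)[1:3]), sp, modality)
}
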