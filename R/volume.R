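#' @keywords internal
"_PACKAGE"

MODALITIES <- c("amyloid", "tau", "neurodegeneration", "raw")

#' Construct a 3D volume grid
#'
#' A `volume_grid` holds a 3D scalar field (e.g. an SUV-ratio map or a
#' z-map), its voxel-to-world affine, and a modality tag. Volumes are
#' assumed to be already spatially normalized to a common template space;
#' no resampling is ever performed.
#'
#' @param values Numeric 3D array. Non-finite entries are treated as missing
#'   downstream (excluded from masked statistics).
#' @param affine 4x4 numeric voxel-to-world transform. Defaults to identity.
#' @param modality One of `"amyloid"`, `"tau"`, `"neurodegeneration"`,
#'   `"raw"`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, affine = diag(4), modality = "raw") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  affine <- as_affine(affine)
  modality <- match.arg(modality, MODALITIES)
  structure(list(values = values, affine = affine,
                 shape = dim(values), modality = modality),
            class = "volume_grid")
}

#' Construct a binary mask volume
#'
#' @param values 3D array; coerced to 0/1 by thresholding at > 0.5 so that
#'   probabilistic masks load consistently.
#' @param affine 4x4 voxel-to-world transform.
#' @param label Free-text label (e.g. `"whole cerebellum"`, `"meta-ROI tau"`).
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(values, affine = diag(4), label = "mask") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  bin <- array(as.numeric(values > 0.5), dim = dim(values))
  if (sum(bin) == 0) stop("mask is empty (no voxel > 0.5)", call. = FALSE)
  structure(list(values = bin, affine = as_affine(affine),
                 shape = dim(bin), label = label),
            class = "mask_volume")
}

as_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  storage.mode(affine) <- "double"
  affine
}

#' Test whether two volumes/masks occupy the same grid
#'
#' Two grids are aligned iff their shapes are identical and their affines
#' agree elementwise within `tol`. Alignment is a precondition of every
#' voxelwise operation in the package.
#'
#' @param a,b `volume_grid`, `mask_volume`, or any object with `shape` and
#'   `affine` fields.
#' @param tol Elementwise affine tolerance (default 1e-4).
#' @export
is_aligned <- function(a, b, tol = 1e-4) {
  identical(as.integer(a$shape), as.integer(b$shape)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!is_aligned(a, b))
    stop("alignment error: ", what, " differ in shape or affine ",
         "(inputs must share one template grid; no resampling is done)",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s, %s, range [%.4g, %.4g]\n",
              paste(x$shape, collapse = "x"), x$modality,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> '%s', %s, %d voxels\n", x$label,
              paste(x$shape, collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag attached to the result.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, modality = "raw") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  volume_grid(vals, affine = RNifti::xform(img), modality = modality)
}

#' Read a NIfTI mask (binarized at > 0.5)
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label Label attached to the mask.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, label = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (is.null(label)) label <- basename(path)
  mask_volume(vals, affine = RNifti::xform(img), label = label)
}

#' Write a volume or mask to NIfTI
#'
#' @param x A [volume_grid()] or [mask_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$values)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Mean of volume values inside a mask, skipping non-finite voxels.
masked_mean <- function(values, mask_values) {
  v <- values[mask_values > 0]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite voxels inside mask", call. = FALSE)
  mean(v)
}
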