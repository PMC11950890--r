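# Core marker pipeline: SUVR normalization -> control model -> z-map ->
# voxel classification -> {fill state, SUVR, abnormal-voxel intensity}.

#' Intensity-normalize a raw uptake volume to a reference region
#'
#' Divides every voxel by the mean raw value inside the reference mask,
#' yielding an SUV-ratio (SUVR) map. By convention the reference region is
#' the whole cerebellum for amyloid and neurodegeneration tracers and the
#' inferior cerebellum for tau tracers; the mask is supplied by the caller.
#'
#' @param raw A [volume_grid()] of raw tracer uptake.
#' @param reference A [mask_volume()] aligned to `raw`.
#' @return A [volume_grid()] whose mean over the reference mask is 1.
#' @export
intensity_normalize <- function(raw, reference) {
  stop_if_misaligned(raw, reference, "raw volume and reference mask")
  ref_mean <- masked_mean(raw$values, reference$values)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("normalization error: reference mean is ", format(ref_mean),
         " (must be finite and > 0)", call. = FALSE)
  volume_grid(raw$values / ref_mean, affine = raw$affine,
              modality = raw$modality)
}

#' Fit a voxelwise control model from a control cohort
#'
#' Computes per-voxel sample mean and sample SD (denominator n - 1) across
#' a list of aligned control SUVR maps. Voxels whose control SD falls below
#' `sd_floor` are clamped to `sd_floor` when z-scoring (see
#' [z_standardize()]) so that constant voxels do not produce infinite
#' z-scores; the number of clamped voxels is recorded.
#'
#' @param controls List of aligned [volume_grid()] SUVR maps (length >= 2).
#' @param modality Modality tag of the model.
#' @param sd_floor Minimum SD in SUVR units (default 1e-6).
#' @return An object of class `control_model` with fields `mean_map`,
#'   `sd_map`, `n_controls`, `modality`, `sd_floor`, `n_clamped`.
#' @export
fit_control_model <- function(controls, modality = "raw", sd_floor = 1e-6) {
  if (!is.list(controls) || length(controls) < 2L)
    stop("insufficient-sample error: need >= 2 control volumes", call. = FALSE)
  ref <- controls[[1L]]
  for (ctl in controls[-1L]) stop_if_misaligned(ref, ctl, "control volumes")
  n <- length(controls)
  stack <- vapply(controls, function(v) as.numeric(v$values),
                  numeric(prod(ref$shape)))
  mu <- rowMeans(stack)
  sdv <- sqrt(rowSums((stack - mu)^2) / (n - 1))
  n_clamped <- sum(sdv < sd_floor)
  control_model(array(mu, ref$shape), array(sdv, ref$shape),
                n_controls = n, modality = modality, affine = ref$affine,
                sd_floor = sd_floor, n_clamped = n_clamped)
}

#' Construct a control model from explicit mean and SD maps
#'
#' Used both by [fit_control_model()] and by the synthetic phantom module,
#' which knows the true population mean/SD fields.
#'
#' @param mean_map,sd_map Aligned 3D arrays (SUVR units; `sd_map >= 0`).
#' @param n_controls Number of controls behind the model (>= 2).
#' @param modality Modality tag.
#' @param affine Shared affine.
#' @param sd_floor Minimum SD used when z-scoring.
#' @param n_clamped Number of voxels with SD below `sd_floor`.
#' @export
control_model <- function(mean_map, sd_map, n_controls, modality = "raw",
                          affine = diag(4), sd_floor = 1e-6,
                          n_clamped = NULL) {
  if (!identical(dim(mean_map), dim(sd_map)))
    stop("alignment error: mean_map and sd_map differ in shape", call. = FALSE)
  if (any(sd_map < 0, na.rm = TRUE)) stop("sd_map must be >= 0", call. = FALSE)
  if (n_controls < 2) stop("insufficient-sample error: n_controls >= 2",
                           call. = FALSE)
  if (is.null(n_clamped)) n_clamped <- sum(sd_map < sd_floor, na.rm = TRUE)
  structure(list(mean_map = mean_map, sd_map = sd_map,
                 shape = dim(mean_map), affine = as_affine(affine),
                 n_controls = as.integer(n_controls),
                 modality = match.arg(modality, MODALITIES),
                 sd_floor = sd_floor, n_clamped = as.integer(n_clamped)),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf(
    "<control_model> %s, %s, n_controls = %d, %d voxel(s) SD-clamped\n",
    paste(x$shape, collapse = "x"), x$modality, x$n_controls, x$n_clamped))
  invisible(x)
}

#' z-standardize a subject SUVR map against a control model
#'
#' z(v) = (subject(v) - mean(v)) / max(sd(v), sd_floor). Plain Gaussian
#' standardization is used (no small-sample t correction).
#'
#' @param subject A [volume_grid()] aligned to `model` with matching
#'   modality.
#' @param model A [control_model()].
#' @return A [volume_grid()] z-map (same modality tag).
#' @export
z_standardize <- function(subject, model) {
  stop_if_misaligned(subject, model, "subject and control model")
  if (subject$modality != model$modality)
    stop("modality error: subject is '", subject$modality,
         "' but model is '", model$modality, "'", call. = FALSE)
  denom <- pmax(model$sd_map, model$sd_floor)
  volume_grid((subject$values - model$mean_map) / denom,
              affine = subject$affine, modality = subject$modality)
}

#' Classify voxels as abnormal within an ROI
#'
#' A voxel is abnormal iff it lies inside the ROI and its z-score strictly
#' exceeds the cutoff in the pathologic direction (z > cutoff for
#' `direction = "greater"`, z < cutoff for `"less"`). Ties at exactly the
#' cutoff are negative. Non-finite z-values are never abnormal and are
#' recorded in `n_missing`.
#'
#' @param zmap A [volume_grid()] z-map.
#' @param roi A [mask_volume()] aligned to `zmap`.
#' @param cutoff Finite z-score threshold (default 1.65, the two-decimal
#'   one-tailed 5\% standard-normal quantile; use -1.65 with
#'   `direction = "less"` for hypometabolism/neurodegeneration).
#' @param direction `"greater"` or `"less"`.
#' @return An object of class `abnormality_map` with binary `values`,
#'   `cutoff`, `direction`, and missing-voxel bookkeeping.
#' @export
classify_voxels <- function(zmap, roi, cutoff = 1.65,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stop_if_misaligned(zmap, roi, "z-map and ROI")
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  if (sum(roi$values) == 0) stop("empty-roi error", call. = FALSE)
  z <- zmap$values
  finite <- is.finite(z)
  hit <- if (direction == "greater") finite & (z > cutoff) else finite & (z < cutoff)
  ab <- array(as.numeric(hit & roi$values > 0), dim = dim(z))
  n_missing <- sum(!finite & roi$values > 0)
  structure(list(values = ab, shape = dim(ab), affine = zmap$affine,
                 cutoff = cutoff, direction = direction,
                 n_missing = as.integer(n_missing)),
            class = "abnormality_map")
}

#' @export
print.abnormality_map <- function(x, ...) {
  cat(sprintf("<abnormality_map> %s, %d abnormal (z %s %.3g)\n",
              paste(x$shape, collapse = "x"), sum(x$values),
              if (x$direction == "greater") ">" else "<", x$cutoff))
  invisible(x)
}

#' Fill state: percentage of abnormal voxels inside an ROI
#'
#' 100 * (abnormal voxels inside the ROI) / (valid ROI voxels). ROI voxels
#' with a non-finite subject value (recorded in the abnormality map) are
#' excluded from both numerator and denominator.
#'
#' @param ab An `abnormality_map` from [classify_voxels()].
#' @param roi The [mask_volume()] defining the denominator region.
#' @return Percentage in [0, 100].
#' @export
fill_state <- function(ab, roi) {
  stop_if_misaligned(ab, roi, "abnormality map and ROI")
  n_roi <- sum(roi$values) - ab$n_missing
  if (n_roi <= 0) stop("empty-roi error", call. = FALSE)
  n_ab <- sum(ab$values[roi$values > 0])
  100 * n_ab / n_roi
}

#' Mean SUVR inside an ROI
#'
#' The conventional intensity marker: the arithmetic mean voxel value of an
#' SUVR map over the ROI (non-finite voxels excluded).
#'
#' @param suvr A [volume_grid()] SUVR map.
#' @param roi A [mask_volume()].
#' @export
roi_suvr <- function(suvr, roi) {
  stop_if_misaligned(suvr, roi, "SUVR map and ROI")
  if (sum(roi$values) == 0) stop("empty-roi error", call. = FALSE)
  masked_mean(suvr$values, roi$values)
}

#' Mean z-score of abnormal voxels
#'
#' The intensity counterpart probed in robustness analyses: the mean z of
#' only those voxels classified abnormal. Undefined (returns `NA_real_`,
#' never 0) when no voxel is abnormal.
#'
#' @param zmap A [volume_grid()] z-map.
#' @param ab An `abnormality_map` aligned to it.
#' @export
abnormal_intensity <- function(zmap, ab) {
  stop_if_misaligned(zmap, ab, "z-map and abnormality map")
  if (sum(ab$values) == 0) return(NA_real_)
  masked_mean(zmap$values, ab$values)
}

#' Compute the full marker set for one subject
#'
#' Deterministic composition of [z_standardize()], [classify_voxels()],
#' [fill_state()], [roi_suvr()] and [abnormal_intensity()].
#'
#' @param subject Subject SUVR [volume_grid()].
#' @param model A [control_model()].
#' @param roi Meta-ROI [mask_volume()].
#' @param cutoff,direction Passed to [classify_voxels()].
#' @return An object of class `marker_set`: `fill_state` (%), `suvr`,
#'   `abnormal_intensity` (mean z of abnormal voxels; `NA` iff fill state
#'   is 0), plus ROI/abnormal voxel counts.
#' @export
compute_markers <- function(subject, model, roi, cutoff = 1.65,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  z <- z_standardize(subject, model)
  ab <- classify_voxels(z, roi, cutoff = cutoff, direction = direction)
  fs <- fill_state(ab, roi)
  structure(list(
    fill_state = fs,
    suvr = roi_suvr(subject, roi),
    abnormal_intensity = abnormal_intensity(z, ab),
    modality = subject$modality,
    roi_label = roi$label,
    cutoff = cutoff, direction = direction,
    n_roi_voxels = as.integer(sum(roi$values) - ab$n_missing),
    n_abnormal_voxels = as.integer(sum(ab$values[roi$values > 0]))),
    class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf(
    "<marker_set> %s / %s: fill state %.2f%%, SUVR %.3f, abn. intensity %s\n",
    x$modality, x$roi_label, x$fill_state, x$suvr,
    if (is.na(x$abnormal_intensity)) "undefined"
    else sprintf("%.3f", x$abnormal_intensity)))
  invisible(x)
}

#' Flatten marker sets into a tidy data frame
#'
#' @param markers Named list of `marker_set` objects; names become
#'   `subject_id`.
#' @return A data frame with columns `subject_id`, `modality`, `roi_label`,
#'   `cutoff`, `direction`, `fill_state_pct`, `suvr`, `abnormal_intensity`,
#'   `n_roi_voxels`, `n_abnormal_voxels`.
#' @export
marker_table <- function(markers) {
  rows <- lapply(names(markers), function(id) {
    m <- markers[[id]]
    data.frame(subject_id = id, modality = m$modality,
               roi_label = m$roi_label, cutoff = m$cutoff,
               direction = m$direction, fill_state_pct = m$fill_state,
               suvr = m$suvr, abnormal_intensity = m$abnormal_intensity,
               n_roi_voxels = m$n_roi_voxels,
               n_abnormal_voxels = m$n_abnormal_voxels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
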