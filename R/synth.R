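# Synthetic 3D phantom cohorts with known ground-truth lesion extent.
# Every generator is a pure function of (config, seed): controls are
# voxelwise Gaussian fields; patients add a contiguous lesion of requested
# fractional extent inside the meta-ROI, shifted by +/- delta SD units.

#' Configuration for the synthetic phantom cohort
#'
#' Defines the grid, ROI/reference/gray-matter geometry, the population
#' mean and SD fields of the control distribution, per-group lesion-extent
#' distributions, and the lesion effect size.
#'
#' Defaults: a 32x32x32 grid; a centered ellipsoid meta-ROI covering about
#' 30\% of the grid; a disjoint reference slab at the top of the grid; a
#' smooth mean field in [1.0, 1.4] SUVR and SD field in [0.05, 0.15]; group
#' mean lesion fractions CN 0.02, SCD 0.10, MCI 0.30, dementia 0.55 with
#' group-specific jitter; effect size delta = 5 control-SD units.
#'
#' @param shape Grid shape (3 integers).
#' @param n_controls Controls used to fit empirical control models.
#' @param group_f Named mean lesion fractions per group, ordered
#'   CN <= SCD <= MCI <= dementia in expectation.
#' @param group_f_sd Named SD of the per-subject lesion-fraction jitter
#'   (truncated to [0, 0.95]).
#' @param mu_range,sigma_range Ranges of the smooth population mean and SD
#'   fields (SUVR units). The fields interpolate across these ranges along
#'   low-frequency spatial gradients; changing them creates
#'   distribution-shifted "external" cohorts.
#' @param delta Lesion effect size in units of the local control SD (> 0).
#' @param direction Named pathologic direction per modality
#'   (hyper-signal `"greater"` for amyloid/tau, hypo-signal `"less"` for
#'   neurodegeneration).
#' @param lesion_mode `"contiguous"` (breadth-first accretion from a seed
#'   voxel, the default, emulating spatial spread) or `"scattered"`
#'   (random ROI voxels, for extent-vs-intensity dissociation checks).
#' @param smooth_fwhm Full-width-half-max (voxels) of an optional Gaussian
#'   smoothing of the noise field; 0 (default) = independent voxel noise.
#' @param seed Base seed recorded in output metadata.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(32L, 32L, 32L),
                           n_controls = 40L,
                           group_f = c(CN = 0.02, SCD = 0.10,
                                       MCI = 0.30, dementia = 0.55),
                           group_f_sd = c(CN = 0.02, SCD = 0.04,
                                          MCI = 0.08, dementia = 0.10),
                           mu_range = c(1.0, 1.4),
                           sigma_range = c(0.05, 0.15),
                           delta = 5,
                           direction = c(amyloid = "greater",
                                         tau = "greater",
                                         neurodegeneration = "less"),
                           lesion_mode = c("contiguous", "scattered"),
                           smooth_fwhm = 0,
                           seed = 1L) {
  lesion_mode <- match.arg(lesion_mode)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), delta > 0)
  if (is.unsorted(group_f[c("CN", "SCD", "MCI", "dementia")]))
    stop("group lesion fractions must be ordered CN <= SCD <= MCI <= dementia",
         call. = FALSE)
  stopifnot(length(mu_range) == 2L, length(sigma_range) == 2L,
            all(sigma_range > 0))
  structure(list(shape = shape, n_controls = as.integer(n_controls),
                 group_f = group_f, group_f_sd = group_f_sd,
                 mu_range = mu_range, sigma_range = sigma_range,
                 delta = delta,
                 direction = direction, lesion_mode = lesion_mode,
                 smooth_fwhm = smooth_fwhm, seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth population fields built from low-frequency cosines; deterministic
# in the config (no RNG).
phantom_fields <- function(config) {
  d <- config$shape
  gx <- (seq_len(d[1]) - 0.5) / d[1]
  gy <- (seq_len(d[2]) - 0.5) / d[2]
  gz <- (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(gx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(gy, each = d[1]), times = d[3]), d)
  Z <- array(rep(gz, each = d[1] * d[2]), d)
  w <- (cos(2 * pi * X) + sin(2 * pi * Y) + cos(2 * pi * Z) + 3) / 6  # in [0,1]
  mu <- config$mu_range[1] + diff(config$mu_range) * w
  sigma <- config$sigma_range[1] + diff(config$sigma_range) * (1 - w)
  list(mu = mu, sigma = sigma)
}

#' Generate the phantom masks (meta-ROI, reference region, gray matter)
#'
#' Deterministic for a given config: the meta-ROI is a centered ellipsoid,
#' the reference region a disjoint slab at the top of the grid (standing in
#' for the cerebellar reference), and the gray-matter mask a larger
#' ellipsoid containing the ROI.
#'
#' @param config A [phantom_config()].
#' @return List with [mask_volume()] elements `roi`, `reference`,
#'   `graymatter`.
#' @export
make_masks <- function(config) {
  d <- config$shape
  ctr <- (d + 1) / 2
  semi <- c(0.44 * d[1], 0.44 * d[2], 0.38 * d[3])
  ctr_z <- ctr[3] - 0.06 * d[3]  # shifted down, away from the reference slab
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  e2 <- ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
        ((iz - ctr_z) / semi[3])^2
  roi <- array(as.numeric(e2 <= 1), d)
  gm <- array(as.numeric(((ix - ctr[1]) / (semi[1] * 1.12))^2 +
                         ((iy - ctr[2]) / (semi[2] * 1.12))^2 +
                         ((iz - ctr_z) / (semi[3] * 1.12))^2 <= 1), d)
  refv <- array(0, d)
  refv[, , (d[3] - 1L):d[3]] <- 1
  if (any(roi * refv > 0))
    stop("config error: ROI and reference region overlap", call. = FALSE)
  list(roi = mask_volume(roi, label = "meta-ROI (phantom ellipsoid)"),
       reference = mask_volume(refv, label = "reference slab (phantom)"),
       graymatter = mask_volume(gm, label = "gray matter (phantom)"))
}

#' True (population) control model of the phantom
#'
#' Returns the exact mean/SD fields the control generator samples from,
#' packaged as a [control_model()]. Useful as a noiseless standard against
#' which estimated control models and null calibration are checked.
#'
#' @param config A [phantom_config()].
#' @param modality Modality tag.
#' @export
true_control_model <- function(config, modality = "raw") {
  f <- phantom_fields(config)
  control_model(f$mu, f$sigma, n_controls = max(config$n_controls, 2L),
                modality = modality)
}

# Separable Gaussian blur used when smooth_fwhm > 0; preserves the marginal
# SD only approximately, so tests use the default (no smoothing).
gaussian_blur3 <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sd <- fwhm / 2.3548
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-r, r), sd = sd); k <- k / sum(k)
  for (axis in 1:3) {
    x <- apply(x, setdiff(1:3, axis), function(v)
      stats::filter(c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)])),
                    k, sides = 2)[(r + 1):(r + length(v))])
    x <- aperm(array(x, dim(x)), order(c(axis, setdiff(1:3, axis))))
  }
  x
}

#' Generate one control phantom volume
#'
#' Voxelwise independent Normal(mu(v), sigma(v)) draws from the phantom's
#' population fields; reproducible for a given (config, seed).
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for this volume.
#' @param modality Modality tag.
#' @return A [volume_grid()].
#' @export
generate_control <- function(config, seed, modality = "raw") {
  generate_patient(config, f = 0, seed = seed, modality = modality)$volume
}

#' Generate one patient phantom volume with known lesion extent
#'
#' A control-like Gaussian background plus a lesion occupying fraction `f`
#' of the meta-ROI voxels, shifted by `+delta * sigma(v)` (hyper-signal,
#' direction `"greater"`) or `-delta * sigma(v)` (hypo-signal). The lesion
#' is grown as a connected region by breadth-first accretion from a random
#' ROI voxel (or sampled uniformly in `"scattered"` mode).
#'
#' @param config A [phantom_config()].
#' @param f Requested lesion fraction in [0, 1].
#' @param seed Integer seed for this volume.
#' @param modality Modality tag; its entry in `config$direction` sets the
#'   lesion sign (default `"greater"` for unknown/raw).
#' @return List with `volume` (a [volume_grid()]), `true_f` (realized
#'   fraction, exact up to voxel rounding), and `lesion` (binary array).
#' @export
generate_patient <- function(config, f, seed, modality = "raw") {
  if (!is.finite(f) || f < 0 || f > 1)
    stop("lesion fraction f must be in [0, 1]", call. = FALSE)
  fields <- phantom_fields(config)
  masks <- make_masks(config)
  roi_idx <- which(masks$roi$values > 0)
  n_target <- round(f * length(roi_idx))
  dirn <- if (modality %in% names(config$direction))
    config$direction[[modality]] else "greater"
  sgn <- if (identical(dirn, "less")) -1 else 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  noise <- array(stats::rnorm(prod(config$shape)), config$shape)
  if (config$smooth_fwhm > 0) noise <- gaussian_blur3(noise, config$smooth_fwhm)
  vals <- fields$mu + fields$sigma * noise
  lesion <- array(0, config$shape)
  if (n_target > 0) {
    les_idx <- if (config$lesion_mode == "contiguous")
      grow_lesion(masks$roi$values, n_target)
    else sample(roi_idx, n_target)
    lesion[les_idx] <- 1
    vals[les_idx] <- vals[les_idx] + sgn * config$delta * fields$sigma[les_idx]
  }
  list(volume = volume_grid(vals, modality = modality),
       true_f = n_target / length(roi_idx),
       lesion = lesion)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Breadth-first accretion of a connected lesion (6-connectivity) inside the
# ROI, starting from a random ROI voxel; neighbor visit order is randomized
# so lesions are blobby rather than perfectly spherical. Consumes the
# current RNG stream. Queue and result are preallocated; neighbors are
# found by stride arithmetic on linear indices.
grow_lesion <- function(roi_values, n_target) {
  d <- dim(roi_values)
  nvox <- length(roi_values)
  in_roi <- roi_values > 0
  roi_idx <- which(in_roi)
  start <- sample(roi_idx, 1)
  s1 <- 1L; s2 <- d[1]; s3 <- d[1] * d[2]
  queued <- logical(nvox)
  queue <- integer(length(roi_idx))
  queue[1L] <- start; queued[start] <- TRUE
  qhead <- 1L; qtail <- 1L
  chosen <- integer(n_target)
  nsel <- 0L
  while (nsel < n_target && qhead <= qtail) {
    take <- queue[qhead]; qhead <- qhead + 1L
    nsel <- nsel + 1L
    chosen[nsel] <- take
    i0 <- take - 1L
    x <- i0 %% d[1]; y <- (i0 %/% s2) %% d[2]; z <- i0 %/% s3
    nbi <- c(if (x > 0L) take - s1, if (x < d[1] - 1L) take + s1,
             if (y > 0L) take - s2, if (y < d[2] - 1L) take + s2,
             if (z > 0L) take - s3, if (z < d[3] - 1L) take + s3)
    nbi <- nbi[in_roi[nbi] & !queued[nbi]]
    if (length(nbi) > 1L) nbi <- sample(nbi)
    if (length(nbi) > 0L) {
      queue[(qtail + 1L):(qtail + length(nbi))] <- nbi
      qtail <- qtail + length(nbi)
      queued[nbi] <- TRUE
    }
  }
  if (nsel < n_target) {  # ROI exhausted (only possible via disconnection)
    extra <- setdiff(roi_idx, chosen[seq_len(nsel)])
    chosen[(nsel + 1L):n_target] <- extra[seq_len(n_target - nsel)]
  }
  chosen
}

#' Model linking true lesion extent and covariates to cognitive scores
#'
#' Three scores (global cognition, memory, executive) are generated as
#' linear functions of the true lesion fraction f, age, sex, and education
#' plus Gaussian noise. All loadings on f are negative: more extent means
#' worse cognition. Defaults give a strong extent-cognition association at
#' cohort sizes of ~100, a global score on an MMSE-like 0-30 scale, and
#' memory/executive on z-score-like scales.
#'
#' @param intercepts,f_loadings,age_loadings,sex_loadings,edu_loadings
#'   Named numeric (global, memory, executive).
#' @param noise_sd Residual SD per score (> 0).
#' @export
cognition_model <- function(
    intercepts = c(global = 29, memory = 0.6, executive = 0.5),
    f_loadings = c(global = -12, memory = -2.8, executive = -2.2),
    age_loadings = c(global = -0.05, memory = -0.02, executive = -0.025),
    sex_loadings = c(global = 0.2, memory = 0.15, executive = 0),
    edu_loadings = c(global = 0.1, memory = 0.04, executive = 0.05),
    noise_sd = c(global = 1.2, memory = 0.45, executive = 0.45)) {
  if (any(f_loadings >= 0))
    stop("all loadings on lesion fraction must be negative", call. = FALSE)
  if (any(noise_sd <= 0)) stop("noise SD must be > 0", call. = FALSE)
  structure(list(intercepts = intercepts, f_loadings = f_loadings,
                 age_loadings = age_loadings, sex_loadings = sex_loadings,
                 edu_loadings = edu_loadings, noise_sd = noise_sd),
            class = "cognition_model")
}

#' Generate a full synthetic phantom cohort
#'
#' Draws per-subject demographics (age ~ Normal(70, 7) truncated to
#' [50, 90]; education ~ Normal(14, 3) truncated to [8, 22]; sex ~
#' Bernoulli(0.5)), a true lesion fraction from the group's distribution,
#' one phantom volume per requested modality (sharing the subject's
#' extent), and cognitive scores from the [cognition_model()]. Controls are
#' the CN group; their amyloid status is labeled by thresholding the
#' amyloid ROI SUVR.
#'
#' @param config A [phantom_config()].
#' @param cognition A [cognition_model()].
#' @param group_sizes Named integer vector over CN/SCD/MCI/dementia.
#' @param modalities Modalities to generate volumes for.
#' @param dir Output directory for NIfTI volumes and `cohort.csv`; `NULL`
#'   (default) keeps volumes in memory.
#' @param amyloid_threshold ROI SUVR above which a subject is labeled
#'   amyloid-positive. The default `NULL` derives it from the phantom's own
#'   population fields (the control ROI mean plus the signal a lesion
#'   covering 5\% of the ROI would add), since absolute literature
#'   thresholds are tracer- and scale-specific.
#' @return List with `cohort` (data frame: subject_id, group, age, sex,
#'   education, global/memory/executive scores, true_f, amyloid_status),
#'   `volumes` (list: subject_id -> modality -> [volume_grid()]; `NULL`
#'   when written to disk), `masks`, `config`, and `manifest`.
#' @export
generate_cohort <- function(config, cognition = cognition_model(),
                            group_sizes = c(CN = 30L, SCD = 30L,
                                            MCI = 30L, dementia = 30L),
                            modalities = c("amyloid", "tau",
                                           "neurodegeneration"),
                            dir = NULL,
                            amyloid_threshold = NULL) {
  stopifnot(all(group_sizes > 0))
  groups <- rep(names(group_sizes), times = group_sizes)
  n <- length(groups)
  masks <- make_masks(config)
  if (is.null(amyloid_threshold) || identical(amyloid_threshold, "auto")) {
    fields <- phantom_fields(config)
    in_roi <- masks$roi$values > 0
    amyloid_threshold <- mean(fields$mu[in_roi]) +
      0.05 * config$delta * mean(fields$sigma[in_roi])
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)
  age <- truncnorm(n, 70, 7, 50, 90)
  edu <- truncnorm(n, 14, 3, 8, 22)
  sex <- stats::rbinom(n, 1, 0.5)
  f_true <- pmin(pmax(stats::rnorm(n, config$group_f[groups],
                                   config$group_f_sd[groups]), 0), 0.95)
  f_true[groups == "CN" & f_true < 0.005] <- 0
  scores <- sapply(c("global", "memory", "executive"), function(s) {
    cognition$intercepts[[s]] +
      cognition$f_loadings[[s]] * f_true +
      cognition$age_loadings[[s]] * (age - 70) +
      cognition$sex_loadings[[s]] * sex +
      cognition$edu_loadings[[s]] * (edu - 14) +
      stats::rnorm(n, 0, cognition$noise_sd[[s]])
  })
  subj_seeds <- sample.int(.Machine$integer.max %/% 2, n * length(modalities))
  ids <- sprintf("sub-%03d", seq_len(n))
  volumes <- if (is.null(dir)) vector("list", n) else NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  amyloid_suvr <- rep(NA_real_, n)
  realized_f <- rep(NA_real_, n)
  k <- 0L
  for (i in seq_len(n)) {
    svol <- list()
    for (m in modalities) {
      k <- k + 1L
      pat <- generate_patient(config, f = f_true[i], seed = subj_seeds[k],
                              modality = m)
      realized_f[i] <- pat$true_f
      if (m == "amyloid" || (is.na(amyloid_suvr[i]) && m == modalities[1]))
        amyloid_suvr[i] <- roi_suvr(pat$volume, masks$roi)
      if (is.null(dir)) svol[[m]] <- pat$volume
      else write_volume(pat$volume,
                        file.path(dir, sprintf("%s_%s.nii.gz", ids[i], m)))
    }
    if (is.null(dir)) volumes[[i]] <- svol
  }
  if (!is.null(volumes)) names(volumes) <- ids
  cohort <- data.frame(
    subject_id = ids, group = groups, age = age, sex = sex, education = edu,
    score_global = scores[, "global"], score_memory = scores[, "memory"],
    score_executive = scores[, "executive"],
    true_f = realized_f, amyloid_suvr = amyloid_suvr,
    amyloid_status = ifelse(amyloid_suvr > amyloid_threshold,
                            "positive", "negative"),
    stringsAsFactors = FALSE)
  manifest <- list(seed = config$seed, shape = config$shape,
                   n_controls = config$n_controls, delta = config$delta,
                   group_sizes = as.list(group_sizes),
                   modalities = modalities,
                   amyloid_threshold = amyloid_threshold,
                   lesion_mode = config$lesion_mode)
  if (!is.null(dir)) {
    utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
    for (mk in names(masks))
      write_volume(masks[[mk]], file.path(dir, paste0("mask_", mk, ".nii.gz")))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cohort = cohort, volumes = volumes, masks = masks, config = config,
       manifest = manifest)
}

truncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}
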