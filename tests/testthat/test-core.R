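# Core marker pipeline: SUVR normalization, control model, z-maps, voxel
# classification, and the three per-subject markers.

test_that("intensity normalization divides by the reference mean", {
  ref <- rand_mask(1)
  uniform <- volume_grid(array(5, c(8, 8, 8)))
  out <- intensity_normalize(uniform, ref)
  expect_equal(out$values, array(1, c(8, 8, 8)))

  raw <- rand_volume(2)
  out <- intensity_normalize(raw, ref)
  ref_mean <- oracle_masked_mean(raw$values, ref$values)
  expect_lt(max(abs(out$values - raw$values / ref_mean)), 1e-12)
  # post-condition: unit mean over the reference region
  expect_equal(oracle_masked_mean(out$values, ref$values), 1, tolerance = 1e-10)
})

test_that("intensity normalization rejects bad references and misalignment", {
  raw <- rand_volume(3)
  neg <- volume_grid(array(-2, c(8, 8, 8)))
  ref <- rand_mask(4)
  expect_error(intensity_normalize(neg, ref), "normalization error")
  other <- mask_volume(array(1, c(4, 4, 4)))
  expect_error(intensity_normalize(raw, other), "alignment error")
  shifted <- mask_volume(ref$values, affine = diag(4) + 1e-2)
  expect_error(intensity_normalize(raw, shifted), "alignment error")
  nudged <- mask_volume(ref$values, affine = diag(4) + 1e-5)
  expect_s3_class(intensity_normalize(raw, nudged), "volume_grid")
})

test_that("control model is the voxelwise sample mean and SD", {
  a <- volume_grid(array(1, c(2, 2, 2)))
  b <- volume_grid(array(3, c(2, 2, 2)))
  m <- fit_control_model(list(a, b))
  expect_equal(m$mean_map, array(2, c(2, 2, 2)))
  expect_equal(m$sd_map, array(sqrt(2), c(2, 2, 2)))
  expect_identical(m$n_controls, 2L)

  # identical controls: zero SD everywhere, flagged by the sd floor
  m0 <- fit_control_model(list(a, a, a))
  expect_true(all(m0$sd_map == 0))
  expect_identical(m0$n_clamped, 8L)

  expect_error(fit_control_model(list(a)), "insufficient-sample")
})

test_that("fitted control model recovers the generating parameters", {
  set.seed(42)
  controls <- lapply(1:20, function(i)
    volume_grid(array(rnorm(512, 1.2, 0.1), c(8, 8, 8))))
  m <- fit_control_model(controls)
  expect_gte(mean(abs(m$mean_map - 1.2) < 0.1), 0.99)
  expect_gte(mean(abs(m$sd_map - 0.1) < 0.05), 0.99)
  # spot-check the SD against the scalar-loop oracle
  arrays <- lapply(controls, function(v) v$values)
  for (i in c(1L, 100L, 512L))
    expect_equal(m$sd_map[i], oracle_voxel_sd(arrays, i), tolerance = 1e-12)
})

test_that("z-standardization matches the per-voxel formula", {
  model <- control_model(array(1.2, c(4, 4, 4)), array(0.1, c(4, 4, 4)),
                         n_controls = 20, modality = "tau")
  same <- volume_grid(array(1.2, c(4, 4, 4)), modality = "tau")
  expect_equal(z_standardize(same, model)$values, array(0, c(4, 4, 4)))

  one <- volume_grid(array(1.5, c(4, 4, 4)), modality = "tau")
  expect_equal(z_standardize(one, model)$values[1], 3.0)

  # brute-force oracle on heterogeneous maps
  set.seed(7)
  mu <- array(runif(64, 1, 1.4), c(4, 4, 4))
  sdv <- array(runif(64, 0.05, 0.15), c(4, 4, 4))
  mdl <- control_model(mu, sdv, n_controls = 30, modality = "amyloid")
  subj <- rand_volume(8, c(4L, 4L, 4L), modality = "amyloid")
  z <- z_standardize(subj, mdl)$values
  for (i in seq_len(64))
    expect_equal(z[i], (subj$values[i] - mu[i]) / max(sdv[i], 1e-6),
                 tolerance = 1e-12)

  wrong <- volume_grid(array(1, c(4, 4, 4)), modality = "amyloid")
  expect_error(z_standardize(wrong, model), "modality error")
})

test_that("sd floor prevents infinite z at constant voxels", {
  mu <- array(1, c(2, 2, 2))
  sdv <- array(0.1, c(2, 2, 2)); sdv[1] <- 0
  mdl <- control_model(mu, sdv, n_controls = 5)
  subj <- volume_grid(array(1.5, c(2, 2, 2)))
  z <- z_standardize(subj, mdl)$values
  expect_true(all(is.finite(z)))
  expect_equal(z[1], 0.5 / 1e-6)
  expect_identical(mdl$n_clamped, 1L)
})

test_that("voxel classification uses strict inequality in the given direction", {
  roi <- mask_volume(array(1, c(8, 8, 8)))
  zero <- volume_grid(array(0, c(8, 8, 8)))
  expect_equal(sum(classify_voxels(zero, roi, 1.65, "greater")$values), 0)

  # ties at the cutoff are negative
  at <- volume_grid(array(1.65, c(8, 8, 8)))
  expect_equal(sum(classify_voxels(at, roi, 1.65, "greater")$values), 0)
  expect_equal(sum(classify_voxels(at, roi, 1.65, "less")$values), 0)

  z <- rand_volume(9, mean = 0, sd = 1)
  m <- rand_mask(10)
  for (dirn in c("greater", "less")) {
    cut <- if (dirn == "greater") 0.8 else -0.8
    ab <- classify_voxels(z, m, cut, dirn)
    expect_equal(sum(ab$values),
                 oracle_count_abnormal(z$values, m$values, cut, dirn))
  }
})

test_that("direction symmetry: negated z-map with flipped direction is identical", {
  z <- rand_volume(11, mean = 0, sd = 1.5)
  neg <- volume_grid(-z$values)
  m <- rand_mask(12)
  a <- classify_voxels(z, m, 1.65, "greater")
  b <- classify_voxels(neg, m, -1.65, "less")
  expect_identical(a$values, b$values)
})

test_that("fill state is the percentage of abnormal voxels in the ROI", {
  d <- c(10L, 10L, 10L)
  roi <- mask_volume(array(1, d))
  z <- array(0, d); z[1:250] <- 3
  ab <- classify_voxels(volume_grid(z), roi, 1.65, "greater")
  expect_equal(fill_state(ab, roi), 25.0)
  z0 <- classify_voxels(volume_grid(array(0, d)), roi, 1.65, "greater")
  expect_equal(fill_state(z0, roi), 0.0)
})

test_that("fill state is nonincreasing in the cutoff (direction greater)", {
  z <- rand_volume(13, mean = 0, sd = 1)
  m <- rand_mask(14)
  cuts <- seq(-2, 3, by = 0.25)
  fs <- vapply(cuts, function(cut)
    fill_state(classify_voxels(z, m, cut, "greater"), m), numeric(1))
  expect_true(all(diff(fs) <= 0))
})

test_that("missing voxels are excluded from numerator and denominator", {
  d <- c(4L, 4L, 4L)
  roi <- mask_volume(array(1, d))
  z <- array(3, d)
  z[1:16] <- NA  # 16 missing, 48 valid and abnormal
  ab <- classify_voxels(volume_grid(z), roi, 1.65, "greater")
  expect_identical(ab$n_missing, 16L)
  expect_equal(fill_state(ab, roi), 100)
})

test_that("ROI SUVR and abnormal intensity match masked-mean oracles", {
  v <- volume_grid(array(1.3, c(4, 4, 4)))
  m <- mask_volume(array(1, c(4, 4, 4)))
  expect_equal(roi_suvr(v, m), 1.3)

  two <- array(0, c(4, 4, 4)); two[1] <- 1; two[2] <- 1
  vals <- array(0, c(4, 4, 4)); vals[1] <- 1.0; vals[2] <- 2.0
  expect_equal(roi_suvr(volume_grid(vals), mask_volume(two)), 1.5)

  suvr <- rand_volume(15)
  msk <- rand_mask(16)
  expect_equal(roi_suvr(suvr, msk),
               oracle_masked_mean(suvr$values, msk$values), tolerance = 1e-12)

  z <- rand_volume(17, mean = 0, sd = 1.3)
  ab <- classify_voxels(z, msk, 1.65, "greater")
  if (sum(ab$values) > 0)
    expect_equal(abnormal_intensity(z, ab),
                 oracle_masked_mean(z$values, ab$values), tolerance = 1e-12)

  # no abnormal voxel: marker undefined, not zero
  none <- classify_voxels(volume_grid(array(0, c(8, 8, 8))), msk,
                          1.65, "greater")
  expect_true(is.na(abnormal_intensity(volume_grid(array(0, c(8, 8, 8))), none)))
})

test_that("compute_markers equals the step-by-step composition", {
  set.seed(21)
  mu <- array(runif(512, 1, 1.4), c(8, 8, 8))
  sdv <- array(runif(512, 0.05, 0.15), c(8, 8, 8))
  mdl <- control_model(mu, sdv, n_controls = 25, modality = "tau")
  subj <- rand_volume(22, modality = "tau")
  roi <- rand_mask(23)

  mk <- compute_markers(subj, mdl, roi, 1.65, "greater")
  z <- z_standardize(subj, mdl)
  ab <- classify_voxels(z, roi, 1.65, "greater")
  expect_identical(mk$fill_state, fill_state(ab, roi))
  expect_identical(mk$suvr, roi_suvr(subj, roi))
  expect_identical(mk$abnormal_intensity, abnormal_intensity(z, ab))
  expect_true(mk$fill_state >= 0 && mk$fill_state <= 100)
  expect_identical(is.na(mk$abnormal_intensity), mk$fill_state == 0)

  # subject at the control mean: no abnormality
  atmean <- volume_grid(mu, modality = "tau")
  mk0 <- compute_markers(atmean, mdl, roi, 1.65, "greater")
  expect_equal(mk0$fill_state, 0)
  expect_true(is.na(mk0$abnormal_intensity))
})

test_that("marker table has the documented tidy schema", {
  mdl <- control_model(array(1, c(4, 4, 4)), array(0.1, c(4, 4, 4)),
                       n_controls = 10, modality = "amyloid")
  subj <- rand_volume(24, c(4L, 4L, 4L), modality = "amyloid")
  roi <- mask_volume(array(1, c(4, 4, 4)), label = "meta-ROI amyloid")
  tab <- marker_table(list(s1 = compute_markers(subj, mdl, roi)))
  expect_named(tab, c("subject_id", "modality", "roi_label", "cutoff",
                      "direction", "fill_state_pct", "suvr",
                      "abnormal_intensity", "n_roi_voxels",
                      "n_abnormal_voxels"))
  expect_identical(tab$subject_id, "s1")
})

test_that("volumes round-trip through NIfTI with affine and values intact", {
  v <- rand_volume(25, modality = "tau")
  aff <- diag(c(2, 2, 2, 1)); aff[1, 4] <- -32
  v <- volume_grid(v$values, affine = aff, modality = "tau")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path, modality = "tau")
  expect_equal(back$values, v$values, tolerance = 1e-6)
  expect_true(is_aligned(v, back))

  m <- rand_mask(26)
  mpath <- tempfile(fileext = ".nii.gz")
  write_volume(m, mpath)
  mback <- read_mask(mpath, "roundtrip")
  expect_identical(mback$values, m$values)
})
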