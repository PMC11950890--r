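# Shared fixtures and independent scalar-loop oracles. The oracles are kept
# deliberately naive (explicit per-voxel loops, exhaustive enumeration) so
# they stay independent of the vectorized implementation paths they check.

rand_volume <- function(seed, shape = c(8L, 8L, 8L), modality = "raw",
                        mean = 1.2, sd = 0.2) {
  set.seed(seed)
  volume_grid(array(rnorm(prod(shape), mean, sd), shape), modality = modality)
}

rand_mask <- function(seed, shape = c(8L, 8L, 8L), p = 0.4) {
  set.seed(seed)
  m <- array(as.numeric(runif(prod(shape)) < p), shape)
  m[1, 1, 1] <- 1  # never empty
  mask_volume(m, label = "random mask")
}

# Per-voxel-loop mean of values where mask == 1 (finite voxels only).
oracle_masked_mean <- function(values, mask) {
  tot <- 0; n <- 0
  for (i in seq_along(values)) {
    if (mask[i] > 0 && is.finite(values[i])) {
      tot <- tot + values[i]; n <- n + 1
    }
  }
  tot / n
}

# Per-voxel-loop sample SD across a list of arrays.
oracle_voxel_sd <- function(arrays, i) {
  v <- vapply(arrays, function(a) a[i], numeric(1))
  sqrt(sum((v - mean(v))^2) / (length(v) - 1))
}

# Per-voxel-loop count of abnormal voxels.
oracle_count_abnormal <- function(z, mask, cutoff, direction) {
  n <- 0
  for (i in seq_along(z)) {
    if (mask[i] > 0 && is.finite(z[i])) {
      hit <- if (direction == "greater") z[i] > cutoff else z[i] < cutoff
      if (hit) n <- n + 1
    }
  }
  n
}

# Exhaustive-enumeration AUC: mean over all (pos, neg) pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

small_phantom <- function(seed = 1L, shape = c(16L, 16L, 16L), ...) {
  phantom_config(shape = shape, seed = seed, ...)
}
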