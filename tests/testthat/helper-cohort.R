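# Small cohort configurations used across the suite. Geometry is scaled down
# from the default study conditions so unit tests stay fast; lesions are kept
# large enough that tissue states are nonempty after the susceptibility and
# perilesional restrictions.

tiny_spec <- function(seed = 1, ...) {
  args <- list(n_controls = 10, n_patients = 8,
               grid_shape = c(26, 26, 26),
               lesion_count_range = c(2, 3),
               lesion_radius_range = c(3.5, 4.5),
               t1l_core_fraction = 0.4,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

tiny_config <- function(spec = tiny_spec(), ...) {
  # the down-scaled lesions carry less than 0.4 cm^3 per state, so the unit
  # tests lower the inclusion volume; acceptance runs keep the default rule
  pipeline_config(cohort_spec = spec, min_volume_cm3 = 0.05, ...)
}

# single-metric, lesion-free configuration for null-calibration checks
null_spec <- function(seed) {
  et <- default_effect_table() * 0
  es <- default_effect_sd() * 0
  cohort_spec(n_controls = 10, n_patients = 12,
              grid_shape = c(16, 16, 16),
              metrics = "FA",
              effect_table = et, between_patient_effect_sd = es,
              noise_correlation = matrix(1, 1, 1, dimnames = list("FA", "FA")),
              lesion_count_range = c(0, 0),
              rater_erosion_prob = NULL,
              seed = seed)
}

# brute-force mm-distance oracle: TRUE where a voxel centre lies within
# radius_mm of any seed voxel centre (all-pairs, used on small grids only)
brute_force_near <- function(mask, radius_mm, voxel_size) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  seeds <- which(mask)
  if (!length(seeds)) return(out)
  si <- arrayInd(seeds, dm)
  all_i <- arrayInd(seq_len(prod(dm)), dm)
  for (v in seq_len(nrow(all_i))) {
    d2 <- (si[, 1] - all_i[v, 1])^2 * voxel_size[1]^2 +
          (si[, 2] - all_i[v, 2])^2 * voxel_size[2]^2 +
          (si[, 3] - all_i[v, 3])^2 * voxel_size[3]^2
    if (min(d2) <= radius_mm^2 + 1e-9) out[v] <- TRUE
  }
  out
}

# exhaustive-pair AUC oracle with the 1/2 tie convention
brute_force_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}
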