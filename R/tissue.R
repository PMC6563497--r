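## Tissue-state segmentation --------------------------------------------------
##
## Each patient's lesion-susceptible white matter is partitioned into three
## mutually exclusive states: NAWM (normal appearing white matter, at least
## 5 mm from any lesion voxel), T2L (T2-hyperintense lesion without
## T1-hypointensity) and T1L (T2-hyperintense and T1-hypointense, the
## "black-hole-like" voxels), with a per-patient volume inclusion rule.

#' Across-patient lesion probability map
#'
#' @param lesion_masks nonempty list of logical arrays on a common grid.
#' @return list: `probabilities` (fraction of patients lesioned per voxel),
#'   `n_patients_contributing`.
#' @export
build_lesion_probability_map <- function(lesion_masks) {
  n <- length(lesion_masks)
  if (n == 0L) stop_wm("need at least one lesion mask")
  acc <- array(0, dim(lesion_masks[[1]]))
  for (m in lesion_masks) {
    check_same_grid(lesion_masks[[1]], m, "lesion masks")
    acc <- acc + m
  }
  list(probabilities = acc / n, n_patients_contributing = n)
}

#' Threshold the lesion probability map into a susceptibility mask
#'
#' Inclusive rule: voxels lesioned in at least `threshold` of patients are
#' retained (a voxel at exactly the threshold is included).
#'
#' @param prob_map a [build_lesion_probability_map()] result (or bare array).
#' @param threshold fraction in (0, 1); default 0.05.
#' @return logical array.
#' @export
threshold_susceptibility <- function(prob_map, threshold = 0.05) {
  if (is.list(prob_map)) prob_map <- prob_map$probabilities
  if (threshold <= 0 || threshold >= 1) stop_wm("threshold must lie in (0, 1)")
  prob_map >= threshold - 1e-12
}

#' NAWM mask: thresholded white matter away from lesions
#'
#' NAWM = (WM probability >= `wm_threshold`) within the susceptibility mask,
#' excluding every voxel whose centre lies within `exclusion_mm` (Euclidean,
#' physical mm) of any lesion voxel centre.
#'
#' @param wm_probability 3D array in `[0, 1]`.
#' @param lesion_mask logical array.
#' @param susceptibility logical array (lesion-susceptible WM restriction).
#' @param voxel_size mm per axis.
#' @param wm_threshold default 0.80.
#' @param exclusion_mm perilesional exclusion radius, default 5 mm.
#' @return logical array.
#' @export
make_nawm_mask <- function(wm_probability, lesion_mask, susceptibility,
                           voxel_size, wm_threshold = 0.80, exclusion_mm = 5.0) {
  check_same_grid(wm_probability, lesion_mask, "WM probability and lesion mask")
  check_same_grid(wm_probability, susceptibility, "WM probability and susceptibility")
  near <- dilate_mm(lesion_mask, exclusion_mm, voxel_size)
  (wm_probability >= wm_threshold) & susceptibility & !near
}

#' Classify lesion voxels into T1L and T2L by T1-weighted intensity
#'
#' The reference distribution is the patient's NAWM T1-weighted intensity;
#' a lesion voxel is T1L when its intensity lies at least 1.5 interquartile
#' ranges below the lower quartile (intensity <= Q1 - 1.5 IQR), otherwise
#' T2L. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param t1w bias-corrected T1-weighted intensity volume.
#' @param lesion_mask logical lesion mask (already susceptibility-restricted
#'   if that restriction is wanted in the output states).
#' @param nawm_mask nonempty logical NAWM mask providing the reference.
#' @return list: `t1l`, `t2l` (disjoint, exhaustive over `lesion_mask`),
#'   `cutoff_report` (q1, q3, iqr, cutoff, n_nawm_reference).
#' @export
classify_lesion_voxels <- function(t1w, lesion_mask, nawm_mask) {
  check_same_grid(t1w, lesion_mask, "T1w and lesion mask")
  ref <- t1w[nawm_mask]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0L) stop_wm("empty NAWM reference: cannot derive the T1 cutoff")
  q <- stats::quantile(ref, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  cutoff <- q[1] - 1.5 * iqr
  t1l <- lesion_mask & is.finite(t1w) & t1w <= cutoff
  t2l <- lesion_mask & !t1l
  list(t1l = t1l, t2l = t2l,
       cutoff_report = list(q1 = q[1], q3 = q[2], iqr = iqr, cutoff = cutoff,
                            n_nawm_reference = length(ref)))
}

#' Per-patient tissue-state inclusion rule
#'
#' A patient enters the cohort analyses only when every tissue state exceeds
#' the minimum volume (strictly greater than `min_volume_cm3`).
#'
#' @param volumes named numeric vector of per-state volumes in cm^3.
#' @param min_volume_cm3 default 0.4.
#' @return logical flag.
#' @export
apply_inclusion_rule <- function(volumes, min_volume_cm3 = 0.4) {
  all(volumes > min_volume_cm3)
}

#' Segment one patient's tissue states
#'
#' Chains the NAWM mask, the T1-intensity lesion classification and the
#' volume inclusion rule. When two rater masks are supplied the more
#' conservative one (smaller volume) is used. The partition invariant
#' (states pairwise disjoint, T1L u T2L = restricted lesion mask) is
#' asserted on every call.
#'
#' @param wm_probability,susceptibility,t1w volumes on a common grid.
#' @param lesion_mask logical mask, or a list of two rater masks.
#' @param voxel_size mm per axis.
#' @param wm_threshold,exclusion_mm,susceptibility_threshold,min_volume_cm3
#'   segmentation parameters (defaults 0.80, 5 mm, unused here, 0.4 cm^3).
#' @return object of class `tissue_states`: `nawm`, `t2l`, `t1l`, `volumes`
#'   (cm^3), `included`, `cutoff_report`.
#' @export
segment_tissue_states <- function(wm_probability, lesion_mask, susceptibility,
                                  t1w, voxel_size,
                                  wm_threshold = 0.80, exclusion_mm = 5.0,
                                  min_volume_cm3 = 0.4) {
  if (is.list(lesion_mask) && !is.array(lesion_mask)) {
    vols <- vapply(lesion_mask, sum, 0)
    lesion_mask <- lesion_mask[[which.min(vols)]]  # more conservative rater
  }
  nawm <- make_nawm_mask(wm_probability, lesion_mask, susceptibility,
                         voxel_size, wm_threshold, exclusion_mm)
  lesion_r <- lesion_mask & susceptibility
  cls <- classify_lesion_voxels(t1w, lesion_r, nawm)
  stopifnot(!any(cls$t1l & cls$t2l), !any(nawm & (cls$t1l | cls$t2l)),
            identical(cls$t1l | cls$t2l, lesion_r))
  volumes <- c(NAWM = mask_volume_cm3(nawm, voxel_size),
               T2L = mask_volume_cm3(cls$t2l, voxel_size),
               T1L = mask_volume_cm3(cls$t1l, voxel_size))
  structure(list(nawm = nawm, t2l = cls$t2l, t1l = cls$t1l,
                 volumes = volumes,
                 included = apply_inclusion_rule(volumes, min_volume_cm3),
                 cutoff_report = cls$cutoff_report),
            class = "tissue_states")
}

#' @export
print.tissue_states <- function(x, ...) {
  cat(sprintf("Tissue states: NAWM %.1f cm3, T2L %.1f cm3, T1L %.1f cm3 [%s]\n",
              x$volumes["NAWM"], x$volumes["T2L"], x$volumes["T1L"],
              if (x$included) "included" else "excluded"))
  invisible(x)
}
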