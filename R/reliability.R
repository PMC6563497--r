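## Inter-rater reliability ----------------------------------------------------
##
## Agreement between two operators' lesion masks: Dice overlap per patient,
## ICC(3,1) over extracted lesion volumes, and the conservativeness contrast.

#' Dice similarity coefficient
#'
#' 2|A n B| / (|A| + |B|). Two empty masks agree perfectly on the absence of
#' lesions and score 1.
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  check_same_grid(mask_a, mask_b, "rater masks")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0L) return(1)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' ICC(3,1): two-way mixed-effects, single-measure, consistency
#'
#' (BMS - EMS) / (BMS + (k - 1) EMS) from the two-way ANOVA mean squares
#' (subjects random, raters fixed). Undefined when there is no
#' between-subject variance.
#'
#' @param volumes n_subjects x k matrix (k raters, here k = 2).
#' @return list: `icc`, `f` (BMS/EMS), `df1`, `df2`, `p`.
#' @export
icc31 <- function(volumes) {
  volumes <- as.matrix(volumes)
  n <- nrow(volumes); k <- ncol(volumes)
  if (n < 3L) stop_wm("icc31 needs at least 3 subjects")
  if (k != 2L) stop_wm("icc31 expects exactly 2 raters")
  grand <- mean(volumes)
  bms <- k * sum((rowMeans(volumes) - grand)^2) / (n - 1)
  jms <- n * sum((colMeans(volumes) - grand)^2) / (k - 1)
  sst <- sum((volumes - grand)^2)
  ems <- (sst - bms * (n - 1) - jms * (k - 1)) / ((n - 1) * (k - 1))
  if (bms == 0 && ems == 0) {
    message("ICC(3,1) undefined: no between-subject or residual variance")
    return(list(icc = NA_real_, f = NA_real_, df1 = n - 1,
                df2 = (n - 1) * (k - 1), p = NA_real_))
  }
  f <- if (ems == 0) Inf else bms / ems
  list(icc = (bms - ems) / (bms + (k - 1) * ems), f = f,
       df1 = n - 1, df2 = (n - 1) * (k - 1),
       p = stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

#' Conservativeness contrast between raters
#'
#' Paired t-test on per-patient volume differences (rater 1 minus rater 2);
#' a consistently negative mean difference means rater 1 marks less tissue.
#'
#' @param volumes n x 2 matrix of lesion volumes (cm^3).
#' @return list: `mean_diff`, `t`, `df`, `p`, `direction`.
#' @export
conservativeness_test <- function(volumes) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) < 2L) stop_wm("conservativeness_test needs >= 2 patients")
  d <- volumes[, 1] - volumes[, 2]
  if (stats::sd(d) == 0) {
    tt <- list(estimate = mean(d),
               statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else tt <- stats::t.test(d)
  md <- unname(tt$estimate)
  list(mean_diff = md, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       direction = if (md < 0) "rater 1 more conservative"
                   else if (md > 0) "rater 2 more conservative" else "no difference")
}

#' Full rater comparison over a cohort
#'
#' @param rater_masks list (per patient) of two logical masks.
#' @param voxel_size mm per axis.
#' @return list: `per_patient` (data.frame patient/dice/vol_1/vol_2),
#'   `mean_dice`, `sd_dice`, `icc`, `conservativeness`.
#' @export
rater_comparison <- function(rater_masks, voxel_size) {
  per <- do.call(rbind, lapply(seq_along(rater_masks), function(i) {
    m <- rater_masks[[i]]
    data.frame(patient = i, dice = dice(m[[1]], m[[2]]),
               vol_1 = mask_volume_cm3(m[[1]], voxel_size),
               vol_2 = mask_volume_cm3(m[[2]], voxel_size))
  }))
  vols <- as.matrix(per[, c("vol_1", "vol_2")])
  list(per_patient = per,
       mean_dice = mean(per$dice), sd_dice = stats::sd(per$dice),
       icc = icc31(vols),
       conservativeness = conservativeness_test(vols))
}
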