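## Normative modelling --------------------------------------------------------
##
## Voxel-wise control mean/SD maps and patient z-score damage maps. A z-score
## of -1 at a voxel means the patient's metric is one control SD below the
## control mean at that location.

#' Fit a voxel-wise normative model from control maps
#'
#' Per-voxel sample mean and sample SD (n - 1 denominator) over the control
#' cohort. Voxels whose SD falls at or below `sd_floor`, or with fewer than
#' `min_contributors` finite contributions, are flagged invalid and never
#' yield z-scores.
#'
#' @param control_maps list of 3D arrays on a common grid (one metric).
#' @param metric metric label carried through for bookkeeping.
#' @param sd_floor native-unit validity floor for the SD map; default
#'   `1e-6` times the observed dynamic range of the control values.
#' @param min_contributors minimum finite contributions per voxel (>= 2).
#' @return object of class `normative_model` with `mean`, `sd`,
#'   `n_contributors`, `valid`, `sd_floor`, `metric`.
#' @export
fit_normative <- function(control_maps, metric = "metric",
                          sd_floor = NULL, min_contributors = 2L) {
  n <- length(control_maps)
  if (n < 2L) stop_wm("fit_normative needs at least 2 controls (SD undefined otherwise)")
  dm <- dim(control_maps[[1]])
  for (m in control_maps) check_same_grid(control_maps[[1]], m, "control maps")
  s <- s2 <- cnt <- array(0, dm)
  for (m in control_maps) {
    fin <- is.finite(m)
    mm <- m; mm[!fin] <- 0
    s <- s + mm; s2 <- s2 + mm^2; cnt <- cnt + fin
  }
  mu <- s / cnt
  ss <- pmax(0, s2 - cnt * mu^2)
  sdv <- sqrt(ss / pmax(cnt - 1, 1))
  if (is.null(sd_floor)) {
    rng <- range(unlist(lapply(control_maps, function(m) range(m[is.finite(m)]))))
    sd_floor <- 1e-6 * max(diff(rng), .Machine$double.eps)
  }
  valid <- cnt >= max(2L, min_contributors) & sdv > sd_floor
  mu[cnt == 0] <- NA_real_
  structure(list(metric = metric, mean = mu, sd = sdv,
                 n_contributors = cnt, valid = valid, sd_floor = sd_floor),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model [%s]: %s grid, %d/%d voxels valid (sd_floor %.3g)\n",
              x$metric, paste(dim(x$mean), collapse = "x"),
              sum(x$valid), length(x$valid), x$sd_floor))
  invisible(x)
}

#' Convert a patient map into a z-score damage map
#'
#' z = (x - mean) / SD per valid voxel; invalid voxels (model-invalid or
#' non-finite input) are returned as NA, never as spurious numbers.
#'
#' @param patient_map 3D array on the model grid.
#' @param model a [fit_normative()] result.
#' @return 3D array of z-scores (NA outside the validity mask).
#' @export
zscore_map <- function(patient_map, model) {
  check_same_grid(patient_map, model$mean, "patient map and normative model")
  z <- (patient_map - model$mean) / model$sd
  z[!model$valid | !is.finite(patient_map)] <- NA_real_
  z
}

#' Magnetisation transfer ratio from paired acquisitions
#'
#' MTR = (S0 - SMT) / S0 x 100, in percent units. Voxels with S0 <= 0 are
#' masked invalid; negative MTR (SMT > S0) is permitted but counted for QC.
#'
#' @param s0 signal without the off-resonance saturation pulse.
#' @param s_mt signal with the pulse.
#' @return list: `mtr` (3D array, NA where invalid), `valid`,
#'   `n_nonpositive_s0`, `n_negative_mtr`.
#' @export
compute_mtr <- function(s0, s_mt) {
  check_same_grid(s0, s_mt, "S0 and SMT volumes")
  valid <- is.finite(s0) & is.finite(s_mt) & s0 > 0
  mtr <- array(NA_real_, dim(s0))
  mtr[valid] <- (s0[valid] - s_mt[valid]) / s0[valid] * 100
  list(mtr = mtr, valid = valid,
       n_nonpositive_s0 = sum(is.finite(s0) & s0 <= 0),
       n_negative_mtr = sum(mtr < 0, na.rm = TRUE))
}
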