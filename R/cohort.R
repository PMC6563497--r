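## Synthetic cohort generation ------------------------------------------------
##
## The generator emulates the statistical structure of a multimodal MS imaging
## study: a healthy control cohort defining voxel-wise normative statistics for
## each metric, and a patient cohort carrying focal lesions whose per-tissue
## damage effects, between-patient heterogeneity and between-metric voxel
## noise correlations are direct generator inputs (in control-SD units).

#' Default per-tissue-state mean damage (control-SD units)
#'
#' Rows are metrics, columns the three tissue states. Damage lowers FA, MTR
#' and MWF (negative entries) and raises RD (positive entries), increasing in
#' severity from NAWM through T2-lesional to T1-lesional tissue.
#' @export
default_effect_table <- function() {
  m <- rbind(FA  = c(-0.31, -0.99, -1.92),
             RD  = c( 0.53,  2.12,  4.84),
             MTR = c(-0.28, -1.41, -4.73),
             MWF = c(-0.70, -2.90, -7.31))
  colnames(m) <- c("NAWM", "T2L", "T1L")
  m
}

#' Default between-patient SD of the per-tissue damage offsets (control-SD units)
#' @export
default_effect_sd <- function() {
  m <- rbind(FA  = c(0.30, 0.380, 0.48),
             RD  = c(0.54, 0.884, 1.75),
             MTR = c(0.79, 1.01,  1.66),
             MWF = c(0.85, 1.21,  1.97))
  colnames(m) <- c("NAWM", "T2L", "T1L")
  m
}

#' Default between-metric voxel-noise correlation matrix
#'
#' Group-mean within-patient voxel-wise correlations between the four damage
#' scores: strongly negative FA-RD coupling (an RD increase lowers FA by
#' construction of the tensor eigenvalues), positive myelin-sensitive
#' couplings among FA, MTR and MWF.
#' @export
default_noise_correlation <- function() {
  r <- matrix(c(1.00, -0.74,  0.38,  0.43,
               -0.74,  1.00, -0.52, -0.58,
                0.38, -0.52,  1.00,  0.67,
                0.43, -0.58,  0.67,  1.00), 4, 4)
  dimnames(r) <- list(c("FA", "RD", "MTR", "MWF"), c("FA", "RD", "MTR", "MWF"))
  r
}

#' Default native-unit baseline parameters per metric
#'
#' `mean` is the spatial average of the smooth baseline field, `amplitude`
#' the SD of its smooth spatial variation, `noise_sd` the voxel-wise control
#' noise SD (all native units: FA and MWF unitless, RD in 1e-3 mm^2/s, MTR in
#' percent), `smoothness_mm` the Gaussian sigma of the baseline field.
#' @export
default_metric_params <- function() {
  data.frame(metric = c("FA", "RD", "MTR", "MWF"),
             mean = c(0.45, 0.60, 38.0, 0.15),
             amplitude = c(0.06, 0.08, 2.5, 0.03),
             noise_sd = c(0.04, 0.05, 1.5, 0.025),
             smoothness_mm = c(6, 6, 6, 6),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' Bundles every generative parameter: cohort sizes, grid geometry, per-metric
#' baseline fields and noise, per-tissue damage effects (mean and
#' between-patient SD, both in control-SD units), the between-metric noise
#' correlation, lesion geometry, the T1-weighted intensity model driving the
#' Q1 - 1.5 IQR classification, and the seed.
#'
#' @param n_controls,n_patients cohort sizes.
#' @param grid_shape three positive integers (voxels per axis).
#' @param voxel_size mm per axis.
#' @param metrics ordered metric identifiers; must index the effect tables.
#' @param metric_params data.frame as [default_metric_params()].
#' @param effect_table,between_patient_effect_sd metric x state matrices
#'   (control-SD units); defaults carry the study's per-state damage profile.
#' @param noise_correlation symmetric positive-definite matrix over `metrics`.
#' @param within_state_sd voxel-level SD of damage inside a tissue state
#'   (control-SD units). Not identified by group summary statistics; default 1.
#' @param lesion_count_range,lesion_radius_range integers / mm.
#' @param t1l_core_fraction fraction of each lesion's voxels (innermost first)
#'   given T1-hypointense ground truth.
#' @param t1w_params list: `nawm_mean`, `nawm_sd` (intensity units),
#'   `t1l_depression` (NAWM-SD units below the NAWM mean), `margin`
#'   (NAWM-SD units kept clear of the generating cutoff on both sides).
#' @param rater_erosion_prob length-2 per-rater boundary erosion probabilities
#'   (second rater more conservative); NULL disables rater simulation.
#' @param age_mean,age_sd length-2 (control, patient) demographics in years.
#' @param age_slope per-metric age slope in z-units per year (confound
#'   coupling; zero by default).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 27,
                        n_patients = 105,
                        grid_shape = c(40, 40, 40),
                        voxel_size = c(1, 1, 1),
                        metrics = c("FA", "RD", "MTR", "MWF"),
                        metric_params = default_metric_params(),
                        effect_table = default_effect_table(),
                        between_patient_effect_sd = default_effect_sd(),
                        noise_correlation = default_noise_correlation(),
                        within_state_sd = 1,
                        lesion_count_range = c(4, 6),
                        lesion_radius_range = c(5, 7),
                        t1l_core_fraction = 0.35,
                        t1w_params = list(nawm_mean = 100, nawm_sd = 10,
                                          t1l_depression = 4, margin = 1),
                        rater_erosion_prob = c(0.25, 0.45),
                        age_mean = c(control = 38.1, patient = 44.2),
                        age_sd = c(control = 11.0, patient = 9.1),
                        age_slope = NULL,
                        seed = 1L) {
  spec <- list(n_controls = as.integer(n_controls),
               n_patients = as.integer(n_patients),
               grid_shape = as.integer(grid_shape),
               voxel_size = check_voxel_size(voxel_size),
               metrics = metrics,
               metric_params = metric_params,
               effect_table = effect_table,
               between_patient_effect_sd = between_patient_effect_sd,
               noise_correlation = noise_correlation,
               within_state_sd = within_state_sd,
               lesion_count_range = as.integer(lesion_count_range),
               lesion_radius_range = lesion_radius_range,
               t1l_core_fraction = t1l_core_fraction,
               t1w_params = t1w_params,
               rater_erosion_prob = rater_erosion_prob,
               age_mean = age_mean, age_sd = age_sd,
               age_slope = age_slope %||% stats::setNames(rep(0, length(metrics)), metrics),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_cohort_spec <- function(spec) {
  m <- spec$metrics
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8))
    stop_wm("grid_shape must be three integers >= 8")
  R <- spec$noise_correlation[m, m, drop = FALSE]
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop_wm("noise_correlation must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8))
    stop_wm("noise_correlation must have a unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_wm(sprintf("noise_correlation is not positive definite (smallest eigenvalue %.3g)",
                    min(ev)))
  et <- spec$effect_table[m, , drop = FALSE]
  lower <- intersect(m, c("FA", "MTR", "MWF"))
  if (length(lower) && any(et[lower, ] > 0))
    stop_wm("effect_table: FA/MTR/MWF damage entries must be <= 0 (damage lowers them)")
  if ("RD" %in% m && any(et["RD", ] < 0))
    stop_wm("effect_table: RD damage entries must be >= 0 (damage raises RD)")
  if (any(spec$between_patient_effect_sd[m, , drop = FALSE] < 0))
    stop_wm("between_patient_effect_sd must be non-negative")
  if (spec$lesion_count_range[1] > 0 &&
      max(spec$lesion_radius_range) * 2 >= min(spec$grid_shape * spec$voxel_size) - 4)
    stop_wm("grid too small for the requested lesion radius")
  ## the WM core must be able to hold three tissue states above 0.4 cm^3
  core_vox <- prod(pmax(spec$grid_shape - 4, 0))
  if (core_vox * prod(spec$voxel_size) / 1000 < 3 * 0.4)
    stop_wm("grid volume too small: each tissue state must be able to exceed 0.4 cm^3")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d controls, %d patients on a %s grid (%s mm voxels)\n",
              x$n_controls, x$n_patients,
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size, collapse = "x")))
  cat(sprintf("  metrics: %s; seed %d\n", paste(x$metrics, collapse = ", "), x$seed))
  invisible(x)
}

#' Draw correlated zero-mean noise
#'
#' @param n number of draws (rows).
#' @param correlation positive-definite correlation matrix.
#' @param sds per-column SDs (native units).
#' @return n x ncol matrix whose empirical correlation converges to
#'   `correlation` as n grows.
#' @export
sample_correlated_noise <- function(n, correlation, sds) {
  k <- ncol(correlation)
  if (length(sds) != k)
    stop_wm("sds length must match the correlation matrix dimension")
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop_wm("correlation matrix is not positive definite"))
  z <- matrix(stats::rnorm(n * k), n, k) %*% ch
  out <- sweep(z, 2, sds, `*`)
  colnames(out) <- colnames(correlation)
  out
}

## White-matter probability field implied by the grid: 1 in the inner core
## (2-voxel margin), 0.5 on a 1-voxel transition shell, 0 outside.
wm_probability_field <- function(grid_shape) {
  dm <- grid_shape
  p <- array(0, dm)
  core <- function(margin) {
    ok <- array(FALSE, dm)
    ok[(1 + margin):(dm[1] - margin), (1 + margin):(dm[2] - margin),
       (1 + margin):(dm[3] - margin)] <- TRUE
    ok
  }
  p[core(1)] <- 0.5
  p[core(2)] <- 1
  p
}

#' Place ground-truth lesions
#'
#' Lesions are unions of random spheres inside the white-matter core; the
#' innermost `t1l_core_fraction` of each sphere's voxels receives the
#' T1-hypointense label. Consumes the current RNG stream.
#'
#' @param spec a [cohort_spec()].
#' @return integer label array: 0 background, 1 NAWM, 2 T2L, 3 T1L.
#' @export
place_lesions <- function(spec) {
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  wm <- wm_probability_field(dm) >= 0.5
  labels <- array(0L, dm)
  labels[wm] <- 1L
  n_les <- if (spec$lesion_count_range[1] == spec$lesion_count_range[2])
    spec$lesion_count_range[1] else
    sample(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1L)
  if (n_les == 0L) return(labels)
  t1l <- array(FALSE, dm)
  lesion <- array(FALSE, dm)
  ax <- lapply(1:3, function(a) (seq_len(dm[a]) - 1) * vs[a])
  for (i in seq_len(n_les)) {
    r <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    ## keep the sphere centre far enough from the WM boundary that it fits
    lo <- pmax(3, ceiling(r / vs) + 2)
    hi <- pmin(dm - 2, dm - 1 - ceiling(r / vs))
    if (any(lo > hi)) stop_wm("grid too small for the requested lesion radius")
    ctr <- sapply(1:3, function(a) sample(seq(lo[a], hi[a]), 1L))
    d2 <- outer(outer((ax[[1]] - ax[[1]][ctr[1]])^2,
                      (ax[[2]] - ax[[2]][ctr[2]])^2, `+`),
                (ax[[3]] - ax[[3]][ctr[3]])^2, `+`)
    inside <- d2 <= r^2
    lesion <- lesion | inside
    n_core <- round(spec$t1l_core_fraction * sum(inside))
    if (n_core > 0) {
      vox <- which(inside)
      t1l[vox[order(d2[vox])[seq_len(n_core)]]] <- TRUE
    }
  }
  lesion <- lesion & wm
  t1l <- t1l & lesion
  labels[lesion] <- 2L
  labels[t1l] <- 3L
  labels
}

#' Simulate two raters' lesion masks
#'
#' Each rater drops a voxel with probability `p^depth`, where depth is the
#' 6-connected erosion depth (1 at the lesion surface), so perturbation
#' concentrates at lesion boundaries; `p = 0` reproduces the mask, `p = 1`
#' deletes it entirely. The rater with the larger probability is
#' systematically more conservative.
#'
#' @param mask logical lesion mask (nonempty).
#' @param erosion_prob length-2 per-rater probabilities.
#' @return list of two logical masks.
#' @export
simulate_raters <- function(mask, erosion_prob = c(0.25, 0.45)) {
  if (!any(mask)) stop_wm("simulate_raters needs a nonempty mask")
  depth <- erosion_depth(mask)
  vox <- which(mask)
  lapply(erosion_prob, function(p) {
    keep <- stats::runif(length(vox)) >= p^depth[vox]
    out <- array(FALSE, dim(mask))
    out[vox[keep]] <- TRUE
    out
  })
}

## Truncated-normal draws via inverse CDF.
rnorm_trunc <- function(n, mean, sd, upper = Inf, lower = -Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec (including its seed). RNG substream order:
#' baseline fields, control ages, control maps, then per patient (age,
#' lesions, damage offsets, voxel noise, T1-weighted intensities, rater
#' masks).
#'
#' Patient damage is injected relative to the *realised* control-cohort
#' mean/SD fields — the reference the normative stage estimates — so the
#' configured z-unit effects are exactly the downstream estimands (see the
#' methods vignette).
#'
#' @param spec a [cohort_spec()].
#' @return object of class `wm_cohort`: list with `spec`, `wm_probability`,
#'   and `subjects` (each with `subject_id`, `group`, `age`, `maps`, `t1w`,
#'   `true_labels`, `rater_masks`).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  nvox <- prod(dm)
  mets <- spec$metrics
  k <- length(mets)
  mp <- spec$metric_params[match(mets, spec$metric_params$metric), ]
  R <- spec$noise_correlation[mets, mets, drop = FALSE]
  eff <- spec$effect_table[mets, , drop = FALSE]
  eff_sd <- spec$between_patient_effect_sd[mets, , drop = FALSE]

  wm_prob <- wm_probability_field(dm)
  wm <- wm_prob >= 0.5

  ## 1. smooth baseline mean fields (unit-SD smoothed noise, rescaled)
  baseline <- lapply(seq_len(k), function(j) {
    f <- smooth_gaussian(array(stats::rnorm(nvox), dm), mp$smoothness_mm[j], vs)
    f <- (f - mean(f)) / stats::sd(f)
    mp$mean[j] + mp$amplitude[j] * f
  })
  names(baseline) <- mets

  ## 2. controls
  age_c <- stats::rnorm(spec$n_controls, spec$age_mean[["control"]], spec$age_sd[["control"]])
  t1p <- spec$t1w_params
  controls <- lapply(seq_len(spec$n_controls), function(i) {
    E <- sample_correlated_noise(nvox, R, mp$noise_sd)
    maps <- lapply(seq_len(k), function(j) {
      v <- baseline[[j]] + array(E[, j], dm) +
        spec$age_slope[[mets[j]]] * (age_c[i] - spec$age_mean[["control"]]) * mp$noise_sd[j]
      v
    })
    names(maps) <- mets
    list(subject_id = sprintf("ctrl%03d", i), group = "control", age = age_c[i],
         maps = maps, t1w = array(stats::rnorm(nvox, t1p$nawm_mean, t1p$nawm_sd), dm),
         true_labels = { l <- array(0L, dm); l[wm] <- 1L; l },
         rater_masks = NULL)
  })

  ## 3. realised control reference fields (the damage scale for patients)
  ref <- control_reference(controls, mets)

  ## generating T1 cutoff from the NAWM intensity model: Q1 - 1.5 IQR of a
  ## normal(mean, sd) distribution
  q1 <- stats::qnorm(0.25, t1p$nawm_mean, t1p$nawm_sd)
  iqr <- (stats::qnorm(0.75) - stats::qnorm(0.25)) * t1p$nawm_sd
  cutoff <- q1 - 1.5 * iqr
  marg <- t1p$margin * t1p$nawm_sd

  ## 4. patients
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    age <- stats::rnorm(1, spec$age_mean[["patient"]], spec$age_sd[["patient"]])
    labels <- place_lesions(spec)
    delta <- matrix(stats::rnorm(k * 3, eff, eff_sd), k, 3,
                    dimnames = list(mets, colnames(eff)))
    E <- sample_correlated_noise(nvox, R, rep(1, k))
    state <- labels  # 1 NAWM, 2 T2L, 3 T1L
    maps <- lapply(seq_len(k), function(j) {
      v <- baseline[[j]] + mp$noise_sd[j] * array(E[, j], dm)
      inwm <- which(labels > 0L)
      dz <- delta[j, state[inwm]] + spec$within_state_sd * E[inwm, j]
      v[inwm] <- ref$mean[[j]][inwm] + dz * ref$sd[[j]][inwm]
      v[inwm] <- v[inwm] +
        spec$age_slope[[mets[j]]] * (age - spec$age_mean[["control"]]) * mp$noise_sd[j]
      v
    })
    names(maps) <- mets
    t1w <- array(stats::rnorm(nvox, t1p$nawm_mean, t1p$nawm_sd), dm)
    i_t2l <- which(labels == 2L); i_t1l <- which(labels == 3L)
    if (length(i_t1l))
      t1w[i_t1l] <- rnorm_trunc(length(i_t1l),
                                t1p$nawm_mean - t1p$t1l_depression * t1p$nawm_sd,
                                t1p$nawm_sd, upper = cutoff - marg)
    if (length(i_t2l))
      t1w[i_t2l] <- rnorm_trunc(length(i_t2l),
                                t1p$nawm_mean - t1p$nawm_sd,
                                t1p$nawm_sd, lower = cutoff + marg)
    raters <- NULL
    if (!is.null(spec$rater_erosion_prob) && any(labels >= 2L))
      raters <- simulate_raters(labels >= 2L, spec$rater_erosion_prob)
    list(subject_id = sprintf("pat%03d", i), group = "patient", age = age,
         maps = maps, t1w = t1w, true_labels = labels, rater_masks = raters)
  })

  structure(list(spec = spec, wm_probability = wm_prob,
                 subjects = c(controls, patients),
                 t1_cutoff_truth = cutoff),
            class = "wm_cohort")
}

## Realised per-voxel mean and sample SD over a list of control subjects.
control_reference <- function(controls, metrics) {
  n <- length(controls)
  mean_maps <- sd_maps <- vector("list", length(metrics))
  names(mean_maps) <- names(sd_maps) <- metrics
  for (m in metrics) {
    s <- s2 <- 0
    for (ctl in controls) { v <- ctl$maps[[m]]; s <- s + v; s2 <- s2 + v^2 }
    mu <- s / n
    mean_maps[[m]] <- mu
    sd_maps[[m]] <- sqrt(pmax(0, (s2 - n * mu^2) / (n - 1)))
  }
  list(mean = mean_maps, sd = sd_maps)
}

#' @export
print.wm_cohort <- function(x, ...) {
  gr <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("Synthetic cohort: %d controls, %d patients, %s grid\n",
              sum(gr == "control"), sum(gr == "patient"),
              paste(x$spec$grid_shape, collapse = "x")))
  invisible(x)
}

#' Cohort subject accessors
#' @param cohort a `wm_cohort`.
#' @export
cohort_controls <- function(cohort)
  Filter(function(s) s$group == "control", cohort$subjects)

#' @rdname cohort_controls
#' @export
cohort_patients <- function(cohort)
  Filter(function(s) s$group == "patient", cohort$subjects)
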