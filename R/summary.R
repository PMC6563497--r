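## Global damage summaries ----------------------------------------------------
##
## Per-patient global damage scores (median z within each tissue state),
## cohort tissue-state contrasts, between- and within-patient correlation
## structure, regression variance explained, and the covariate confound
## projection.

#' Global damage score: median z within a tissue-state mask
#'
#' @param damage_map z-score array (NA outside validity).
#' @param state_mask logical array.
#' @return median z over valid mask voxels; NA (with a `reason` attribute)
#'   when the intersection is empty.
#' @export
global_damage <- function(damage_map, state_mask) {
  check_same_grid(damage_map, state_mask, "damage map and state mask")
  v <- damage_map[state_mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    return(structure(NA_real_, reason = "empty mask/validity intersection"))
  stats::median(v)
}

#' Cohort damage table
#'
#' One row per included patient x metric x tissue-state holding the median
#' z-score. Patients whose tissue states fail the inclusion rule are dropped;
#' empty mask/validity intersections are omitted with a logged reason.
#'
#' @param damage_maps nested list: `damage_maps[[patient]][[metric]]`.
#' @param tissue list of [segment_tissue_states()] results per patient.
#' @param patient_ids character vector.
#' @return data.frame: patient, metric, state, median_z.
#' @export
cohort_damage_table <- function(damage_maps, tissue, patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- sprintf("pat%03d", seq_along(damage_maps))
  rows <- list()
  for (i in seq_along(damage_maps)) {
    ts <- tissue[[i]]
    if (!isTRUE(ts$included)) next
    masks <- list(NAWM = ts$nawm, T2L = ts$t2l, T1L = ts$t1l)
    for (metric in names(damage_maps[[i]])) {
      for (state in names(masks)) {
        md <- global_damage(damage_maps[[i]][[metric]], masks[[state]])
        if (is.na(md)) {
          message(sprintf("dropping %s/%s/%s: %s", patient_ids[i], metric, state,
                          attr(md, "reason")))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient = patient_ids[i], metric = metric, state = state,
          median_z = as.numeric(md), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop_wm("cohort damage table is empty")
  out <- do.call(rbind, rows)
  out$state <- factor(out$state, levels = c("NAWM", "T2L", "T1L"))
  out
}

#' Tissue-state contrasts on the cohort damage table
#'
#' Per metric: a one-sample t-test of the NAWM damage scores against 0, a
#' paired t-test T2L vs NAWM, and a paired t-test T1L vs T2L.
#'
#' @param table a [cohort_damage_table()].
#' @return data.frame: metric, contrast, estimate (mean difference), t, df, p.
#' @export
tissue_state_tests <- function(table) {
  out <- list()
  for (metric in unique(table$metric)) {
    w <- stats::reshape(table[table$metric == metric, c("patient", "state", "median_z")],
                        idvar = "patient", timevar = "state", direction = "wide")
    names(w) <- sub("^median_z\\.", "", names(w))
    if (nrow(w) < 2L) stop_wm("tissue_state_tests needs at least 2 included patients")
    tt <- function(x, y = NULL, contrast) {
      d <- if (is.null(y)) x else x - y
      if (stats::sd(d) == 0) {
        ## degenerate contrast: no variability in the (paired) scores
        r <- list(estimate = mean(d),
                  statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  parameter = length(d) - 1,
                  p.value = if (mean(d) == 0) 1 else 0)
      } else r <- stats::t.test(d)
      data.frame(metric = metric, contrast = contrast,
                 estimate = unname(r$estimate[1]), t = unname(r$statistic),
                 df = unname(r$parameter), p = r$p.value, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- tt(w$NAWM, contrast = "NAWM vs 0")
    if (!is.null(w$T2L)) out[[length(out) + 1L]] <- tt(w$T2L, w$NAWM, "T2L vs NAWM")
    if (!is.null(w$T1L) && !is.null(w$T2L))
      out[[length(out) + 1L]] <- tt(w$T1L, w$T2L, "T1L vs T2L")
  }
  do.call(rbind, out)
}

#' Between-patient correlations of global damage scores
#'
#' Pearson correlations between metrics across patients, per tissue state,
#' with Bonferroni-corrected significance (the default comparison count of 36
#' reproduces a corrected threshold of 0.05/36 = 0.0014).
#'
#' @param table a [cohort_damage_table()].
#' @param alpha nominal level, default 0.05.
#' @param n_comparisons Bonferroni divisor, default 36.
#' @return list per state with `r`, `p`, `significant`, plus
#'   `corrected_threshold`.
#' @export
between_patient_correlations <- function(table, alpha = 0.05, n_comparisons = 36) {
  thr <- alpha / n_comparisons
  mets <- unique(table$metric)
  out <- list()
  for (state in levels(table$state)) {
    sub <- table[table$state == state, ]
    if (!nrow(sub)) next
    w <- stats::reshape(sub[, c("patient", "metric", "median_z")],
                        idvar = "patient", timevar = "metric", direction = "wide")
    x <- as.matrix(w[, -1, drop = FALSE])
    colnames(x) <- sub("^median_z\\.", "", colnames(x))
    x <- x[, mets, drop = FALSE]
    if (nrow(x) < 3L) stop_wm("between-patient correlations need >= 3 patients per state")
    k <- length(mets)
    r <- p <- matrix(NA_real_, k, k, dimnames = list(mets, mets))
    diag(r) <- 1; diag(p) <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (stats::sd(x[, i]) == 0 || stats::sd(x[, j]) == 0) next  # undefined pair
      ct <- stats::cor.test(x[, i], x[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    stopifnot(all(abs(r[is.finite(r)]) <= 1 + 1e-12))
    out[[state]] <- list(r = r, p = p, significant = p < thr)
  }
  out$corrected_threshold <- thr
  out
}

#' Within-patient voxel-wise correlations between damage maps
#'
#' For each patient, Pearson correlations between every metric pair across
#' the white-matter voxels; the group mean is computed through the Fisher
#' z-transform (transform, average, back-transform) and the SD is reported on
#' the raw r scale.
#'
#' @param damage_maps nested list `[[patient]][[metric]]`.
#' @param wm_masks logical array or list of arrays (per patient).
#' @return list: `mean_r`, `sd_r` (metric x metric), `per_patient`
#'   (data.frame patient/metric_a/metric_b/r), `n_excluded`.
#' @export
within_patient_correlations <- function(damage_maps, wm_masks) {
  n <- length(damage_maps)
  mets <- names(damage_maps[[1]])
  if (length(mets) < 2L) stop_wm("need at least two metrics")
  if (is.array(wm_masks)) wm_masks <- rep(list(wm_masks), n)
  rows <- list(); n_excluded <- 0L
  for (i in seq_len(n)) {
    vals <- sapply(mets, function(m) damage_maps[[i]][[m]][wm_masks[[i]]])
    keep <- rowSums(!is.finite(vals)) == 0
    vals <- vals[keep, , drop = FALSE]
    for (a in seq_along(mets)[-length(mets)]) for (b in (a + 1):length(mets)) {
      if (stats::sd(vals[, a]) == 0 || stats::sd(vals[, b]) == 0) {
        n_excluded <- n_excluded + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient = i, metric_a = mets[a], metric_b = mets[b],
        r = stats::cor(vals[, a], vals[, b]), stringsAsFactors = FALSE)
    }
  }
  pp <- do.call(rbind, rows)
  k <- length(mets)
  mean_r <- sd_r <- matrix(NA_real_, k, k, dimnames = list(mets, mets))
  diag(mean_r) <- 1; diag(sd_r) <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    r <- pp$r[pp$metric_a == mets[a] & pp$metric_b == mets[b]]
    mean_r[a, b] <- mean_r[b, a] <- fisher_mean(r)
    sd_r[a, b] <- sd_r[b, a] <- stats::sd(r)
  }
  list(mean_r = mean_r, sd_r = sd_r, per_patient = pp, n_excluded = n_excluded)
}

#' Spatial variance in one metric explained by the others
#'
#' Per patient, an OLS regression (with intercept) of the target metric's
#' voxel values on the remaining metrics over the white-matter mask;
#' reported as R-squared x 100, averaged over patients.
#'
#' @inheritParams within_patient_correlations
#' @return data.frame: metric, mean_pct, sd_pct, n_patients.
#' @export
variance_explained <- function(damage_maps, wm_masks) {
  n <- length(damage_maps)
  mets <- names(damage_maps[[1]])
  if (is.array(wm_masks)) wm_masks <- rep(list(wm_masks), n)
  per <- matrix(NA_real_, n, length(mets), dimnames = list(NULL, mets))
  for (i in seq_len(n)) {
    vals <- sapply(mets, function(m) damage_maps[[i]][[m]][wm_masks[[i]]])
    vals <- vals[rowSums(!is.finite(vals)) == 0, , drop = FALSE]
    if (nrow(vals) < 10L) stop_wm("variance_explained needs >= 10 voxels per patient")
    d <- as.data.frame(vals)
    for (m in mets) {
      fit <- stats::lm(stats::reformulate(setdiff(mets, m), response = m), data = d)
      if (fit$rank < length(mets)) {
        message(sprintf("patient %d: rank-deficient design for %s, excluded", i, m))
        next
      }
      per[i, m] <- 100 * summary(fit)$r.squared
    }
  }
  data.frame(metric = mets,
             mean_pct = colMeans(per, na.rm = TRUE),
             sd_pct = apply(per, 2, stats::sd, na.rm = TRUE),
             n_patients = colSums(is.finite(per)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate confound projection
#'
#' Voxel-wise simple-regression slopes of the control damage maps on a
#' covariate (e.g. age in years), averaged over a mask, then projected onto a
#' covariate gap: expected change = mean slope x gap (z-units).
#'
#' @param control_damage_maps list of z-score arrays (one per control).
#' @param covariate numeric vector (same length, e.g. years).
#' @param mask logical array.
#' @param gap covariate difference to project (years).
#' @return list: `mean_slope` (z per covariate unit), `gap`,
#'   `expected_change`, `n_controls`.
#' @export
confound_projection <- function(control_damage_maps, covariate, mask, gap) {
  n <- length(control_damage_maps)
  if (n < 3L) stop_wm("confound_projection needs >= 3 controls")
  if (length(covariate) != n) stop_wm("one covariate value per control required")
  if (stats::sd(covariate) == 0) stop_wm("covariate has zero variance")
  z <- sapply(control_damage_maps, function(m) m[mask])
  cc <- covariate - mean(covariate)
  slopes <- as.vector(z %*% cc) / sum(cc^2)
  mean_slope <- mean(slopes[is.finite(slopes)])
  list(mean_slope = mean_slope, gap = gap,
       expected_change = mean_slope * gap, n_controls = n)
}
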