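## End-to-end driver ----------------------------------------------------------
##
## Chains all stages over a synthetic (or supplied) cohort: normative fit,
## z-score damage maps, tissue-state segmentation, damage table and contrasts,
## correlation structure, pooled PCA with score maps, ROC sensitivity, and
## rater reliability. Every stage exchanges plain containers so outputs can be
## serialised (NIfTI volumes, TSV tables, JSON models).

#' Pipeline configuration
#'
#' @param cohort_spec a [cohort_spec()] describing the synthetic cohort.
#' @param wm_threshold,susceptibility_threshold,exclusion_mm,min_volume_cm3
#'   segmentation thresholds (defaults 0.80, 0.05, 5 mm, 0.4 cm^3).
#' @param bonferroni_correlations,bonferroni_roc comparison counts for the
#'   corrected thresholds (defaults 36 and 10).
#' @param lesion_mask_source `"truth"` (generator labels) or
#'   `"conservative_rater"` (smaller of the two simulated rater masks).
#' @param output_dir optional directory for serialised outputs.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec = wmdamage::cohort_spec(),
                            wm_threshold = 0.80,
                            susceptibility_threshold = 0.05,
                            exclusion_mm = 5.0,
                            min_volume_cm3 = 0.4,
                            bonferroni_correlations = 36,
                            bonferroni_roc = 10,
                            lesion_mask_source = c("truth", "conservative_rater"),
                            output_dir = NULL) {
  stopifnot(wm_threshold > 0, wm_threshold <= 1,
            susceptibility_threshold > 0, susceptibility_threshold < 1,
            exclusion_mm >= 0, min_volume_cm3 >= 0)
  structure(list(cohort_spec = cohort_spec,
                 wm_threshold = wm_threshold,
                 susceptibility_threshold = susceptibility_threshold,
                 exclusion_mm = exclusion_mm,
                 min_volume_cm3 = min_volume_cm3,
                 bonferroni_correlations = bonferroni_correlations,
                 bonferroni_roc = bonferroni_roc,
                 lesion_mask_source = match.arg(lesion_mask_source),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full damage-mapping pipeline
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally a pre-generated [generate_cohort()] result
#'   (must match `config$cohort_spec`); generated when NULL.
#' @return object of class `wm_pipeline`: the cohort, normative models,
#'   per-patient damage maps and tissue states, the damage table, tissue
#'   contrasts, correlation summaries, variance explained, PCA model and
#'   score maps, ROC tables and comparisons, reliability report, manifest.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  spec <- config$cohort_spec
  if (spec$n_patients < 2L) stop_wm("pipeline needs at least 2 patients")
  if (is.null(cohort)) cohort <- generate_cohort(spec)
  vs <- spec$voxel_size
  mets <- spec$metrics
  controls <- cohort_controls(cohort)
  patients <- cohort_patients(cohort)

  ## --- normative stage ---
  models <- lapply(mets, function(m)
    fit_normative(lapply(controls, function(s) s$maps[[m]]), metric = m))
  names(models) <- mets

  damage <- lapply(patients, function(p) {
    z <- lapply(mets, function(m) zscore_map(p$maps[[m]], models[[m]]))
    names(z) <- mets
    z
  })

  ## --- tissue-state stage ---
  lesion_masks <- lapply(patients, function(p) p$true_labels >= 2L)
  prob_map <- build_lesion_probability_map(lesion_masks)
  susceptibility <- threshold_susceptibility(prob_map, config$susceptibility_threshold)
  tissue <- lapply(seq_along(patients), function(i) {
    lm <- if (config$lesion_mask_source == "conservative_rater" &&
              !is.null(patients[[i]]$rater_masks))
      patients[[i]]$rater_masks else lesion_masks[[i]]
    segment_tissue_states(cohort$wm_probability, lm, susceptibility,
                          patients[[i]]$t1w, vs,
                          wm_threshold = config$wm_threshold,
                          exclusion_mm = config$exclusion_mm,
                          min_volume_cm3 = config$min_volume_cm3)
  })
  included <- vapply(tissue, function(t) isTRUE(t$included), TRUE)
  patient_ids <- vapply(patients, `[[`, "", "subject_id")

  ## --- damage summaries ---
  table <- cohort_damage_table(damage, tissue, patient_ids)
  contrasts <- tissue_state_tests(table)
  between <- between_patient_correlations(
    table, n_comparisons = config$bonferroni_correlations)
  ## analysis WM mask per patient: the union of its three tissue states
  wm_masks <- lapply(tissue, function(t) t$nawm | t$t2l | t$t1l)
  within <- within_patient_correlations(damage[included], wm_masks[included])
  varexp <- variance_explained(damage[included], wm_masks[included])

  ## --- composite score ---
  pooled <- pool_wm_voxels(damage[included], wm_masks[included])
  pca <- fit_pca(pooled)
  score_maps <- lapply(damage, component_score_map, model = pca)

  ## --- ROC sensitivity ---
  damage_plus <- lapply(seq_along(damage), function(i)
    c(damage[[i]], list(PCA = score_maps[[i]])))
  rocs <- roc_table(damage_plus, tissue, patient_ids = patient_ids)
  roc_comparisons <- compare_metrics(rocs, n_tests = config$bonferroni_roc)

  ## --- reliability ---
  reliability <- NULL
  rmasks <- lapply(patients, `[[`, "rater_masks")
  have <- !vapply(rmasks, is.null, TRUE)
  if (any(have)) reliability <- rater_comparison(rmasks[have], vs)

  manifest <- list(package_version = as.character(utils::packageVersion("wmdamage")),
                   seed = spec$seed,
                   n_controls = spec$n_controls, n_patients = spec$n_patients,
                   n_included = sum(included),
                   config_hash = config_hash(config))
  res <- structure(list(cohort = cohort, models = models, damage = damage,
                        susceptibility = susceptibility, tissue = tissue,
                        included = included, patient_ids = patient_ids,
                        table = table, contrasts = contrasts,
                        between = between, within = within,
                        variance_explained = varexp,
                        pca = pca, score_maps = score_maps,
                        rocs = rocs, roc_comparisons = roc_comparisons,
                        reliability = reliability, manifest = manifest),
                   class = "wm_pipeline")
  if (!is.null(config$output_dir)) write_pipeline(res, config$output_dir, vs)
  res
}

#' @export
print.wm_pipeline <- function(x, ...) {
  cat(sprintf("Damage-mapping pipeline run: %d/%d patients included (seed %d)\n",
              x$manifest$n_included, x$manifest$n_patients, x$manifest$seed))
  cat(sprintf("  PC1 variance %.1f%%, KMO %.2f\n",
              100 * x$pca$variance_fraction[1], x$pca$kmo))
  invisible(x)
}

## Stable hash of the configuration: md5 of its canonical JSON serialisation.
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(plain, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Write a volume as NIfTI-1 with explicit voxel dimensions
#'
#' Masks and labels are written as integers, scalar maps as float.
#' @param volume 3D array (logical, integer or numeric).
#' @param path output path (`.nii.gz`).
#' @param voxel_size mm per axis.
#' @export
write_volume <- function(volume, path, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  if (is.logical(volume)) volume <- array(as.integer(volume), dim(volume))
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume back as a plain array
#' @param path NIfTI file.
#' @return list: `volume` (array), `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img)[1:3])
}

## Serialise the report bundle: NIfTI volumes, TSV tables, JSON models.
write_pipeline <- function(res, dir, voxel_size) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  write_tsv(res$table, file.path(dir, "damage_table.tsv"))
  write_tsv(res$contrasts, file.path(dir, "tissue_state_tests.tsv"))
  write_tsv(res$rocs, file.path(dir, "roc.tsv"))
  write_tsv(res$roc_comparisons, file.path(dir, "roc_comparisons.tsv"))
  write_tsv(res$variance_explained, file.path(dir, "variance_explained.tsv"))
  vols <- do.call(rbind, lapply(seq_along(res$tissue), function(i)
    data.frame(patient = res$patient_ids[i], t(res$tissue[[i]]$volumes),
               included = res$included[i])))
  write_tsv(vols, file.path(dir, "tissue_volumes.tsv"))
  if (!is.null(res$reliability))
    write_tsv(res$reliability$per_patient, file.path(dir, "reliability.tsv"))
  jsonlite::write_json(
    list(weights = res$pca$weights[, 1], eigenvalues = res$pca$eigenvalues,
         variance_fraction = res$pca$variance_fraction, kmo = res$pca$kmo,
         center = res$pca$center, scale = res$pca$scale),
    file.path(dir, "pca_model.json"), digits = NA)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(res$damage)) {
    id <- res$patient_ids[i]
    for (m in names(res$damage[[i]]))
      write_volume(res$damage[[i]][[m]],
                   file.path(dir, "maps", sprintf("%s_%s_z.nii.gz", id, m)),
                   voxel_size)
    write_volume(res$score_maps[[i]],
                 file.path(dir, "maps", sprintf("%s_PCA_score.nii.gz", id)),
                 voxel_size)
  }
  invisible(dir)
}
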