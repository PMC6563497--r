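#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 27 healthy controls and 105 MS
# patients on a common 40 mm^3 grid, four co-registered metric maps each
# (FA, RD, MTR, MWF), focal lesions with a T1-hypointense core, a
# T1-weighted channel, and two simulated raters' lesion masks.

# run from the repository root: Rscript analysis/01_simulate_cohort.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "01_cohort")
dir.create(out, showWarnings = FALSE)

spec <- study_spec()
co <- generate_cohort(spec)
print(co)

# cohort manifest: group, age, lesion burden per subject
vs <- spec$voxel_size
manifest <- do.call(rbind, lapply(co$subjects, function(s) {
  data.frame(subject_id = s$subject_id, group = s$group, age = round(s$age, 1),
             lesion_cm3 = mask_volume_cm3(s$true_labels >= 2L, vs),
             t1l_core_cm3 = mask_volume_cm3(s$true_labels == 3L, vs))
}))
write.table(manifest, file.path(out, "cohort_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# serialise the generating configuration
jsonlite::write_json(
  list(n_controls = spec$n_controls, n_patients = spec$n_patients,
       grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
       metrics = spec$metrics, effect_table = spec$effect_table,
       between_patient_effect_sd = spec$between_patient_effect_sd,
       noise_correlation = spec$noise_correlation, seed = spec$seed),
  file.path(out, "cohort_spec.json"), digits = NA, pretty = TRUE)

# one example patient's volumes for visual QC
p <- cohort_patients(co)[[1]]
for (m in spec$metrics)
  write_volume(p$maps[[m]], file.path(out, sprintf("example_%s.nii.gz", m)), vs)
write_volume(p$t1w, file.path(out, "example_T1w.nii.gz"), vs)
write_volume(p$true_labels, file.path(out, "example_labels.nii.gz"), vs)

pat <- manifest[manifest$group == "patient", ]
say("patients: lesion burden %.1f +/- %.1f cm3 (T1L core %.1f +/- %.1f cm3)",
    mean(pat$lesion_cm3), sd(pat$lesion_cm3),
    mean(pat$t1l_core_cm3), sd(pat$t1l_core_cm3))
say("wrote %s", out)
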