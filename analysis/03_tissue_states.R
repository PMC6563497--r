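#!/usr/bin/env Rscript
# Tissue-state stage: lesion probability map thresholded at 5%, NAWM with the
# 80% WM threshold and 5 mm perilesional exclusion, T1L/T2L classification by
# the Q1 - 1.5 IQR T1-intensity cutoff, and the >0.4 cm^3 inclusion rule.

# run from the repository root: Rscript analysis/03_tissue_states.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "03_tissue")
dir.create(out, showWarnings = FALSE)

res <- get_run()
spec <- res$cohort$spec

vols <- do.call(rbind, lapply(seq_along(res$tissue), function(i) {
  ts <- res$tissue[[i]]
  data.frame(patient = res$patient_ids[i],
             nawm_cm3 = ts$volumes[["NAWM"]],
             t2l_cm3 = ts$volumes[["T2L"]],
             t1l_cm3 = ts$volumes[["T1L"]],
             t1_cutoff = ts$cutoff_report$cutoff,
             included = res$included[i])
}))
write.table(vols, file.path(out, "tissue_volumes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_volume(res$susceptibility, file.path(out, "susceptibility_mask.nii.gz"),
             spec$voxel_size)
p1 <- which(res$included)[1]
ts1 <- res$tissue[[p1]]
lab <- array(0L, spec$grid_shape)
lab[ts1$nawm] <- 1L; lab[ts1$t2l] <- 2L; lab[ts1$t1l] <- 3L
write_volume(lab, file.path(out, "example_states.nii.gz"), spec$voxel_size)

say("included %d/%d patients (all states > 0.4 cm^3)",
    sum(vols$included), nrow(vols))
say("volumes: NAWM %.1f +/- %.1f, T2L %.1f +/- %.1f, T1L %.1f +/- %.1f cm3",
    mean(vols$nawm_cm3), sd(vols$nawm_cm3),
    mean(vols$t2l_cm3), sd(vols$t2l_cm3),
    mean(vols$t1l_cm3), sd(vols$t1l_cm3))
# classification accuracy against generator ground truth
pats <- cohort_patients(res$cohort)
acc <- sapply(seq_along(pats), function(i) {
  lesioned <- (pats[[i]]$true_labels >= 2L) & res$susceptibility
  if (!any(lesioned)) return(NA_real_)
  mean((res$tissue[[i]]$t1l == (pats[[i]]$true_labels == 3L & res$susceptibility))[lesioned])
})
say("voxel-level T1L/T2L classification accuracy vs ground truth: %.1f%%",
    100 * mean(acc, na.rm = TRUE))
say("wrote %s", out)
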