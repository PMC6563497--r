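#!/usr/bin/env Rscript
# Normative stage: voxel-wise control mean/SD maps per metric, z-score damage
# maps for every patient, and the standardisation QC (self-z-scoring the
# control cohort must give per-voxel mean 0 / SD 1).

# run from the repository root: Rscript analysis/02_normative_damage.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "02_normative")
dir.create(out, showWarnings = FALSE)

res <- get_run()
spec <- res$cohort$spec

qc <- do.call(rbind, lapply(res$models, function(m) {
  controls <- cohort_controls(res$cohort)
  zs <- sapply(controls, function(s) zscore_map(s$maps[[m$metric]], m))
  ok <- as.vector(m$valid)
  data.frame(metric = m$metric,
             n_valid_voxels = sum(m$valid),
             n_invalid_voxels = sum(!m$valid),
             sd_floor = m$sd_floor,
             selfz_mean_absmax = max(abs(rowMeans(zs)[ok])),
             selfz_sd_absdev = max(abs(apply(zs, 1, sd)[ok] - 1)))
}))
write.table(qc, file.path(out, "normative_qc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(qc, row.names = FALSE)

# example damage maps for the first patient
p1 <- which(res$included)[1]
for (m in spec$metrics)
  write_volume(res$damage[[p1]][[m]],
               file.path(out, sprintf("example_%s_z.nii.gz", m)), spec$voxel_size)

say("self-z QC: worst per-voxel mean deviation %.2e, worst SD deviation %.2e",
    max(qc$selfz_mean_absmax), max(qc$selfz_sd_absdev))
say("wrote %s", out)
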