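#!/usr/bin/env Rscript
# Composite damage score: pooled-voxel PCA over the four damage scores with
# KMO sampling adequacy, plus a desk reconstruction of the same quantities
# from the group-mean within-patient correlation matrix alone.

# run from the repository root: Rscript analysis/05_composite_pca.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "05_pca")
dir.create(out, showWarnings = FALSE)

res <- get_run()
spec <- res$cohort$spec
print(res$pca)

jsonlite::write_json(
  list(weights_pc1 = res$pca$weights[, 1],
       eigenvalues = res$pca$eigenvalues,
       variance_fraction = res$pca$variance_fraction,
       kmo = res$pca$kmo,
       n_retained_kaiser = res$pca$n_retained_kaiser,
       n_voxels = res$pca$n_voxels),
  file.path(out, "pca_model.json"), digits = NA, pretty = TRUE)

# desk reconstruction from the group-mean correlation matrix (the generator's
# coupling target): eigenstructure and KMO without any voxel data
R <- default_noise_correlation()
e <- eigen(R, symmetric = TRUE)
w <- e$vectors[, 1] * sign(e$vectors[4, 1])
say("desk check from the group-mean correlation matrix:")
say("  PC1 variance %.1f%%, KMO %.3f", 100 * e$values[1] / 4, kmo_index(R))
say("  weights: %s", paste(sprintf("%s %.2f", rownames(R), w), collapse = ", "))

# example component score map
p1 <- which(res$included)[1]
write_volume(res$score_maps[[p1]],
             file.path(out, "example_PCA_score.nii.gz"), spec$voxel_size)
say("wrote %s", out)
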