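## Composite damage score -----------------------------------------------------
##
## All patients' white-matter voxels are pooled across the damage scores and
## the first principal component of their correlation matrix serves as a
## single composite damage score, with the Kaiser-Meyer-Olkin index
## quantifying sampling adequacy.

#' Pool white-matter voxels across patients
#'
#' Stacks every patient's white-matter voxel values (one column per metric),
#' keeping provenance so score maps can be reconstructed. Voxels invalid in
#' any metric are dropped (complete-case pooling) and counted.
#'
#' @param damage_maps nested list `[[patient]][[metric]]` of z-score arrays.
#' @param wm_masks logical array or per-patient list.
#' @return list: `values` (voxel x metric matrix), `patient`, `voxel`
#'   (linear indices), `n_dropped`.
#' @export
pool_wm_voxels <- function(damage_maps, wm_masks) {
  n <- length(damage_maps)
  if (n == 0L) stop_wm("no patients to pool")
  mets <- names(damage_maps[[1]])
  if (is.array(wm_masks)) wm_masks <- rep(list(wm_masks), n)
  vals <- list(); pat <- list(); vox <- list(); dropped <- 0L
  for (i in seq_len(n)) {
    idx <- which(wm_masks[[i]])
    if (!length(idx)) stop_wm(sprintf("patient %d has an empty WM mask", i))
    m <- sapply(mets, function(met) damage_maps[[i]][[met]][idx])
    keep <- rowSums(!is.finite(m)) == 0
    dropped <- dropped + sum(!keep)
    vals[[i]] <- m[keep, , drop = FALSE]
    pat[[i]] <- rep(i, sum(keep))
    vox[[i]] <- idx[keep]
  }
  values <- do.call(rbind, vals)
  if (!nrow(values)) stop_wm("pooled voxel table is empty")
  list(values = values, patient = unlist(pat), voxel = unlist(vox),
       n_dropped = dropped)
}

#' Fit the pooled-voxel PCA
#'
#' Standardised (correlation-based) PCA of the pooled table: columns are
#' centred and scaled by the pooled mean/SD, the correlation matrix is
#' eigendecomposed, and the first component is sign-oriented so the
#' `orient_metric` weight is positive. Kaiser retention (eigenvalues > 1) is
#' reported; downstream analyses always use component 1.
#'
#' @param pooled a [pool_wm_voxels()] result (or bare matrix).
#' @param orient_metric metric whose first-component weight is forced
#'   positive; default `"MWF"` (falls back to the last column when absent).
#' @return object of class `wm_pca`: `weights` (full orthonormal matrix, PC1
#'   in column 1), `eigenvalues`, `variance_fraction`, `kmo`, `center`,
#'   `scale`, `correlation`, `n_retained_kaiser`, `n_voxels`.
#' @export
fit_pca <- function(pooled, orient_metric = "MWF") {
  x <- if (is.list(pooled)) pooled$values else pooled
  if (nrow(x) < 5L) stop_wm("PCA needs at least 5 pooled voxels")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) stop_wm("constant column in the pooled table")
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  w <- e$vectors
  dimnames(w) <- list(colnames(x), paste0("PC", seq_len(ncol(w))))
  j <- if (orient_metric %in% rownames(w)) orient_metric else nrow(w)
  for (c0 in seq_len(ncol(w))) if (w[j, c0] < 0) w[, c0] <- -w[, c0]
  kmo <- tryCatch(kmo_index(R), error = function(e) {
    message("KMO not computable for this pool: ", conditionMessage(e))
    NA_real_
  })
  structure(list(weights = w, eigenvalues = e$values,
                 variance_fraction = e$values / sum(e$values),
                 kmo = kmo,
                 center = ctr, scale = scl, correlation = R,
                 n_retained_kaiser = sum(e$values > 1),
                 n_voxels = nrow(x)),
            class = "wm_pca")
}

#' @export
print.wm_pca <- function(x, ...) {
  cat(sprintf("Pooled-voxel PCA over %d voxels\n", x$n_voxels))
  cat(sprintf("  PC1 explains %.1f%% of variance (KMO %.2f, %d component(s) with eigenvalue > 1)\n",
              100 * x$variance_fraction[1], x$kmo, x$n_retained_kaiser))
  cat("  PC1 weights:", paste(sprintf("%s %.2f", rownames(x$weights), x$weights[, 1]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Kaiser-Meyer-Olkin sampling adequacy index
#'
#' KMO = sum of squared off-diagonal correlations divided by that sum plus
#' the sum of squared off-diagonal anti-image partial correlations, the
#' partials being `p_ij = -inv_ij / sqrt(inv_ii inv_jj)` from the matrix
#' inverse. Undefined (NA, with a message) for a diagonal correlation matrix.
#'
#' @param correlation correlation matrix (invertible).
#' @return scalar in `[0, 1]`, or NA when undefined.
#' @export
kmo_index <- function(correlation) {
  inv <- tryCatch(solve(correlation),
                  error = function(e) stop_wm("correlation matrix is singular"))
  partial <- -inv / sqrt(outer(diag(inv), diag(inv)))
  off <- upper.tri(correlation)
  s_r <- sum(correlation[off]^2)
  if (s_r == 0) {
    message("KMO undefined: no off-diagonal correlation")
    return(NA_real_)
  }
  s_r / (s_r + sum(partial[off]^2))
}

#' Component score map for one patient
#'
#' Per-voxel weighted sum of the standardised metric values using the first
#' component's weights; NA wherever any metric is invalid.
#'
#' @param maps named list of z-score arrays (metrics matching the model).
#' @param model a [fit_pca()] result.
#' @return 3D score array.
#' @export
component_score_map <- function(maps, model) {
  mets <- rownames(model$weights)
  score <- array(0, dim(maps[[1]]))
  ok <- array(TRUE, dim(maps[[1]]))
  for (m in mets) {
    std <- (maps[[m]] - model$center[m]) / model$scale[m]
    ok <- ok & is.finite(std)
    std[!is.finite(std)] <- 0
    score <- score + model$weights[m, 1] * std
  }
  score[!ok] <- NA_real_
  score
}
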