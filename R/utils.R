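#' @keywords internal
"_PACKAGE"

## Internal helpers shared across the pipeline. All 3D volumes are plain R
## arrays; physical geometry (voxel size in mm per axis) is always passed
## explicitly so that distances are computed in mm, never in voxel units.

stop_wm <- function(...) stop(..., call. = FALSE)

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop_wm(sprintf("%s are on different grids: %s vs %s", what,
                    paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 3 || any(voxel_size <= 0))
    stop_wm("voxel_size must be three positive mm lengths")
  as.numeric(voxel_size)
}

#' Mask volume in cubic centimetres
#'
#' @param mask logical 3D array.
#' @param voxel_size mm per axis (length 3).
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  sum(mask, na.rm = TRUE) * prod(voxel_size) / 1000
}

## Integer voxel offsets whose centre-to-centre distance in mm is <= radius.
## Anisotropic voxels are handled by scaling each axis by its mm size.
ball_offsets <- function(radius_mm, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  r <- ceiling(radius_mm / voxel_size)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 + (g$dz * voxel_size[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

## Binary dilation of a mask by a physical radius: TRUE wherever the voxel
## centre lies within radius_mm of any seed voxel centre.
dilate_mm <- function(mask, radius_mm, voxel_size) {
  dm <- dim(mask)
  seeds <- which(mask)
  out <- array(FALSE, dm)
  if (length(seeds) == 0L) return(out)
  idx <- arrayInd(seeds, dm)
  off <- ball_offsets(radius_mm, voxel_size)
  for (k in seq_len(nrow(off))) {
    x <- idx[, 1] + off[k, 1]; y <- idx[, 2] + off[k, 2]; z <- idx[, 3] + off[k, 3]
    ok <- x >= 1 & x <= dm[1] & y >= 1 & y <= dm[2] & z >= 1 & z <= dm[3]
    if (any(ok)) out[cbind(x[ok], y[ok], z[ok])] <- TRUE
  }
  out
}

## 6-connected erosion depth: 1 for voxels on the mask surface, increasing
## inwards; 0 outside the mask. Used by the rater simulator.
erosion_depth <- function(mask) {
  dm <- dim(mask)
  depth <- array(0L, dm)
  cur <- mask
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    ## a voxel survives erosion if all 6 face neighbours are in the mask
    shift1 <- function(m, axis, by) {
      out <- array(FALSE, dm)
      src <- dst <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
      n <- dm[axis]
      if (by > 0) { dst[[axis]] <- seq(1 + by, n); src[[axis]] <- seq(1, n - by) }
      else        { dst[[axis]] <- seq(1, n + by); src[[axis]] <- seq(1 - by, n) }
      out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      out
    }
    core <- cur &
      shift1(cur, 1, 1) & shift1(cur, 1, -1) &
      shift1(cur, 2, 1) & shift1(cur, 2, -1) &
      shift1(cur, 3, 1) & shift1(cur, 3, -1)
    depth[cur & !core] <- d
    if (all(core == cur)) { depth[cur] <- pmax(depth[cur], d) ; break }
    cur <- core
  }
  depth
}

## Separable Gaussian smoothing of a 3D array, kernel width given as a
## standard deviation in mm per-axis (converted to voxels internally).
smooth_gaussian <- function(arr, sigma_mm, voxel_size) {
  voxel_size <- check_voxel_size(voxel_size)
  dm <- dim(arr)
  for (axis in 1:3) {
    s_vox <- sigma_mm / voxel_size[axis]
    if (s_vox < 1e-8) next
    half <- max(1L, ceiling(3 * s_vox))
    k <- stats::dnorm(-half:half, sd = s_vox)
    k <- k / sum(k)
    acc <- array(0, dm)
    n <- dm[axis]
    for (j in seq_along(k)) {
      by <- j - half - 1L
      src <- dst <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
      ## replicate-pad: clamp source indices at the volume edge
      ids <- pmin(pmax(seq_len(n) + by, 1L), n)
      src[[axis]] <- ids
      acc <- acc + k[j] * arr[src[[1]], src[[2]], src[[3]]]
    }
    arr <- acc
  }
  arr
}

## Fisher (arctanh) averaging of correlation coefficients; values clamped
## just inside (-1, 1) so a degenerate perfect correlation stays finite.
fisher_mean <- function(r) {
  r <- r[is.finite(r)]
  if (length(r) == 0L) return(NA_real_)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
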