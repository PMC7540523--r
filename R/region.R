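# MV vortex ring region: streamline seeding, growth on the divergence-free
# field, and pruning of outlier branches.

#' Streamline seed points around a vortex core
#'
#' The voxels containing the core points plus their 26-neighbourhoods,
#' restricted to the LV mask, returned as voxel-center positions.
#'
#' @param core a [VortexCore-class].
#' @param grid the [FlowGrid-class] of the working volume.
#' @param mask logical array on the grid (LV mask of the frame); seeds
#'   outside it are dropped.
#' @return M x 3 matrix of physical seed positions (mm); zero rows for an
#'   empty core.
#' @export
seedPoints <- function(core, grid, mask = NULL) {
  if (!nrow(core@points)) return(matrix(numeric(0), 0, 3))
  vox <- round(physicalToVoxel(grid, core@points))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  all <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
    sweep(vox, 2, offs[o, ], "+")))
  ok <- all[, 1] >= 1 & all[, 1] <= grid@shape[1] &
    all[, 2] >= 1 & all[, 2] <= grid@shape[2] &
    all[, 3] >= 1 & all[, 3] <= grid@shape[3]
  all <- unique(all[ok, , drop = FALSE])
  if (!is.null(mask)) {
    keep <- mask[all]
    all <- all[keep, , drop = FALSE]
  }
  voxelToPhysical(grid, all)
}

#' Grow the vortex ring region by streamlines
#'
#' From every seed a streamline of the (frame-frozen) divergence-free field
#' is integrated in both directions with 4th-order Runge-Kutta on trilinear
#' interpolation, step 0.5 x min spacing, until it reaches non-positive
#' interpolated Q, leaves the LV mask, or exceeds `maxLen` steps. Every
#' voxel entered along the way is marked; the region is the union of marked
#' voxels, restricted to voxels whose own Q is positive.
#'
#' @param seeds M x 3 matrix of physical seed positions (mm).
#' @param rField divergence-free vector volume `c(dims, 3)` (m/s).
#' @param qFrame scalar Q volume.
#' @param mask logical array (LV mask of the frame).
#' @param grid the (cropped) [FlowGrid-class] of the volumes.
#' @param maxLen maximal steps per direction.
#' @param frame frame index stored in the result.
#' @return a [VortexRegion-class] with voxel indices on `grid`.
#' @export
growRegion <- function(seeds, rField, qFrame, mask, grid, maxLen = 1000L,
                       frame = 1L) {
  dims <- grid@shape
  if (!nrow(seeds)) {
    return(new("VortexRegion", voxels = matrix(integer(0), 0, 3),
               frame = as.integer(frame)))
  }
  lin <- grow_region_cpp(as.numeric(rField), as.numeric(qFrame),
                         as.logical(mask), as.integer(dims),
                         as.numeric(grid@spacing), as.numeric(grid@origin),
                         as.matrix(seeds), 0.5 * min(grid@spacing),
                         as.integer(maxLen))
  keep <- lin[qFrame[lin] > 0]
  new("VortexRegion", voxels = arrayInd(keep, dims),
      frame = as.integer(frame))
}

#' Prune outlier streamline branches from a region
#'
#' Iteratively removes voxels with fewer than `minNeighbors` occupied
#' 26-neighbours until a fixpoint is reached. Each iteration is a
#' simultaneous sweep (all under-connected voxels of the current set are
#' removed together), which makes the result independent of voxel order.
#' The default of 8 neighbours removes 1-voxel-wide branches formed by
#' outlier streamlines while retaining the solid ring.
#'
#' @param voxelIdx M x 3 matrix of 1-based voxel indices (or a
#'   [VortexRegion-class]).
#' @param dims grid dimensions the indices refer to (unused when a region
#'   is given -- any bounding dims work since only adjacency matters).
#' @param minNeighbors removal threshold on occupied 26-neighbours.
#' @return matrix of retained voxels (or a [VortexRegion-class] when one
#'   was given); possibly empty.
#' @export
pruneRegion <- function(voxelIdx, dims = NULL, minNeighbors = 8L) {
  isRegion <- is(voxelIdx, "VortexRegion")
  vox <- if (isRegion) voxelIdx@voxels else voxelIdx
  if (nrow(vox)) {
    if (is.null(dims)) dims <- apply(vox, 2, max) + 1L
    repeat {
      if (!nrow(vox)) break
      lin <- vox[, 1] + (vox[, 2] - 1L) * dims[1] +
        (vox[, 3] - 1L) * dims[1] * dims[2]
      occ <- logical(prod(dims))
      occ[lin] <- TRUE
      cnt <- integer(nrow(vox))
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ni <- vox[, 1] + di; nj <- vox[, 2] + dj; nk <- vox[, 3] + dk
        ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
          nk >= 1L & nk <= dims[3]
        nlin <- ni[ok] + (nj[ok] - 1L) * dims[1] +
          (nk[ok] - 1L) * dims[1] * dims[2]
        cnt[ok] <- cnt[ok] + occ[nlin]
      }
      keep <- cnt >= minNeighbors
      if (all(keep)) break
      vox <- vox[keep, , drop = FALSE]
    }
  }
  if (isRegion) {
    voxelIdx@voxels <- vox
    voxelIdx
  } else vox
}
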