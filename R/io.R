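# Volume and result I/O: NIfTI velocity/mask series, bounding box, result
# export (regions as NIfTI, cores as JSON, parameters as CSV), YAML config.

#' Load a velocity series
#'
#' Accepts, in order of preference: a character vector of per-frame NIfTI
#' files each holding a `c(nx, ny, nz, 3)` volume; a list with components
#' `vx`, `vy`, `vz`, each a character vector of per-frame scalar NIfTI
#' files; a single 5D NIfTI file of dim `c(nx, ny, nz, N, 3)`; or an
#' in-memory list of `c(nx, ny, nz, 3)` arrays. Values are converted to SI
#' (m/s) on load according to the declared unit.
#'
#' @param velocityPaths file paths or arrays as described.
#' @param config list with at least `units` (`"m/s"` or `"cm/s"`); optional
#'   `spacing` (mm), `origin` (mm) and `frameDuration` (ms) override the
#'   NIfTI header geometry.
#' @return a [VelocitySeries-class] in m/s.
#' @export
loadVelocitySeries <- function(velocityPaths, config = list()) {
  units <- config$units %||% "m/s"
  stopifnot(units %in% c("m/s", "cm/s"))
  hdrSpacing <- NULL
  if (is.list(velocityPaths) && !is.null(velocityPaths$vx)) {
    nf <- length(velocityPaths$vx)
    stopifnot(length(velocityPaths$vy) == nf, length(velocityPaths$vz) == nf)
    frames <- vector("list", nf)
    for (i in seq_len(nf)) {
      comp <- lapply(c("vx", "vy", "vz"), function(cn) {
        v <- RNifti::readNifti(velocityPaths[[cn]][i])
        if (i == 1L && cn == "vx") hdrSpacing <<- RNifti::pixdim(v)[1:3]
        array(as.numeric(v), dim(v)[1:3])
      })
      frames[[i]] <- array(unlist(comp), c(dim(comp[[1]]), 3L))
    }
  } else if (is.character(velocityPaths) && length(velocityPaths) == 1L) {
    v <- RNifti::readNifti(velocityPaths)
    hdrSpacing <- RNifti::pixdim(v)[1:3]
    a <- array(as.numeric(v), dim(v))
    if (length(dim(a)) == 4L && dim(a)[4] == 3L) {
      frames <- list(a)
    } else {
      stopifnot(length(dim(a)) == 5L, dim(a)[5] == 3L)
      frames <- lapply(seq_len(dim(a)[4]), function(i) a[, , , i, ])
    }
  } else if (is.character(velocityPaths)) {
    frames <- lapply(seq_along(velocityPaths), function(i) {
      v <- RNifti::readNifti(velocityPaths[i])
      if (i == 1L) hdrSpacing <<- RNifti::pixdim(v)[1:3]
      a <- array(as.numeric(v), dim(v))
      stopifnot(length(dim(a)) == 4L, dim(a)[4] == 3L)
      a
    })
  } else {
    stopifnot(is.list(velocityPaths))
    frames <- velocityPaths
  }
  shp <- dim(frames[[1]])[1:3]
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]])[1:3], shp) ||
        length(dim(frames[[i]])) != 4L || dim(frames[[i]])[4] != 3L)
      stop("frame ", i, " has a different shape than frame 1")
    if (!all(is.finite(frames[[i]])))
      stop("frame ", i, " contains non-finite velocity values")
  }
  if (units == "cm/s") frames <- lapply(frames, function(f) f / 100)
  spacing <- config$spacing %||% hdrSpacing %||% c(1, 1, 1)
  grid <- FlowGrid(shp, spacing = spacing,
                   origin = config$origin %||% c(0, 0, 0),
                   frameDuration = config$frameDuration %||% 33,
                   nFrames = length(frames))
  VelocitySeries(grid, frames, unitsIn = units)
}

#' Load a mask series
#'
#' Per-frame NIfTI scalar volumes (or one 4D volume, or in-memory arrays),
#' binarized by thresholding at 0.5. Empty frames raise a warning; an
#' all-empty series is rejected.
#'
#' @param maskPaths file paths or arrays.
#' @param grid the [FlowGrid-class] the masks must match.
#' @return a [MaskSeries-class] with provenance `"reference"`.
#' @export
loadMaskSeries <- function(maskPaths, grid) {
  if (is.character(maskPaths) && length(maskPaths) == 1L) {
    v <- RNifti::readNifti(maskPaths)
    a <- array(as.numeric(v), dim(v))
    frames <- if (length(dim(a)) == 4L)
      lapply(seq_len(dim(a)[4]), function(i) a[, , , i]) else list(a)
  } else if (is.character(maskPaths)) {
    frames <- lapply(maskPaths, function(p) {
      v <- RNifti::readNifti(p)
      array(as.numeric(v), dim(v)[1:3])
    })
  } else {
    frames <- maskPaths
  }
  frames <- lapply(frames, function(m) {
    if (!identical(dim(m)[1:3], grid@shape))
      stop("mask shape does not match the grid")
    array(m > 0.5, grid@shape)
  })
  empt <- vapply(frames, function(m) !any(m), logical(1))
  if (all(empt)) stop("all mask frames are empty")
  if (any(empt)) warning("empty mask in frame(s) ",
                         paste(which(empt), collapse = ", "))
  g <- grid
  g@nFrames <- length(frames)
  MaskSeries(g, frames, provenance = "reference")
}

#' Bounding box around the segmented LV
#'
#' Smallest axis-aligned box containing the union of all mask frames,
#' expanded by `margin` voxels per axis and clipped to the grid. Returned
#' half-open in 0-based indices.
#'
#' @param masks a [MaskSeries-class].
#' @param margin voxels added on each side per axis.
#' @return a [BoundingBox-class].
#' @export
boundingBox <- function(masks, margin = 2L) {
  un <- Reduce(`|`, masks@frames)
  if (!any(un)) stop("all mask frames are empty")
  idx <- arrayInd(which(un), dim(un))
  lo <- apply(idx, 2, min) - 1L # to 0-based
  hi <- apply(idx, 2, max)      # 0-based exclusive = 1-based max
  lo <- pmax(lo - margin, 0L)
  hi <- pmin(hi + margin, masks@grid@shape)
  BoundingBox(lo, hi)
}

#' Export extraction results
#'
#' Writes per-frame ring region masks as NIfTI volumes
#' (`region_frame###.nii.gz`, 1 inside the region), the core polylines with
#' shape and membership attributes as JSON (`cores.json`), and the
#' parameter table as `params.csv` with one row per frame and columns
#' `frame, present, vol_mL, vort_max_s1, vort_mean_s1, ekin_abs_mJ,
#' ekin_rel_Jm3, alpha_deg, ci`.
#'
#' @param cores per-frame list of [VortexCore-class] or `NULL`.
#' @param regions per-frame list of [VortexRegion-class] or `NULL`
#'   (full-grid voxel indices).
#' @param params per-frame parameter data.frame.
#' @param outDir output directory (created if needed).
#' @param grid the full [FlowGrid-class].
#' @return invisibly, the paths written.
#' @export
exportResults <- function(cores, regions, params, outDir, grid) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  paths <- character(0)
  p <- file.path(outDir, "params.csv")
  utils::write.csv(params, p, row.names = FALSE)
  paths <- c(paths, p)
  for (f in seq_along(regions)) {
    rg <- regions[[f]]
    if (is.null(rg) || !nrow(rg@voxels)) next
    vol <- array(0L, grid@shape)
    vol[rg@voxels] <- 1L
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- grid@spacing
    fp <- file.path(outDir, sprintf("region_frame%03d.nii.gz", f))
    RNifti::writeNifti(img, fp)
    paths <- c(paths, fp)
  }
  cj <- lapply(seq_along(cores), function(f) {
    cl <- cores[[f]]
    if (is.null(cl)) return(NULL)
    list(frame = f, shape = cl@shape, closed = cl@closed,
         is_mv_ring = cl@isMVRing, major_axis_mm = cl@majorAxis,
         minor_axis_mm = cl@minorAxis, centroid_mm = cl@centroid,
         points_mm = cl@points)
  })
  fp <- file.path(outDir, "cores.json")
  jsonlite::write_json(cj[!vapply(cj, is.null, logical(1))], fp,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, fp))
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [mvringConfig()]
#' defaults.
#'
#' @param path YAML file.
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(mvringConfig, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
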