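#' @name accessors
#' @title Accessors for mvring data objects
#'
#' @description Small accessor generics: grid geometry, frame access, voxel
#' sets and physical coordinates. Slot access from user code should go
#' through these.
#'
#' @param x an mvring object.
#' @param i frame index.
NULL

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("corePoints", function(x) standardGeneric("corePoints"))
#' @rdname accessors
#' @export
setGeneric("coreShape", function(x) standardGeneric("coreShape"))
#' @rdname accessors
#' @export
setGeneric("isMVRing", function(x) standardGeneric("isMVRing"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("vortexFrames", function(x) standardGeneric("vortexFrames"))
#' @rdname accessors
#' @export
setGeneric("peakFrames", function(x) standardGeneric("peakFrames"))
#' @rdname accessors
#' @export
setGeneric("qThresholds", function(x) standardGeneric("qThresholds"))
#' @rdname accessors
#' @export
setGeneric("maxQCurve", function(x) standardGeneric("maxQCurve"))
#' @rdname accessors
#' @export
setGeneric("ringParams", function(x) standardGeneric("ringParams"))
#' @rdname accessors
#' @export
setGeneric("ringPresence", function(x) standardGeneric("ringPresence"))
#' @rdname accessors
#' @export
setGeneric("ringPeaks", function(x) standardGeneric("ringPeaks"))

#' @rdname accessors
setMethod("gridShape", "FlowGrid", function(x) x@shape)
#' @rdname accessors
setMethod("gridSpacing", "FlowGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "FlowGrid", function(x) x@origin)
#' @rdname accessors
setMethod("nFrames", "FlowGrid", function(x) x@nFrames)
#' @rdname accessors
setMethod("frameDuration", "FlowGrid", function(x) x@frameDuration)

for (cl in c("VelocitySeries", "MaskSeries", "QSeries")) {
  setMethod("gridShape", cl, function(x) x@grid@shape)
  setMethod("gridSpacing", cl, function(x) x@grid@spacing)
  setMethod("gridOrigin", cl, function(x) x@grid@origin)
  setMethod("nFrames", cl, function(x) x@grid@nFrames)
  setMethod("frameDuration", cl, function(x) x@grid@frameDuration)
}

#' @rdname accessors
setMethod("getFrame", "VelocitySeries", function(x, i) x@frames[[i]])
#' @rdname accessors
setMethod("getFrame", "MaskSeries", function(x, i) x@frames[[i]])
#' @rdname accessors
setMethod("getFrame", "QSeries", function(x, i) x@qFrames[[i]])

#' @rdname accessors
setMethod("provenance", "MaskSeries", function(x) x@provenance)
#' @rdname accessors
setMethod("voxels", "VortexRegion", function(x) x@voxels)
#' @rdname accessors
setMethod("voxels", "VortexCandidate", function(x) x@voxels)
#' @rdname accessors
setMethod("corePoints", "VortexCore", function(x) x@points)
#' @rdname accessors
setMethod("coreShape", "VortexCore", function(x) x@shape)
#' @rdname accessors
setMethod("isMVRing", "VortexCore", function(x) x@isMVRing)
#' @rdname accessors
setMethod("vortexFrames", "QSeries", function(x) x@vortexFrames)
#' @rdname accessors
setMethod("peakFrames", "QSeries", function(x) x@peakFrames)
#' @rdname accessors
setMethod("qThresholds", "QSeries", function(x) x@thresholds)
#' @rdname accessors
setMethod("maxQCurve", "QSeries", function(x) x@maxCurve)

#' @rdname accessors
setMethod("ringParams", "MVRingResult", function(x) x@params)
#' @rdname accessors
setMethod("ringPresence", "MVRingResult", function(x) x@presence)
#' @rdname accessors
setMethod("ringPeaks", "MVRingResult", function(x) x@peaks)
#' @rdname accessors
setMethod("vortexFrames", "MVRingResult", function(x) x@qseries@vortexFrames)
#' @rdname accessors
setMethod("peakFrames", "MVRingResult", function(x) x@qseries@peakFrames)

# ---- coordinate helpers ----------------------------------------------------

#' Physical voxel-center positions
#'
#' Converts 1-based voxel indices to physical positions in mm using the
#' voxel-center convention (`origin + (index - 1) * spacing`).
#'
#' @param grid a [FlowGrid-class].
#' @param idx M x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return M x 3 matrix of positions in mm.
#' @export
voxelToPhysical <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  sweep(sweep(idx - 1, 2, grid@spacing, "*"), 2, grid@origin, "+")
}

#' Continuous voxel coordinates of physical points
#'
#' Inverse of [voxelToPhysical()]; returns fractional 1-based voxel
#' coordinates.
#'
#' @param grid a [FlowGrid-class].
#' @param pts M x 3 matrix of positions in mm.
#' @export
physicalToVoxel <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  sweep(sweep(pts, 2, grid@origin, "-"), 2, grid@spacing, "/") + 1
}

#' Crop a grid to a bounding box
#'
#' Returns the [FlowGrid-class] of the sub-volume covered by `box`, with the
#' origin shifted so physical coordinates are unchanged.
#'
#' @param grid a [FlowGrid-class].
#' @param box a [BoundingBox-class].
#' @export
cropGrid <- function(grid, box) {
  FlowGrid(box@upper - box@lower,
           spacing = grid@spacing,
           origin = grid@origin + box@lower * grid@spacing,
           frameDuration = grid@frameDuration,
           nFrames = grid@nFrames)
}

#' 1-based index ranges of a bounding box
#'
#' @param box a [BoundingBox-class].
#' @return list of three integer ranges, one per axis.
#' @export
boxRanges <- function(box) {
  lapply(1:3, function(a) (box@lower[a] + 1L):box@upper[a])
}

# crop one 3D (or 4D vector) array to a box
.cropArray <- function(arr, box) {
  rg <- boxRanges(box)
  if (length(dim(arr)) == 4L) arr[rg[[1]], rg[[2]], rg[[3]], , drop = FALSE]
  else arr[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "FlowGrid", function(object) {
  cat(sprintf("FlowGrid: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d frames (dt = %.3g ms)\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@nFrames, object@frameDuration))
})

setMethod("show", "VelocitySeries", function(object) {
  rng <- range(vapply(object@frames, function(f) max(abs(f)), numeric(1)))
  cat(sprintf("VelocitySeries: %d frames, |v|max per frame in [%.3g, %.3g] m/s (input %s)\n",
              length(object@frames), rng[1], rng[2], object@unitsIn))
  show(object@grid)
})

setMethod("show", "MaskSeries", function(object) {
  cnt <- vapply(object@frames, sum, numeric(1))
  cat(sprintf("MaskSeries [%s]: %d frames, %d-%d voxels per frame\n",
              object@provenance, length(object@frames), min(cnt), max(cnt)))
  show(object@grid)
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox: [%d,%d) x [%d,%d) x [%d,%d) (0-based, half-open)\n",
              object@lower[1], object@upper[1], object@lower[2],
              object@upper[2], object@lower[3], object@upper[3]))
})

setMethod("show", "QSeries", function(object) {
  cat(sprintf("QSeries: %d frames on box; vortex window %s; peaks %s\n",
              object@grid@nFrames,
              if (length(object@vortexFrames))
                paste0(object@vortexFrames[1], "..",
                       object@vortexFrames[length(object@vortexFrames)])
              else "(none)",
              paste(object@peakFrames, collapse = ", ")))
})

setMethod("show", "VortexCore", function(object) {
  cat(sprintf("VortexCore (frame %d): %d points, shape %s%s, major/minor = %.1f/%.1f mm%s\n",
              object@frame, nrow(object@points), object@shape,
              if (isTRUE(object@closed)) " (closed)" else "",
              object@majorAxis, object@minorAxis,
              if (isTRUE(object@isMVRing)) ", MV ring" else ""))
})

setMethod("show", "VortexRegion", function(object) {
  cat(sprintf("VortexRegion (frame %d): %d voxels\n",
              object@frame, nrow(object@voxels)))
})

setMethod("show", "RingSpec", function(object) {
  cat(sprintf("RingSpec: R = %.1f mm, a = %.1f mm, Gamma = %.3g m^2/s, %d-frame amplitude curve\n",
              object@radius, object@coreRadius, object@circulation,
              length(object@amplitudeCurve)))
})

setMethod("show", "ConfusionMatrix2x2", function(object) {
  cat("ConfusionMatrix2x2 (rows: automated, cols: reference)\n")
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(c("absent", "present"), c("absent", "present")))
  print(m)
})

setMethod("show", "MVRingResult", function(object) {
  per <- rle(object@presence)
  nper <- sum(per$values)
  cat(sprintf("MVRingResult: MV ring present in %d/%d frames (%d period%s)\n",
              sum(object@presence), length(object@presence), nper,
              if (nper == 1) "" else "s"))
  show(object@qseries)
})
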