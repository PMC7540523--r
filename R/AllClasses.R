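#' @import methods
NULL

#' Sampling grid of a 4D-flow acquisition
#'
#' `FlowGrid` records the voxel lattice and timing of a time-resolved
#' three-directional velocity acquisition: the volume dimensions, the
#' (generally anisotropic) voxel spacing, the physical position of the first
#' voxel center, the duration of one cardiac frame and the number of frames.
#'
#' Physical coordinates follow the voxel-center convention:
#' `position = origin + (index - 1) * spacing` for 1-based voxel indices, with
#' spacing and origin in millimetres.
#'
#' @slot shape integer(3), volume dimensions (nx, ny, nz); each >= 3 so that
#'   central differences have an interior.
#' @slot spacing numeric(3), voxel spacing in mm per axis; all > 0.
#' @slot origin numeric(3), physical position (mm) of voxel (1, 1, 1).
#' @slot frameDuration numeric(1), time between cardiac frames in ms.
#' @slot nFrames integer(1), number of cardiac frames N (>= 1).
#'
#' @examples
#' FlowGrid(c(64L, 64L, 40L), spacing = c(1.8, 2.5, 4), nFrames = 30L)
#' @export
setClass("FlowGrid", representation(
  shape = "integer",
  spacing = "numeric",
  origin = "numeric",
  frameDuration = "numeric",
  nFrames = "integer"
))

setValidity("FlowGrid", function(object) {
  msg <- character(0)
  if (length(object@shape) != 3L || any(object@shape < 3L))
    msg <- c(msg, "'shape' must be three integers >= 3")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive lengths (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite 3-vector (mm)")
  if (length(object@frameDuration) != 1L || object@frameDuration <= 0)
    msg <- c(msg, "'frameDuration' must be a positive time (ms)")
  if (length(object@nFrames) != 1L || object@nFrames < 1L)
    msg <- c(msg, "'nFrames' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param shape integer(3) volume dimensions.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) position of the first voxel center in mm.
#' @param frameDuration frame duration in ms.
#' @param nFrames number of cardiac frames.
#' @rdname FlowGrid-class
#' @export
FlowGrid <- function(shape, spacing, origin = c(0, 0, 0),
                     frameDuration = 33, nFrames = 1L) {
  new("FlowGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin), frameDuration = as.numeric(frameDuration),
      nFrames = as.integer(nFrames))
}

#' Time series of three-directional velocity volumes
#'
#' One 3-component vector volume per cardiac frame. Velocities are stored in
#' SI units (m/s) regardless of the declared input unit; [loadVelocitySeries()]
#' converts cm/s input on read.
#'
#' @slot grid a [FlowGrid-class] object.
#' @slot frames list of N arrays, each with dim `c(shape, 3)`, in m/s.
#' @slot unitsIn declared unit of the source data, `"m/s"` or `"cm/s"`.
#' @export
setClass("VelocitySeries", representation(
  grid = "FlowGrid",
  frames = "list",
  unitsIn = "character"
))

setValidity("VelocitySeries", function(object) {
  msg <- character(0)
  if (length(object@frames) != object@grid@nFrames)
    msg <- c(msg, "number of frames does not match grid@nFrames")
  want <- c(object@grid@shape, 3L)
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.array(f) || !identical(dim(f), want))
      msg <- c(msg, sprintf("frame %d has wrong shape", i))
    else if (!all(is.finite(f)))
      msg <- c(msg, sprintf("frame %d contains non-finite velocities", i))
  }
  if (!object@unitsIn %in% c("m/s", "cm/s"))
    msg <- c(msg, "unitsIn must be 'm/s' or 'cm/s'")
  if (length(msg)) msg[seq_len(min(3, length(msg)))] else TRUE
})

#' @param grid,frames,unitsIn slots of the class.
#' @rdname VelocitySeries-class
#' @export
VelocitySeries <- function(grid, frames, unitsIn = "m/s") {
  new("VelocitySeries", grid = grid, frames = frames, unitsIn = unitsIn)
}

#' Per-frame binary left-ventricle masks
#'
#' Binary LV segmentation masks aligned with the velocity grid, one per
#' cardiac frame. `provenance` records how the mask series was produced,
#' mirroring the segmentation-sensitivity experiment conditions.
#'
#' @slot grid a [FlowGrid-class].
#' @slot frames list of N logical arrays of dim `shape`.
#' @slot provenance one of `"reference"`, `"subsampled-kd"`,
#'   `"static-end-dia"`, `"eroded"`, `"dilated"`, `"synthetic"`.
#' @export
setClass("MaskSeries", representation(
  grid = "FlowGrid",
  frames = "list",
  provenance = "character"
))

.maskProvenance <- c("reference", "subsampled-kd", "static-end-dia",
                     "eroded", "dilated", "synthetic")

setValidity("MaskSeries", function(object) {
  msg <- character(0)
  if (length(object@frames) != object@grid@nFrames)
    msg <- c(msg, "number of mask frames does not match grid@nFrames")
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.array(f) || !identical(dim(f), object@grid@shape) || !is.logical(f))
      msg <- c(msg, sprintf("mask frame %d must be a logical array of grid shape", i))
  }
  if (!object@provenance %in% .maskProvenance)
    msg <- c(msg, paste("provenance must be one of:",
                        paste(.maskProvenance, collapse = ", ")))
  if (length(msg)) msg[seq_len(min(3, length(msg)))] else TRUE
})

#' @param grid,frames,provenance slots of the class.
#' @rdname MaskSeries-class
#' @export
MaskSeries <- function(grid, frames, provenance = "reference") {
  new("MaskSeries", grid = grid, frames = frames, provenance = provenance)
}

#' Axis-aligned voxel bounding box
#'
#' Half-open box `[lower, upper)` in 0-based voxel indices, i.e. the box
#' contains voxels with 0-based index `lower <= i < upper` per axis
#' (equivalently 1-based R indices `lower + 1` to `upper`).
#'
#' @slot lower integer(3), inclusive 0-based lower corner.
#' @slot upper integer(3), exclusive 0-based upper corner.
#' @export
setClass("BoundingBox", representation(lower = "integer", upper = "integer"))

setValidity("BoundingBox", function(object) {
  if (length(object@lower) != 3L || length(object@upper) != 3L)
    return("lower/upper must be integer(3)")
  if (any(object@lower < 0L) || any(object@upper <= object@lower))
    return("need 0 <= lower < upper per axis")
  TRUE
})

#' @param lower,upper 0-based inclusive/exclusive corners.
#' @rdname BoundingBox-class
#' @export
BoundingBox <- function(lower, upper) {
  new("BoundingBox", lower = as.integer(lower), upper = as.integer(upper))
}

#' Vector-potential solution of the curl-curl system
#'
#' Result of the discrete Helmholtz-Hodge extraction on a bounding box: the
#' vector potential (zero-clamped on the box boundary shell), the
#' divergence-free field reconstructed as its discrete curl, and the achieved
#' relative least-squares residual of the curl-curl solve.
#'
#' @slot psi array `c(box dims, 3)`, vector potential.
#' @slot r array `c(box dims, 3)`, divergence-free field, the discrete curl of `psi`.
#' @slot residual achieved relative residual (dimensionless).
#' @slot iterations LSQR iterations used.
#' @export
setClass("HodgeSolution", representation(
  psi = "array", r = "array", residual = "numeric", iterations = "integer"))

#' Q-criterion series with thresholds and the vortex-frame window
#'
#' Per-frame scalar Q fields on the LV bounding box after filtering and
#' masking, together with the frame-specific thresholds, the curve of
#' per-frame Q maxima and its argmax locations, the cyclically contiguous
#' vortex-frame window, and the two peak frames (E and A) of the maximum-Q
#' time curve.
#'
#' @slot grid cropped [FlowGrid-class] of the bounding box.
#' @slot box the [BoundingBox-class] in the full grid.
#' @slot qFrames list of N scalar volumes (s^-2) on the box.
#' @slot thresholds numeric(N), frame-specific thresholds thr_i (s^-2).
#' @slot maxCurve numeric(N), per-frame maximum of masked Q.
#' @slot maxLocations N x 3 matrix of 1-based box voxel indices of the
#'   per-frame Q maxima.
#' @slot vortexFrames integer vector of frame indices in cyclic order forming
#'   the vortex-frame window.
#' @slot peakFrames integer(2), E- and A-peak frame indices (window order).
#' @export
setClass("QSeries", representation(
  grid = "FlowGrid", box = "BoundingBox", qFrames = "list",
  thresholds = "numeric", maxCurve = "numeric", maxLocations = "matrix",
  vortexFrames = "integer", peakFrames = "integer"))

setValidity("QSeries", function(object) {
  n <- object@grid@nFrames
  msg <- character(0)
  if (length(object@qFrames) != n) msg <- c(msg, "qFrames length != nFrames")
  if (length(object@thresholds) != n || any(object@thresholds < 0))
    msg <- c(msg, "thresholds must be N non-negative values")
  if (length(object@maxCurve) != n) msg <- c(msg, "maxCurve length != nFrames")
  if (length(object@peakFrames) &&
      !all(object@peakFrames %in% object@vortexFrames))
    msg <- c(msg, "peak frames must lie inside the vortex-frame window")
  if (length(msg)) msg else TRUE
})

#' Connected vortex candidate region
#'
#' A 26-connected voxel component of the thresholded Q field, with its
#' candidate factor (the MV-ring membership score), the maximal long-axis
#' projected distance to the first-principal-component maximum, and the
#' physical centroid.
#'
#' @slot voxels M x 3 matrix of 1-based box voxel indices.
#' @slot fc candidate factor (1/mm scale, dimensionless score).
#' @slot dMax maximal long-axis-projected distance to the w1 maximum (mm).
#' @slot centroid physical centroid (mm).
#' @slot frame frame index.
#' @export
setClass("VortexCandidate", representation(
  voxels = "matrix", fc = "numeric", dMax = "numeric",
  centroid = "numeric", frame = "integer"))

#' Traced vortex core line
#'
#' Ordered sub-voxel polyline of the vortex core with its shape label,
#' closure flag, ellipsoid axis lengths and MV-ring membership flag.
#'
#' @slot points P x 3 matrix of physical positions (mm).
#' @slot shape one of `"torus"`, `"U"`, `"bracket"`, `"none"`.
#' @slot closed logical; `TRUE` for a closed ring (always for torus).
#' @slot frame frame index.
#' @slot isMVRing logical membership flag set by temporal tracking.
#' @slot majorAxis,minorAxis largest and second-largest principal axis
#'   lengths (mm) of an ellipsoid fitted to the core points.
#' @slot centroid physical centroid (mm).
#' @export
setClass("VortexCore", representation(
  points = "matrix", shape = "character", closed = "logical",
  frame = "integer", isMVRing = "logical",
  majorAxis = "numeric", minorAxis = "numeric", centroid = "numeric"))

setValidity("VortexCore", function(object) {
  msg <- character(0)
  if (!object@shape %in% c("torus", "U", "bracket", "none"))
    msg <- c(msg, "invalid shape label")
  if (identical(object@shape, "torus") && !isTRUE(object@closed))
    msg <- c(msg, "torus cores must be closed")
  if (length(object@majorAxis) && length(object@minorAxis) &&
      (object@minorAxis > object@majorAxis || object@minorAxis < 0))
    msg <- c(msg, "need majorAxis >= minorAxis >= 0")
  if (length(msg)) msg else TRUE
})

#' MV vortex ring region
#'
#' Voxel set of the ring region in one frame, grown from streamlines seeded
#' near the core. Voxels are stored as 1-based indices into the full grid.
#'
#' @slot voxels M x 3 matrix of 1-based full-grid voxel indices.
#' @slot frame frame index.
#' @export
setClass("VortexRegion", representation(voxels = "matrix", frame = "integer"))

#' Analytic vortex-ring specification for the flow phantom
#'
#' Geometry and strength of a circular vortex filament with a Gaussian
#' (Lamb-Oseen-like) regularized core, plus the per-frame amplitude
#' modulation of its circulation over the cardiac cycle.
#'
#' @slot center ring center (mm).
#' @slot normal unit normal of the ring plane.
#' @slot radius ring radius R (mm).
#' @slot coreRadius core regularization radius a (mm), 0 < a < R.
#' @slot circulation circulation Gamma (m^2/s) at amplitude 1.
#' @slot amplitudeCurve numeric(N) in \[0, 1\], per-frame scaling of Gamma.
#' @export
setClass("RingSpec", representation(
  center = "numeric", normal = "numeric", radius = "numeric",
  coreRadius = "numeric", circulation = "numeric",
  amplitudeCurve = "numeric"))

setValidity("RingSpec", function(object) {
  msg <- character(0)
  if (!(object@radius > object@coreRadius && object@coreRadius > 0))
    msg <- c(msg, "need radius > coreRadius > 0")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    msg <- c(msg, "normal must be a unit vector")
  if (any(object@amplitudeCurve < 0) || any(object@amplitudeCurve > 1))
    msg <- c(msg, "amplitudeCurve values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param center,normal,radius,coreRadius,circulation,amplitudeCurve slots
#'   of the class; the normal is normalized.
#' @rdname RingSpec-class
#' @export
RingSpec <- function(center, normal, radius, coreRadius, circulation,
                     amplitudeCurve) {
  n <- as.numeric(normal); n <- n / sqrt(sum(n^2))
  new("RingSpec", center = as.numeric(center), normal = n,
      radius = as.numeric(radius), coreRadius = as.numeric(coreRadius),
      circulation = as.numeric(circulation),
      amplitudeCurve = as.numeric(amplitudeCurve))
}

#' Ground truth of a synthetic flow phantom
#'
#' Recorded before any contamination is added: the analytic core circle per
#' frame, the true ring region (voxels where the clean-field Q is positive),
#' per-frame presence flags and the LV long-axis direction.
#'
#' @slot coreCircles per-frame list; each entry `NULL` (ring absent) or a
#'   list with `center`, `normal`, `radius` (mm).
#' @slot regionTruth per-frame list of M x 3 matrices of 1-based full-grid
#'   voxel indices (true ring region), or `NULL`.
#' @slot presence logical(N); `TRUE` iff the ring amplitude is positive.
#' @slot longAxis unit 3-vector, LV long-axis direction.
#' @export
setClass("PhantomTruth", representation(
  coreCircles = "list", regionTruth = "list", presence = "logical",
  longAxis = "numeric"))

#' Tunables of the predictor-corrector core tracer
#'
#' All lengths in mm. Defaults are derived from the grid spacing by
#' [traceConfig()]; every value is configurable.
#'
#' @slot step predictor step size.
#' @slot patternMesh0 initial pattern-search mesh size.
#' @slot patternMeshMin final pattern-search mesh size.
#' @slot patternRadius search radius around the predictor point.
#' @slot closeTol closure distance to the start point / forward line.
#' @slot stuckTol minimal displacement below which the trace is stuck.
#' @slot maxSteps maximal number of corrector points per direction.
#' @slot minLoopSteps minimal steps before closure is accepted.
#' @slot uTurnDeg total turning angle (degrees) required for a U shape.
#' @slot bracketGap endpoint gap (mm) for the two-line bracket test.
#' @slot trackDist maximal centroid displacement (mm) between frames for
#'   MV-ring membership.
#' @slot trackAxisChange maximal relative major-axis change between frames.
#' @export
setClass("TraceConfig", representation(
  step = "numeric", patternMesh0 = "numeric", patternMeshMin = "numeric",
  patternRadius = "numeric", closeTol = "numeric", stuckTol = "numeric",
  maxSteps = "integer", minLoopSteps = "integer", uTurnDeg = "numeric",
  bracketGap = "numeric", trackDist = "numeric", trackAxisChange = "numeric"))

setValidity("TraceConfig", function(object) {
  lens <- c(object@step, object@patternMesh0, object@patternMeshMin,
            object@patternRadius, object@closeTol, object@stuckTol,
            object@bracketGap, object@trackDist)
  if (any(lens <= 0)) return("all lengths must be positive")
  if (object@maxSteps < object@minLoopSteps || object@minLoopSteps < 3L)
    return("need maxSteps >= minLoopSteps >= 3")
  TRUE
})

#' First-principal-component fields of the thresholded Q series
#'
#' @slot w1 scalar volume on the box: spatial map of the first principal
#'   component of the thresholded Q fields over the vortex-frame window.
#' @slot explainedVarianceRatio fraction of variance carried by w1.
#' @slot w1MaxLocation physical position (mm) of the w1 maximum.
#' @slot w1MaxVoxel 1-based box voxel index of the w1 maximum.
#' @export
setClass("PCFields", representation(
  w1 = "array", explainedVarianceRatio = "numeric",
  w1MaxLocation = "numeric", w1MaxVoxel = "integer"))

#' 2x2 confusion matrix of ring presence
#'
#' Frame counts of automated vs reference (e.g. visual) MV vortex ring
#' detection: `a` both absent, `b` automated absent / reference present,
#' `c` automated present / reference absent, `d` both present.
#'
#' @slot a,b,c,d non-negative counts.
#' @export
setClass("ConfusionMatrix2x2", representation(
  a = "numeric", b = "numeric", c = "numeric", d = "numeric"))

setValidity("ConfusionMatrix2x2", function(object) {
  cnt <- c(object@a, object@b, object@c, object@d)
  if (any(cnt < 0) || sum(cnt) <= 0) return("counts must be >= 0 with total > 0")
  TRUE
})

#' @param a,b,c,d counts: both absent; automated absent / reference present;
#'   automated present / reference absent; both present.
#' @rdname ConfusionMatrix2x2-class
#' @export
confusionMatrix2x2 <- function(a, b, c, d) {
  new("ConfusionMatrix2x2", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d))
}

#' Complete result of an MV vortex ring extraction
#'
#' Returned by [extractVortexRing()]: the bounding box, the Q series, the
#' per-frame cores and regions, the per-frame parameter table and the E/A
#' peak summaries.
#'
#' @slot grid the full acquisition [FlowGrid-class].
#' @slot box LV [BoundingBox-class] used for the decomposition.
#' @slot qseries the [QSeries-class].
#' @slot cores per-frame list of [VortexCore-class] or `NULL`.
#' @slot regions per-frame list of [VortexRegion-class] or `NULL`.
#' @slot params per-frame parameter `data.frame` (one row per frame).
#' @slot peaks list with E- and A-period peak parameter summaries.
#' @slot presence logical(N), per-frame MV-ring presence.
#' @slot longAxis unit 3-vector used as the LV long axis.
#' @slot config configuration list used for the run.
#' @export
setClass("MVRingResult", representation(
  grid = "FlowGrid", box = "BoundingBox", qseries = "QSeries",
  cores = "list", regions = "list", params = "data.frame",
  peaks = "list", presence = "logical", longAxis = "numeric",
  config = "list"))
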