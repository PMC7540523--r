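# Vortex core line tracing (predictor-corrector), shape classification and
# temporal tracking of MV-ring membership.

#' Default tracer configuration for a grid
#'
#' Derives the tunables of the predictor-corrector tracer from the voxel
#' spacing: step = 0.5 x min spacing; pattern-search mesh from 1 x min
#' spacing contracting by 0.5 down to 0.1 x min spacing; search radius
#' 2 x max spacing (prevents jumping to a neighbouring vortex); closure
#' tolerance = half the voxel diagonal (the corrected core line wobbles at
#' the voxel scale on anisotropic grids, so closure is declared when the
#' path returns within the same voxel cell of the start); stuck tolerance
#' = 0.1 x step. Shape tests: 150 degrees
#' total turning for a U, endpoint gap 2 x max spacing for a bracket.
#' Tracking: 10 mm maximal centroid displacement and 50% maximal relative
#' major-axis change between consecutive frames.
#'
#' @param grid a [FlowGrid-class] (only the spacing is used).
#' @param ... named overrides for any slot of [TraceConfig-class].
#' @return a [TraceConfig-class].
#' @export
traceConfig <- function(grid, ...) {
  hmin <- min(grid@spacing); hmax <- max(grid@spacing)
  defaults <- list(
    step = 0.5 * hmin,
    patternMesh0 = hmin,
    patternMeshMin = 0.1 * hmin,
    patternRadius = 2 * hmax,
    closeTol = 0.5 * sqrt(sum(grid@spacing^2)),
    stuckTol = 0.05 * hmin,
    maxSteps = 500L,
    minLoopSteps = 6L,
    uTurnDeg = 150,
    bracketGap = 2 * hmax,
    trackDist = 10,
    trackAxisChange = 0.5)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(defaults)))
  defaults[names(ov)] <- ov
  do.call(new, c(list("TraceConfig"),
                 lapply(defaults, function(x)
                   if (is.numeric(x) && !is.integer(x)) as.numeric(x) else x)))
}

# trilinear samplers bound to a grid: Q (outside -> -Inf) and the vorticity
# direction (renormalized after interpolation)
.makeSamplers <- function(qFrame, vortFrame, grid) {
  list(
    q = function(pts) {
      .interp3(qFrame, physicalToVoxel(grid, pts), outside = -Inf)
    },
    vortDir = function(pts) {
      w <- .interp3v(vortFrame, physicalToVoxel(grid, pts), outside = 0)
      nn <- sqrt(rowSums(w^2))
      ok <- nn > 1e-12
      w[ok, ] <- w[ok, , drop = FALSE] / nn[ok]
      list(dir = w, mag = nn)
    })
}

# pattern-search maximization of Q on the plane through x0 perpendicular to
# nrm, confined to `radius` around x0; mesh contracts x0.5 from mesh0 to
# meshMin; only improving moves are accepted
.patternSearchQ <- function(qf, x0, nrm, mesh0, meshMin, radius) {
  B <- .planeBasis(nrm)
  x <- x0
  qx <- qf(matrix(x, 1, 3))
  mesh <- mesh0
  evals <- 0L
  while (mesh >= meshMin && evals < 400L) {
    cand <- rbind(x + mesh * B[1, ], x - mesh * B[1, ],
                  x + mesh * B[2, ], x - mesh * B[2, ])
    d <- sqrt(rowSums(sweep(cand, 2, x0, "-")^2))
    qc <- qf(cand)
    qc[d > radius] <- -Inf
    evals <- evals + 4L
    best <- which.max(qc)
    if (is.finite(qc[best]) && qc[best] > qx) {
      x <- cand[best, ]
      qx <- qc[best]
    } else {
      mesh <- mesh / 2
    }
  }
  list(x = x, q = qx)
}

# moving-average regularization of a polyline: damps the voxel-scale
# zigzag of the corrector points (the in-plane argmax of trilinearly
# interpolated Q jitters by up to a voxel on anisotropic grids) without
# moving the line off the core. Closed lines are smoothed cyclically; open
# lines keep their endpoints.
.smoothPolyline <- function(pts, closed, iters = 4L) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  for (it in seq_len(iters)) {
    if (closed) {
      prv <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
      nxt <- pts[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
      pts <- 0.25 * prv + 0.5 * pts + 0.25 * nxt
    } else {
      mid <- 2:(n - 1L)
      pts[mid, ] <- 0.25 * pts[mid - 1L, , drop = FALSE] +
        0.5 * pts[mid, , drop = FALSE] +
        0.25 * pts[mid + 1L, , drop = FALSE]
    }
  }
  pts
}

# distance from point s to the segment [a, b]
.pointSegDist <- function(s, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 > 0) max(0, min(1, sum((s - a) * ab) / L2)) else 0
  sqrt(sum((s - (a + t * ab))^2))
}

# one-directional trace; dirSign +1 follows the vorticity, -1 opposes it.
# Returns the corrector points (excluding the seed) and the stop reason.
.traceDirection <- function(sam, seed, cfg, dirSign) {
  pts <- matrix(numeric(0), 0, 3)
  cur <- seed
  reason <- "max_steps"
  for (k in seq_len(cfg@maxSteps)) {
    vd <- sam$vortDir(matrix(cur, 1, 3))
    if (vd$mag < 1e-12) { reason <- "stuck"; break }
    pred <- cur + dirSign * cfg@step * vd$dir[1, ]
    vp <- sam$vortDir(matrix(pred, 1, 3))
    nrm <- if (vp$mag >= 1e-12) vp$dir[1, ] else vd$dir[1, ]
    ps <- .patternSearchQ(sam$q, pred, nrm, cfg@patternMesh0,
                          cfg@patternMeshMin, cfg@patternRadius)
    if (!is.finite(ps$q) || ps$q <= 0) { reason <- "q_nonpositive"; break }
    corr <- ps$x
    # closed ring: the path returns to the start after enough steps (the
    # whole segment travelled this step is checked, not only its endpoint)
    if (k >= cfg@minLoopSteps &&
        .pointSegDist(seed, cur, corr) < cfg@closeTol) {
      reason <- "closed"
      break
    }
    # stuck: no displacement, or revisiting an earlier point
    if (sqrt(sum((corr - cur)^2)) < cfg@stuckTol) { reason <- "stuck"; break }
    if (nrow(pts) > 2L) {
      dPrev <- sqrt(rowSums(sweep(pts[seq_len(nrow(pts) - 2L), , drop = FALSE],
                                  2, corr, "-")^2))
      if (any(dPrev < cfg@stuckTol)) { reason <- "stuck"; break }
    }
    pts <- rbind(pts, corr)
    cur <- corr
  }
  list(points = pts, reason = reason)
}

#' Trace a vortex core line by the predictor-corrector method
#'
#' Starting at the seed (normally the Q maximum of a vortex candidate), the
#' core is elongated along the local vorticity direction (predictor) and
#' corrected to the Q maximum on the plane perpendicular to the vorticity at
#' the predictor point, found by pattern search. Forward tracing stops on
#' arriving back at the start (closed ring), getting stuck, or reaching
#' non-positive Q. If the forward line did not close, a backward trace
#' (negated vorticity) is run with the same rules, closing by fusion when it
#' comes within the closure tolerance of the forward line; otherwise the
#' merged open line is returned.
#'
#' @param qFrame scalar Q volume on the box.
#' @param vortFrame vector vorticity volume on the box (used for the local
#'   direction; interpolated and renormalized).
#' @param seedPoint physical position (mm) with positive interpolated Q.
#' @param grid the (cropped) [FlowGrid-class] of the volumes.
#' @param cfg a [TraceConfig-class].
#' @param frame frame index stored in the result.
#' @return a [VortexCore-class] (shape label not yet assigned:
#'   [classifyShape()] / [trackCores()] set it).
#' @export
traceCore <- function(qFrame, vortFrame, seedPoint, grid, cfg,
                      frame = 1L) {
  sam <- .makeSamplers(qFrame, vortFrame, grid)
  q0 <- sam$q(matrix(seedPoint, 1, 3))
  if (!is.finite(q0) || q0 <= 0)
    stop("seed outside vortex (interpolated Q <= 0)")
  # refine the seed onto the sub-voxel core with one corrector application
  # (the raw seed is a voxel center, up to half a voxel off the core line;
  # closure is tested against the start, so the start must lie on the core)
  vd0 <- sam$vortDir(matrix(seedPoint, 1, 3))
  if (vd0$mag >= 1e-12) {
    ps0 <- .patternSearchQ(sam$q, seedPoint, vd0$dir[1, ], cfg@patternMesh0,
                           cfg@patternMeshMin, cfg@patternRadius)
    if (is.finite(ps0$q) && ps0$q > 0) seedPoint <- ps0$x
  }
  fwd <- .traceDirection(sam, seedPoint, cfg, +1)
  closed <- identical(fwd$reason, "closed")
  pts <- rbind(seedPoint, fwd$points)
  if (!closed) {
    bwd <- .traceDirection(sam, seedPoint, cfg, -1)
    bp <- bwd$points
    # fusion: backward line meets the forward line (or the start point)
    if (nrow(bp) && nrow(fwd$points)) {
      for (k in seq_len(nrow(bp))) {
        dmin <- min(sqrt(rowSums(sweep(fwd$points, 2, bp[k, ], "-")^2)))
        if (k >= 3L && dmin < cfg@closeTol) {
          bp <- bp[seq_len(k), , drop = FALSE]
          closed <- TRUE
          break
        }
      }
    }
    if (identical(bwd$reason, "closed")) closed <- TRUE
    if (nrow(bp)) pts <- rbind(bp[rev(seq_len(nrow(bp))), , drop = FALSE], pts)
  }
  rownames(pts) <- NULL
  # regularize; points that smoothing would push out of the vortex
  # (interpolated Q <= 0) are kept at their corrector positions
  if (nrow(pts) >= 3L) {
    sm <- .smoothPolyline(pts, closed)
    qsm <- sam$q(sm)
    bad <- !is.finite(qsm) | qsm <= 0
    sm[bad, ] <- pts[bad, ]
    pts <- sm
  }
  ax <- if (nrow(pts) >= 3L) tryCatch(ellipsoidAxes(pts),
                                      error = function(e) NULL) else NULL
  new("VortexCore", points = pts, shape = "none", closed = closed,
      frame = as.integer(frame), isMVRing = FALSE,
      majorAxis = if (is.null(ax)) 0 else ax$major,
      minorAxis = if (is.null(ax)) 0 else ax$minor,
      centroid = colMeans(pts))
}

# total turning angle (degrees) along an ordered polyline
.turningAngle <- function(pts) {
  if (nrow(pts) < 3L) return(0)
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 1e-9
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) < 2L) return(0)
  u <- seg / sqrt(rowSums(seg^2))
  cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  sum(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
}

#' Classify the shape of traced core lines
#'
#' A closed line is a torus. An open line whose total turning angle reaches
#' `uTurnDeg` is a U. Two open lines whose endpoint pairs are mutually
#' within `bracketGap` and whose combined turning reaches `uTurnDeg` form a
#' bracket. Anything else is "none".
#'
#' @param lines one [VortexCore-class] or a list of one or two.
#' @param cfg a [TraceConfig-class].
#' @return shape label: `"torus"`, `"U"`, `"bracket"` or `"none"`.
#' @export
classifyShape <- function(lines, cfg) {
  if (is(lines, "VortexCore")) lines <- list(lines)
  stopifnot(length(lines) >= 1L)
  if (length(lines) == 1L) {
    cl <- lines[[1]]
    if (isTRUE(cl@closed)) return("torus")
    if (.turningAngle(cl@points) >= cfg@uTurnDeg) return("U")
    return("none")
  }
  a <- lines[[1]]; b <- lines[[2]]
  if (isTRUE(a@closed) || isTRUE(b@closed)) return("none")
  ea <- rbind(a@points[1, ], a@points[nrow(a@points), ])
  eb <- rbind(b@points[1, ], b@points[nrow(b@points), ])
  gaps <- as.matrix(stats::dist(rbind(ea, eb)))[1:2, 3:4]
  # each endpoint of a must pair with a distinct endpoint of b
  pairing <- min(gaps[1, 1] + gaps[2, 2], gaps[1, 2] + gaps[2, 1]) / 2
  turning <- .turningAngle(a@points) + .turningAngle(b@points)
  if (pairing <= cfg@bracketGap && turning >= cfg@uTurnDeg) "bracket"
  else "none"
}

#' Principal axis lengths of an ellipsoid fitted to core points
#'
#' Principal component analysis of the point coordinates; the axis length
#' along each principal direction is twice the maximal absolute projection
#' of the centered points onto it. Returns the two largest lengths and the
#' centroid.
#'
#' @param pts P x 3 matrix of positions (mm), P >= 3, non-collinear.
#' @return list with `major`, `minor` (mm) and `centroid`.
#' @export
ellipsoidAxes <- function(pts) {
  if (is.null(dim(pts)) || nrow(pts) < 3L)
    stop("need at least 3 core points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr, "-")
  sv <- svd(X, nu = 0)
  if (sv$d[2] <= 1e-9 * sv$d[1])
    stop("core points are collinear")
  proj <- abs(X %*% sv$v)
  lens <- sort(2 * apply(proj, 2, max), decreasing = TRUE)
  list(major = lens[1], minor = lens[2], centroid = ctr)
}

# trace all (<= 2) candidates of one frame and reduce them to a single
# possible MV core following the two-candidate rule
.traceFrame <- function(cands, qFrame, vortFrame, grid, cfg, frame,
                        prevCentroid = NULL) {
  cores <- list()
  for (cd in cands) {
    qvals <- qFrame[cd@voxels]
    seedIdx <- cd@voxels[which.max(qvals), ]
    seed <- drop(voxelToPhysical(grid, seedIdx))
    cl <- tryCatch(
      traceCore(qFrame, vortFrame, seed, grid, cfg, frame = frame),
      error = function(e) NULL)
    if (!is.null(cl) && nrow(cl@points) >= 3L) cores <- c(cores, list(cl))
  }
  if (!length(cores)) return(NULL)
  if (length(cores) == 1L) {
    cores[[1]]@shape <- classifyShape(cores[[1]], cfg)
    return(cores[[1]])
  }
  # two cores: individually torus/U, else jointly bracket, else pick the one
  # nearer the previous frame's MV core centroid
  sh <- vapply(cores, function(cl) classifyShape(cl, cfg), character(1))
  if (all(sh == "none")) {
    br <- classifyShape(cores, cfg)
    if (identical(br, "bracket")) {
      pts <- rbind(cores[[1]]@points, cores[[2]]@points)
      ax <- tryCatch(ellipsoidAxes(pts), error = function(e) NULL)
      return(new("VortexCore", points = pts, shape = "bracket",
                 closed = FALSE, frame = as.integer(frame), isMVRing = FALSE,
                 majorAxis = if (is.null(ax)) 0 else ax$major,
                 minorAxis = if (is.null(ax)) 0 else ax$minor,
                 centroid = colMeans(pts)))
    }
  }
  for (i in seq_along(cores)) cores[[i]]@shape <- sh[i]
  ringish <- which(sh != "none")
  pool <- if (length(ringish)) cores[ringish] else cores
  if (!is.null(prevCentroid) && length(pool) > 1L) {
    d <- vapply(pool, function(cl) sqrt(sum((cl@centroid - prevCentroid)^2)),
                numeric(1))
    pool[[which.min(d)]]
  } else {
    qbest <- which.max(vapply(pool, function(cl) nrow(cl@points), numeric(1)))
    pool[[qbest]]
  }
}

#' Track vortex cores over the cardiac cycle
#'
#' Cores are first traced at the two peak frames of the maximum-Q time
#' curve, seeding MV-ring membership there (membership at a peak requires a
#' ring-like shape, i.e. not "none"). Detection then proceeds frame by
#' frame: from the E peak backward to the window start and forward up to
#' (not past) the inter-peak minimum of the curve, and from the A peak
#' forward to the window end and backward down to the minimum. In each
#' frame up to two candidates are traced; with two distinct non-bracket
#' cores the one whose centroid is nearer the previous frame's MV core is
#' kept. Membership propagates when the previous visited frame held an MV
#' ring and both the centroid displacement and the relative major-axis
#' change are small (`trackDist`, `trackAxisChange`).
#'
#' @param candidatesByFrame list indexed by frame of candidate lists (as
#'   from [selectCandidates()]).
#' @param qs a [QSeries-class] with window and peaks set.
#' @param vortFrames list of per-frame vorticity volumes on the box.
#' @param cfg a [TraceConfig-class].
#' @return per-frame list of [VortexCore-class] (or `NULL`), with
#'   `isMVRing` flags set.
#' @export
trackCores <- function(candidatesByFrame, qs, vortFrames, cfg) {
  grid <- qs@grid
  n <- grid@nFrames
  window <- qs@vortexFrames
  pk <- qs@peakFrames
  cores <- vector("list", n)
  if (!length(window) || !length(pk)) return(cores)
  wpos <- seq_along(window)
  pEpos <- match(pk[1], window)
  pApos <- match(pk[2], window)
  # inter-peak minimum of the max-Q curve marks the E/A border
  if (pApos > pEpos + 1L) {
    seg <- (pEpos + 1L):(pApos - 1L)
    minPos <- seg[which.max(-qs@maxCurve[window[seg]])]
  } else minPos <- pEpos
  chains <- list(
    seq(pEpos, 1L),                                  # E backward
    if (minPos > pEpos) seq(pEpos, minPos) else pEpos, # E forward
    seq(pApos, length(window)),                      # A forward
    if (pApos > minPos + 1L) seq(pApos, minPos + 1L) else pApos) # A backward
  if (pApos == pEpos) chains <- chains[1:2]
  visited <- rep(FALSE, n)
  for (ch in chains) {
    prev <- NULL
    for (p in ch) {
      fr <- window[p]
      atPeak <- fr %in% pk
      if (visited[fr]) { prev <- cores[[fr]]; next }
      cands <- candidatesByFrame[[fr]]
      if (is.null(cands) || !length(cands)) {
        visited[fr] <- TRUE
        prev <- NULL
        next
      }
      cl <- .traceFrame(cands, qs@qFrames[[fr]], vortFrames[[fr]], grid, cfg,
                        fr, prevCentroid = if (!is.null(prev)) prev@centroid)
      if (!is.null(cl)) {
        if (atPeak) {
          cl@isMVRing <- cl@shape != "none"
        } else if (!is.null(prev) && isTRUE(prev@isMVRing) &&
                   cl@shape != "none") {
          dd <- sqrt(sum((cl@centroid - prev@centroid)^2))
          dax <- if (prev@majorAxis > 0)
            abs(cl@majorAxis - prev@majorAxis) / prev@majorAxis else Inf
          cl@isMVRing <- dd <= cfg@trackDist && dax <= cfg@trackAxisChange
        } else cl@isMVRing <- FALSE
        cores[[fr]] <- cl
      }
      visited[fr] <- TRUE
      prev <- cl
    }
  }
  cores
}
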