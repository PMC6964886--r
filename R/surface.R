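# Surface detection: turn the membrane-marker channel of a Z-stack into a
# smooth, gap-free height map of the outer tissue surface.
#
# Detection rule: after optional 3-D Gaussian pre-smoothing, each (y, x)
# column is scanned from slice 0 (the stack entry side, nearest the
# objective) upward in z; the surface is the first z at which the marker
# is at or above threshold for `minRun` consecutive slices.  The crossing
# is recorded at the integer slice; sub-slice heights arise only from the
# later regularization.  Columns with no qualifying run are invalid and
# are filled from their nearest valid neighbour by fillGaps().

resolveThreshold <- function(smoothed, threshold, rawRange) {
  if (is.character(threshold)) {
    rng <- range(smoothed)
    if (diff(rng) == 0)
      stopDetection("no surface contrast: marker channel is constant, cannot compute an Otsu threshold")
    norm <- (smoothed - rng[1L]) / diff(rng)
    t01 <- EBImage::otsu(matrix(norm, nrow = dim(smoothed)[1L]),
                         range = c(0, 1), levels = 256L)
    rng[1L] + t01 * diff(rng)
  } else {
    if (threshold < rawRange[1L] || threshold > rawRange[2L])
      warning(sprintf(
        "fixed threshold %g lies outside the marker intensity range [%g, %g]",
        threshold, rawRange[1L], rawRange[2L]), call. = FALSE)
    threshold
  }
}

#' Detect the contoured tissue surface in a Z-stack
#'
#' Scans every (y, x) column of the (optionally pre-smoothed) marker
#' channel from slice 0 upward and records the first z at which intensity
#' is at or above threshold for \code{minRun} consecutive slices.  Columns
#' without such a run are marked invalid.  An \code{"otsu"} threshold is
#' resolved once globally on the pre-smoothed marker channel.
#'
#' The raw map is typically post-processed with \code{\link{fillGaps}} and
#' \code{\link{regularizeHeightMap}} before peeling.
#'
#' @param stack an \code{\linkS4class{ImageStack}} with slice 0 nearest
#'   the objective (the outer surface side).
#' @param params a \code{\linkS4class{SurfaceParams}}.
#' @return A \code{\linkS4class{HeightMap}} of zero-based z coordinates.
#' @examples
#' v <- array(0, c(10, 8, 8)); v[6:10, , ] <- 100   # surface at z = 5
#' s <- ImageStack(v)
#' hm <- detectSurface(s, SurfaceParams(threshold = 50, preSmoothSigma = 0))
#' unique(as.vector(heightValues(hm)))
#' @export
detectSurface <- function(stack, params = SurfaceParams()) {
  stopifnot(is(stack, "ImageStack"), is(params, "SurfaceParams"))
  d <- stackDim(stack)
  nz <- d[1L]
  if (params@channel > nChannels(stack))
    stopInput("channel %d does not exist (stack has %d channel(s))",
              params@channel, nChannels(stack))
  if (nz < params@minRun)
    stopInput("stack has %d slice(s), fewer than minRun = %d",
              nz, params@minRun)
  ch <- voxels(stack)[params@channel, , , ]
  if (nz == 1L) ch <- array(ch, d)
  sm <- if (params@preSmoothSigma > 0) gaussSmooth(ch, params@preSmoothSigma)
        else ch
  thr <- resolveThreshold(sm, params@threshold, range(ch))
  above <- sm >= thr
  r <- params@minRun
  nRun <- nz - r + 1L
  ok <- above[seq_len(nRun), , , drop = FALSE]
  if (r > 1L) {
    for (j in seq_len(r - 1L))
      ok <- ok & above[seq_len(nRun) + j, , , drop = FALSE]
  }
  height <- matrix(NA_real_, d[2L], d[3L])
  found <- matrix(FALSE, d[2L], d[3L])
  for (z in seq_len(nRun)) {
    sel <- ok[z, , ] & !found
    if (any(sel)) {
      height[sel] <- z - 1   # zero-based slice index
      found <- found | sel
    }
    if (all(found)) break
  }
  HeightMap(height, found, nz = nz)
}

#' Fill invalid height-map pixels from their nearest valid neighbour
#'
#' Every invalid pixel receives the height of the closest valid pixel in
#' Euclidean (y, x) distance; ties are broken toward the pixel with the
#' smallest (y, x) in lexicographic order, making the fill deterministic
#' and parameter-free.  Valid pixels are unchanged, and a fully valid map
#' is returned identically.
#'
#' @param hm a \code{\linkS4class{HeightMap}} with at least one valid
#'   pixel.
#' @return A fully valid \code{HeightMap}.
#' @export
fillGaps <- function(hm) {
  stopifnot(is(hm, "HeightMap"))
  v <- validMask(hm)
  if (!any(v))
    stopDetection("no surface found: height map has zero valid pixels")
  if (all(v)) return(hm)
  h <- heightValues(hm)
  ny <- nrow(h)
  nx <- ncol(h)
  # pass 1: per row, nearest valid pixel within the row (left-preferred on
  # distance ties), giving squared x-distance and its height
  rowD2 <- matrix(Inf, ny, nx)
  rowVal <- matrix(NA_real_, ny, nx)
  xs <- seq_len(nx)
  for (yy in seq_len(ny)) {
    vx <- which(v[yy, ])
    if (length(vx) == 0L) next
    # nearest valid x' for every x: merge a left and a right sweep
    idx <- findInterval(xs, vx)              # last valid <= x (0 if none)
    leftX <- ifelse(idx >= 1L, vx[pmax(idx, 1L)], NA_integer_)
    rightX <- ifelse(idx < length(vx), vx[pmin(idx + 1L, length(vx))],
                     NA_integer_)
    dl <- ifelse(is.na(leftX), Inf, xs - leftX)
    dr <- ifelse(is.na(rightX), Inf, rightX - xs)
    useLeft <- dl <= dr                      # tie -> left (smaller x')
    src <- ifelse(useLeft, leftX, rightX)
    rowD2[yy, ] <- pmin(dl, dr)^2
    rowVal[yy, ] <- h[yy, src]
  }
  # pass 2: combine rows; scanning source rows in increasing y' with a
  # strict improvement test keeps the smallest y' on distance ties
  best <- matrix(Inf, ny, nx)
  bestVal <- matrix(NA_real_, ny, nx)
  ys <- seq_len(ny)
  for (s in seq_len(ny)) {
    if (all(is.infinite(rowD2[s, ]))) next
    cand <- outer((ys - s)^2, rep(1, nx)) +
      matrix(rowD2[s, ], ny, nx, byrow = TRUE)
    upd <- cand < best
    if (any(upd)) {
      best[upd] <- cand[upd]
      srcVal <- matrix(rowVal[s, ], ny, nx, byrow = TRUE)
      bestVal[upd] <- srcVal[upd]
    }
  }
  h[!v] <- bestVal[!v]
  HeightMap(h, matrix(TRUE, ny, nx), nz = hm@nz)
}

#' Regularize a height map
#'
#' Applies a median filter of radius \code{mapMedianRadius} (despiking),
#' then Gaussian smoothing with \code{mapSmoothSigma} (sub-slice
#' smoothing of the staircase left by slice-level detection), and clips
#' the result to \code{[0, nz - 1]}.  Radius 0 and sigma 0 return the
#' input unchanged.  The operation is contractive on range: output values
#' never exceed the input range.
#'
#' @param hm a fully valid \code{\linkS4class{HeightMap}} (apply
#'   \code{\link{fillGaps}} first).
#' @param params a \code{\linkS4class{SurfaceParams}} supplying
#'   \code{mapMedianRadius} and \code{mapSmoothSigma}.
#' @return A fully valid, smoothed \code{HeightMap}.
#' @export
regularizeHeightMap <- function(hm, params = SurfaceParams()) {
  stopifnot(is(hm, "HeightMap"), is(params, "SurfaceParams"))
  if (!all(validMask(hm)))
    stopInput("height map has invalid pixels; apply fillGaps() before regularizing")
  if (params@mapMedianRadius == 0L && params@mapSmoothSigma == 0)
    return(hm)
  h <- medianFilter2D(heightValues(hm), params@mapMedianRadius)
  if (params@mapSmoothSigma > 0) h <- gaussSmooth(h, params@mapSmoothSigma)
  h <- pmin(pmax(h, 0), hm@nz - 1L)
  HeightMap(h, matrix(TRUE, nrow(h), ncol(h)), nz = hm@nz)
}

#' Run the full surface pipeline: detect, fill gaps, regularize
#'
#' @inheritParams detectSurface
#' @return A fully valid, regularized \code{\linkS4class{HeightMap}}.
#' @export
extractSurface <- function(stack, params = SurfaceParams()) {
  regularizeHeightMap(fillGaps(detectSurface(stack, params)), params)
}
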