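#' @import methods
NULL

#' ImageStack: a multi-channel 3-D confocal image stack
#'
#' In-memory container for voxel intensities of a confocal Z-stack.  The
#' canonical axis order is \code{(channel, z, y, x)} and every function in
#' the package assumes it; \code{\link{readStack}} normalizes files into
#' this order.  The z axis runs in acquisition order: slice 0 is the stack
#' entry side, i.e. the slice nearest the objective and therefore the outer
#' tissue surface when imaging through the epidermis into deeper cell
#' layers.  Z coordinates everywhere in the package (height maps, offsets)
#' are zero-based slice indices under this convention.
#'
#' @slot voxels numeric array, \code{dim = c(nChannels, nz, ny, nx)}, all
#'   values finite and non-negative.
#' @slot channelNames character vector, one label per channel.
#' @slot voxelSize numeric length-3, voxel pitch \code{(dz, dy, dx)} in
#'   micrometres, all strictly positive.
#' @slot zOrigin single string, \code{"first"} when slice 0 is the stack
#'   entry side (the package-wide convention; \code{readStack} can flip
#'   stacks acquired the other way round).
#'
#' @seealso \code{\link{ImageStack}} (constructor), \code{\link{readStack}}
#' @name ImageStack-class
#' @rdname ImageStack-class
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    voxels = "array",
    channelNames = "character",
    voxelSize = "numeric",
    zOrigin = "character"
  )
)

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 4L)
    return("'voxels' must be a 4-D array (channel, z, y, x)")
  if (any(dim(v) < 1L))
    return("all dimensions of 'voxels' must be >= 1")
  if (!is.numeric(v))
    return("'voxels' must be numeric")
  if (anyNA(v) || any(!is.finite(v)))
    return("voxel intensities must all be finite")
  if (any(v < 0))
    return("voxel intensities must be non-negative")
  if (length(object@channelNames) != dim(v)[1L])
    return("length(channelNames) must equal the channel count")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("'voxelSize' must be three strictly positive values (dz, dy, dx)")
  if (length(object@zOrigin) != 1L || !object@zOrigin %in% c("first", "last"))
    return("'zOrigin' must be \"first\" or \"last\"")
  TRUE
})

#' HeightMap: per-pixel surface z-coordinate
#'
#' The detected tissue surface as a per-(y, x) map of zero-based z
#' coordinates (real-valued; sub-slice values arise from regularization).
#' Pixels where no surface crossing was found are invalid: \code{NA} in
#' \code{height} and \code{FALSE} in \code{valid}.  \code{\link{fillGaps}}
#' replaces invalid pixels by nearest-valid-neighbour interpolation.
#'
#' @slot height numeric matrix (ny x nx); \code{NA} exactly where invalid.
#' @slot valid logical matrix (ny x nx), \code{TRUE} where a surface
#'   crossing was found before any gap filling.
#' @slot nz integer, slice count of the source stack; valid heights lie in
#'   \code{[0, nz - 1]}.
#'
#' @seealso \code{\link{detectSurface}}, \code{\link{fillGaps}},
#'   \code{\link{regularizeHeightMap}}
#' @name HeightMap-class
#' @rdname HeightMap-class
#' @exportClass HeightMap
setClass("HeightMap",
  representation(height = "matrix", valid = "matrix", nz = "integer")
)

setValidity("HeightMap", function(object) {
  h <- object@height
  v <- object@valid
  if (!is.numeric(h)) return("'height' must be numeric")
  if (!is.logical(v)) return("'valid' must be logical")
  if (!identical(dim(h), dim(v)))
    return("'height' and 'valid' must have identical dimensions")
  if (anyNA(v)) return("'valid' must not contain NA")
  if (anyNA(h[v])) return("valid pixels must have non-NA heights")
  if (!all(is.na(h[!v]))) return("invalid pixels must have NA heights")
  if (length(object@nz) != 1L || is.na(object@nz) || object@nz < 1L)
    return("'nz' must be a single positive integer")
  hv <- h[v]
  if (length(hv) && (min(hv) < 0 || max(hv) > object@nz - 1L))
    return("valid heights must lie in [0, nz - 1]")
  TRUE
})

#' SurfaceParams: parameters of the surface detection step
#'
#' @slot channel integer, 1-based index of the marker channel used for
#'   detection.
#' @slot preSmoothSigma numeric >= 0, sigma (voxels) of the isotropic 3-D
#'   Gaussian applied to the marker channel before thresholding.
#' @slot threshold either a single non-negative number (fixed intensity
#'   threshold) or the string \code{"otsu"}; \code{"otsu"} is resolved once
#'   globally on the pre-smoothed marker channel.
#' @slot minRun integer >= 1, consecutive above-threshold slices required
#'   to accept a surface crossing (rejects single-voxel noise spikes).
#' @slot mapMedianRadius integer >= 0, median-filter radius (pixels)
#'   applied to the height map by \code{regularizeHeightMap}.
#' @slot mapSmoothSigma numeric >= 0, Gaussian sigma (pixels) applied to
#'   the height map after the median filter.
#'
#' @seealso \code{\link{SurfaceParams}} (constructor)
#' @name SurfaceParams-class
#' @rdname SurfaceParams-class
#' @exportClass SurfaceParams
setClass("SurfaceParams",
  representation(
    channel = "integer",
    preSmoothSigma = "numeric",
    threshold = "ANY",
    minRun = "integer",
    mapMedianRadius = "integer",
    mapSmoothSigma = "numeric"
  )
)

setValidity("SurfaceParams", function(object) {
  if (length(object@channel) != 1L || object@channel < 1L)
    return("'channel' must be a single index >= 1")
  if (length(object@preSmoothSigma) != 1L || object@preSmoothSigma < 0)
    return("'preSmoothSigma' must be a single value >= 0")
  th <- object@threshold
  okTh <- (is.character(th) && length(th) == 1L && th == "otsu") ||
    (is.numeric(th) && length(th) == 1L && is.finite(th) && th >= 0)
  if (!okTh)
    return("'threshold' must be a single non-negative number or \"otsu\"")
  if (length(object@minRun) != 1L || object@minRun < 1L)
    return("'minRun' must be a single integer >= 1")
  if (length(object@mapMedianRadius) != 1L || object@mapMedianRadius < 0L)
    return("'mapMedianRadius' must be a single integer >= 0")
  if (length(object@mapSmoothSigma) != 1L || object@mapSmoothSigma < 0)
    return("'mapSmoothSigma' must be a single value >= 0")
  TRUE
})

#' PeelSpec: offset and depth of a layer below the surface
#'
#' A layer is the half-open z interval \code{[h + offset, h + offset +
#' depth)} below the per-pixel surface height \code{h}.  Adjacent specs
#' \code{(0, d1)} and \code{(d1, d2)} therefore tile a column with no
#' shared voxel, so epidermis and mesophyll signal is never double-counted.
#'
#' @slot offset numeric >= 0, distance from the surface to the top of the
#'   layer, in \code{units}.
#' @slot depth numeric > 0, layer thickness in \code{units}.
#' @slot units \code{"slices"} or \code{"um"}; micrometre specs are
#'   converted with the stack's z voxel pitch.
#'
#' @seealso \code{\link{PeelSpec}} (constructor), \code{\link{makeLayerMask}}
#' @name PeelSpec-class
#' @rdname PeelSpec-class
#' @exportClass PeelSpec
setClass("PeelSpec",
  representation(offset = "numeric", depth = "numeric", units = "character")
)

setValidity("PeelSpec", function(object) {
  if (length(object@offset) != 1L || !is.finite(object@offset) ||
      object@offset < 0)
    return("'offset' must be a single finite value >= 0")
  if (length(object@depth) != 1L || !is.finite(object@depth) ||
      object@depth <= 0)
    return("'depth' must be a single finite value > 0")
  if (length(object@units) != 1L || !object@units %in% c("slices", "um"))
    return("'units' must be \"slices\" or \"um\"")
  TRUE
})

#' LayerMask: boolean voxel selection of a peeled layer
#'
#' @slot mask logical array (nz, ny, nx).  In masks produced by
#'   \code{\link{makeLayerMask}} the selected z indices of every (y, x)
#'   column form a single contiguous run (possibly empty after clipping at
#'   the stack boundaries).
#'
#' @name LayerMask-class
#' @rdname LayerMask-class
#' @exportClass LayerMask
setClass("LayerMask", representation(mask = "array"))

setValidity("LayerMask", function(object) {
  m <- object@mask
  if (length(dim(m)) != 3L) return("'mask' must be a 3-D array (z, y, x)")
  if (!is.logical(m) || anyNA(m)) return("'mask' must be logical with no NA")
  TRUE
})

#' ProjectionImage: 2-D per-channel rendering of a peeled layer
#'
#' @slot pixels numeric array (nChannels, ny, nx).
#' @slot method \code{"sum"} (Z-sum projection) or \code{"max"}.
#' @slot channelNames character, one label per channel.
#'
#' @seealso \code{\link{projectLayer}}
#' @name ProjectionImage-class
#' @rdname ProjectionImage-class
#' @exportClass ProjectionImage
setClass("ProjectionImage",
  representation(pixels = "array", method = "character",
                 channelNames = "character")
)

setValidity("ProjectionImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L)
    return("'pixels' must be a 3-D array (channel, y, x)")
  if (anyNA(p) || any(!is.finite(p))) return("pixel values must be finite")
  if (length(object@method) != 1L || !object@method %in% c("sum", "max"))
    return("'method' must be \"sum\" or \"max\"")
  if (length(object@channelNames) != dim(p)[1L])
    return("length(channelNames) must equal the channel count")
  TRUE
})

#' PhantomSpec: parameters of the synthetic leaf-stack generator
#'
#' Describes a two-tissue phantom emulating a confocal stack acquired
#' through the outer epidermis into the mesophyll: a smooth surface model,
#' an epidermal layer of fixed slice thickness directly below the surface,
#' an optional dark gap, and a mesophyll layer beneath that.  Channel 1 is
#' a membrane-marker channel (bright shell at the surface plus sparse
#' cell-wall texture inside the layers); channel 2 is a reporter channel
#' with a homogeneous mean per tissue layer.  See \code{\link{phantomSpec}}
#' for field semantics and defaults.
#'
#' @slot shape integer length-3 \code{(nz, ny, nx)}.
#' @slot surfaceModel one of \code{"flat"}, \code{"plane"}, \code{"sine"},
#'   \code{"bump"}.
#' @slot surfaceArgs named list of surface-model parameters (baseDepth,
#'   tiltX, tiltY, amplitude, period, center, width).
#' @slot epidermisThickness integer > 0 (slices).
#' @slot mesophyllGap integer >= 0 (slices).
#' @slot mesophyllThickness integer > 0 (slices).
#' @slot markerIntensity numeric > 0.
#' @slot reporterMeans numeric length-2 \code{(epidermis, mesophyll)} >= 0.
#' @slot noiseSigma numeric >= 0, additive Gaussian noise SD (clipped at 0).
#' @slot poisson logical, add Poisson shot noise instead of pure Gaussian.
#' @slot seed integer, master seed; all randomness derives from it.
#'
#' @name PhantomSpec-class
#' @rdname PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "integer",
    surfaceModel = "character",
    surfaceArgs = "list",
    epidermisThickness = "integer",
    mesophyllGap = "integer",
    mesophyllThickness = "integer",
    markerIntensity = "numeric",
    reporterMeans = "numeric",
    noiseSigma = "numeric",
    poisson = "logical",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("'shape' must be three positive integers (nz, ny, nx)")
  if (!object@surfaceModel %in% c("flat", "plane", "sine", "bump"))
    return("'surfaceModel' must be flat, plane, sine or bump")
  if (object@epidermisThickness < 1L)
    return("'epidermisThickness' must be >= 1 slice")
  if (object@mesophyllGap < 0L) return("'mesophyllGap' must be >= 0")
  if (object@mesophyllThickness < 1L)
    return("'mesophyllThickness' must be >= 1 slice")
  if (object@markerIntensity <= 0) return("'markerIntensity' must be > 0")
  if (length(object@reporterMeans) != 2L || any(object@reporterMeans < 0))
    return("'reporterMeans' must be two non-negative values")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  TRUE
})

#' PhantomTruth: exact ground truth of a simulated stack
#'
#' @slot height numeric matrix (ny x nx): the voxel-level true surface, the
#'   zero-based z index of the first marker-shell slice in each column.
#'   This is the surface a slice-level detector can recover exactly.
#' @slot heightAnalytic numeric matrix (ny x nx): the continuous surface
#'   model evaluated at each pixel, before rasterization to slices.
#' @slot labels integer array (nz, ny, nx): per-voxel tissue label, 0 =
#'   background, 1 = epidermis, 2 = mesophyll; the label sets partition the
#'   stack and are disjoint by construction.
#' @slot spec the generating \code{\linkS4class{PhantomSpec}}.
#'
#' @name PhantomTruth-class
#' @rdname PhantomTruth-class
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(height = "matrix", heightAnalytic = "matrix",
                 labels = "array", spec = "PhantomSpec")
)
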