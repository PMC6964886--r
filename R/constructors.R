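#' Construct an ImageStack
#'
#' Wraps a voxel array in an \code{\linkS4class{ImageStack}}.  3-D input is
#' promoted to a single-channel 4-D array.
#'
#' @param voxels numeric array, either \code{(channel, z, y, x)} or a
#'   single-channel \code{(z, y, x)} array.
#' @param channelNames character labels, one per channel; defaults to
#'   \code{"ch1"}, \code{"ch2"}, ...
#' @param voxelSize voxel pitch \code{(dz, dy, dx)} in micrometres.
#' @param zOrigin \code{"first"} when slice 0 is the stack entry side.
#' @return An \code{ImageStack}.
#' @examples
#' s <- ImageStack(array(0, c(5, 8, 8)))
#' stackDim(s)
#' @export
ImageStack <- function(voxels, channelNames = NULL,
                       voxelSize = c(1, 1, 1), zOrigin = "first") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, 1L, dim(voxels)))
  if (length(dim(voxels)) == 3L)
    voxels <- array(voxels, c(1L, dim(voxels)))
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(voxels)[1L]))
  new("ImageStack", voxels = voxels, channelNames = as.character(channelNames),
      voxelSize = as.numeric(voxelSize), zOrigin = zOrigin)
}

#' Construct a HeightMap
#'
#' @param height numeric matrix (ny x nx) of zero-based surface z
#'   coordinates; \code{NA} marks invalid pixels.
#' @param valid logical matrix; defaults to \code{!is.na(height)}.
#' @param nz slice count of the source stack.
#' @return A \code{\linkS4class{HeightMap}}.
#' @export
HeightMap <- function(height, valid = !is.na(height), nz) {
  storage.mode(height) <- "double"
  height[!valid] <- NA_real_
  new("HeightMap", height = height, valid = valid, nz = as.integer(nz))
}

#' Construct surface-detection parameters
#'
#' Defaults are mild regularization settings appropriate for
#' membrane-marker stacks: light 3-D pre-smoothing (sigma 0.5 voxels —
#' large enough to damp shot noise, small enough that the marker's
#' smeared axial skirt stays below a global threshold, which would
#' otherwise pull the detected crossing a slice toward the objective), a
#' global Otsu threshold, a two-slice run requirement to reject
#' single-voxel noise spikes, and a 2-pixel median + 2-pixel Gaussian
#' height-map cleanup.  All are overridable.
#'
#' @param channel 1-based marker channel index used for detection.
#' @param preSmoothSigma 3-D Gaussian sigma in voxels, >= 0.
#' @param threshold fixed intensity threshold, or \code{"otsu"} (resolved
#'   once globally on the pre-smoothed marker channel).
#' @param minRun consecutive above-threshold slices required, >= 1.
#' @param mapMedianRadius height-map median filter radius in pixels, >= 0.
#' @param mapSmoothSigma height-map Gaussian sigma in pixels, >= 0.
#' @return A \code{\linkS4class{SurfaceParams}}.
#' @examples
#' SurfaceParams(threshold = 50, minRun = 1)
#' @export
SurfaceParams <- function(channel = 1L, preSmoothSigma = 0.5,
                          threshold = "otsu", minRun = 2L,
                          mapMedianRadius = 2L, mapSmoothSigma = 2) {
  new("SurfaceParams", channel = as.integer(channel),
      preSmoothSigma = as.numeric(preSmoothSigma), threshold = threshold,
      minRun = as.integer(minRun),
      mapMedianRadius = as.integer(mapMedianRadius),
      mapSmoothSigma = as.numeric(mapSmoothSigma))
}

#' Construct a peel specification
#'
#' @param offset distance below the surface to the top of the layer, >= 0.
#' @param depth layer thickness, > 0.
#' @param units \code{"slices"} (default) or \code{"um"}.
#' @return A \code{\linkS4class{PeelSpec}}.
#' @examples
#' PeelSpec(offset = 0, depth = 4)            # epidermis, slice units
#' PeelSpec(offset = 6, depth = 10, units = "um")
#' @export
PeelSpec <- function(offset, depth, units = c("slices", "um")) {
  units <- match.arg(units)
  new("PeelSpec", offset = as.numeric(offset), depth = as.numeric(depth),
      units = units)
}

#' Construct a LayerMask
#'
#' @param mask logical array (nz, ny, nx).
#' @return A \code{\linkS4class{LayerMask}}.
#' @export
LayerMask <- function(mask) {
  storage.mode(mask) <- "logical"
  new("LayerMask", mask = mask)
}

# ---- accessors ---------------------------------------------------------

#' @describeIn ImageStack-class voxel array \code{(channel, z, y, x)}.
#' @param object,x an object of the documented class.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ImageStack-class
#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)

#' @describeIn ImageStack-class channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(object) object@channelNames)

#' @rdname ProjectionImage-class
#' @export
setMethod("channelNames", "ProjectionImage",
          function(object) object@channelNames)

#' @describeIn ImageStack-class voxel pitch \code{(dz, dy, dx)} in um.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname ImageStack-class
#' @export
setMethod("voxelSize", "ImageStack", function(object) object@voxelSize)

#' @describeIn ImageStack-class number of channels.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname ImageStack-class
#' @export
setMethod("nChannels", "ImageStack", function(object) dim(object@voxels)[1L])

#' @describeIn ImageStack-class spatial dimensions \code{c(nz, ny, nx)}.
#' @export
setGeneric("stackDim", function(object) standardGeneric("stackDim"))

#' @rdname ImageStack-class
#' @export
setMethod("stackDim", "ImageStack", function(object) dim(object@voxels)[2:4])

#' @describeIn HeightMap-class height matrix (\code{NA} where invalid).
#' @export
setGeneric("heightValues", function(object) standardGeneric("heightValues"))

#' @rdname HeightMap-class
#' @export
setMethod("heightValues", "HeightMap", function(object) object@height)

#' @describeIn HeightMap-class logical matrix of detected pixels.
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname HeightMap-class
#' @export
setMethod("validMask", "HeightMap", function(object) object@valid)

#' @describeIn LayerMask-class logical voxel array (z, y, x).
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname LayerMask-class
#' @export
setMethod("maskArray", "LayerMask", function(object) object@mask)

#' @describeIn ProjectionImage-class pixel array (channel, y, x).
#' @export
setGeneric("projectionPixels",
           function(object) standardGeneric("projectionPixels"))

#' @rdname ProjectionImage-class
#' @export
setMethod("projectionPixels", "ProjectionImage", function(object) object@pixels)

#' @describeIn PhantomTruth-class voxel-level true surface (z index of the
#'   first marker-shell slice per column).
#' @export
setGeneric("trueHeight", function(object) standardGeneric("trueHeight"))

#' @rdname PhantomTruth-class
#' @export
setMethod("trueHeight", "PhantomTruth", function(object) object@height)

#' @describeIn PhantomTruth-class continuous surface model per pixel.
#' @export
setGeneric("analyticHeight", function(object) standardGeneric("analyticHeight"))

#' @rdname PhantomTruth-class
#' @export
setMethod("analyticHeight", "PhantomTruth",
          function(object) object@heightAnalytic)

#' @describeIn PhantomTruth-class tissue label array (0 background,
#'   1 epidermis, 2 mesophyll).
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))

#' @rdname PhantomTruth-class
#' @export
setMethod("tissueLabels", "PhantomTruth", function(object) object@labels)

# ---- show methods ------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d channel(s) x %d z x %d y x %d x\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat(sprintf("  voxel size (dz, dy, dx): %.3g x %.3g x %.3g um\n",
              object@voxelSize[1L], object@voxelSize[2L],
              object@voxelSize[3L]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "HeightMap", function(object) {
  d <- dim(object@height)
  nv <- sum(object@valid)
  cat(sprintf("HeightMap: %d y x %d x (source nz = %d)\n",
              d[1L], d[2L], object@nz))
  cat(sprintf("  valid: %d / %d pixels (%.1f%%)\n",
              nv, length(object@valid), 100 * nv / length(object@valid)))
  if (nv > 0)
    cat(sprintf("  height range (valid): [%.3g, %.3g] slices\n",
                min(object@height, na.rm = TRUE),
                max(object@height, na.rm = TRUE)))
})

setMethod("show", "LayerMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("LayerMask: %d z x %d y x %d x; %d voxels selected (%.1f%%)\n",
              d[1L], d[2L], d[3L], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "ProjectionImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ProjectionImage (%s): %d channel(s) x %d y x %d x\n",
              object@method, d[1L], d[2L], d[3L]))
})

setMethod("show", "SurfaceParams", function(object) {
  th <- if (is.character(object@threshold)) object@threshold
        else format(object@threshold)
  cat("SurfaceParams:\n")
  cat(sprintf("  channel = %d, preSmoothSigma = %g vox, threshold = %s\n",
              object@channel, object@preSmoothSigma, th))
  cat(sprintf("  minRun = %d, mapMedianRadius = %d px, mapSmoothSigma = %g px\n",
              object@minRun, object@mapMedianRadius, object@mapSmoothSigma))
})

setMethod("show", "PeelSpec", function(object) {
  cat(sprintf("PeelSpec: offset %g, depth %g (%s)\n",
              object@offset, object@depth, object@units))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s surface, shape (nz %d, ny %d, nx %d), seed %d\n",
              object@surfaceModel, object@shape[1L], object@shape[2L],
              object@shape[3L], object@seed))
  cat(sprintf("  epidermis %d sl / gap %d sl / mesophyll %d sl; marker %g; reporter (%g, %g); sigma %g\n",
              object@epidermisThickness, object@mesophyllGap,
              object@mesophyllThickness, object@markerIntensity,
              object@reporterMeans[1L], object@reporterMeans[2L],
              object@noiseSigma))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %s surface; labels: %d epidermis, %d mesophyll voxels\n",
              object@spec@surfaceModel, sum(object@labels == 1L),
              sum(object@labels == 2L)))
})
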