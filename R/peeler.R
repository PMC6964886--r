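# Layer peeling: select the voxels lying a given offset and depth below
# the detected surface, render projections, and quantify layer signal.
#
# The layer of a column with surface height h is the half-open real
# interval [h + offset, h + offset + depth); integer slices are selected
# by ceil(lower) <= z < ceil(upper).  Half-open intervals make adjacent
# layers tile the column exactly: (0, d1) and (d1, d2) are disjoint and
# their union is (0, d1 + d2), so epidermis and mesophyll signal is never
# double-counted.  Selections are clipped to [0, nz) silently — deep
# offsets at stack edges are routine, not errors.

peelOffsets <- function(spec, dz) {
  if (spec@units == "um") {
    if (!is.finite(dz) || dz <= 0)
      stopInput("micrometre peel units require a positive z voxel size")
    c(spec@offset / dz, spec@depth / dz)
  } else {
    c(spec@offset, spec@depth)
  }
}

#' Build the boolean voxel mask of a layer below the surface
#'
#' For each (y, x) column with surface height \code{h} (zero-based
#' slices), selects integer z with \code{ceil(h + offset) <= z <
#' ceil(h + offset + depth)}, clipped to the stack; columns whose interval
#' falls entirely outside the stack get an empty selection.
#'
#' @param x an \code{\linkS4class{ImageStack}}, or an integer vector
#'   \code{c(nz, ny, nx)} of stack dimensions.
#' @param hm a fully valid \code{\linkS4class{HeightMap}} matching
#'   (ny, nx).
#' @param spec a \code{\linkS4class{PeelSpec}}; micrometre units are
#'   converted with the z voxel pitch.
#' @param voxelSize voxel pitch \code{(dz, dy, dx)} in micrometres (only
#'   used for the dimension-vector method; the \code{ImageStack} method
#'   takes it from the stack).
#' @return A \code{\linkS4class{LayerMask}}.
#' @examples
#' hm <- HeightMap(matrix(5, 8, 8), nz = 12)
#' m <- makeLayerMask(c(12L, 8L, 8L), hm, PeelSpec(offset = 0, depth = 3))
#' which(maskArray(m)[, 1, 1]) - 1   # zero-based slices 5, 6, 7
#' @export
setGeneric("makeLayerMask",
           function(x, hm, spec, voxelSize = c(1, 1, 1))
             standardGeneric("makeLayerMask"))

#' @rdname makeLayerMask
#' @export
setMethod("makeLayerMask", "ImageStack", function(x, hm, spec, voxelSize) {
  makeLayerMask(stackDim(x), hm, spec, voxelSize = voxelSize(x))
})

#' @rdname makeLayerMask
#' @export
setMethod("makeLayerMask", "numeric", function(x, hm, spec, voxelSize) {
  stopifnot(is(hm, "HeightMap"), is(spec, "PeelSpec"))
  if (length(x) != 3L || any(x < 1))
    stopInput("stack dimensions must be c(nz, ny, nx)")
  nz <- as.integer(x[1L])
  if (!identical(dim(heightValues(hm)), as.integer(x[2:3])))
    stopInput("height map shape (%d, %d) does not match stack (ny, nx) = (%d, %d)",
              nrow(heightValues(hm)), ncol(heightValues(hm)), x[2L], x[3L])
  if (!all(validMask(hm)))
    stopInput("height map has invalid pixels; apply fillGaps() first")
  od <- peelOffsets(spec, voxelSize[1L])
  h <- heightValues(hm)
  zlo <- ceiling(h + od[1L])
  zhi <- ceiling(h + od[1L] + od[2L])
  m <- array(FALSE, c(nz, nrow(h), ncol(h)))
  for (z0 in seq_len(nz) - 1L)
    m[z0 + 1L, , ] <- (zlo <= z0) & (z0 < zhi)
  LayerMask(m)
})

checkMaskShape <- function(stack, mask) {
  if (!identical(stackDim(stack), dim(maskArray(mask))))
    stopInput("mask shape (%s) does not match stack spatial shape (%s)",
              paste(dim(maskArray(mask)), collapse = ", "),
              paste(stackDim(stack), collapse = ", "))
}

#' Peel a stack: keep masked voxels, zero the rest
#'
#' Returns a stack identical to the input inside the mask and zero
#' outside, in every channel.  Zero (not NA) filling keeps downstream sum
#' projections well-defined; display scaling is a separate concern.
#'
#' @param stack an \code{\linkS4class{ImageStack}}.
#' @param mask a \code{\linkS4class{LayerMask}} matching the stack's
#'   spatial shape.
#' @return The peeled \code{ImageStack}.
#' @export
peelStack <- function(stack, mask) {
  stopifnot(is(stack, "ImageStack"), is(mask, "LayerMask"))
  checkMaskShape(stack, mask)
  v <- voxels(stack)
  m <- maskArray(mask)
  for (ci in seq_len(dim(v)[1L]))
    v[ci, , , ] <- v[ci, , , ] * m
  new("ImageStack", voxels = v, channelNames = channelNames(stack),
      voxelSize = voxelSize(stack), zOrigin = stack@zOrigin)
}

#' Project a (peeled) layer to 2-D
#'
#' \code{"sum"} gives the Z-sum projection of the masked voxels of each
#' channel; \code{"max"} the maximum over selected z (0 where a column
#' selects nothing).  With \code{mask = NULL} the whole stack is
#' projected, which for \code{"sum"} is the classic Z-sum projection.
#' Accumulation is in double precision, so integer inputs cannot
#' overflow.
#'
#' @param stack an \code{\linkS4class{ImageStack}}.
#' @param mask a \code{\linkS4class{LayerMask}}, or \code{NULL} for the
#'   full stack.
#' @param method \code{"sum"} or \code{"max"}.
#' @return A \code{\linkS4class{ProjectionImage}}.
#' @export
projectLayer <- function(stack, mask = NULL, method = c("sum", "max")) {
  stopifnot(is(stack, "ImageStack"))
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("sum", "max"))
    stopInput("unknown projection method '%s' (use \"sum\" or \"max\")",
              method)
  method <- match.arg(method)
  d <- stackDim(stack)
  if (is.null(mask)) mask <- LayerMask(array(TRUE, d))
  stopifnot(is(mask, "LayerMask"))
  checkMaskShape(stack, mask)
  v <- voxels(stack)
  m <- maskArray(mask)
  nc <- nChannels(stack)
  px <- array(0, c(nc, d[2L], d[3L]))
  for (ci in seq_len(nc)) {
    chan <- array(v[ci, , , ], d)
    if (method == "sum") {
      px[ci, , ] <- colSums(chan * m)
    } else {
      acc <- matrix(-Inf, d[2L], d[3L])
      for (z in seq_len(d[1L])) {
        sl <- chan[z, , ]
        sl[!m[z, , ]] <- -Inf
        acc <- pmax(acc, sl)
      }
      acc[is.infinite(acc)] <- 0
      px[ci, , ] <- acc
    }
  }
  new("ProjectionImage", pixels = px, method = method,
      channelNames = channelNames(stack))
}

#' Quantify per-channel signal inside a layer
#'
#' @param stack an \code{\linkS4class{ImageStack}}.
#' @param mask a \code{\linkS4class{LayerMask}} matching the stack; must
#'   select at least one voxel.
#' @param channels channel indices to quantify (default: all).
#' @return A \code{data.frame} with columns \code{channel},
#'   \code{channel_name}, \code{voxel_count}, \code{total_intensity},
#'   \code{mean_intensity}.
#' @export
quantifyLayer <- function(stack, mask, channels = NULL) {
  stopifnot(is(stack, "ImageStack"), is(mask, "LayerMask"))
  checkMaskShape(stack, mask)
  m <- maskArray(mask)
  n <- sum(m)
  if (n == 0L)
    stopInput("empty layer: the mask selects no voxels")
  if (is.null(channels)) channels <- seq_len(nChannels(stack))
  if (any(channels < 1L) || any(channels > nChannels(stack)))
    stopInput("channel index out of range")
  v <- voxels(stack)
  d <- stackDim(stack)
  totals <- vapply(channels, function(ci) sum(array(v[ci, , , ], d)[m]),
                   numeric(1))
  data.frame(
    channel = as.integer(channels),
    channel_name = channelNames(stack)[channels],
    voxel_count = rep.int(n, length(channels)),
    total_intensity = totals,
    mean_intensity = totals / n,
    stringsAsFactors = FALSE
  )
}
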