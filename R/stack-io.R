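# TIFF reading/writing for stacks, height maps, masks and projections.
#
# On-disk layout: a plain multi-page TIFF plus a JSON sidecar
# ("<path>.json") carrying what baseline TIFF cannot: voxel size, channel
# layout, channel names, dtype and the intensity scale.  Integer data
# (max <= 65535) is stored as 16-bit pages (bit-exact round trip);
# everything else as 32-bit pages divided by a power-of-two scale; the
# codec stores those as 32-bit fixed point, so the absolute round-trip
# error is bounded by scale * 2^-32 — tighter than single-precision
# float for values within an order of magnitude of the scale.  Foreign
# TIFFs without a sidecar are still readable;
# their voxel size defaults to (1, 1, 1) um with a warning.

sidecarPath <- function(path) paste0(path, ".json")

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

checkWritable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stopIO("cannot write '%s': directory '%s' does not exist", path, dir)
}

readPages <- function(path) {
  if (!file.exists(path)) stopIO("file not found: '%s'", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stopIO("cannot read TIFF '%s': %s", path,
                               conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stopIO("TIFF '%s' contains no pages", path)
  # keep codec attributes (bit depth) available but off the data matrices
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    attributes(p) <- list(dim = dim(p))
    attr(p, "bits.per.sample") <- bits
    p
  })
}

# Decode one page to raw intensities.  Integer pages come back from the
# codec scaled into [0,1] by (2^bits - 1); float pages come back as-is.
decodePage <- function(page, scale = NULL) {
  bits <- attr(page, "bits.per.sample")
  if (length(dim(page)) == 3L)
    stopConfig("multi-sample TIFF pages are not supported; expected one grayscale sample per page")
  if (!is.null(scale)) return(page * scale)
  if (!is.null(bits) && bits %in% c(8L, 16L)) return(page * (2^bits - 1))
  page
}

#' Read a multi-page TIFF into an ImageStack
#'
#' Pages are arranged into the canonical \code{(channel, z, y, x)} axis
#' order.  Files written by \code{\link{writeStack}} carry a JSON sidecar
#' with the full layout and voxel size; foreign TIFFs are interpreted with
#' the \code{channels}/\code{pageOrder} hints (single channel, z-major by
#' default) and fall back to a voxel size of (1, 1, 1) micrometres with a
#' warning.
#'
#' @param path TIFF file path.
#' @param channels hint: number of channels interleaved in the pages of a
#'   foreign TIFF (ignored when a sidecar is present).
#' @param pageOrder hint: \code{"cz"} when all z slices of channel 1 come
#'   first (channel-major, the package's own layout), \code{"zc"} when
#'   channels are interleaved per slice.
#' @param flipZ reverse the z axis on read, for stacks acquired with the
#'   objective-near side last.
#' @return An \code{\linkS4class{ImageStack}}; slice 0 is the stack entry
#'   side.
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, channels = NULL, pageOrder = c("cz", "zc"),
                      flipZ = FALSE) {
  pageOrder <- match.arg(pageOrder)
  pages <- readPages(path)
  meta <- readSidecar(path)
  haveMeta <- !is.null(meta) && identical(meta$format, "PeelStack-ImageStack")
  if (haveMeta) {
    nc <- as.integer(meta$n_channels)
    scale <- as.numeric(meta$scale)
    pageOrder <- "cz"
  } else {
    nc <- if (is.null(channels)) 1L else as.integer(channels)
    scale <- NULL
  }
  np <- length(pages)
  if (np %% nc != 0L)
    stopConfig("page count (%d) is not a multiple of the channel count (%d); pass a resolving 'channels' hint",
               np, nc)
  nz <- np %/% nc
  d1 <- dim(pages[[1L]])
  mats <- lapply(pages, decodePage, scale = scale)
  for (m in mats)
    if (!identical(dim(m), d1))
      stopConfig("TIFF pages have inconsistent dimensions")
  v <- array(0, c(nc, nz, d1[1L], d1[2L]))
  for (p in seq_len(np)) {
    if (pageOrder == "cz") {
      ci <- (p - 1L) %/% nz + 1L
      zi <- (p - 1L) %% nz + 1L
    } else {
      ci <- (p - 1L) %% nc + 1L
      zi <- (p - 1L) %/% nc + 1L
    }
    v[ci, zi, , ] <- mats[[p]]
  }
  if (haveMeta) {
    cn <- as.character(meta$channel_names)
    vs <- as.numeric(meta$voxel_size_um)
  } else {
    cn <- paste0("ch", seq_len(nc))
    vs <- c(1, 1, 1)
    warning("no voxel-size metadata for '", path,
            "': defaulting to (1, 1, 1) um", call. = FALSE)
  }
  if (flipZ) v <- v[, rev(seq_len(nz)), , , drop = FALSE]
  ImageStack(v, channelNames = cn, voxelSize = vs, zOrigin = "first")
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Pages are channel-major (all z slices of channel 1, then channel 2,
#' ...).  Integer-valued stacks with a maximum of at most 65535 are stored
#' as 16-bit pages and round-trip bit-exactly; all other stacks are stored
#' as 32-bit float pages.  Voxel size, channel names and the intensity
#' scale are recorded in a JSON sidecar next to the file.
#'
#' @param stack an \code{\linkS4class{ImageStack}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  checkWritable(path)
  v <- voxels(stack)
  d <- dim(v)
  vmax <- max(v)
  integral <- isWholeNumber(v) && vmax <= 65535
  if (integral) {
    scale <- 65535
    bits <- 16L
    dtype <- "uint16"
  } else {
    scale <- pow2Ceiling(vmax)
    bits <- 32L
    dtype <- "float32"
  }
  pages <- vector("list", d[1L] * d[2L])
  p <- 1L
  for (ci in seq_len(d[1L])) {
    for (zi in seq_len(d[2L])) {
      pages[[p]] <- v[ci, zi, , ] / scale
      p <- p + 1L
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE),
    error = function(e) stopIO("cannot write TIFF '%s': %s", path,
                               conditionMessage(e)),
    warning = function(w) stopIO("cannot write TIFF '%s': %s", path,
                                 conditionMessage(w))
  )
  writeSidecar(path, list(
    format = "PeelStack-ImageStack", version = 1L,
    n_channels = d[1L], nz = d[2L], ny = d[3L], nx = d[4L],
    channel_names = as.list(channelNames(stack)),
    voxel_size_um = voxelSize(stack), z_origin = stack@zOrigin,
    dtype = dtype, scale = scale, page_order = "channel_major"
  ))
  invisible(path)
}

#' Write / read a height map
#'
#' Stored as a two-page TIFF: a 32-bit height page (invalid pixels coded
#' 0) and a validity-mask page (the spec of validity; invalid pixels are
#' re-coded \code{NA} on read so they can never leak into the valid set).
#' Heights round-trip within \code{scale * 2^-32} of their values, i.e.
#' at better than single-precision accuracy for in-range heights.
#'
#' @param hm a \code{\linkS4class{HeightMap}}.
#' @param path output TIFF path.
#' @return \code{path} (write) or a \code{HeightMap} (read).
#' @export
writeHeightMap <- function(hm, path) {
  stopifnot(is(hm, "HeightMap"))
  checkWritable(path)
  h <- heightValues(hm)
  v <- validMask(hm)
  h0 <- h
  h0[!v] <- 0
  scale <- pow2Ceiling(max(h0, 1))
  tryCatch(
    tiff::writeTIFF(list(h0 / scale, v * 1.0), path,
                    bits.per.sample = 32L, reduce = FALSE),
    error = function(e) stopIO("cannot write TIFF '%s': %s", path,
                               conditionMessage(e))
  )
  writeSidecar(path, list(
    format = "PeelStack-HeightMap", version = 1L,
    ny = nrow(h), nx = ncol(h), nz = hm@nz, scale = scale
  ))
  invisible(path)
}

#' @rdname writeHeightMap
#' @export
readHeightMap <- function(path) {
  pages <- readPages(path)
  meta <- readSidecar(path)
  if (is.null(meta) || !identical(meta$format, "PeelStack-HeightMap"))
    stopConfig("'%s' is not a PeelStack height map (missing or foreign sidecar)",
               path)
  if (length(pages) != 2L)
    stopConfig("height-map file '%s' must have exactly 2 pages", path)
  h <- pages[[1L]] * as.numeric(meta$scale)
  attributes(h) <- list(dim = dim(h))
  valid <- pages[[2L]] > 0.5
  h[!valid] <- NA_real_
  HeightMap(h, valid, nz = as.integer(meta$nz))
}

#' Write / read a layer mask
#'
#' Stored as 8-bit 0/255 pages, one per z slice.
#'
#' @param mask a \code{\linkS4class{LayerMask}}.
#' @param path output TIFF path.
#' @return \code{path} (write) or a \code{LayerMask} (read).
#' @export
writeLayerMask <- function(mask, path) {
  stopifnot(is(mask, "LayerMask"))
  checkWritable(path)
  m <- maskArray(mask)
  d <- dim(m)
  pages <- lapply(seq_len(d[1L]), function(z) m[z, , ] * 1.0)
  tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE),
    error = function(e) stopIO("cannot write TIFF '%s': %s", path,
                               conditionMessage(e))
  )
  writeSidecar(path, list(
    format = "PeelStack-LayerMask", version = 1L,
    nz = d[1L], ny = d[2L], nx = d[3L]
  ))
  invisible(path)
}

#' @rdname writeLayerMask
#' @export
readLayerMask <- function(path) {
  pages <- readPages(path)
  d1 <- dim(pages[[1L]])
  m <- array(FALSE, c(length(pages), d1[1L], d1[2L]))
  for (z in seq_along(pages)) m[z, , ] <- pages[[z]] > 0.5
  LayerMask(m)
}

#' Write / read a projection image
#'
#' Stored as one 32-bit float page per channel plus a JSON sidecar with
#' the projection method, channel names and intensity scale.
#'
#' @param proj a \code{\linkS4class{ProjectionImage}}.
#' @param path output TIFF path.
#' @return \code{path} (write) or a \code{ProjectionImage} (read).
#' @export
writeProjection <- function(proj, path) {
  stopifnot(is(proj, "ProjectionImage"))
  checkWritable(path)
  p <- projectionPixels(proj)
  d <- dim(p)
  scale <- pow2Ceiling(max(p, 1))
  pages <- lapply(seq_len(d[1L]), function(ci) p[ci, , ] / scale)
  tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE),
    error = function(e) stopIO("cannot write TIFF '%s': %s", path,
                               conditionMessage(e))
  )
  writeSidecar(path, list(
    format = "PeelStack-Projection", version = 1L,
    n_channels = d[1L], ny = d[2L], nx = d[3L],
    channel_names = as.list(channelNames(proj)),
    method = proj@method, scale = scale
  ))
  invisible(path)
}

#' @rdname writeProjection
#' @export
readProjection <- function(path) {
  pages <- readPages(path)
  meta <- readSidecar(path)
  if (is.null(meta) || !identical(meta$format, "PeelStack-Projection"))
    stopConfig("'%s' is not a PeelStack projection (missing or foreign sidecar)",
               path)
  d1 <- dim(pages[[1L]])
  p <- array(0, c(length(pages), d1[1L], d1[2L]))
  for (ci in seq_along(pages))
    p[ci, , ] <- pages[[ci]] * as.numeric(meta$scale)
  new("ProjectionImage", pixels = p, method = as.character(meta$method),
      channelNames = as.character(meta$channel_names))
}

#' Export a projection channel as an 8-bit PNG for display
#'
#' Applies explicit min/max display scaling (values are clipped); this is
#' a display export only and is lossy by design — quantitative output
#' stays in the float TIFF written by \code{\link{writeProjection}}.
#'
#' @param proj a \code{\linkS4class{ProjectionImage}}.
#' @param path output PNG path.
#' @param channel channel index to export.
#' @param min,max display range; defaults to the channel's data range.
#' @return \code{path}, invisibly.
#' @export
exportPNG <- function(proj, path, channel = 1L, min = NULL, max = NULL) {
  stopifnot(is(proj, "ProjectionImage"))
  checkWritable(path)
  img <- projectionPixels(proj)[channel, , ]
  if (is.null(min)) min <- base::min(img)
  if (is.null(max)) max <- base::max(img)
  if (max <= min) max <- min + 1
  scaled <- pmin(pmax((img - min) / (max - min), 0), 1)
  png::writePNG(scaled, path)
  invisible(path)
}
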