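# Ground-truthed synthetic data: two-tissue confocal leaf phantoms for
# the imaging pipeline, plus tabular count and Ct fixtures for the
# phenotype formulas.  All generators are deterministic under their seed;
# per-step sub-seeds are derived from the single master seed.

#' Construct a synthetic leaf-stack specification
#'
#' Describes a phantom emulating a confocal Z-stack acquired through the
#' outer (abaxial) epidermis into the mesophyll: a smooth curved surface,
#' a bright thin epidermal layer directly below it and a deeper mesophyll
#' layer, with noise.  Channel 1 is a plasma-membrane marker: a 2-slice
#' bright shell at the surface (two slices so the shell satisfies the
#' detector's default two-slice run requirement, mimicking the axial
#' spread of a real membrane marker) plus sparse cell-wall texture inside
#' both tissue layers.  Channel 2 is a reporter with a homogeneous mean
#' per tissue.
#'
#' Surface models (heights are zero-based slice coordinates; x and y
#' below are zero-based pixel coordinates):
#' \itemize{
#'   \item \code{"flat"}: \code{h = baseDepth}
#'   \item \code{"plane"}: \code{h = baseDepth + tiltX * x + tiltY * y}
#'   \item \code{"sine"}: \code{h = baseDepth + amplitude *
#'     sin(2 pi x / period) * sin(2 pi y / period)}
#'   \item \code{"bump"}: \code{h = baseDepth - amplitude *
#'     exp(-((x - cx)^2 + (y - cy)^2) / (2 width^2))}
#' }
#' The rasterized surface must stay at least one slice away from both z
#' boundaries.
#'
#' @param shape stack shape \code{c(nz, ny, nx)}.
#' @param surfaceModel \code{"flat"}, \code{"plane"}, \code{"sine"} or
#'   \code{"bump"}.
#' @param baseDepth mean surface depth in slices.
#' @param tiltX,tiltY plane tilt in slices per pixel.
#' @param amplitude sine/bump amplitude in slices.
#' @param period sine period in pixels.
#' @param center bump centre \code{c(y, x)} in pixels (default: image
#'   centre).
#' @param width bump Gaussian width in pixels.
#' @param epidermisThickness epidermal layer thickness in slices, >= 1.
#' @param mesophyllGap dark gap between the tissues in slices, >= 0.
#' @param mesophyllThickness mesophyll layer thickness in slices, >= 1.
#' @param markerIntensity membrane-marker shell intensity, > 0.
#' @param reporterMeans reporter means \code{c(epidermis, mesophyll)}.
#' @param noiseSigma additive Gaussian noise SD (clipped at 0), >= 0.
#' @param poisson also apply Poisson shot noise to the clean signal.
#' @param seed master seed; all randomness derives from it.
#' @return A \code{\linkS4class{PhantomSpec}}.
#' @examples
#' phantomSpec(surfaceModel = "flat", baseDepth = 5, noiseSigma = 0)
#' @export
phantomSpec <- function(shape = c(30L, 256L, 256L),
                        surfaceModel = c("sine", "flat", "plane", "bump"),
                        baseDepth = 5, tiltX = 0.02, tiltY = 0,
                        amplitude = 3, period = 64,
                        center = NULL, width = 32,
                        epidermisThickness = 4L, mesophyllGap = 2L,
                        mesophyllThickness = 8L,
                        markerIntensity = 100,
                        reporterMeans = c(80, 40),
                        noiseSigma = 5, poisson = FALSE, seed = 1L) {
  surfaceModel <- match.arg(surfaceModel)
  if (is.null(center)) center <- (shape[2:3] - 1) / 2
  new("PhantomSpec",
      shape = as.integer(shape), surfaceModel = surfaceModel,
      surfaceArgs = list(baseDepth = baseDepth, tiltX = tiltX,
                         tiltY = tiltY, amplitude = amplitude,
                         period = period, center = center, width = width),
      epidermisThickness = as.integer(epidermisThickness),
      mesophyllGap = as.integer(mesophyllGap),
      mesophyllThickness = as.integer(mesophyllThickness),
      markerIntensity = as.numeric(markerIntensity),
      reporterMeans = as.numeric(reporterMeans),
      noiseSigma = as.numeric(noiseSigma),
      poisson = isTRUE(poisson), seed = as.integer(seed))
}

# Continuous surface model evaluated on the pixel grid (ny x nx).
analyticSurface <- function(spec) {
  a <- spec@surfaceArgs
  ny <- spec@shape[2L]
  nx <- spec@shape[3L]
  x0 <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  y0 <- matrix(seq_len(ny) - 1, ny, nx)
  switch(spec@surfaceModel,
    flat = matrix(a$baseDepth, ny, nx),
    plane = a$baseDepth + a$tiltX * x0 + a$tiltY * y0,
    sine = a$baseDepth + a$amplitude *
      sin(2 * pi * x0 / a$period) * sin(2 * pi * y0 / a$period),
    bump = a$baseDepth - a$amplitude *
      exp(-((x0 - a$center[2L])^2 + (y0 - a$center[1L])^2) /
            (2 * a$width^2))
  )
}

#' Simulate a two-tissue confocal leaf stack with exact ground truth
#'
#' Rasterizes the surface model to its nearest slice per pixel, labels an
#' epidermal and a mesophyll layer below it, paints the membrane-marker
#' and reporter channels, and adds seeded noise.  Identical spec and seed
#' give bit-identical output.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return A list: \code{stack} (an \code{\linkS4class{ImageStack}} with
#'   channels \code{"membrane"} and \code{"reporter"}) and \code{truth}
#'   (a \code{\linkS4class{PhantomTruth}}).
#' @examples
#' sim <- simulateStack(phantomSpec(shape = c(15L, 32L, 32L),
#'                                  surfaceModel = "flat", noiseSigma = 0))
#' sim$stack
#' @export
simulateStack <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  nz <- spec@shape[1L]
  ny <- spec@shape[2L]
  nx <- spec@shape[3L]
  hA <- analyticSurface(spec)
  s0 <- floor(hA + 0.5)          # nearest-slice rasterization, zero-based
  if (min(s0) < 1 || max(s0) > nz - 2)
    stopInput("surface model exits stack bounds: rasterized surface must stay in [1, nz - 2]")
  zIdx <- array(rep(seq_len(nz) - 1, ny * nx), c(nz, ny, nx))
  s0Arr <- aperm(array(s0, c(ny, nx, nz)), c(3L, 1L, 2L))
  epiTop <- s0Arr
  epiBot <- s0Arr + spec@epidermisThickness            # exclusive
  mesTop <- epiBot + spec@mesophyllGap
  mesBot <- mesTop + spec@mesophyllThickness           # exclusive
  labels <- array(0L, c(nz, ny, nx))
  labels[zIdx >= epiTop & zIdx < epiBot] <- 1L
  labels[zIdx >= mesTop & zIdx < mesBot] <- 2L
  shell <- zIdx >= epiTop & zIdx < epiTop + 2   # 2-slice marker shell
  withSeed(spec@seed, {
    marker <- array(0, c(nz, ny, nx))
    # sparse cell-wall texture inside the tissue layers
    inTissue <- labels > 0L
    walls <- inTissue & array(stats::runif(nz * ny * nx) < 0.03,
                              c(nz, ny, nx))
    marker[walls] <- 0.6 * spec@markerIntensity
    marker[shell] <- spec@markerIntensity
    reporter <- array(0, c(nz, ny, nx))
    reporter[labels == 1L] <- spec@reporterMeans[1L]
    reporter[labels == 2L] <- spec@reporterMeans[2L]
    if (spec@poisson) {
      marker <- array(stats::rpois(length(marker), marker), dim(marker))
      reporter <- array(stats::rpois(length(reporter), reporter),
                        dim(reporter))
    }
    if (spec@noiseSigma > 0) {
      marker <- marker + stats::rnorm(length(marker), sd = spec@noiseSigma)
      reporter <- reporter +
        stats::rnorm(length(reporter), sd = spec@noiseSigma)
    }
    marker <- pmax(marker, 0)
    reporter <- pmax(reporter, 0)
  })
  v <- array(0, c(2L, nz, ny, nx))
  v[1L, , , ] <- marker
  v[2L, , , ] <- reporter
  stack <- ImageStack(v, channelNames = c("membrane", "reporter"))
  truth <- new("PhantomTruth", height = s0, heightAnalytic = hA,
               labels = labels, spec = spec)
  list(stack = stack, truth = truth)
}

#' Simulate stomatal count records
#'
#' Per sample, the stomatal count is binomial over \code{cellsPerRoi}
#' epidermal cells with success probability \code{siTrue / 100};
#' non-stomatal cells make up the remainder.
#'
#' @param nSamples number of counting regions.
#' @param siTrue true stomatal index in percent, in [0, 100].
#' @param cellsPerRoi total epidermal cells per counting region.
#' @param seed RNG seed.
#' @param roiAreaMm2 counting-region area (default 0.16 mm^2, a
#'   400 um x 400 um region).
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{stomata}, \code{epidermal_cells}, \code{roi_area_mm2}.
#' @export
simulateCounts <- function(nSamples, siTrue, cellsPerRoi, seed = 1L,
                           roiAreaMm2 = 0.16) {
  if (!is.finite(siTrue) || siTrue < 0 || siTrue > 100)
    stopInput("siTrue must be a percentage in [0, 100]")
  stomata <- withSeed(seed,
    stats::rbinom(nSamples, size = cellsPerRoi, prob = siTrue / 100))
  data.frame(
    sample_id = sprintf("roi%03d", seq_len(nSamples)),
    stomata = stomata,
    epidermal_cells = cellsPerRoi - stomata,
    roi_area_mm2 = roiAreaMm2,
    stringsAsFactors = FALSE
  )
}

#' Simulate qRT-PCR Ct records with known fold-changes
#'
#' Target Ct is \code{baseCt - log2(fold)} plus Gaussian replicate noise;
#' the reference gene's Ct is \code{baseCt} plus noise.  Running
#' \code{\link{relativeExpression}} on the output with the fold-1
#' condition as calibrator recovers the fold-changes in expectation.
#'
#' @param foldChanges named numeric vector of true fold-changes per
#'   condition (names are the condition labels), all > 0; the calibrator
#'   condition should have fold 1.
#' @param baseCt baseline cycle-threshold value.
#' @param replicateSigma SD of per-measurement Gaussian Ct noise.
#' @param nReplicates biological replicates per condition.
#' @param seed RNG seed.
#' @param gene,referenceGene labels for the target and normalizer gene.
#' @return A Ct \code{data.frame} as accepted by
#'   \code{\link{relativeExpression}}.
#' @examples
#' ct <- simulateCt(c(control = 1, treated = 4), replicateSigma = 0)
#' relativeExpression(ct, calibrator = "control")
#' @export
simulateCt <- function(foldChanges, baseCt = 25, replicateSigma = 0.2,
                       nReplicates = 3L, seed = 1L,
                       gene = "TARGET", referenceGene = "UBC21") {
  if (is.null(names(foldChanges)) || any(!nzchar(names(foldChanges))))
    stopInput("foldChanges must be a named vector (names = conditions)")
  if (any(!is.finite(foldChanges)) || any(foldChanges <= 0))
    stopInput("fold-changes must be finite and > 0")
  conds <- names(foldChanges)
  rows <- withSeed(seed, {
    out <- vector("list", length(conds))
    for (i in seq_along(conds)) {
      ids <- sprintf("%s_rep%d", conds[i], seq_len(nReplicates))
      tgt <- baseCt - log2(foldChanges[i]) +
        stats::rnorm(nReplicates, sd = replicateSigma)
      ref <- baseCt + stats::rnorm(nReplicates, sd = replicateSigma)
      out[[i]] <- data.frame(
        sample_id = rep(ids, 2L),
        condition = conds[i],
        gene = rep(c(gene, referenceGene), each = nReplicates),
        ct = c(tgt, ref),
        reference_gene = referenceGene,
        stringsAsFactors = FALSE
      )
    }
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
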