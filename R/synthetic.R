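#' @include imaging.R indentation.R
NULL

.ellipseMask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c_ - center[2]) / axes[2])^2 <= 1
}

#' Render a synthetic labelled cell image with known n/c ratio
#'
#' Draws an elliptical cell with an elliptical nucleus; nuclear pixels have
#' mean intensity `targetRatio` times the cytoplasmic mean, so the true
#' nuclear/cytoplasmic ratio is known by construction (and exact in the
#' noise-free case). Optional Gaussian or Poisson (photon-counting) noise.
#' Exact masks are returned with the image; rendering is reproducible given
#' the spec's seed.
#'
#' @param spec An [ImageSpec].
#' @return A [LabeledCellImage]; the ground-truth ratio is attached as
#'   attribute `trueRatio`.
#' @examples
#' img <- makeCellImage(ImageSpec(targetRatio = 4))
#' ncRatioSparse(img)  # exactly 4
#' @export
makeCellImage <- function(spec = ImageSpec()) {
  validObject(spec)
  shape <- spec@imageShape
  cellCenter <- if (length(spec@cellCenter)) spec@cellCenter else shape / 2
  nucCenter <- if (length(spec@nucleusCenter)) spec@nucleusCenter else
    cellCenter
  cellMask <- .ellipseMask(shape, cellCenter, spec@cellAxes)
  nucMask <- .ellipseMask(shape, nucCenter, spec@nucleusAxes)
  if (any(nucMask & !cellMask))
    stop("nucleus ellipse is not contained in the cell ellipse")
  if (!any(cellMask & !nucMask))
    stop("cell ellipse leaves no cytoplasmic region around the nucleus")

  mean_ <- matrix(0.025 * spec@cytoplasmMean, shape[1], shape[2])
  mean_[cellMask] <- spec@cytoplasmMean
  mean_[nucMask] <- spec@targetRatio * spec@cytoplasmMean

  set.seed(spec@seed)
  intensity <- switch(
    spec@noiseModel,
    none = mean_,
    gaussian = pmax(0, mean_ + rnorm(length(mean_),
                                     sd = spec@gaussianSdFraction *
                                       spec@cytoplasmMean)),
    poisson = matrix(rpois(length(mean_), mean_), shape[1], shape[2]))
  dim(intensity) <- shape

  out <- LabeledCellImage(intensity = intensity, nucleusMasks = nucMask,
                          cellMask = cellMask,
                          saturationValue = spec@saturationValue)
  attr(out, "trueRatio") <- spec@targetRatio
  out
}

#' Tile a synthetic cell into a confluent zone
#'
#' Renders one cell from `spec` and tiles `nCells` copies side by side; the
#' zone mask is the union of the cell masks and each nucleus keeps its own
#' mask. Because the tiles are identical, the zone-averaged ratio of
#' [ncRatioConfluent()] equals the single-cell ratio exactly, noise or not.
#'
#' @param spec An [ImageSpec].
#' @param nCells Number of tiled copies (>= 1).
#' @return A [LabeledCellImage] whose `cellMask` is the zone.
#' @examples
#' ncRatioConfluent(makeConfluentImage(ImageSpec(targetRatio = 2), 3))
#' @export
makeConfluentImage <- function(spec = ImageSpec(), nCells = 2L) {
  stopifnot(nCells >= 1)
  one <- makeCellImage(spec)
  shape <- dim(one@intensity)
  intensity <- do.call(cbind, rep(list(one@intensity), nCells))
  zone <- do.call(cbind, rep(list(one@cellMask), nCells))
  empty <- matrix(FALSE, shape[1], shape[2])
  nucMasks <- lapply(seq_len(nCells), function(k) {
    blocks <- rep(list(empty), nCells)
    blocks[[k]] <- one@nucleusMasks[[1]]
    do.call(cbind, blocks)
  })
  out <- LabeledCellImage(intensity = intensity, nucleusMasks = nucMasks,
                          cellMask = zone,
                          saturationValue = spec@saturationValue)
  attr(out, "trueRatio") <- spec@targetRatio
  out
}

#' Synthetic ellipsoidal nucleus z-stack
#'
#' Renders a solid ellipsoid (axis lengths `length` >= `width` >= `height`,
#' micrometres) on a voxel grid, bright interior over dim background, with
#' optional per-slice Gaussian blur emulating in-plane optics. The
#' ellipsoid centre sits on voxel boundaries so the discretized silhouette
#' is symmetric. Ground truth is returned alongside the stack.
#'
#' @param length,width,height Ellipsoid axis lengths, um.
#' @param voxelSize Voxel edges `c(x, y, z)`, um; the 0.5 um z-step matches
#'   typical confocal stacks.
#' @param blurSigma In-plane Gaussian blur sd, um (0 disables).
#' @param seed RNG seed (reserved; rendering is deterministic).
#' @return A list with `stack` (3-D array), `voxelSize`, `trueLength`,
#'   `trueHeight` and `trueFlattening` (= length/height).
#' @examples
#' stk <- makeNucleusZstack(20, 10, 5)
#' stk$trueFlattening
#' @export
makeNucleusZstack <- function(length, width, height,
                              voxelSize = c(0.2, 0.2, 0.5),
                              blurSigma = 0, seed = 1L) {
  stopifnot(length >= width, width >= height, height > 0,
            is.numeric(voxelSize), base::length(voxelSize) == 3,
            all(voxelSize > 0), blurSigma >= 0)
  if (any(voxelSize > c(length, width, height)))
    stop("voxel size exceeds an ellipsoid axis; the shape cannot be ",
         "resolved")
  semi <- c(length, width, height) / 2
  dims <- 2L * (as.integer(ceiling(semi / voxelSize)) + 3L)
  centre <- dims / 2 * voxelSize   # on a voxel boundary in every axis
  ax <- (seq_len(dims[1]) - 0.5) * voxelSize[1]
  ay <- (seq_len(dims[2]) - 0.5) * voxelSize[2]
  az <- (seq_len(dims[3]) - 0.5) * voxelSize[3]
  dx2 <- ((ax - centre[1]) / semi[1])^2
  dy2 <- ((ay - centre[2]) / semi[2])^2
  dz2 <- ((az - centre[3]) / semi[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  stack <- array(10, dims)
  stack[inside] <- 200
  if (blurSigma > 0) {
    sigmaPx <- blurSigma / voxelSize[1]
    for (k in seq_len(dims[3]))
      stack[, , k] <- EBImage::gblur(stack[, , k], sigma = sigmaPx)
  }
  list(stack = stack, voxelSize = voxelSize, trueLength = length,
       trueHeight = height, trueFlattening = length / height)
}

#' Synthetic co-localization channel pair with known overlap
#'
#' Builds two bimodal intensity channels whose Otsu-positive areas overlap
#' by a prescribed fraction of channel A's positive area (up to one pixel
#' of rounding). Channel B keeps a disjoint positive block so its positive
#' area is non-empty even at zero overlap.
#'
#' @param overlapFraction Target `|A+ and B+| / |A+|` in \[0, 1\].
#' @param shape Image dimensions in pixels.
#' @param seed RNG seed (reserved; construction is deterministic).
#' @return A list with `channelA`, `channelB`, `roi` and `trueFraction`
#'   (percent).
#' @examples
#' m <- makeColocMasks(0.5)
#' colocalizationFraction(m$channelA, m$channelB, m$roi)
#' @export
makeColocMasks <- function(overlapFraction, shape = c(64L, 64L),
                           seed = 1L) {
  stopifnot(overlapFraction >= 0, overlapFraction <= 1,
            all(shape >= 56))
  aMask <- matrix(FALSE, shape[1], shape[2])
  aMask[17:36, 9:28] <- TRUE
  nA <- sum(aMask)
  nOver <- round(overlapFraction * nA)
  bMask <- matrix(FALSE, shape[1], shape[2])
  bMask[which(aMask)[seq_len(nOver)]] <- TRUE
  bMask[45:54, 41:50] <- TRUE   # disjoint from A, keeps B+ non-empty
  toChannel <- function(m) matrix(ifelse(m, 200, 10), shape[1], shape[2])
  list(channelA = toChannel(aMask), channelB = toChannel(bMask),
       roi = matrix(TRUE, shape[1], shape[2]),
       trueFraction = 100 * nOver / nA)
}

#' Synthetic Hertz load-indentation curve
#'
#' Evaluates the forward Hertz model on an even depth grid and applies
#' multiplicative Gaussian noise to the loads,
#' `P = P_hertz * (1 + e)`, `e ~ N(0, noiseFraction^2)`; reproducible given
#' the spec's seed.
#'
#' @param spec A [CurveSpec].
#' @return An [IndentationCurve]; the ground-truth modulus is attached as
#'   attribute `trueModulus`.
#' @examples
#' fitYoungModulus(makeIndentationCurve(CurveSpec(trueModulus = 20e3)))
#' @export
makeIndentationCurve <- function(spec = CurveSpec()) {
  validObject(spec)
  h <- seq(0, spec@maxIndentation, length.out = spec@nPoints)
  p <- hertzLoad(spec@trueModulus, spec@poissonRatio, spec@tipRadius, h)
  if (spec@noiseFraction > 0) {
    set.seed(spec@seed)
    p <- p * (1 + rnorm(length(p), sd = spec@noiseFraction))
  }
  out <- IndentationCurve(indentation = h, load = p,
                          tipRadius = spec@tipRadius,
                          poissonRatio = spec@poissonRatio)
  attr(out, "trueModulus") <- spec@trueModulus
  out
}
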