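#' @include AllGenerics.R
NULL

# Otsu threshold of a numeric vector (maximal between-class variance on a
# 256-bin histogram). EBImage's otsu() operates on whole 2-D frames; the
# package also needs thresholds of masked regions and of 3-D stacks, so the
# histogram search is applied to the raw value vector here (validated
# against EBImage on full frames in the test suite).
.otsu <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to threshold")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- as.numeric(tabulate(findInterval(values, breaks,
                                             all.inside = TRUE),
                                nbins = levels))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / w1
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / w2
  between <- w1 * w2 * (m1 - m2)^2
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

.checkSaturation <- function(img) {
  if (any(img@intensity[img@cellMask] >= img@saturationValue))
    stop("saturated fluorescence inside the cell mask; image excluded ",
         "from ratio quantification")
}

#' Nuclear/cytoplasmic intensity ratio of a sparse cell
#'
#' Area-weighted ratio of total nuclear to total cytoplasmic fluorescence,
#' \deqn{R_{NC} = \frac{I_{nucleus}/A_{nucleus}}
#'   {(I_{cell}-I_{nucleus})/(A_{cell}-A_{nucleus})},}
#' with areas in pixels (units cancel, so the result is independent of
#' pixel size and of any positive rescaling of the intensities). Images
#' with saturated fluorescence inside the cell are rejected.
#'
#' @param img A [LabeledCellImage] with exactly one nucleus mask.
#' @return The nuclear/cytoplasmic ratio.
#' @examples
#' nc_ratio <- ncRatioSparse(makeCellImage(ImageSpec(targetRatio = 2)))
#' @export
ncRatioSparse <- function(img) {
  validObject(img)
  if (length(img@nucleusMasks) != 1)
    stop("ncRatioSparse expects exactly one nucleus mask; use ",
         "ncRatioConfluent for multi-nucleus zones")
  .checkSaturation(img)
  nuc <- img@nucleusMasks[[1]]
  iNuc <- sum(img@intensity[nuc])
  aNuc <- sum(nuc)
  iCell <- sum(img@intensity[img@cellMask])
  aCell <- sum(img@cellMask)
  cyto <- (iCell - iNuc) / (aCell - aNuc)
  if (cyto <= 0)
    stop("cytoplasmic mean intensity is not positive; ",
         "nuclear/cytoplasmic ratio undefined")
  (iNuc / aNuc) / cyto
}

#' Average nuclear/cytoplasmic ratio over a confluent zone
#'
#' Pools all nuclei inside a multicellular zone:
#' \deqn{R_{NC} = \frac{\sum_i I^i_{nuc} / \sum_i A^i_{nuc}}
#'   {(I_{zone}-\sum_i I^i_{nuc})/(A_{zone}-\sum_i A^i_{nuc})}.}
#' With a single nucleus and the zone equal to the cell mask this reduces
#' exactly to [ncRatioSparse()].
#'
#' @param img A [LabeledCellImage] whose `cellMask` delineates the zone and
#'   whose `nucleusMasks` are the (disjoint) nuclei inside it.
#' @return The zone-averaged nuclear/cytoplasmic ratio.
#' @examples
#' img <- makeConfluentImage(ImageSpec(targetRatio = 2), nCells = 3)
#' ncRatioConfluent(img)
#' @export
ncRatioConfluent <- function(img) {
  validObject(img)
  masks <- img@nucleusMasks
  if (length(masks) > 1) {
    overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (any(overlap > 1L)) stop("nucleus masks must be disjoint")
  }
  .checkSaturation(img)
  iNuc <- sum(vapply(masks, function(m) sum(img@intensity[m]), numeric(1)))
  aNuc <- sum(vapply(masks, sum, numeric(1)))
  iZone <- sum(img@intensity[img@cellMask])
  aZone <- sum(img@cellMask)
  cyto <- (iZone - iNuc) / (aZone - aNuc)
  if (cyto <= 0)
    stop("cytoplasmic mean intensity is not positive; ",
         "nuclear/cytoplasmic ratio undefined")
  (iNuc / aNuc) / cyto
}

#' Nuclear flattening from a 3-D z-stack
#'
#' Segments the nucleus by a global Otsu threshold on the stack and keeps
#' the largest 6-connected component. The in-plane length is the extent of
#' the x-y projection along its principal axis and the height the z extent
#' of the x-z projection, both measured by the second-moment rule for a
#' filled ellipse (extent = 4 sd), which is sub-voxel accurate and robust
#' to moderate blur. Flattening is length/height; values below 1 trigger a
#' warning but are returned.
#'
#' @param zstack 3-D numeric array (x, y, z) of intensities.
#' @param voxelSize Voxel edge lengths in micrometres, `c(x, y, z)`; the
#'   default matches 0.2 um pixels with 0.5 um z-steps.
#' @return A `NucleusGeometry` with length, height (um) and flattening.
#' @examples
#' stk <- makeNucleusZstack(20, 10, 5)
#' nuclearFlattening(stk$stack, stk$voxelSize)
#' @export
nuclearFlattening <- function(zstack, voxelSize = c(0.2, 0.2, 0.5)) {
  if (!is.array(zstack) || length(dim(zstack)) != 3)
    stop("zstack must be a 3-D array")
  stopifnot(is.numeric(voxelSize), length(voxelSize) == 3,
            all(voxelSize > 0))
  mask <- zstack > .otsu(as.vector(zstack))
  if (!any(mask)) stop("empty segmentation: no voxels above threshold")
  labels <- label3d(as.vector(mask), dim(zstack))
  keep <- which.max(tabulate(labels[labels > 0]))
  idx <- which(labels == keep, arr.ind = TRUE)
  # voxel centres in um
  x <- (idx[, 1] - 0.5) * voxelSize[1]
  y <- (idx[, 2] - 0.5) * voxelSize[2]
  z <- (idx[, 3] - 0.5) * voxelSize[3]

  # x-y projection: principal-axis extent of the filled silhouette
  xy <- unique(cbind(x, y))
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  len <- 4 * sqrt(max(ev))
  # x-z projection: z extent of the silhouette
  xz <- unique(cbind(x, z))
  hei <- 4 * stats::sd(xz[, 2])
  if (!is.finite(hei) || hei == 0)  # single z-slice: fall back to voxel size
    hei <- voxelSize[3]
  flat <- len / hei
  if (flat < 1)
    warning(sprintf("flattening %.3f < 1: measured height exceeds length",
                    flat))
  new("NucleusGeometry", length = len, height = hei, flattening = flat)
}

#' Thresholded co-localization fraction
#'
#' Percentage of the first channel's positive area that is also positive in
#' the second channel (a Manders M1-style area overlap): both channels are
#' binarized by an Otsu threshold computed within the region of interest,
#' and the fraction `100 * |A+ and B+| / |A+|` is returned. The measure is
#' deliberately asymmetric in (A, B).
#'
#' @param channelA,channelB Numeric intensity matrices of equal shape
#'   (e.g. N-cadherin and beta-catenin channels).
#' @param roiMask Logical matrix selecting the region of interest
#'   (non-empty).
#' @return Overlap percentage in \[0, 100\].
#' @examples
#' m <- makeColocMasks(0.5)
#' colocalizationFraction(m$channelA, m$channelB, m$roi)
#' @export
colocalizationFraction <- function(channelA, channelB,
                                   roiMask = NULL) {
  if (!is.matrix(channelA) || !is.matrix(channelB) ||
      !all(dim(channelA) == dim(channelB)))
    stop("channelA and channelB must be matrices of equal shape")
  if (is.null(roiMask)) roiMask <- matrix(TRUE, nrow(channelA),
                                          ncol(channelA))
  if (!is.logical(roiMask) || !all(dim(roiMask) == dim(channelA)))
    stop("roiMask must be a logical matrix matching the channels")
  if (!any(roiMask)) stop("roiMask must be non-empty")
  aPos <- channelA > .otsu(channelA[roiMask]) & roiMask
  bPos <- channelB > .otsu(channelB[roiMask]) & roiMask
  if (!any(aPos))
    stop("no positive area in channel A; overlap fraction undefined")
  100 * sum(aPos & bPos) / sum(aPos)
}

#' Fraction of marker-positive cells
#'
#' `100 * nPositive / nTotal`, e.g. OCN- or ALP-positive cells over the
#' total count from DAPI staining.
#'
#' @param nPositive Number of marker-positive cells (0 <= nPositive <=
#'   nTotal).
#' @param nTotal Total number of cells (> 0).
#' @return Percentage in \[0, 100\].
#' @examples
#' positiveCellFraction(21, 60)
#' @export
positiveCellFraction <- function(nPositive, nTotal) {
  stopifnot(is.numeric(nPositive), is.numeric(nTotal))
  if (any(nTotal <= 0)) stop("nTotal must be > 0")
  if (any(nPositive < 0) || any(nPositive > nTotal))
    stop("nPositive must satisfy 0 <= nPositive <= nTotal")
  100 * nPositive / nTotal
}
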