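#' Construct a circular ROI specification
#'
#' @param centerMm (x, y) physical center in mm.
#' @param diameterMm circle diameter in mm.
#' @param slice 1-based slice index for 3D volumes.
#' @return a [RoiSpec-class].
#' @export
roiSpec <- function(centerMm, diameterMm, slice = 1L) {
    new("RoiSpec", centerMm = as.numeric(centerMm),
        diameterMm = diameterMm, slice = as.integer(slice))
}

# Logical mask of voxel centers inside the ROI circle; errors if the circle
# extends past the image bounds.
.roiMask <- function(image, roi) {
    v <- .sliceValues(image, roi@slice)
    sp <- spacing(image)[1:2]
    org <- origin(image)[1:2]
    d <- dim(v)
    r <- roi@diameterMm / 2
    lo <- org - sp / 2
    hi <- org + (d - 0.5) * sp
    if (any(roi@centerMm - r < lo) || any(roi@centerMm + r > hi))
        stop("ROI circle extends beyond the image bounds")
    x <- org[1] + (seq_len(d[1]) - 1) * sp[1]
    y <- org[2] + (seq_len(d[2]) - 1) * sp[2]
    outer(x - roi@centerMm[1], y - roi@centerMm[2],
          function(a, b) a^2 + b^2 <= r^2)
}

#' Mean over a circular ROI
#'
#' Voxel membership is by the voxel-center-in-circle test, with no
#' partial-volume weighting.
#'
#' @param image a [VoxelImage-class].
#' @param roi a [roiSpec()].
#' @return scalar mean of the included voxels.
#' @examples
#' img <- voxelImage(matrix(2, 64, 64), 2.4)
#' roiMean(img, roiSpec(c(0, 0), 20))
#' @export
roiMean <- function(image, roi) {
    m <- .roiMask(image, roi)
    if (!any(m)) stop("ROI contains no voxel centers")
    mean(.sliceValues(image, roi@slice)[m])
}

#' Slice uniformity from peripheral and central ROI means
#'
#' The larger absolute relative deviation of the extreme peripheral means
#' from the central mean: `max(|max(B) - A1|, |min(B) - A1|) / A1`.  A
#' constant image gives exactly 0; the statistic is invariant under global
#' rescaling.
#'
#' @param B numeric vector of the four peripheral 60 mm ROI means.
#' @param A1 central 120 mm ROI mean (> 0).
#' @return scalar uniformity (a fraction; multiply by 100 for percent).
#' @export
sliceUniformity <- function(B, A1) {
    if (length(B) != 4L) stop("B must hold the four peripheral ROI means")
    if (A1 <= 0) stop("central ROI mean must be positive")
    max(abs(max(B) - A1), abs(min(B) - A1)) / A1
}

#' The five-slice, five-circle uniformity layout
#'
#' Five analysis planes at the axial center and +/-30, +/-60 mm; per plane a
#' central 120 mm circle (A1) and four peripheral 60 mm circles (B1-B4)
#' placed at +/-`bOffsetMm` along the two transaxial axes — an axial cross
#' that keeps the 60 mm circles inside a 200 mm phantom with margin.
#'
#' @param sliceOffsetsMm axial analysis-plane offsets in mm.
#' @param bOffsetMm distance of the B-circle centers from the phantom
#'   center.
#' @param bDiameterMm,aDiameterMm peripheral / central circle diameters.
#' @param centerMm transaxial phantom center.
#' @return a layout list consumed by [imageUniformity()].
#' @export
uniformityLayout <- function(sliceOffsetsMm = c(-60, -30, 0, 30, 60),
                             bOffsetMm = 45, bDiameterMm = 60,
                             aDiameterMm = 120, centerMm = c(0, 0)) {
    list(sliceOffsetsMm = sliceOffsetsMm, bOffsetMm = bOffsetMm,
         bDiameterMm = bDiameterMm, aDiameterMm = aDiameterMm,
         centerMm = centerMm)
}

#' Whole-image uniformity over the five-slice layout
#'
#' For each analysis plane, the four B means and the A1 mean are measured
#' and combined by [sliceUniformity()]; the whole-image uniformity is the
#' maximum over planes.  A 2D image is treated as a single-plane fallback.
#' For 3D volumes each requested offset is mapped to the nearest slice.
#'
#' @param volume a 2D or 3D [VoxelImage-class].
#' @param layout a [uniformityLayout()].
#' @return a [UniformityResult-class].
#' @export
imageUniformity <- function(volume, layout = uniformityLayout()) {
    v <- values(volume)
    is3d <- length(dim(v)) == 3L
    offsets <- if (is3d) layout$sliceOffsetsMm else 0
    cx <- layout$centerMm
    bo <- layout$bOffsetMm
    bCenters <- list(cx + c(bo, 0), cx + c(-bo, 0),
                     cx + c(0, bo), cx + c(0, -bo))
    rows <- lapply(offsets, function(off) {
        sl <- if (is3d) .nearestSlice(volume, off) else 1L
        B <- vapply(bCenters, function(cc)
            roiMean(volume, roiSpec(cc, layout$bDiameterMm, sl)),
            numeric(1))
        A1 <- roiMean(volume, roiSpec(cx, layout$aDiameterMm, sl))
        data.frame(offsetMm = off, B1 = B[1], B2 = B[2], B3 = B[3],
                   B4 = B[4], A1 = A1,
                   uniformity = sliceUniformity(B, A1))
    })
    per <- do.call(rbind, rows)
    new("UniformityResult", perSlice = per,
        wholeImage = max(per$uniformity))
}

.nearestSlice <- function(volume, offsetMm) {
    nz <- dim(values(volume))[3]
    z <- origin(volume)[3] + (seq_len(nz) - 1) * spacing(volume)[3]
    if (offsetMm < min(z) - spacing(volume)[3] / 2 ||
        offsetMm > max(z) + spacing(volume)[3] / 2)
        stop("requested slice offset outside the volume axial extent")
    which.min(abs(z - offsetMm))
}

#' 50% isocontour VOI around a lesion
#'
#' Voxels within the search region at or above `fraction` times the
#' regional maximum (inclusive threshold), restricted to the connected
#' component containing the maximum voxel (8-connectivity).  The mask
#' always contains the argmax voxel, and its size is nonincreasing in
#' `fraction`.
#'
#' @param image a 2D [VoxelImage-class].
#' @param searchRegion logical mask (same grid) or a [roiSpec()] circle.
#' @param fraction isocontour threshold fraction of the maximum (default
#'   0.5).
#' @return logical mask array.
#' @export
voiIsocontour <- function(image, searchRegion, fraction = 0.5) {
    v <- values(image)
    if (length(dim(v)) != 2L) stop("VOI extraction operates on 2D slices")
    region <- if (is(searchRegion, "RoiSpec"))
        .roiMask(image, searchRegion)
    else searchRegion
    if (!identical(dim(region), dim(v)))
        stop("search region is not on the image grid")
    if (!any(region)) stop("empty search region")
    vmax <- max(v[region])
    if (vmax <= 0) stop("search region contains no positive voxel")
    thr <- region & v >= fraction * vmax
    lab <- EBImage::bwlabel(thr)
    argmax <- which(region & v == vmax)[1]
    array(lab == lab[argmax], dim(v))
}

#' SUV scaling
#'
#' Standardized uptake value: activity concentration times body weight over
#' injected dose.  Under the simulation convention dose = weight, SUV
#' equals the reconstructed activity unchanged.
#'
#' @param image a [VoxelImage-class] of activity.
#' @param injectedDose injected dose (> 0), arbitrary units.
#' @param bodyWeight body weight (> 0), same unit convention.
#' @return a [VoxelImage-class] in SUV.
#' @export
suvScale <- function(image, injectedDose, bodyWeight) {
    if (injectedDose <= 0 || bodyWeight <= 0)
        stop("dose and weight must be positive")
    voxelImage(values(image) * bodyWeight / injectedDose,
               spacing(image), origin(image))
}

#' Mean and maximum over a VOI mask
#'
#' @param image a [VoxelImage-class].
#' @param mask logical array on the image grid.
#' @return named numeric `c(mean, max)`.
#' @export
voiStats <- function(image, mask) {
    v <- values(image)
    if (!any(mask)) stop("empty VOI mask")
    c(mean = mean(v[mask]), max = max(v[mask]))
}
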