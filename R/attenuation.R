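#' Convert CT Hounsfield units to 511 keV LAC (continuous CT mu-map)
#'
#' The standard two-segment ("bilinear") conversion: below 0 HU the LAC
#' scales linearly between air and water, `0.0096 * (1 + HU/1000)` mm^-1
#' (floored at 0); above 0 HU a shallower bone segment applies,
#' `0.0096 + 5.1e-6 * HU` mm^-1.  The mapping is monotone nondecreasing and
#' hits air (-1000 HU -> 0), water (0 HU -> 0.0096 mm^-1) and bone.
#'
#' @param ctHu a [VoxelImage-class] in Hounsfield units (>= -1024).
#' @return a [MuMap-class] with provenance `"ct_continuous"`.
#' @examples
#' hu <- voxelImage(matrix(c(-1000, 0, 1000, 500), 2, 2), 2.4)
#' values(huToLac(hu))
#' @export
huToLac <- function(ctHu) {
    hu <- values(ctHu)
    if (any(!is.finite(hu))) stop("non-finite HU values")
    if (any(hu < -1024)) stop("HU values below -1024")
    lac <- ifelse(hu <= 0, pmax(0, 0.0096 * (1 + hu / 1000)),
                  0.0096 + 5.1e-6 * hu)
    muMap(array(lac, dim(hu)), spacing(ctHu), origin(ctHu),
          provenance = "ct_continuous")
}

# Inverse of the bilinear conversion, per-LAC (mm^-1) -> HU.
.lacToHu <- function(lac) {
    ifelse(lac <= 0.0096, 1000 * (lac / 0.0096 - 1),
           (lac - 0.0096) / 5.1e-6)
}

#' Synthesize a CT image (HU) from ground-truth tissue labels
#'
#' Inverts the bilinear HU-to-LAC conversion on each class's ground-truth
#' LAC, so that `huToLac(synthCtFromLabels(labels))` reproduces the true
#' mu-map to within 1e-6 mm^-1 (noiseless).  Optional additive Gaussian HU
#' noise emulates CT measurement noise.
#'
#' @param labels a [TissueLabelMap-class].
#' @param noiseSdHu standard deviation of additive HU noise (0 = none).
#' @param seed seed for the noise.
#' @return a [VoxelImage-class] in HU.
#' @export
synthCtFromLabels <- function(labels, noiseSdHu = 0, seed = NULL) {
    lacs <- labels@lacTable[labels@classes]
    huClass <- .lacToHu(lacs)
    if (any(huClass > 3071))
        stop("a class LAC exceeds the representable CT range (3071 HU)")
    hu <- array(huClass[labels@labels], dim(labels@labels))
    if (noiseSdHu > 0)
        hu <- hu + .withSeed(seed,
            array(stats::rnorm(length(hu), 0, noiseSdHu), dim(hu)))
    hu <- pmax(hu, -1000)
    voxelImage(hu, labels@spacing, labels@origin)
}

#' Segmented-CT LAC rule
#'
#' Ordered half-open LAC bins with assigned values (all mm^-1): below 0.003
#' air (0); [0.003, 0.009) fat (0.008); [0.009, 0.011) water (0.0096);
#' >= 0.011 bone (0.0161).  Lung regions are overridden to 0.0032 after
#' binning, since the lung value falls inside the fat bin and cannot be
#' produced by thresholds alone.
#'
#' @param thresholds named numeric, strictly increasing bin edges.
#' @param assigned named numeric, values assigned per bin plus `lung`.
#' @return a list-based rule validated for strictly increasing thresholds
#'   and for each non-lung assigned value lying inside its own bin (which
#'   makes the segmentation idempotent).
#' @export
lacSegmentationRule <- function(
        thresholds = c(air = 0.003, fat = 0.009, water = 0.011),
        assigned = c(air = 0, fat = 0.008, water = 0.0096,
                     bone = 0.0161, lung = 0.0032)) {
    if (any(diff(thresholds) <= 0))
        stop("thresholds must be strictly increasing")
    bins <- rbind(c(-Inf, thresholds[["air"]]),
                  c(thresholds[["air"]], thresholds[["fat"]]),
                  c(thresholds[["fat"]], thresholds[["water"]]),
                  c(thresholds[["water"]], Inf))
    vals <- assigned[c("air", "fat", "water", "bone")]
    ok <- vals >= bins[, 1] & vals < bins[, 2]
    if (!all(ok))
        stop("assigned values must fall inside their own bins: ",
             paste(names(vals)[!ok], collapse = ", "))
    structure(list(thresholds = thresholds, assigned = assigned),
              class = "LacSegmentationRule")
}

#' Segment a continuous CT mu-map into discrete LACs
#'
#' Applies the threshold rule of [lacSegmentationRule()] voxelwise, then
#' overrides lung-mask voxels to the lung LAC.  The output contains only the
#' five assigned values, and the operation is idempotent for a fixed lung
#' mask.  For non-lung voxels it is monotone nondecreasing in the input LAC.
#'
#' @param muCt a [MuMap-class] in mm^-1.
#' @param lungMask logical array on the same grid (or NULL for none).
#' @param rule a [lacSegmentationRule()].
#' @return a [MuMap-class] with provenance `"ct_segmented"`.
#' @export
segmentCtLac <- function(muCt, lungMask = NULL,
                         rule = lacSegmentationRule()) {
    v <- values(muCt)
    if (!is.null(lungMask) && !identical(dim(lungMask), dim(v)))
        stop("lung mask is not on the mu-map grid")
    th <- rule$thresholds
    asg <- rule$assigned
    out <- array(asg[["bone"]], dim(v))
    out[v < th[["water"]]] <- asg[["water"]]
    out[v < th[["fat"]]] <- asg[["fat"]]
    out[v < th[["air"]]] <- asg[["air"]]
    if (!is.null(lungMask)) out[lungMask] <- asg[["lung"]]
    muMap(out, spacing(muCt), origin(muCt), provenance = "ct_segmented")
}

#' Four-class MRAC attenuation coefficients
#'
#' The predetermined LACs of segmentation-based MRAC — soft tissue
#' 0.096 cm^-1, fat 0.080 cm^-1, lung 0.032 cm^-1, air 0 — stored
#' internally in mm^-1.  There is deliberately no bone entry: bone is not
#' distinguished by the four-class segmentation, the central MRAC
#' limitation.
#'
#' @return named numeric of exactly four classes (mm^-1).
#' @export
mracClassTable <- function() {
    c(soft = 0.0096, fat = 0.0080, lung = 0.0032, air = 0)
}

#' Build the segmented MRAC mu-map from tissue labels
#'
#' Emulates four-class MR segmentation applied to the phantom: fat keeps its
#' fat LAC, lung its lung LAC, air and hardware become 0, and *everything
#' else* — soft tissue, liver, lesions and, crucially, bone — receives the
#' soft-tissue value.  Patient-tissue LAC therefore never exceeds
#' 0.0096 mm^-1, the source of the systematic bone under-attenuation this
#' package studies.  With `includeHardware`, a hardware mu-map (the
#' "hardcoded" CT-derived template of the rigid structures) is composited
#' in.
#'
#' @param labels a [TissueLabelMap-class].
#' @param includeHardware composite the hardware mu-map into the output.
#' @param hardwareMu a [MuMap-class] of the hardware alone (see
#'   [hardwareMuMap()]); required when `includeHardware` is TRUE.
#' @param classTable the four-class LAC table, see [mracClassTable()].
#' @return a [MuMap-class] with provenance `"mrac"` (or
#'   `"mrac_no_hardware"` when hardware is present in the labels but
#'   excluded from the map).
#' @export
mracMuMap <- function(labels, includeHardware = FALSE, hardwareMu = NULL,
                      classTable = mracClassTable()) {
    if (length(classTable) != 4L ||
        !setequal(names(classTable), c("soft", "fat", "lung", "air")))
        stop("classTable must hold exactly soft, fat, lung and air")
    if (includeHardware && is.null(hardwareMu))
        stop("includeHardware = TRUE requires a hardware mu-map")
    cls <- labels@classes
    assign <- setNames(rep(classTable[["soft"]], length(cls)), cls)
    assign["fat"] <- classTable[["fat"]]
    assign["lung"] <- classTable[["lung"]]
    assign["air"] <- classTable[["air"]]
    assign[grep("^hardware_", cls)] <- 0
    v <- array(assign[labels@labels], dim(labels@labels))
    prov <- "mrac"
    if (includeHardware) {
        .checkSameGrid(hardwareMu, labels, "hardware mu-map and labels")
        v <- pmax(v, values(hardwareMu))
    } else if (any(grepl("^hardware_", cls[unique(as.vector(labels@labels))]))) {
        prov <- "mrac_no_hardware"
    }
    muMap(array(v, dim(labels@labels)), labels@spacing, labels@origin,
          provenance = prov)
}

#' MRAC truncation completion (identity in the synthetic setting)
#'
#' Clinical MRAC recovers arms truncated by the MR field of view from the
#' non-attenuation-corrected PET contour.  The synthetic phantoms simulate
#' no truncation, so this completion step is the identity; the operation
#' exists so pipelines can call it unconditionally.
#'
#' @param mu a [MuMap-class].
#' @return `mu`, unchanged.
#' @export
completeTruncation <- function(mu) mu
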