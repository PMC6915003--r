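#' @import methods
NULL

#' VoxelImage: a scalar voxel grid with physical spacing
#'
#' The common carrier for activity distributions, linear attenuation
#' coefficient (LAC) images and reconstructed PET images.  Values are stored
#' as a 2D matrix (one transaxial slice) or a 3D array (thin-3D stack); the
#' first dimension is x, the second y, the optional third z.  `spacing` gives
#' the voxel size in mm per dimension and `origin` the physical coordinate
#' (mm) of the center of voxel (1,1[,1]).
#'
#' @slot values numeric matrix or 3D array.
#' @slot spacing numeric voxel size in mm, one entry per dimension, all > 0.
#' @slot origin numeric physical position (mm) of the first voxel center.
#'
#' @exportClass VoxelImage
setClass("VoxelImage",
    representation(values = "array", spacing = "numeric", origin = "numeric"))

setValidity("VoxelImage", function(object) {
    d <- dim(object@values)
    if (length(d) < 2L || length(d) > 3L)
        return("values must be a 2D matrix or 3D array")
    if (length(object@spacing) != length(d))
        return("spacing must have one entry per dimension")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
        return("all spacing components must be positive and finite")
    if (length(object@origin) != length(d))
        return("origin must have one entry per dimension")
    if (any(!is.finite(object@values)))
        return("values must be finite")
    TRUE
})

#' MuMap: a 511 keV linear-attenuation-coefficient image
#'
#' A [VoxelImage] whose values are LACs in mm^-1 at 511 keV, together with a
#' provenance tag recording how the map was obtained (ground truth, continuous
#' CT conversion, segmented CT, MRAC, ...).  Values must be nonnegative and
#' below 0.05 mm^-1 (a sanity bound, more than twice cortical bone).
#'
#' @slot provenance character, one of `"truth"`, `"ct_continuous"`,
#'   `"ct_segmented"`, `"mrac"`, `"mrac_no_hardware"`, `"custom"`.
#'
#' @exportClass MuMap
setClass("MuMap", contains = "VoxelImage",
    representation(provenance = "character"))

.muProvenances <- c("truth", "ct_continuous", "ct_segmented", "mrac",
                    "mrac_no_hardware", "custom")

setValidity("MuMap", function(object) {
    if (length(object@provenance) != 1L ||
        !object@provenance %in% .muProvenances)
        return(paste("provenance must be one of:",
                     paste(.muProvenances, collapse = ", ")))
    if (any(object@values < 0)) return("LAC values must be nonnegative")
    if (any(object@values > 0.05))
        return("LAC values exceed the 0.05 mm^-1 sanity bound")
    TRUE
})

#' TissueLabelMap: per-voxel tissue classes with ground-truth lookups
#'
#' Integer label codes index into `classes`; `lacTable` and `uptakeTable` map
#' every class name to its ground-truth 511 keV LAC (mm^-1) and its relative
#' tracer activity concentration.  Air always has LAC 0; hardware classes
#' always have uptake 0.
#'
#' @slot labels integer matrix/array of 1-based codes into `classes`.
#' @slot classes character vector of class names.
#' @slot lacTable named numeric, LAC in mm^-1 per class.
#' @slot uptakeTable named numeric, relative activity per class.
#' @slot spacing,origin as in [VoxelImage-class].
#'
#' @exportClass TissueLabelMap
setClass("TissueLabelMap",
    representation(labels = "array", classes = "character",
                   lacTable = "numeric", uptakeTable = "numeric",
                   spacing = "numeric", origin = "numeric"))

setValidity("TissueLabelMap", function(object) {
    cls <- object@classes
    if (!all(cls %in% names(object@lacTable)))
        return("every class needs an entry in lacTable")
    if (!all(cls %in% names(object@uptakeTable)))
        return("every class needs an entry in uptakeTable")
    codes <- unique(as.vector(object@labels))
    if (any(codes < 1L) || any(codes > length(cls)))
        return("label codes out of range")
    if ("air" %in% cls && object@lacTable[["air"]] != 0)
        return("air must have LAC 0")
    if (any(object@lacTable < 0)) return("LACs must be nonnegative")
    if (length(object@spacing) != length(dim(object@labels)))
        return("spacing must match label dimensionality")
    TRUE
})

#' PhantomSpec: geometry of a digital phantom
#'
#' @slot kind `"cylinder"` or `"body_slice"`.
#' @slot diameterMm cylinder diameter in mm (default 200).
#' @slot hardwareConfig which rigid attenuators sit in the field of view.
#' @slot seed integer seed controlling any randomized geometry.
#' @slot lesions data.frame with columns x, y, radiusMm, uptake, type
#'   (`"lesion_soft"`/`"lesion_bone"`); zero rows = use defaults.
#' @slot randomLesions logical; sample lesion placement/uptake from `seed`.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(kind = "character", diameterMm = "numeric",
                   hardwareConfig = "character", seed = "integer",
                   lesions = "data.frame", randomLesions = "logical"))

#' Enumerated hardware configurations, each a superset of its predecessor.
#' @export
hardwareConfigs <- function() {
    c("none", "track", "track+bed", "track+bed+spine",
      "track+bed+spine+head_base", "track+bed+spine+head_full")
}

setValidity("PhantomSpec", function(object) {
    if (!object@kind %in% c("cylinder", "body_slice"))
        return("kind must be 'cylinder' or 'body_slice'")
    if (!object@hardwareConfig %in% hardwareConfigs())
        return("unknown hardware configuration")
    if (object@diameterMm < 0) return("diameterMm must be nonnegative")
    TRUE
})

#' ProjectionGeometry: parallel-beam sinogram geometry
#'
#' @slot angles projection angles in radians over [0, pi).
#' @slot sCenters radial bin centers in mm, symmetric about the rotation
#'   center (the grid center).
#' @slot binWidthMm radial bin width in mm.
#'
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry",
    representation(angles = "numeric", sCenters = "numeric",
                   binWidthMm = "numeric"))

setValidity("ProjectionGeometry", function(object) {
    if (length(object@angles) < 1L) return("need at least one angle")
    if (object@binWidthMm <= 0) return("binWidthMm must be positive")
    TRUE
})

#' Sinogram: projection-domain emission data
#'
#' `counts` holds observed (Poisson) or expected (noise-free) counts, one row
#' per angle and one column per radial bin.  `attenuationFactors` holds the
#' Beer-Lambert factors exp(-integral of mu) of the mu-map used to generate
#' the data; they are carried along for the reconstructor's convenience but
#' the reconstructor recomputes its own factors from whatever AC map it is
#' given.
#'
#' @slot counts numeric matrix [angles x radial bins], nonnegative.
#' @slot attenuationFactors numeric matrix, same shape, values in (0, 1].
#' @slot geometry a [ProjectionGeometry-class].
#' @slot scale expected total true counts.
#'
#' @exportClass Sinogram
setClass("Sinogram",
    representation(counts = "matrix", attenuationFactors = "matrix",
                   geometry = "ProjectionGeometry", scale = "numeric"))

setValidity("Sinogram", function(object) {
    g <- object@geometry
    if (!all(dim(object@counts) ==
             c(length(g@angles), length(g@sCenters))))
        return("counts shape must match geometry")
    if (!all(dim(object@attenuationFactors) == dim(object@counts)))
        return("attenuationFactors shape must match counts")
    if (any(object@counts < 0)) return("counts must be nonnegative")
    af <- object@attenuationFactors
    if (any(af <= 0) || any(af > 1 + 1e-12))
        return("attenuation factors must lie in (0, 1]")
    TRUE
})

#' ReconParams: OSEM reconstruction parameters
#'
#' Defaults mirror a common clinical whole-body protocol: 20 subsets,
#' 3 iterations, 3 mm FWHM Gaussian post-filter.
#'
#' @slot nSubsets integer number of ordered subsets.
#' @slot nIterations integer number of full iterations.
#' @slot postFilterFwhmMm Gaussian post-filter FWHM in mm (0 = none).
#'
#' @exportClass ReconParams
setClass("ReconParams",
    representation(nSubsets = "integer", nIterations = "integer",
                   postFilterFwhmMm = "numeric"))

setValidity("ReconParams", function(object) {
    if (object@nSubsets < 1L) return("nSubsets must be >= 1")
    if (object@nIterations < 1L) return("nIterations must be >= 1")
    if (object@postFilterFwhmMm < 0) return("postFilterFwhmMm must be >= 0")
    TRUE
})

#' RoiSpec: a circular region of interest in physical coordinates
#'
#' @slot centerMm (x, y) center in mm.
#' @slot diameterMm circle diameter in mm (organ ROIs 20 mm; uniformity
#'   circles 60 mm peripheral / 120 mm central).
#' @slot slice 1-based slice index for 3D volumes.
#'
#' @exportClass RoiSpec
setClass("RoiSpec",
    representation(centerMm = "numeric", diameterMm = "numeric",
                   slice = "integer"))

setValidity("RoiSpec", function(object) {
    if (length(object@centerMm) != 2L) return("centerMm must be (x, y)")
    if (object@diameterMm <= 0) return("diameterMm must be positive")
    TRUE
})

#' UniformityResult: per-slice ROI means and uniformities
#'
#' @slot perSlice data.frame with columns offsetMm, B1..B4, A1, uniformity.
#' @slot wholeImage the maximum slice uniformity (a fraction, not percent).
#'
#' @exportClass UniformityResult
setClass("UniformityResult",
    representation(perSlice = "data.frame", wholeImage = "numeric"))

setValidity("UniformityResult", function(object) {
    need <- c("offsetMm", "B1", "B2", "B3", "B4", "A1", "uniformity")
    if (!all(need %in% names(object@perSlice)))
        return("perSlice is missing required columns")
    if (any(object@perSlice$uniformity < 0))
        return("slice uniformities must be nonnegative")
    if (abs(object@wholeImage - max(object@perSlice$uniformity)) > 1e-12)
        return("wholeImage must equal the maximum slice uniformity")
    TRUE
})
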