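#' Construct a parallel-beam projection geometry
#'
#' Angles are spread evenly over [0, pi); radial bins (default width = the
#' voxel size) are centered on the rotation center (the grid center) and
#' cover the image diagonal, so no ray through the support is lost.
#'
#' @param grid an [imageGrid()] (or a [VoxelImage-class] whose grid to use).
#' @param nAngles number of projection angles (default 180).
#' @param binWidthMm radial bin width in mm; defaults to the smaller voxel
#'   dimension.
#' @return a [ProjectionGeometry-class].
#' @export
projectionGeometry <- function(grid = imageGrid(), nAngles = 180L,
                               binWidthMm = NULL) {
    if (is(grid, "VoxelImage"))
        grid <- list(n = dim(values(grid))[1:2], spacing = spacing(grid)[1:2])
    if (is.null(binWidthMm)) binWidthMm <- min(grid$spacing[1:2])
    halfDiag <- sqrt(sum((grid$n[1:2] * grid$spacing[1:2])^2)) / 2
    k <- ceiling(halfDiag / binWidthMm)
    s <- seq(-k, k) * binWidthMm
    new("ProjectionGeometry",
        angles = (seq_len(nAngles) - 1) * pi / nAngles,
        sCenters = s, binWidthMm = binWidthMm)
}

# Geometry coverage check: the radial extent must reach the image diagonal.
.checkCoverage <- function(image, geom) {
    d <- dim(values(image))[1:2]
    halfDiag <- sqrt(sum((d * spacing(image)[1:2])^2)) / 2
    reach <- max(abs(geom@sCenters)) + geom@binWidthMm / 2
    if (reach < halfDiag - 1e-9)
        stop("projection geometry does not cover the image diagonal")
    invisible(TRUE)
}

#' Exact parallel-beam line integrals (Radon transform)
#'
#' Entry (theta, s) is the exact line integral of the image along the ray at
#' angle `theta` and radial offset `s`, in value x mm, computed by
#' pixel-intersection (Siddon-style) traversal in compiled code.  The
#' operator is linear in the image, and [backproject()] is its exact
#' adjoint.
#'
#' @param image a 2D [VoxelImage-class].
#' @param geom a [ProjectionGeometry-class] covering the image diagonal.
#' @return numeric matrix `[n_angles x n_radial]`.
#' @examples
#' disk <- makeCylinderPhantom(phantomSpec("cylinder"), imageGrid(64, 4.8))
#' g <- projectionGeometry(imageGrid(64, 4.8), nAngles = 12)
#' p <- lineIntegrals(disk$activity, g)
#' max(p)   # ~ the 200 mm diameter
#' @export
lineIntegrals <- function(image, geom) {
    .checkCoverage(image, geom)
    v <- values(image)
    if (length(dim(v)) != 2L) stop("projection operates on 2D slices")
    sp <- spacing(image)
    .cpp_radon_forward(v, sp[1], sp[2], geom@angles, geom@sCenters)
}

#' Adjoint of [lineIntegrals()] (backprojection)
#'
#' Scatters sinogram values back along rays with the identical intersection
#' weights used by the forward projector, making the pair an exact
#' transpose: `sum(lineIntegrals(x) * y) == sum(values(backproject(y)) *
#' values(x))` to floating-point rounding.
#'
#' @param sino numeric matrix `[n_angles x n_radial]`.
#' @param geom a [ProjectionGeometry-class].
#' @param grid an [imageGrid()] describing the target image grid.
#' @return a [VoxelImage-class].
#' @export
backproject <- function(sino, geom, grid = imageGrid()) {
    v <- .cpp_radon_back(sino, grid$spacing[1], grid$spacing[2],
                         geom@angles, geom@sCenters,
                         grid$n[1], grid$n[2])
    voxelImage(v, grid$spacing)
}

#' Beer-Lambert attenuation factors of a mu-map
#'
#' Per-ray survival probabilities `exp(-integral of mu)` in (0, 1]; exactly
#' 1 for rays whose mu line integral is zero.
#'
#' @param mu a [MuMap-class] in mm^-1.
#' @param geom a [ProjectionGeometry-class].
#' @return numeric matrix `[n_angles x n_radial]`.
#' @export
attenuationFactors <- function(mu, geom) {
    if (any(values(mu) < 0)) stop("negative attenuation coefficients")
    exp(-lineIntegrals(mu, geom))
}

#' Simulate attenuated PET emission data
#'
#' The expected sinogram is the activity's line integrals multiplied by the
#' Beer-Lambert factors of the *true* mu-map, rescaled so its sum equals
#' `totalCounts`; observed counts are then Poisson draws with the given
#' seed.  Scatter, randoms, normalization and decay are not modeled:
#' attenuation is deliberately the only physics effect so that
#' attenuation-correction arms can be compared on otherwise identical data.
#'
#' @param activity a 2D [VoxelImage-class] (nonnegative).
#' @param muTrue the ground-truth [MuMap-class] (tissue + any hardware).
#' @param geom a [ProjectionGeometry-class].
#' @param totalCounts expected total true counts (default 5e6 per slice);
#'   `NULL` keeps the raw expected sinogram unscaled.
#' @param seed integer seed for the Poisson draw.
#' @param poisson set FALSE for noise-free data (counts = expectation).
#' @return a [Sinogram-class]; `attenuationOf()` returns the true
#'   attenuation factors used.
#' @export
simulateEmission <- function(activity, muTrue, geom, totalCounts = 5e6,
                             seed = NULL, poisson = TRUE) {
    .checkSameGrid(activity, muTrue, "activity and mu-map")
    if (any(values(activity) < 0)) stop("negative activity")
    proj <- lineIntegrals(activity, geom)
    af <- attenuationFactors(muTrue, geom)
    expected <- proj * af
    tot <- sum(expected)
    if (!is.null(totalCounts)) {
        if (totalCounts <= 0) stop("totalCounts must be positive")
        if (tot <= 0)
            stop("all-zero activity cannot produce the requested counts")
        expected <- expected * (totalCounts / tot)
        tot <- totalCounts
    }
    obs <- if (poisson) {
        .withSeed(seed, matrix(stats::rpois(length(expected), expected),
                               nrow(expected), ncol(expected)))
    } else expected
    new("Sinogram", counts = obs, attenuationFactors = af,
        geometry = geom, scale = tot)
}

#' @rdname accessors
#' @export
setMethod("counts", "Sinogram", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("attenuationOf", "Sinogram", function(x) x@attenuationFactors)

#' @rdname accessors
#' @export
setMethod("geometry", "Sinogram", function(x) x@geometry)
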