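#' Construct a VoxelImage
#'
#' @param values numeric matrix (2D) or array (3D).
#' @param spacing voxel size in mm, one entry per dimension (recycled if
#'   scalar).
#' @param origin physical coordinate (mm) of the first voxel center; by
#'   default the grid is centered on the physical origin, matching the
#'   rotation center used by the projector.
#' @return a [VoxelImage-class].
#' @examples
#' img <- voxelImage(matrix(0, 64, 64), spacing = 2.4)
#' spacing(img)
#' @export
voxelImage <- function(values, spacing = 1,
                       origin = centeredOrigin(dim(values), spacing)) {
    values <- as.array(values)
    nd <- length(dim(values))
    if (length(spacing) == 1L) spacing <- rep(spacing, nd)
    new("VoxelImage", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Origin that centers a grid on the physical (0,0[,0]) point
#'
#' @param dims integer grid dimensions.
#' @param spacing voxel size in mm (recycled if scalar).
#' @return numeric origin in mm.
#' @export
centeredOrigin <- function(dims, spacing) {
    if (length(spacing) == 1L) spacing <- rep(spacing, length(dims))
    -(dims - 1) / 2 * spacing
}

#' @rdname accessors
#' @export
setMethod("values", "VoxelImage", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("spacing", "VoxelImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("origin", "VoxelImage", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("provenance", "MuMap", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("spacing", "TissueLabelMap", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("origin", "TissueLabelMap", function(x) x@origin)

setMethod("show", "VoxelImage", function(object) {
    d <- dim(object@values)
    cat(class(object), ": ", paste(d, collapse = " x "),
        " voxels, spacing ", paste(format(object@spacing), collapse = " x "),
        " mm\n", sep = "")
    cat("  value range: [", format(min(object@values)), ", ",
        format(max(object@values)), "]\n", sep = "")
    if (is(object, "MuMap"))
        cat("  provenance: ", object@provenance, "\n", sep = "")
})

setMethod("show", "TissueLabelMap", function(object) {
    d <- dim(object@labels)
    cat("TissueLabelMap: ", paste(d, collapse = " x "), " voxels\n", sep = "")
    tab <- table(factor(object@classes[object@labels],
                        levels = object@classes))
    tab <- tab[tab > 0]
    cat("  classes: ",
        paste(names(tab), " (", as.integer(tab), ")",
              sep = "", collapse = ", "), "\n", sep = "")
})

setMethod("show", "Sinogram", function(object) {
    g <- object@geometry
    cat("Sinogram: ", length(g@angles), " angles x ", length(g@sCenters),
        " radial bins, total counts ", format(sum(object@counts)),
        "\n", sep = "")
})

setMethod("show", "UniformityResult", function(object) {
    cat("UniformityResult: whole-image uniformity ",
        sprintf("%.2f%%", 100 * object@wholeImage), " over ",
        nrow(object@perSlice), " slice(s)\n", sep = "")
})

#' Construct a MuMap
#'
#' @param values,spacing,origin as in [voxelImage()].
#' @param provenance provenance tag; see [MuMap-class].
#' @return a [MuMap-class].
#' @export
muMap <- function(values, spacing = 1,
                  origin = centeredOrigin(dim(values), spacing),
                  provenance = "custom") {
    values <- as.array(values)
    nd <- length(dim(values))
    if (length(spacing) == 1L) spacing <- rep(spacing, nd)
    new("MuMap", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin), provenance = provenance)
}

# Physical x/y coordinates (mm) of voxel centers along each axis.
.axisCoords <- function(dims, spacing, origin) {
    lapply(seq_along(dims),
           function(k) origin[k] + (seq_len(dims[k]) - 1) * spacing[k])
}

# Shared grid-compatibility check used across modules.
.checkSameGrid <- function(a, b, what = "images") {
    da <- if (is(a, "TissueLabelMap")) dim(a@labels) else dim(a@values)
    db <- if (is(b, "TissueLabelMap")) dim(b@labels) else dim(b@values)
    if (!identical(da, db) ||
        !isTRUE(all.equal(spacing(a), spacing(b))) ||
        !isTRUE(all.equal(origin(a), origin(b))))
        stop(what, " are not on the same voxel grid")
    invisible(TRUE)
}

# 2D slice extraction from 2D or 3D values.
.sliceValues <- function(img, slice = 1L) {
    v <- img@values
    if (length(dim(v)) == 2L) {
        if (slice != 1L) stop("2D image has a single slice")
        return(v)
    }
    if (slice < 1L || slice > dim(v)[3])
        stop("slice index out of range")
    v[, , slice]
}
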