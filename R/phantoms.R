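#' Ground-truth tissue properties
#'
#' LACs are 511 keV linear attenuation coefficients in mm^-1; uptake values
#' are relative activity concentrations (soft tissue = 1).  Soft tissue,
#' liver and lesions sit slightly above the 0.0096 mm^-1 water value used by
#' segmented attenuation maps, as real soft tissue does; bone uses the
#' standard segmented-CT bone value; hardware attenuators (bed/track slabs,
#' coil shells) carry zero activity.
#'
#' @return named numeric vector.
#' @export
tissueLacTable <- function() {
    c(air = 0, lung = 0.0034, fat = 0.0086, soft = 0.0100, liver = 0.0100,
      bone = 0.0161, lesion_soft = 0.0100, lesion_bone = 0.0100,
      hardware_track = 0.020, hardware_bed = 0.020,
      hardware_spine = 0.012, hardware_head = 0.012)
}

#' @rdname tissueLacTable
#' @export
tissueUptakeTable <- function() {
    c(air = 0, lung = 0.3, fat = 0.4, soft = 1.0, liver = 1.2, bone = 0.6,
      lesion_soft = 4.0, lesion_bone = 4.0,
      hardware_track = 0, hardware_bed = 0,
      hardware_spine = 0, hardware_head = 0)
}

#' Construct a PhantomSpec
#'
#' @param kind `"cylinder"` (uniform 20 cm germanium-cylinder analog) or
#'   `"body_slice"` (transaxial body slice with lungs, fat rim, soft tissue,
#'   liver analog, a vertebra analog and FDG-avid lesions).
#' @param diameterMm cylinder diameter in mm.
#' @param hardwareConfig one of [hardwareConfigs()].
#' @param seed integer seed for randomized geometry.
#' @param lesions data.frame(x, y, radiusMm, uptake, type) overriding the
#'   default lesion set of the body phantom.
#' @param randomLesions sample lesion placement and uptake from `seed`
#'   (used for cohort emulation).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(kind = c("cylinder", "body_slice"), diameterMm = 200,
                        hardwareConfig = "none", seed = 1L,
                        lesions = NULL, randomLesions = FALSE) {
    kind <- match.arg(kind)
    if (is.null(lesions))
        lesions <- data.frame(x = numeric(0), y = numeric(0),
                              radiusMm = numeric(0), uptake = numeric(0),
                              type = character(0))
    new("PhantomSpec", kind = kind, diameterMm = diameterMm,
        hardwareConfig = hardwareConfig, seed = as.integer(seed),
        lesions = lesions, randomLesions = isTRUE(randomLesions))
}

#' Image-grid descriptor
#'
#' @param n grid dimensions (scalar = square), default 256.
#' @param spacingMm voxel size in mm, default 2.4 (clinical reconstruction
#'   matrix).
#' @return list with `n` and `spacing`.
#' @export
imageGrid <- function(n = 256L, spacingMm = 2.4) {
    if (length(n) == 1L) n <- c(n, n)
    list(n = as.integer(n), spacing = rep(spacingMm, length.out = length(n)))
}

# Voxel-center coordinate matrices for a 2D grid.
.gridXY <- function(grid) {
    org <- centeredOrigin(grid$n, grid$spacing)
    x <- org[1] + (seq_len(grid$n[1]) - 1) * grid$spacing[1]
    y <- org[2] + (seq_len(grid$n[2]) - 1) * grid$spacing[2]
    list(x = matrix(x, grid$n[1], grid$n[2]),
         y = matrix(y, grid$n[1], grid$n[2], byrow = TRUE),
         origin = org)
}

.newLabelMap <- function(codes, grid, xy) {
    cls <- names(tissueLacTable())
    new("TissueLabelMap", labels = codes, classes = cls,
        lacTable = tissueLacTable(), uptakeTable = tissueUptakeTable(),
        spacing = grid$spacing, origin = xy$origin)
}

.code <- function(cls) match(cls, names(tissueLacTable()))

#' Masks and ground-truth images from a label map
#'
#' `labelMask` returns the logical mask of one tissue class; `lacImage` the
#' ground-truth mu-map (provenance `"truth"`); `activityImage` the
#' ground-truth activity distribution implied by the uptake table.
#'
#' @param labels a [TissueLabelMap-class].
#' @param class a tissue class name.
#' @return logical array, [MuMap-class], or [VoxelImage-class].
#' @export
labelMask <- function(labels, class) {
    stopifnot(class %in% labels@classes)
    array(labels@labels == .code(class), dim(labels@labels))
}

#' @rdname labelMask
#' @export
lacImage <- function(labels) {
    v <- array(labels@lacTable[labels@classes][labels@labels],
               dim(labels@labels))
    muMap(v, labels@spacing, labels@origin, provenance = "truth")
}

#' @rdname labelMask
#' @export
activityImage <- function(labels) {
    v <- array(labels@uptakeTable[labels@classes][labels@labels],
               dim(labels@labels))
    voxelImage(v, labels@spacing, labels@origin)
}

#' Ground-truth mu-map of the hardware structures alone
#'
#' Used to composite the "hardcoded" hardware attenuation into MRAC maps,
#' emulating how rigid-structure CT templates enter clinical reconstruction.
#'
#' @param labels a [TissueLabelMap-class].
#' @return a [MuMap-class] (provenance `"custom"`), zero outside hardware.
#' @export
hardwareMuMap <- function(labels) {
    hw <- grep("^hardware_", labels@classes, value = TRUE)
    v <- array(0, dim(labels@labels))
    for (h in hw) v[labelMask(labels, h)] <- labels@lacTable[[h]]
    muMap(v, labels@spacing, labels@origin, provenance = "custom")
}

# Hardware shapes (2D, physical mm; phantom/rotation center at the origin).
# Track and bed are horizontal slabs below the phantom; spine coil a lower
# arc shell; head coil a shell (base = lower arc, full = complete ring).
# Each configuration is a strict superset of its predecessor.
.hardwareParts <- function(config) {
    all <- c("track", "bed", "spine", "head_base", "head_full")
    switch(config,
        "none" = character(0),
        "track" = "track",
        "track+bed" = all[1:2],
        "track+bed+spine" = all[1:3],
        "track+bed+spine+head_base" = all[1:4],
        "track+bed+spine+head_full" = all[1:5],
        stop("unknown hardware configuration: ", config))
}

.paintHardware <- function(codes, xy, config) {
    parts <- .hardwareParts(config)
    r <- sqrt(xy$x^2 + xy$y^2)
    paint <- function(mask, cls) {
        m <- mask & codes == .code("air")   # never overwrite the phantom
        codes[m] <<- .code(cls)
    }
    if ("track" %in% parts)
        paint(xy$y >= -150 & xy$y <= -142 & abs(xy$x) <= 250,
              "hardware_track")
    if ("bed" %in% parts)
        paint(xy$y >= -141 & xy$y <= -133 & abs(xy$x) <= 220, "hardware_bed")
    if ("spine" %in% parts)
        paint(r >= 112 & r <= 120 & xy$y < -40, "hardware_spine")
    if ("head_base" %in% parts)
        paint(r >= 124 & r <= 130 & xy$y < 0, "hardware_head")
    if ("head_full" %in% parts)
        paint(r >= 124 & r <= 130, "hardware_head")
    codes
}

#' Generate the uniform cylinder phantom
#'
#' A uniform activity-filled cylinder of the given diameter (default 200 mm)
#' centered in the grid, labeled soft tissue inside and air outside, with
#' optional rigid hardware attenuators (track / bed / coil analogs) that
#' attenuate but carry no activity.
#'
#' @param spec a [PhantomSpec-class] with `kind = "cylinder"`.
#' @param grid an [imageGrid()].
#' @param activityValue activity concentration inside the cylinder
#'   (relative units).
#' @return list with `activity` ([VoxelImage-class]), `labels`
#'   ([TissueLabelMap-class]).
#' @examples
#' ph <- makeCylinderPhantom(phantomSpec("cylinder"), imageGrid(128, 4.8))
#' sum(values(ph$activity) > 0)
#' @export
makeCylinderPhantom <- function(spec, grid = imageGrid(),
                                activityValue = 1) {
    if (spec@kind != "cylinder") stop("spec is not a cylinder phantom")
    R <- spec@diameterMm / 2
    halfExtent <- grid$n * grid$spacing / 2
    if (R > min(halfExtent[1:2]))
        stop("cylinder of diameter ", spec@diameterMm,
             " mm exceeds the grid extent")
    xy <- .gridXY(grid)
    codes <- array(.code("air"), grid$n)
    inside <- xy$x^2 + xy$y^2 <= R^2
    codes[inside] <- .code("soft")
    codes <- .paintHardware(codes, xy, spec@hardwareConfig)
    labels <- .newLabelMap(codes, grid, xy)
    act <- array(0, grid$n)
    act[inside] <- activityValue
    list(activity = voxelImage(act, grid$spacing, xy$origin),
         labels = labels)
}

#' Add hardware structures to an existing label map
#'
#' Structures are cumulative: each configuration is a superset of the
#' previous one in [hardwareConfigs()].  Hardware is only painted on air
#' voxels, has zero activity and the LACs of [tissueLacTable()].
#'
#' @param labels a [TissueLabelMap-class].
#' @param config one of [hardwareConfigs()].
#' @return a new [TissueLabelMap-class].
#' @export
addHardware <- function(labels, config) {
    config <- match.arg(config, hardwareConfigs())
    if (config == "none") return(labels)
    grid <- list(n = dim(labels@labels), spacing = labels@spacing)
    xy <- .gridXY(grid)
    codes <- .paintHardware(labels@labels, xy, config)
    out <- labels
    out@labels <- codes
    validObject(out)
    out
}

# Default body geometry (mm): outer ellipse, fat rim thickness, lungs,
# liver analog, vertebra analog.
.bodyGeom <- list(
    bodyA = 150, bodyB = 100, fatRim = 8,
    lungCenters = list(c(-60, 25), c(60, 25)), lungA = 35, lungB = 28,
    liverCenter = c(55, -20), liverA = 35, liverB = 22,
    boneCenter = c(0, -55), boneR = 16)

.defaultLesions <- data.frame(
    x = c(-60, 12), y = c(-20, -48), radiusMm = c(8, 6),
    uptake = c(4, 4),
    type = c("lesion_soft", "lesion_bone"),
    stringsAsFactors = FALSE)

.inEllipse <- function(xy, center, a, b)
    ((xy$x - center[1]) / a)^2 + ((xy$y - center[2]) / b)^2 <= 1

# Sample lesion placement/uptake for cohort emulation: one soft-tissue
# lesion uniform over the soft/liver interior, one lesion centered just
# inside the vertebra rim; radii 4-10 mm, uptake 3-5x background.
.sampleLesions <- function(codes, xy, geom) {
    softOk <- codes == .code("soft") | codes == .code("liver")
    les <- NULL
    for (i in 1:200) {
        cx <- stats::runif(1, -110, 110)
        cy <- stats::runif(1, -60, 60)
        rad <- stats::runif(1, 5, 10)
        disk <- (xy$x - cx)^2 + (xy$y - cy)^2 <= rad^2
        if (any(disk) && all(softOk[disk])) {
            les <- data.frame(x = cx, y = cy, radiusMm = rad,
                              uptake = stats::runif(1, 3, 5),
                              type = "lesion_soft")
            break
        }
    }
    if (is.null(les)) stop("could not place a soft-tissue lesion")
    phi <- stats::runif(1, 0, 2 * pi)
    bc <- geom$boneCenter + (geom$boneR - 2) * c(cos(phi), sin(phi))
    les2 <- data.frame(x = bc[1], y = bc[2],
                       radiusMm = stats::runif(1, 4, 7),
                       uptake = stats::runif(1, 3, 5), type = "lesion_bone")
    rbind(les, les2)
}

#' Generate the body-slice phantom
#'
#' A transaxial body slice standing in for a patient study: elliptical body
#' with a subcutaneous fat rim, two lungs (low uptake, low LAC), a liver
#' analog (uptake 1.2), a vertebra analog (bone), and FDG-avid lesions in
#' soft tissue and in/around bone (uptake >= 2x local background).  With
#' `spec@randomLesions`, lesion placement, size and uptake are sampled
#' deterministically from `spec@seed`.
#'
#' Soft-tissue lesions must lie entirely on soft tissue/liver and bone
#' lesions on bone/soft tissue; a lesion overlapping an incompatible class
#' (air, lung, fat) is rejected with an error.
#'
#' @param spec a [PhantomSpec-class] with `kind = "body_slice"`.
#' @param grid an [imageGrid()].
#' @return list with `activity`, `labels`, `lesions` (realized lesion
#'   table) and `organs` (named list of organ ROI centers in mm).
#' @export
makeBodyPhantom <- function(spec, grid = imageGrid()) {
    if (spec@kind != "body_slice") stop("spec is not a body-slice phantom")
    g <- .bodyGeom
    xy <- .gridXY(grid)
    halfExtent <- grid$n * grid$spacing / 2
    if (g$bodyA > halfExtent[1] || g$bodyB > halfExtent[2])
        stop("body outline exceeds the grid extent")
    codes <- array(.code("air"), grid$n)
    body <- .inEllipse(xy, c(0, 0), g$bodyA, g$bodyB)
    inner <- .inEllipse(xy, c(0, 0), g$bodyA - g$fatRim, g$bodyB - g$fatRim)
    codes[body] <- .code("fat")
    codes[inner] <- .code("soft")
    for (lc in g$lungCenters)
        codes[.inEllipse(xy, lc, g$lungA, g$lungB) & inner] <- .code("lung")
    codes[.inEllipse(xy, g$liverCenter, g$liverA, g$liverB) &
          codes == .code("soft")] <- .code("liver")
    bone <- (xy$x - g$boneCenter[1])^2 + (xy$y - g$boneCenter[2])^2 <=
        g$boneR^2
    codes[bone & inner] <- .code("bone")

    lesions <- spec@lesions
    if (spec@randomLesions) {
        lesions <- .withSeed(spec@seed, .sampleLesions(codes, xy, g))
    } else if (nrow(lesions) == 0L) {
        lesions <- .defaultLesions
    }
    for (i in seq_len(nrow(lesions))) {
        L <- lesions[i, ]
        disk <- (xy$x - L$x)^2 + (xy$y - L$y)^2 <= L$radiusMm^2
        under <- codes[disk]
        ok <- if (L$type == "lesion_soft")
            c(.code("soft"), .code("liver"))
        else c(.code("bone"), .code("soft"), .code("liver"))
        if (!length(under) || !all(under %in% c(ok, .code("lesion_soft"),
                                                .code("lesion_bone"))))
            stop("lesion ", i, " overlaps an incompatible tissue class")
        codes[disk] <- .code(L$type)
    }

    labels <- .newLabelMap(codes, grid, xy)
    act <- values(activityImage(labels))
    # per-lesion uptake override (the class table carries the default 4x)
    for (i in seq_len(nrow(lesions))) {
        L <- lesions[i, ]
        disk <- (xy$x - L$x)^2 + (xy$y - L$y)^2 <= L$radiusMm^2
        act[disk & codes == .code(L$type)] <- L$uptake
    }
    list(activity = voxelImage(act, grid$spacing, xy$origin),
         labels = labels, lesions = lesions,
         organs = list(bone = g$boneCenter, liver = g$liverCenter,
                       lung = g$lungCenters[[2]]))
}

# Evaluate expr with a temporarily-seeded RNG, restoring global state.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and an index.
.subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               2147483629)
}
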