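#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: at least three pairs and
#' nonzero variance in both vectors are required.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least three pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance")
    stats::cor(x, y, method = "pearson")
}

#' Paired comparison of absolute relative differences
#'
#' Paired t-test on `|a| - |b|`, the comparison used to ask whether one
#' attenuation-correction arm deviates more than another in magnitude.
#' Two-sided p from the t distribution with n - 1 degrees of freedom.  A
#' zero-variance difference vector is guarded: all-zero differences give
#' statistic 0 and p = 1; constant nonzero differences get the standard
#' error floored at machine epsilon, yielding an effectively zero p.
#'
#' @param a,b numeric vectors of equal length >= 3 (e.g. RD1 and RD2).
#' @return list with `statistic`, `p`, `df`, `meanDiff`.
#' @export
pairedDiffTest <- function(a, b) {
    if (length(a) != length(b)) stop("a and b must have equal length")
    n <- length(a)
    if (n < 3L) stop("need at least three pairs")
    d <- abs(a) - abs(b)
    m <- mean(d)
    s <- stats::sd(d)
    if (s < .Machine$double.eps) {
        if (abs(m) < .Machine$double.eps)
            return(list(statistic = 0, p = 1, df = n - 1, meanDiff = 0))
        s <- .Machine$double.eps
    }
    stat <- m / (s / sqrt(n))
    list(statistic = stat, p = 2 * stats::pt(-abs(stat), n - 1),
         df = n - 1, meanDiff = m)
}

# One cylinder simulation + reconstruction under a hardware configuration.
# Returns the 5-slice (or single-slice) reconstructed volume.
.cylinderRecon <- function(config, grid, geom, countsPerSlice, seed,
                           params, sliceOffsetsMm, hardwareInAc = TRUE,
                           nSlices = length(sliceOffsetsMm)) {
    ph <- makeCylinderPhantom(phantomSpec("cylinder",
                                          hardwareConfig = config), grid)
    muTrue <- lacImage(ph$labels)
    muAc <- mracMuMap(ph$labels,
                      includeHardware = hardwareInAc && config != "none",
                      hardwareMu = if (config != "none")
                          hardwareMuMap(ph$labels))
    slices <- lapply(seq_len(nSlices), function(s) {
        sino <- simulateEmission(ph$activity, muTrue, geom,
                                 totalCounts = countsPerSlice,
                                 seed = .subSeed(seed, s))
        values(osemReconstruct(sino, muAc, params))
    })
    vol <- array(unlist(slices), c(grid$n, nSlices))
    dz <- if (nSlices > 1) diff(sliceOffsetsMm[1:2]) else 1
    voxelImage(vol, c(grid$spacing, dz),
               c(centeredOrigin(grid$n, grid$spacing), sliceOffsetsMm[1]))
}

#' Hardware-configuration uniformity study
#'
#' For each hardware configuration, simulates Poisson emission data from
#' the uniform cylinder attenuated by the true mu-map (phantom plus
#' hardware), reconstructs each analysis plane with OSEM using an AC map
#' that includes the hardware (emulating hardcoded rigid-structure
#' templates), and computes the whole-image uniformity over the five-slice
#' layout.  With `ablation = TRUE` a second arm reconstructs the same data
#' with the hardware *excluded* from the AC map, quantifying the bias of
#' unmodeled hardware attenuation.
#'
#' The transaxial slice carries all the physics at this scale, so the five
#' analysis planes are simulated as independent replicate slices.
#'
#' @param configs hardware configurations to sweep (default: the four
#'   scanner configurations — track; track+bed+spine; plus head-coil base;
#'   plus full head coil).
#' @param grid an [imageGrid()].
#' @param geom a [ProjectionGeometry-class] (default built from `grid`).
#' @param countsPerSlice expected true counts per slice (default 5e6).
#' @param seed base seed; per-slice seeds are derived from it.
#' @param params a [reconParams()].
#' @param layout a [uniformityLayout()].
#' @param ablation also run the hardware-excluded AC arm.
#' @return list with `table` (data.frame: config, hardwareInAc,
#'   uniformity) and `results` (the per-run [UniformityResult-class]
#'   objects).
#' @export
runUniformityStudy <- function(
        configs = c("track", "track+bed+spine",
                    "track+bed+spine+head_base",
                    "track+bed+spine+head_full"),
        grid = imageGrid(), geom = projectionGeometry(grid),
        countsPerSlice = 5e6, seed = 1L, params = reconParams(),
        layout = uniformityLayout(), ablation = FALSE) {
    arms <- data.frame(config = configs, hardwareInAc = TRUE)
    if (ablation)
        arms <- rbind(arms, data.frame(config = configs,
                                       hardwareInAc = FALSE))
    results <- list()
    rows <- lapply(seq_len(nrow(arms)), function(i) {
        cfg <- arms$config[i]
        inAc <- arms$hardwareInAc[i]
        vol <- .cylinderRecon(cfg, grid, geom, countsPerSlice,
                              .subSeed(seed, match(cfg, configs)),
                              params, layout$sliceOffsetsMm,
                              hardwareInAc = inAc)
        u <- imageUniformity(vol, layout)
        results[[paste(cfg, if (inAc) "ac" else "noac", sep = "_")]] <<- u
        data.frame(config = cfg, hardwareInAc = inAc,
                   uniformity = u@wholeImage)
    })
    list(table = do.call(rbind, rows), results = results)
}

# Quantify one reconstructed body image: organ ROI means + lesion VOI
# mean/max.  Lesion VOIs are drawn on each arm's own image (50% of the
# regional max within a search circle around the known lesion center).
.quantifyBody <- function(image, phantom, roiDiameterMm = 20,
                          searchMarginMm = 8) {
    rows <- lapply(names(phantom$organs), function(org) {
        m <- roiMean(image, roiSpec(phantom$organs[[org]], roiDiameterMm))
        data.frame(target = org, type = "organ", suvMean = m,
                   suvMax = NA_real_)
    })
    les <- phantom$lesions
    for (i in seq_len(nrow(les))) {
        sr <- roiSpec(c(les$x[i], les$y[i]),
                      2 * (les$radiusMm[i] + searchMarginMm))
        mask <- voiIsocontour(image, sr)
        st <- voiStats(image, mask)
        rows[[length(rows) + 1L]] <-
            data.frame(target = paste0(les$type[i], "_", i),
                       type = les$type[i], suvMean = st[["mean"]],
                       suvMax = st[["max"]])
    }
    do.call(rbind, rows)
}

#' Three-arm attenuation-correction comparison study
#'
#' Emulates the patient comparison with seeded body-slice phantoms: per
#' replicate, one Poisson emission simulation with the TRUE mu-map, then
#' one OSEM reconstruction per arm differing only in the AC mu-map —
#' continuous CT (`ct_continuous`, the bilinear HU conversion of a
#' synthesized CT), segmented CT (`ct_segmented`), four-class MRAC
#' (`mrac`), and optionally ground truth (`truth`).  All arms of one
#' replicate consume the identical sinogram.  SUVs are measured in 20 mm
#' organ ROIs (bone, liver analog, lung) and 50%-isocontour lesion VOIs,
#' and relative differences RD1 = (SUV_MR - SUV_CT)/SUV_CT and
#' RD2 = (SUV_MR - SUV_CTSeg)/SUV_CTSeg are formed per target.
#'
#' @param nReplicates number of seeded phantoms (cohort emulation,
#'   default 30).
#' @param grid an [imageGrid()].
#' @param geom a [ProjectionGeometry-class].
#' @param totalCounts expected true counts per replicate slice.
#' @param seed base seed; replicate seeds are derived from it.
#' @param params a [reconParams()].
#' @param arms reconstruction arms to run.
#' @param randomLesions randomize lesion placement/size/uptake per
#'   replicate.
#' @return list with `quant` (one row per replicate x target x arm),
#'   `rd` (one row per replicate x target with RD1/RD2 for mean and max)
#'   and `stats` (per-group summary, see [comparisonStats()]).
#' @export
runAcComparison <- function(nReplicates = 30L, grid = imageGrid(),
                            geom = projectionGeometry(grid),
                            totalCounts = 5e6, seed = 1L,
                            params = reconParams(),
                            arms = c("truth", "ct_continuous",
                                     "ct_segmented", "mrac"),
                            randomLesions = TRUE) {
    need <- c("ct_continuous", "ct_segmented", "mrac")
    if (!all(need %in% arms))
        stop("arms must include ", paste(need, collapse = ", "))
    quant <- list()
    for (r in seq_len(nReplicates)) {
        rSeed <- .subSeed(seed, r)
        ph <- makeBodyPhantom(phantomSpec("body_slice", seed = rSeed,
                                          randomLesions = randomLesions),
                              grid)
        muTruth <- lacImage(ph$labels)
        muCt <- huToLac(synthCtFromLabels(ph$labels))
        muMaps <- list(
            truth = muTruth,
            ct_continuous = muCt,
            ct_segmented = segmentCtLac(muCt,
                lungMask = labelMask(ph$labels, "lung")),
            mrac = mracMuMap(ph$labels))
        sino <- simulateEmission(ph$activity, muTruth, geom,
                                 totalCounts = totalCounts, seed = rSeed)
        for (arm in arms) {
            img <- osemReconstruct(sino, muMaps[[arm]], params)
            q <- .quantifyBody(img, ph)
            q$arm <- arm
            q$replicate <- r
            quant[[length(quant) + 1L]] <- q
        }
    }
    quant <- do.call(rbind, quant)
    rd <- .relativeDifferences(quant)
    list(quant = quant, rd = rd, stats = comparisonStats(rd, quant))
}

# RD1/RD2 per replicate x target, for SUVmean and (lesions) SUVmax.
.relativeDifferences <- function(quant) {
    wide <- function(col) {
        stats::reshape(quant[, c("replicate", "target", "type", "arm", col)],
                       idvar = c("replicate", "target", "type"),
                       timevar = "arm", direction = "wide")
    }
    wm <- wide("suvMean")
    out <- data.frame(replicate = wm$replicate, target = wm$target,
                      type = wm$type)
    out$rd1Mean <- (wm$suvMean.mrac - wm$suvMean.ct_continuous) /
        wm$suvMean.ct_continuous
    out$rd2Mean <- (wm$suvMean.mrac - wm$suvMean.ct_segmented) /
        wm$suvMean.ct_segmented
    wx <- wide("suvMax")
    out$rd1Max <- (wx$suvMax.mrac - wx$suvMax.ct_continuous) /
        wx$suvMax.ct_continuous
    out$rd2Max <- (wx$suvMax.mrac - wx$suvMax.ct_segmented) /
        wx$suvMax.ct_segmented
    out
}

#' Per-group comparison statistics
#'
#' For each target group (organ ROIs; bone lesions; soft-tissue lesions),
#' the Pearson correlation between the MRAC and continuous-CT arm SUVs,
#' the mean and SD of RD1 and RD2 in percent, and the paired test between
#' |RD1| and |RD2| (see [pairedDiffTest()]).
#'
#' @param rd relative-difference table from [runAcComparison()].
#' @param quant quantification table from [runAcComparison()].
#' @return data.frame, one row per group.
#' @export
comparisonStats <- function(rd, quant) {
    groups <- list(bone = rd$target == "bone",
                   liver = rd$target == "liver",
                   lung = rd$target == "lung",
                   bone_lesions = rd$type == "lesion_bone",
                   soft_lesions = rd$type == "lesion_soft")
    rows <- lapply(names(groups), function(g) {
        sel <- groups[[g]]
        key <- paste(rd$replicate, rd$target)[sel]
        mr <- quant$suvMean[quant$arm == "mrac"]
        ct <- quant$suvMean[quant$arm == "ct_continuous"]
        keyQ <- paste(quant$replicate, quant$target)[quant$arm == "mrac"]
        sel2 <- keyQ %in% key
        rho <- if (sum(sel2) >= 3 && stats::sd(mr[sel2]) > 0 &&
                   stats::sd(ct[sel2]) > 0)
            pearsonR(mr[sel2], ct[sel2]) else NA_real_
        pt <- if (sum(sel) >= 3)
            pairedDiffTest(rd$rd1Mean[sel], rd$rd2Mean[sel])
        else list(p = NA_real_)
        data.frame(group = g, n = sum(sel), rho = rho,
                   rd1MeanPct = 100 * mean(rd$rd1Mean[sel]),
                   rd1SdPct = 100 * stats::sd(rd$rd1Mean[sel]),
                   rd2MeanPct = 100 * mean(rd$rd2Mean[sel]),
                   rd2SdPct = 100 * stats::sd(rd$rd2Mean[sel]),
                   p3 = pt$p)
    })
    do.call(rbind, rows)
}
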