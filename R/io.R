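#' Read and write voxel images as NIfTI
#'
#' Volumes are written with the voxel spacing in the NIfTI pixdim and the
#' origin in the sform translation; [MuMap-class] objects additionally get
#' a JSON sidecar (`<path>.json`) carrying the provenance tag, which
#' `readMuMap` restores.
#'
#' @param x a [VoxelImage-class] or [MuMap-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `readVoxelImage`/`readMuMap` return the reconstructed object;
#'   writers return `path` invisibly.
#' @export
writeVoxelImage <- function(x, path) {
    nd <- length(dim(values(x)))
    aff <- diag(4)
    diag(aff)[seq_len(nd)] <- spacing(x)
    aff[seq_len(nd), 4] <- origin(x)
    ni <- RNifti::asNifti(values(x))
    RNifti::pixdim(ni) <- spacing(x)
    RNifti::qform(ni) <- structure(aff, code = 2L)
    RNifti::writeNifti(ni, path)
    if (is(x, "MuMap"))
        jsonlite::write_json(list(provenance = provenance(x)),
                             paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeVoxelImage
#' @export
readVoxelImage <- function(path) {
    ni <- RNifti::readNifti(path)
    v <- array(as.numeric(ni), dim(ni))
    nd <- length(dim(v))
    aff <- RNifti::xform(ni)
    voxelImage(v, spacing = RNifti::pixdim(ni)[seq_len(nd)],
               origin = aff[seq_len(nd), 4])
}

#' @rdname writeVoxelImage
#' @export
readMuMap <- function(path) {
    img <- readVoxelImage(path)
    side <- paste0(path, ".json")
    prov <- if (file.exists(side))
        jsonlite::read_json(side)$provenance else "custom"
    muMap(values(img), spacing(img), origin(img), provenance = prov)
}

#' Serialize and restore phantom specifications
#'
#' [PhantomSpec-class] objects round-trip through YAML (or JSON, by file
#' extension) with their explicit seed, so a phantom is fully reproducible
#' from its config file.
#'
#' @param spec a [PhantomSpec-class].
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @export
writePhantomSpec <- function(spec, path) {
    x <- list(kind = spec@kind, diameterMm = spec@diameterMm,
              hardwareConfig = spec@hardwareConfig, seed = spec@seed,
              randomLesions = spec@randomLesions,
              lesions = if (nrow(spec@lesions)) spec@lesions)
    if (grepl("\\.json$", path))
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    else
        yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
    x <- if (grepl("\\.json$", path))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    lesions <- if (!is.null(x$lesions)) as.data.frame(x$lesions)
    phantomSpec(kind = x$kind, diameterMm = x$diameterMm,
                hardwareConfig = x$hardwareConfig, seed = x$seed,
                lesions = lesions,
                randomLesions = isTRUE(x$randomLesions))
}

#' Write quantification or uniformity tables to CSV
#'
#' @param x a data.frame (e.g. the `quant`, `rd` or `stats` tables of
#'   [runAcComparison()], or the `table` of [runUniformityStudy()]), or a
#'   [UniformityResult-class] whose per-slice table is written.
#' @param path output CSV path.
#' @export
writeResultCsv <- function(x, path) {
    if (is(x, "UniformityResult")) x <- x@perSlice
    utils::write.csv(x, path, row.names = FALSE)
    invisible(path)
}
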