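#' Read and write grid volumes as NIfTI
#'
#' Grid geometry (spacing and origin) is carried in the NIfTI sform as a
#' diagonal affine, so it round-trips exactly. The voxel type follows the R
#' storage (double), so values round-trip bit-exactly too.
#'
#' @param x a \linkS4class{GridVolume}.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume` returns an object of class `class`; `writeVolume`
#'   returns `path` invisibly.
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "GridVolume"))
  img <- RNifti::asNifti(gridValues(x))
  m <- diag(c(gridSpacing(x), 1))
  m[1:3, 4] <- gridOrigin(x)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @param class target class: `"HUImage"`, `"RLSPMap"`, `"DoseGrid"` or
#'   `"LabelMap"`.
#' @export
readVolume <- function(path, class = "HUImage") {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  spacing <- abs(diag(m)[1:3])
  origin <- m[1:3, 4]
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  ctor <- switch(class, HUImage = huImage, RLSPMap = rlspMap,
                 DoseGrid = doseGrid, LabelMap = labelMap,
                 stop("unknown class '", class, "'"))
  ctor(vals, spacing, origin)
}

#' Read and write structure sets
#'
#' One uint8 NIfTI mask volume per structure plus a JSON manifest mapping
#' structure names to file names.
#'
#' @param x a \linkS4class{StructureSet}.
#' @param dir output directory (created if missing).
#' @return `readStructureSet` returns the set; the writer returns the
#'   manifest path invisibly.
#' @export
writeStructureSet <- function(x, dir) {
  stopifnot(is(x, "StructureSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (nm in structureNames(x)) {
    fn <- paste0("mask_", nm, ".nii.gz")
    m <- structureMask(x, nm)
    vol <- huImage(array(as.numeric(m), dim(m)), x@spacing, x@origin)
    writeVolume(vol, file.path(dir, fn))
    manifest[[nm]] <- fn
  }
  mf <- file.path(dir, "structures.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  invisible(mf)
}

#' @rdname writeStructureSet
#' @export
readStructureSet <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "structures.json"),
                                  simplifyVector = TRUE)
  vols <- lapply(manifest, function(fn)
    readVolume(file.path(dir, fn), "HUImage"))
  masks <- lapply(vols, function(v) gridValues(v) > 0.5)
  names(masks) <- names(manifest)
  structureSet(masks, gridSpacing(vols[[1]]), gridOrigin(vols[[1]]))
}

#' Read and write sinograms
#'
#' Values and metal trace are stored as an RDS payload next to a JSON
#' geometry sidecar (angles, bin spacing, source grid, water attenuation),
#' so the geometry is inspectable without loading the array.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param path payload path (`.rds`); the sidecar gets `.json` appended.
#' @return `readSinogram` returns the sinogram; the writer returns `path`
#'   invisibly.
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  saveRDS(list(values = sino@values, metalTrace = sino@metalTrace), path)
  jsonlite::write_json(
    list(angles = sino@angles, binSpacing = sino@binSpacing,
         imgDim = sino@imgDim, imgSpacing = sino@imgSpacing,
         imgOrigin = sino@imgOrigin, muWater = sino@muWater),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  payload <- readRDS(path)
  g <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("Sinogram", values = payload$values, angles = g$angles,
      binSpacing = g$binSpacing, metalTrace = payload$metalTrace,
      imgDim = as.integer(g$imgDim), imgSpacing = g$imgSpacing,
      imgOrigin = g$imgOrigin, muWater = g$muWater)
}
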