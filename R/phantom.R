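#' Tissue-substitute material table
#'
#' The materials a phantom may reference, with mean CT number and Gaussian
#' noise SD per material. `defaultMaterials()` returns the stock table used by
#' [defaultPhantom()]; means anchor to the calibration-curve tissue classes
#' (air -1000, fat -100, soft tissue ~40) and the metal mean sits far above
#' any bone so segmentation thresholds separate it cleanly. All values are
#' configurable; none are measured values of a physical phantom.
#'
#' @param entries data.frame with columns `material`, `hu`, `sd`.
#' @param metalThreshold HU threshold the downstream metal segmentation will
#'   use; the metal mean must exceed it.
#' @return a validated `data.frame` of materials.
#' @examples
#' defaultMaterials()
#' @export
materialTable <- function(entries,
                          metalThreshold = 3000) {
  stopifnot(is.data.frame(entries),
            all(c("material", "hu", "sd") %in% names(entries)))
  required <- c("air", "fat", "soft_tissue", "gel", "bone_cortical",
                "bone_trabecular", "metal")
  missing <- setdiff(required, entries$material)
  if (length(missing))
    stop("material table lacks: ", paste(missing, collapse = ", "))
  if (anyDuplicated(entries$material))
    stop("duplicated material names")
  if (entries$hu[entries$material == "air"] != -1000)
    stop("air mean HU must be -1000")
  if (any(entries$sd < 0))
    stop("HU noise SD must be >= 0")
  if (entries$hu[entries$material == "metal"] <= metalThreshold)
    stop("metal mean HU must exceed the metal segmentation threshold (",
         metalThreshold, ")")
  entries[c("material", "hu", "sd")]
}

#' @rdname materialTable
#' @param noise logical; `FALSE` zeroes all noise SDs.
#' @export
defaultMaterials <- function(noise = TRUE) {
  tab <- data.frame(
    material = c("air", "fat", "soft_tissue", "gel",
                 "bone_trabecular", "bone_cortical", "metal"),
    hu = c(-1000, -100, 40, 20, 300, 1200, 8000),
    sd = c(5, 8, 8, 8, 20, 30, 50))
  if (!noise) tab$sd <- 0
  materialTable(tab)
}

#' Analytic phantom shape
#'
#' Shapes are painted into the label map in list order (later shapes
#' overwrite). An `ellipse` has an in-plane `center` (mm), `semi` axes (mm)
#' and optional rotation `rot` (degrees, counter-clockwise); a `capsule` is
#' the set of points within radius `r` of the segment `p1`--`p2`.
#'
#' @param type `"ellipse"` or `"capsule"`.
#' @param material a material name resolved against the material table.
#' @param center,semi,rot ellipse parameters (mm, mm, degrees).
#' @param p1,p2,r capsule parameters (mm).
#' @param role `"anatomy"` or `"implant"`; implant shapes are the ones
#'   added/mirrored by the implant configuration machinery.
#' @param side `"left"`, `"right"` or `"mid"` tag (image axes: +x is right).
#' @return a shape descriptor list.
#' @export
phantomShape <- function(type = c("ellipse", "capsule"), material,
                         center = c(0, 0), semi = c(10, 10), rot = 0,
                         p1 = NULL, p2 = NULL, r = NULL,
                         role = c("anatomy", "implant"),
                         side = "mid") {
  type <- match.arg(type)
  role <- match.arg(role)
  s <- list(type = type, material = material, role = role, side = side)
  if (type == "ellipse") {
    stopifnot(length(center) == 2, length(semi) == 2, all(semi > 0))
    s$center <- as.numeric(center); s$semi <- as.numeric(semi)
    s$rot <- as.numeric(rot)
  } else {
    stopifnot(length(p1) == 2, length(p2) == 2, r > 0)
    s$p1 <- as.numeric(p1); s$p2 <- as.numeric(p2); s$r <- as.numeric(r)
  }
  s
}

.shapeCentroidX <- function(s) {
  if (s$type == "ellipse") s$center[1] else (s$p1[1] + s$p2[1]) / 2
}

.mirrorShape <- function(s) {
  if (s$type == "ellipse") {
    s$center[1] <- -s$center[1]
    s$rot <- -s$rot
  } else {
    s$p1[1] <- -s$p1[1]; s$p2[1] <- -s$p2[1]
  }
  s$side <- switch(s$side, left = "right", right = "left", "mid")
  s
}

#' Default digital pelvic phantom
#'
#' A desk-scale stand-in for an anthropomorphic pelvic phantom: an elliptical
#' body with a subcutaneous fat rim, a sacrum, two hip bones and two femoral
#' heads (cortical shell + trabecular core), a gel-filled bladder-like cavity,
#' an air-filled rectum-like cavity, and two target volumes (a central
#' prostate-like PTV and a lateral sarcoma-like PTV near the implant side).
#' With `implantConfig = "unilateral"` the right femoral head interior is
#' replaced by a high-density metal implant; `"bilateral"` adds its mirror
#' image across the midsagittal (x = 0) plane.
#'
#' @param implantConfig `"none"`, `"unilateral"` or `"bilateral"`.
#' @param dim grid size in voxels (x, y, slices).
#' @param spacing voxel spacing in mm.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- defaultPhantom("unilateral", dim = c(64, 64, 2), spacing = 8)
#' spec
#' @export
defaultPhantom <- function(implantConfig = c("none", "unilateral",
                                             "bilateral"),
                           dim = c(256, 256, 10),
                           spacing = c(2, 2, 2)) {
  implantConfig <- match.arg(implantConfig)
  sh <- list(
    phantomShape("ellipse", "fat", c(0, 0), c(170, 110)),
    phantomShape("ellipse", "soft_tissue", c(0, 0), c(160, 100)),
    phantomShape("ellipse", "bone_cortical", c(0, -70), c(40, 26)),
    phantomShape("ellipse", "bone_trabecular", c(0, -70), c(32, 18)),
    phantomShape("ellipse", "bone_cortical", c(-66, -5), c(18, 34),
                 rot = 20, side = "left"),
    phantomShape("ellipse", "bone_trabecular", c(-66, -5), c(12, 26),
                 rot = 20, side = "left"),
    phantomShape("ellipse", "bone_cortical", c(66, -5), c(18, 34),
                 rot = -20, side = "right"),
    phantomShape("ellipse", "bone_trabecular", c(66, -5), c(12, 26),
                 rot = -20, side = "right"),
    phantomShape("ellipse", "bone_cortical", c(-100, -10), c(24, 24),
                 side = "left"),
    phantomShape("ellipse", "bone_trabecular", c(-100, -10), c(18, 18),
                 side = "left"),
    phantomShape("ellipse", "bone_cortical", c(100, -10), c(24, 24),
                 side = "right"),
    phantomShape("ellipse", "bone_trabecular", c(100, -10), c(18, 18),
                 side = "right"),
    phantomShape("ellipse", "gel", c(0, 38), c(30, 22)),
    phantomShape("ellipse", "air", c(0, -42), c(12, 12)))
  if (implantConfig != "none")
    sh <- c(sh, list(phantomShape("ellipse", "metal", c(100, -10), c(20, 20),
                                  role = "implant", side = "right")))
  structures <- list(
    body = phantomShape("ellipse", "soft_tissue", c(0, 0), c(170, 110)),
    ptv_prostate = phantomShape("ellipse", "soft_tissue", c(0, -2),
                                c(24, 16)),
    ptv_sarcoma = phantomShape("ellipse", "soft_tissue", c(58, -16),
                               c(18, 14)),
    bladder = phantomShape("ellipse", "gel", c(0, 38), c(30, 22)),
    rectum = phantomShape("ellipse", "air", c(0, -42), c(14, 14)))
  spec <- new("PhantomSpec", dim = as.integer(dim),
              spacing = {
                s <- as.numeric(spacing)
                if (length(s) == 1L) rep(s, 3L) else s
              },
              origin = numeric(3), shapes = sh, structures = structures,
              implantConfig = if (implantConfig == "bilateral") "unilateral"
                              else implantConfig)
  spec@origin <- -(spec@dim - 1) / 2 * spec@spacing
  if (implantConfig == "bilateral") spec <- mirrorImplant(spec)
  spec
}

#' Mirror a unilateral implant into a bilateral configuration
#'
#' Reflects every implant-role shape across the midsagittal plane (x = 0) and
#' appends the mirror image, leaving all anatomy shapes untouched. Applying it
#' to an already bilateral spec is an error (the operation is defined on
#' unilateral configurations only).
#'
#' @param spec a \linkS4class{PhantomSpec} with `implantConfig = "unilateral"`.
#' @return the bilateral \linkS4class{PhantomSpec}.
#' @export
mirrorImplant <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (spec@implantConfig != "unilateral")
    stop("mirrorImplant() requires a unilateral spec")
  implants <- Filter(function(s) s$role == "implant", spec@shapes)
  if (length(implants) == 0L)
    stop("unilateral spec has no implant shape")
  spec@shapes <- c(spec@shapes, lapply(implants, .mirrorShape))
  spec@implantConfig <- "bilateral"
  validObject(spec)
  spec
}

.rasterShape <- function(s, xs, ys) {
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  if (s$type == "ellipse") {
    th <- s$rot * pi / 180
    dx <- X - s$center[1]; dy <- Y - s$center[2]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    (u / s$semi[1])^2 + (v / s$semi[2])^2 <= 1
  } else {
    d <- s$p2 - s$p1
    len2 <- sum(d^2)
    t <- pmin(1, pmax(0, ((X - s$p1[1]) * d[1] + (Y - s$p1[2]) * d[2]) /
                        max(len2, 1e-12)))
    (X - (s$p1[1] + t * d[1]))^2 + (Y - (s$p1[2] + t * d[2]))^2 <= s$r^2
  }
}

#' Rasterize a phantom specification
#'
#' Rasterizes the shape list by centre-of-voxel inclusion into a label map
#' (slices are identical in shape), draws the ground-truth HU image as
#' per-voxel material mean plus seeded Gaussian noise of the material's SD,
#' and rasterizes the structure masks. A `metal` mask (implant voxels) is
#' added to the structure set.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param materials a material table (see [materialTable()]).
#' @param seed integer seed for the HU noise.
#' @return a list with elements `label` (\linkS4class{LabelMap}), `image`
#'   (\linkS4class{HUImage}) and `structures` (\linkS4class{StructureSet}).
#' @examples
#' ph <- buildPhantom(defaultPhantom("none", dim = c(64, 64, 2), spacing = 8),
#'                    defaultMaterials(noise = FALSE), seed = 1)
#' ph$image
#' @export
buildPhantom <- function(spec, materials = defaultMaterials(), seed = 1) {
  stopifnot(is(spec, "PhantomSpec"))
  materials <- materialTable(materials)
  d <- spec@dim
  xs <- spec@origin[1] + (seq_len(d[1]) - 1) * spec@spacing[1]
  ys <- spec@origin[2] + (seq_len(d[2]) - 1) * spec@spacing[2]

  matIdx <- stats::setNames(seq_len(nrow(materials)), materials$material)
  lab2d <- matrix(matIdx[["air"]], d[1], d[2])
  for (s in spec@shapes) {
    if (!s$material %in% names(matIdx))
      stop("shape references unknown material '", s$material, "'")
    inside <- .rasterShape(s, xs, ys)
    if (!any(inside))
      stop("shape of material '", s$material, "' lies outside the grid")
    lab2d[inside] <- matIdx[[s$material]]
  }
  lab <- array(lab2d, d)

  hu <- .withSeed(seed, {
    noise <- stats::rnorm(length(lab)) * materials$sd[lab]
    materials$hu[lab] + noise
  })
  hu <- array(hu, d)

  masks <- lapply(spec@structures, function(s) {
    m <- .rasterShape(s, xs, ys)
    if (!any(m)) stop("structure mask is empty")
    array(m, d)
  })
  masks$metal <- lab == matIdx[["metal"]]
  ptvs <- grep("^ptv", names(masks), value = TRUE)
  for (p in ptvs)
    if (any(masks[[p]] & masks$metal))
      stop("target '", p, "' overlaps the metal implant")

  list(label = labelMap(lab, spec@spacing, spec@origin),
       image = huImage(hu, spec@spacing, spec@origin),
       structures = structureSet(masks, spec@spacing, spec@origin))
}

#' Read and write phantom specifications
#'
#' Serializes the full phantom description (grid, shapes, structures,
#' implant configuration) and optionally a material table to YAML or JSON,
#' chosen by file extension, so a phantom configuration can be versioned
#' and shared as plain text.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param materials optional material table stored alongside the spec.
#' @return `readPhantomSpec` returns a list with elements `spec` and
#'   `materials` (`NULL` if none stored); the writer returns `path`
#'   invisibly.
#' @export
writePhantomSpec <- function(spec, path, materials = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  payload <- list(dim = spec@dim, spacing = spec@spacing,
                  origin = spec@origin, implantConfig = spec@implantConfig,
                  shapes = spec@shapes, structures = spec@structures)
  if (!is.null(materials))
    payload$materials <- as.list(materialTable(materials))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension (use .yaml or .json)")
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else stop("unsupported extension (use .yaml or .json)")
  fix <- function(s) {
    for (f in c("center", "semi", "p1", "p2"))
      if (!is.null(s[[f]])) s[[f]] <- as.numeric(s[[f]])
    for (f in c("rot", "r")) if (!is.null(s[[f]])) s[[f]] <- as.numeric(s[[f]])
    s
  }
  spec <- new("PhantomSpec", dim = as.integer(unlist(x$dim)),
              spacing = as.numeric(unlist(x$spacing)),
              origin = as.numeric(unlist(x$origin)),
              shapes = lapply(x$shapes, fix),
              structures = lapply(x$structures, fix),
              implantConfig = x$implantConfig)
  validObject(spec)
  mats <- if (!is.null(x$materials))
    materialTable(as.data.frame(x$materials)) else NULL
  list(spec = spec, materials = mats)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s grid, %s mm spacing, implants '%s'\n",
    paste(object@dim, collapse = " x "),
    paste(format(object@spacing, digits = 3), collapse = " x "),
    object@implantConfig))
  cat(sprintf("  %d shapes, structures: %s\n", length(object@shapes),
              paste(names(object@structures), collapse = ", ")))
})

# evaluate expr under a temporary RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage seed derived from a global seed
.deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
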