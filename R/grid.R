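#' Construct voxel-grid objects
#'
#' Low-level constructors for the grid containers. `values` may be a matrix
#' (promoted to a single-slice 3-D array). If `origin` is `NULL` the grid is
#' centred on world (0, 0, 0).
#'
#' @param values numeric array (2-D or 3-D).
#' @param spacing voxel spacing in mm; a scalar is recycled to length 3.
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1), or
#'   `NULL` to centre the grid at the world origin.
#' @return an object of the requested class.
#' @examples
#' img <- huImage(array(0, c(8, 8, 2)), spacing = 2)
#' gridDim(img)
#' @export
huImage <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  g <- .asGrid(values, spacing, origin)
  new("HUImage", values = g$values, spacing = g$spacing, origin = g$origin)
}

#' @rdname huImage
#' @export
labelMap <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  g <- .asGrid(values, spacing, origin)
  new("LabelMap", values = g$values, spacing = g$spacing, origin = g$origin)
}

#' @rdname huImage
#' @param overrideMask logical array marking voxels set by an override rule.
#' @export
rlspMap <- function(values, spacing = c(1, 1, 1), origin = NULL,
                    overrideMask = NULL) {
  g <- .asGrid(values, spacing, origin)
  if (is.null(overrideMask))
    overrideMask <- array(FALSE, dim(g$values))
  new("RLSPMap", values = g$values, spacing = g$spacing, origin = g$origin,
      overrideMask = overrideMask)
}

#' @rdname huImage
#' @param prescription prescription dose the grid is normalised to.
#' @export
doseGrid <- function(values, spacing = c(1, 1, 1), origin = NULL,
                     prescription = 100) {
  g <- .asGrid(values, spacing, origin)
  new("DoseGrid", values = g$values, spacing = g$spacing, origin = g$origin,
      prescription = prescription)
}

#' @rdname StructureSet-class
#' @param masks named list of logical arrays (2-D masks are promoted).
#' @param spacing,origin grid geometry (see [huImage()]).
#' @export
structureSet <- function(masks, spacing = c(1, 1, 1), origin = NULL) {
  masks <- lapply(masks, function(m) {
    if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
    m
  })
  g <- .asGrid(masks[[1]] * 0, spacing, origin)
  new("StructureSet", masks = masks, spacing = g$spacing, origin = g$origin)
}

.asGrid <- function(values, spacing, origin) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("values must be a 2-D or 3-D array")
  storage.mode(values) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (is.null(origin))
    origin <- -(dim(values) - 1) / 2 * spacing
  list(values = values, spacing = spacing, origin = as.numeric(origin))
}

#' @rdname grid-accessors
setMethod("gridValues", "GridVolume", function(x) x@values)
#' @rdname grid-accessors
setMethod("gridSpacing", "GridVolume", function(x) x@spacing)
#' @rdname grid-accessors
setMethod("gridOrigin", "GridVolume", function(x) x@origin)
#' @rdname grid-accessors
setMethod("gridDim", "GridVolume", function(x) dim(x@values))
#' @rdname grid-accessors
setMethod("gridSpacing", "StructureSet", function(x) x@spacing)
#' @rdname grid-accessors
setMethod("gridOrigin", "StructureSet", function(x) x@origin)
#' @rdname grid-accessors
setMethod("gridDim", "StructureSet", function(x) dim(x@masks[[1]]))

#' @rdname StructureSet-class
setMethod("structureNames", "StructureSet", function(x) names(x@masks))
#' @rdname StructureSet-class
setMethod("structureMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop("no structure named '", name, "'")
  x@masks[[name]]
})

#' Override mask of an RLSP map
#'
#' Logical array marking the voxels whose RLSP came from an override rule
#' rather than the calibration curve.
#' @param x an \linkS4class{RLSPMap}.
#' @return logical array of the grid's dimension.
#' @export
overrideMask <- function(x) {
  stopifnot(is(x, "RLSPMap"))
  x@overrideMask
}

.showGrid <- function(object, what) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n", what,
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  v <- object@values
  cat(sprintf("  range [%.6g, %.6g]\n", min(v), max(v)))
}

setMethod("show", "HUImage", function(object) .showGrid(object, "HUImage (HU)"))
setMethod("show", "LabelMap", function(object) .showGrid(object, "LabelMap"))
setMethod("show", "RLSPMap", function(object) {
  .showGrid(object, "RLSPMap (relative to water)")
  n <- sum(object@overrideMask)
  if (n > 0) cat(sprintf("  %d voxels overridden\n", n))
})
setMethod("show", "DoseGrid", function(object) {
  .showGrid(object, "DoseGrid (% of prescription)")
})
setMethod("show", "StructureSet", function(object) {
  d <- gridDim(object)
  cat(sprintf("StructureSet on %d x %d x %d grid:\n", d[1], d[2], d[3]))
  for (nm in names(object@masks))
    cat(sprintf("  %-14s %d voxels\n", nm, sum(object@masks[[nm]])))
})
setMethod("show", "Sinogram", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "Sinogram: %d bins x %d views x %d slices, bin spacing %.3g mm\n",
    d[1], d[2], d[3], object@binSpacing))
  cat(sprintf("  metal trace: %d samples\n", sum(object@metalTrace)))
})
setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: %d control points (%d linear segments), %s\n",
    length(object@hu), length(object@hu) - 1L, object@extrapolation))
  print(data.frame(hu = object@hu, rlsp = object@rlsp), row.names = FALSE)
})

# world coordinates of in-plane voxel centres
.worldX <- function(x) x@origin[1] + (seq_len(dim(x@values)[1]) - 1) * x@spacing[1]
.worldY <- function(x) x@origin[2] + (seq_len(dim(x@values)[2]) - 1) * x@spacing[2]

#' Bilinear in-plane sampling of a grid slice
#'
#' Samples a slice at arbitrary in-plane world coordinates; points outside the
#' grid return `outside` (air, by default 0).
#'
#' @param slice numeric matrix (one slice of a grid object).
#' @param spacing,origin in-plane geometry (length-2 vectors, mm).
#' @param xy n x 2 matrix of world coordinates (mm).
#' @param outside value returned for points outside the grid.
#' @return numeric vector of sampled values.
#' @keywords internal
sampleBilinear <- function(slice, spacing, origin, xy, outside = 0) {
  fx <- (xy[, 1] - origin[1]) / spacing[1]
  fy <- (xy[, 2] - origin[2]) / spacing[2]
  nx <- nrow(slice); ny <- ncol(slice)
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  get <- function(i, j) {
    ok <- i >= 0 & i <= nx - 1 & j >= 0 & j <= ny - 1
    v <- numeric(length(i))
    v[ok] <- slice[cbind(i[ok] + 1L, j[ok] + 1L)]
    v[!ok] <- outside
    v
  }
  (1 - wx) * (1 - wy) * get(i0, j0) +
    wx * (1 - wy) * get(i0 + 1, j0) +
    (1 - wx) * wy * get(i0, j0 + 1) +
    wx * wy * get(i0 + 1, j0 + 1)
}
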