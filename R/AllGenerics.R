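#' @import methods
NULL

#' Grid accessors
#'
#' Accessors for the voxel-grid containers (\linkS4class{HUImage},
#' \linkS4class{LabelMap}, \linkS4class{RLSPMap}, \linkS4class{DoseGrid},
#' \linkS4class{StructureSet}).
#'
#' @param x a grid object.
#' @return `gridValues` returns the voxel array, `gridSpacing` the voxel
#'   spacing in mm (length 3), `gridOrigin` the world coordinate (mm) of the
#'   centre of voxel (1,1,1), and `gridDim` the grid dimensions.
#' @name grid-accessors
#' @aliases gridValues gridSpacing gridOrigin gridDim
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @param name structure name.
#' @rdname StructureSet-class
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname StructureSet-class
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @param x a \linkS4class{CalibrationCurve}.
#' @rdname CalibrationCurve-class
#' @export
setGeneric("controlPoints", function(x) standardGeneric("controlPoints"))
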