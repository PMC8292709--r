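#' @importFrom Rcpp sourceCpp
#' @useDynLib marbench, .registration = TRUE
NULL

.checkGrid <- function(object) {
  msg <- NULL
  v <- object@values
  if (length(dim(v)) != 3L)
    msg <- c(msg, "'values' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  msg
}

#' Voxel-grid containers
#'
#' `GridVolume` is the virtual parent of all image-like containers: a 3-D
#' voxel array plus spacing (mm/voxel) and world origin (mm, at the centre of
#' voxel (1,1,1)). Concrete subclasses are `HUImage` (CT numbers in Hounsfield
#' units), `LabelMap` (integer material labels), `RLSPMap` (relative linear
#' stopping power, unitless, relative to water) and `DoseGrid` (dose in % of
#' prescription units).
#'
#' @slot values 3-D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot origin numeric(3), world coordinate of the first voxel centre in mm.
#'
#' @aliases GridVolume HUImage-class LabelMap-class RLSPMap-class
#'   DoseGrid-class
#' @name GridVolume-class
#' @exportClass GridVolume
setClass("GridVolume",
         representation("VIRTUAL",
                        values = "array",
                        spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
           msg <- .checkGrid(object)
           if (is.null(msg)) TRUE else msg
         })

#' @exportClass HUImage
setClass("HUImage", contains = "GridVolume",
         validity = function(object) {
           if (any(!is.finite(object@values)))
             "HU values must be finite" else TRUE
         })

#' @exportClass LabelMap
setClass("LabelMap", contains = "GridVolume",
         validity = function(object) {
           v <- object@values
           if (any(v != round(v)) || any(v < 0))
             "labels must be non-negative integers" else TRUE
         })

#' @slot overrideMask for `RLSPMap`: logical array flagging voxels whose value
#'   came from a structure override rather than the calibration curve.
#' @rdname GridVolume-class
#' @exportClass RLSPMap
setClass("RLSPMap", contains = "GridVolume",
         representation(overrideMask = "array"),
         validity = function(object) {
           msg <- NULL
           if (any(!is.finite(object@values)) || any(object@values < 0))
             msg <- c(msg, "RLSP values must be finite and >= 0")
           if (!identical(dim(object@overrideMask), dim(object@values)))
             msg <- c(msg, "overrideMask must match the value grid")
           if (is.null(msg)) TRUE else msg
         })

#' @slot prescription for `DoseGrid`: the prescription dose the grid is
#'   normalised against (100 = prescription).
#' @rdname GridVolume-class
#' @exportClass DoseGrid
setClass("DoseGrid", contains = "GridVolume",
         representation(prescription = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (any(!is.finite(object@values)) || any(object@values < 0))
             msg <- c(msg, "dose must be finite and >= 0")
           if (length(object@prescription) != 1L || object@prescription <= 0)
             msg <- c(msg, "prescription must be a single positive number")
           if (is.null(msg)) TRUE else msg
         })

#' Named structure masks on a voxel grid
#'
#' A `StructureSet` holds named boolean masks (PTVs, bladder, rectum, metal,
#' body, override regions) sharing one grid geometry.
#'
#' @slot masks named list of logical 3-D arrays, all of identical dimension.
#' @slot spacing,origin grid geometry, as for \linkS4class{GridVolume}.
#' @exportClass StructureSet
setClass("StructureSet",
         representation(masks = "list", spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
           msg <- NULL
           m <- object@masks
           if (length(m) == 0L || is.null(names(m)) || any(names(m) == ""))
             msg <- c(msg, "masks must be a non-empty named list")
           dims <- lapply(m, dim)
           if (length(unique(dims)) > 1L)
             msg <- c(msg, "all masks must share one grid")
           if (!all(vapply(m, is.logical, TRUE)))
             msg <- c(msg, "masks must be logical arrays")
           if (is.null(msg)) TRUE else msg
         })

#' Parallel-beam sinogram
#'
#' Line integrals of linear attenuation (unitless) on a parallel-beam
#' geometry: detector bin x view angle x slice. Carries the source-image grid
#' so reconstruction can return to the same voxel lattice, and a metal-trace
#' mask (sinogram samples whose rays intersect segmented metal).
#'
#' @slot values numeric array `[nBins, nAngles, nSlices]` of line integrals.
#' @slot angles view angles in radians over `[0, pi)`.
#' @slot binSpacing detector bin spacing in mm.
#' @slot metalTrace logical array, same shape as `values`.
#' @slot imgDim,imgSpacing,imgOrigin geometry of the source image grid.
#' @slot muWater linear attenuation of water (per mm) used for the HU<->mu
#'   conversion.
#' @exportClass Sinogram
setClass("Sinogram",
         representation(values = "array", angles = "numeric",
                        binSpacing = "numeric", metalTrace = "array",
                        imgDim = "integer", imgSpacing = "numeric",
                        imgOrigin = "numeric", muWater = "numeric"),
         validity = function(object) {
           msg <- NULL
           d <- dim(object@values)
           if (length(d) != 3L)
             msg <- c(msg, "values must be [nBins, nAngles, nSlices]")
           if (length(object@angles) != d[2])
             msg <- c(msg, "length(angles) must equal nAngles")
           if (length(object@angles) < 2L)
             msg <- c(msg, "at least 2 view angles required")
           if (any(!is.finite(object@values)))
             msg <- c(msg, "line integrals must be finite")
           if (!identical(dim(object@metalTrace), d))
             msg <- c(msg, "metalTrace must match values")
           if (object@muWater <= 0)
             msg <- c(msg, "muWater must be > 0")
           if (is.null(msg)) TRUE else msg
         })

#' HU to RLSP calibration curve
#'
#' Ordered control points defining a piecewise-linear map from CT number (HU)
#' to relative linear stopping power, with a policy for values outside the
#' control-point range.
#'
#' @slot hu control-point HU values, strictly increasing.
#' @slot rlsp control-point RLSP values, non-decreasing; the first must be 0
#'   (air anchors the curve).
#' @slot extrapolation `"clamp"` (hold endpoint values) or `"linear"` (extend
#'   the end segments).
#' @seealso [defaultCalibration()], [rlspAt()], [applyCalibration()]
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
         representation(hu = "numeric", rlsp = "numeric",
                        extrapolation = "character"),
         validity = function(object) {
           msg <- NULL
           if (length(object@hu) < 2L ||
               length(object@hu) != length(object@rlsp))
             msg <- c(msg, "need >= 2 (hu, rlsp) control points")
           if (any(diff(object@hu) <= 0))
             msg <- c(msg, "HU control points must be strictly increasing")
           if (any(diff(object@rlsp) < 0))
             msg <- c(msg, "RLSP control points must be non-decreasing")
           if (object@rlsp[1] != 0)
             msg <- c(msg, "first control point must have RLSP 0")
           if (!object@extrapolation %in% c("clamp", "linear"))
             msg <- c(msg, "extrapolation must be 'clamp' or 'linear'")
           if (is.null(msg)) TRUE else msg
         })

#' Digital pelvic phantom specification
#'
#' Declarative description of the synthetic pelvic phantom: grid geometry, an
#' ordered list of analytic shapes (painted in order, later shapes overwrite
#' earlier ones) and named structure definitions (PTVs, bladder, rectum).
#' Slices are identical in shape; the phantom is a 3-D stack so volume-based
#' metrics are meaningful.
#'
#' @slot dim integer(3) grid size in voxels.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) world coordinate of the first voxel centre (mm).
#' @slot shapes list of shape descriptors (see [phantomShape()]).
#' @slot structures named list of shape descriptors defining structure masks.
#' @slot implantConfig one of `"none"`, `"unilateral"`, `"bilateral"`.
#' @seealso [defaultPhantom()], [buildPhantom()], [mirrorImplant()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(dim = "integer", spacing = "numeric",
                        origin = "numeric", shapes = "list",
                        structures = "list", implantConfig = "character"),
         validity = function(object) {
           msg <- NULL
           if (length(object@dim) != 3L || any(object@dim < 1L))
             msg <- c(msg, "dim must be 3 positive integers")
           if (length(object@spacing) != 3L || any(object@spacing <= 0))
             msg <- c(msg, "spacing must be 3 positive values")
           if (!object@implantConfig %in% c("none", "unilateral", "bilateral"))
             msg <- c(msg,
               "implantConfig must be 'none', 'unilateral' or 'bilateral'")
           if (length(object@structures) == 0L ||
               is.null(names(object@structures)))
             msg <- c(msg, "structures must be a named list")
           if (is.null(msg)) TRUE else msg
         })

#' Parameters of the iterated NMAR + FSMAR correction
#'
#' @slot metalThreshold HU at and above which a voxel is metal.
#' @slot airThreshold,boneThreshold HU class boundaries for the prior image
#'   (air/soft and soft/bone); must satisfy
#'   `airThreshold < boneThreshold < metalThreshold`.
#' @slot airValue,softValue replacement HU for the air and soft-tissue classes
#'   of the prior (bone voxels keep their measured HU).
#' @slot nIter number of NMAR+FSMAR iterations, >= 1.
#' @slot sigma frequency-split Gaussian sigma in mm.
#' @slot weightBand numeric(2), distance band (mm from metal) over which the
#'   FSMAR weight ramps from 0 (at and inside `weightBand[1]`) to 1 (beyond
#'   `weightBand[2]`).
#' @slot reinsertMetal put the original reconstructed metal voxels back after
#'   the final iteration so implants stay visible.
#' @seealso [marParams()], [imar()]
#' @exportClass MARParams
setClass("MARParams",
         representation(metalThreshold = "numeric", airThreshold = "numeric",
                        boneThreshold = "numeric", airValue = "numeric",
                        softValue = "numeric", nIter = "integer",
                        sigma = "numeric", weightBand = "numeric",
                        reinsertMetal = "logical"),
         validity = function(object) {
           msg <- NULL
           if (!(object@airThreshold < object@boneThreshold &&
                 object@boneThreshold < object@metalThreshold))
             msg <- c(msg, "thresholds must be strictly increasing")
           if (object@nIter < 1L)
             msg <- c(msg, "nIter must be >= 1")
           if (object@sigma <= 0)
             msg <- c(msg, "sigma must be > 0")
           if (length(object@weightBand) != 2L ||
               object@weightBand[1] < 0 ||
               diff(object@weightBand) <= 0)
             msg <- c(msg, "weightBand must be increasing and >= 0")
           if (is.null(msg)) TRUE else msg
         })

#' Analytic spread-out Bragg peak depth-dose model
#'
#' Surrogate depth-dose template indexed by cumulative water-equivalent depth:
#' an entrance plateau at `entranceRatio` of the SOBP level, a logistic
#' proximal buildup to the plateau at depth `R - M`, a flat plateau on
#' `[R - M, R]`, and a logistic distal falloff at `R` with the given 80-20%
#' distance. It reproduces the range sensitivity that drives the evaluation
#' (a sharp, WEPL-indexed distal edge), not any beamline's physics.
#'
#' @slot plateau plateau dose level (relative units, normalised later).
#' @slot falloff distal 80-20% falloff distance in mm WEPL.
#' @slot buildup proximal 20-80% buildup distance in mm WEPL.
#' @slot entranceRatio entrance dose as a fraction of the plateau, in [0, 1).
#' @seealso [sobpModel()], [computeDose()]
#' @exportClass SobpModel
setClass("SobpModel",
         representation(plateau = "numeric", falloff = "numeric",
                        buildup = "numeric", entranceRatio = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (object@falloff <= 0 || object@buildup <= 0)
             msg <- c(msg, "falloff and buildup distances must be > 0")
           if (object@entranceRatio < 0 || object@entranceRatio >= 1)
             msg <- c(msg, "entranceRatio must be in [0, 1)")
           if (object@plateau <= object@plateau * object@entranceRatio)
             TRUE
           if (is.null(msg)) TRUE else msg
         })

#' Single-field beam specification
#'
#' One in-slice beam with frozen range/modulation. Angles follow the
#' convention: direction of travel is `(cos(a), -sin(a))` in world (x, y), so
#' 90 degrees is the anterior-posterior vertical beam and 0/180 degrees are
#' lateral beams.
#'
#' @slot angle gantry angle in degrees (in-slice).
#' @slot raySpacing lateral ray spacing in mm.
#' @slot range distal range R in mm WEPL.
#' @slot modulation modulation width M in mm WEPL (plateau spans `[R-M, R]`).
#' @slot lateralMargin lateral field margin beyond the target in mm.
#' @slot penumbraSigma lateral Gaussian penumbra sigma in mm.
#' @slot weight beam weight (fraction of prescription carried by this field).
#' @slot latRange numeric(2), beam's-eye-view lateral aperture (mm, relative
#'   to isocentre), margins included.
#' @slot iso numeric(2), in-plane isocentre (mm).
#' @exportClass BeamSpec
setClass("BeamSpec",
         representation(angle = "numeric", raySpacing = "numeric",
                        range = "numeric", modulation = "numeric",
                        lateralMargin = "numeric", penumbraSigma = "numeric",
                        weight = "numeric", latRange = "numeric",
                        iso = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (!(object@range > object@modulation && object@modulation >= 0))
             msg <- c(msg, "need range > modulation >= 0")
           if (object@weight <= 0)
             msg <- c(msg, "weight must be > 0")
           if (length(object@latRange) != 2L || diff(object@latRange) <= 0)
             msg <- c(msg, "latRange must be an increasing pair")
           if (is.null(msg)) TRUE else msg
         })

#' Treatment plan: frozen beams plus normalisation
#'
#' Produced by [planBeams()]; `scale` is fixed at planning time so that the
#' mean PTV dose on the planning image equals the prescription, and is reused
#' unchanged when the plan is recalculated on another image
#' ([recalculateDose()]).
#'
#' @slot beams list of \linkS4class{BeamSpec}.
#' @slot prescription prescription dose (100 = prescription, doses are
#'   reported in % of prescription).
#' @slot scale normalisation factor frozen at planning time.
#' @slot model the \linkS4class{SobpModel} used at planning time.
#' @slot gridDim dimensions of the planning grid (recalculation requires a
#'   congruent grid).
#' @exportClass TreatmentPlan
setClass("TreatmentPlan",
         representation(beams = "list", prescription = "numeric",
                        scale = "numeric", model = "SobpModel",
                        gridDim = "integer"),
         validity = function(object) {
           msg <- NULL
           if (length(object@beams) == 0L ||
               !all(vapply(object@beams, is, TRUE, "BeamSpec")))
             msg <- c(msg, "beams must be a non-empty list of BeamSpec")
           if (object@prescription <= 0)
             msg <- c(msg, "prescription must be > 0")
           if (object@scale <= 0)
             msg <- c(msg, "scale must be > 0")
           if (is.null(msg)) TRUE else msg
         })

#' Gamma-analysis parameters
#'
#' Criteria for the gamma comparison of two dose grids: dose-difference
#' criterion as % of the local reference dose, distance-to-agreement in mm,
#' and a low-dose cutoff as a fraction of the maximum of the reference
#' (calculated) distribution.
#'
#' @slot ddPercent dose-difference criterion, % of local reference dose.
#' @slot dtaMm distance-to-agreement in mm.
#' @slot cutoff low-dose cutoff as a fraction of the reference maximum; ref
#'   voxels below it are not evaluated.
#' @slot normalization `"local"` (only mode implemented: the criterion scales
#'   with the reference voxel's own dose).
#' @slot searchFactor search radius as a multiple of `dtaMm`.
#' @slot subvoxel refine the search below voxel resolution by minimising
#'   gamma analytically along lattice edges (exact for linearly interpolated
#'   evaluated dose); `FALSE` searches voxel centres only.
#' @seealso [gammaParams()], [gammaIndex()]
#' @exportClass GammaParams
setClass("GammaParams",
         representation(ddPercent = "numeric", dtaMm = "numeric",
                        cutoff = "numeric", normalization = "character",
                        searchFactor = "numeric", subvoxel = "logical"),
         validity = function(object) {
           msg <- NULL
           if (object@ddPercent <= 0 || object@dtaMm <= 0)
             msg <- c(msg, "criteria must be > 0")
           if (object@cutoff < 0 || object@cutoff >= 1)
             msg <- c(msg, "cutoff must be in [0, 1)")
           if (object@normalization != "local")
             msg <- c(msg, "only local normalization is implemented")
           if (object@searchFactor < 1)
             msg <- c(msg, "searchFactor must be >= 1")
           if (is.null(msg)) TRUE else msg
         })

#' Result of a gamma analysis
#'
#' @slot passRate3d global 3-D pass rate, % of evaluated voxels with gamma<1.
#' @slot sliceRates per-slice 2-D pass rates (%, in-plane search only); `NA`
#'   for slices with no voxel above the cutoff.
#' @slot worstSlice index of the slice with the lowest 2-D pass rate.
#' @slot worstSliceRate the lowest 2-D per-slice pass rate (%).
#' @slot gammaMap 3-D array of gamma values (`NA` below the cutoff).
#' @exportClass GammaResult
setClass("GammaResult",
         representation(passRate3d = "numeric", sliceRates = "numeric",
                        worstSlice = "integer", worstSliceRate = "numeric",
                        gammaMap = "array"),
         validity = function(object) {
           ok3 <- object@passRate3d >= 0 && object@passRate3d <= 100
           okw <- is.na(object@worstSliceRate) ||
             (object@worstSliceRate >= 0 && object@worstSliceRate <= 100)
           if (ok3 && okw) TRUE else "pass rates must lie in [0, 100]"
         })

#' Sampled ray through the image grid
#'
#' @slot start in-plane start point (x, y) in mm.
#' @slot direction in-plane unit direction.
#' @slot length total physical length in mm.
#' @slot step sampling step in mm.
#' @slot slice slice index the ray lives in.
#' @seealso [rayPath()], [traceWEPL()], [rayBundle()]
#' @exportClass RayPath
setClass("RayPath",
         representation(start = "numeric", direction = "numeric",
                        length = "numeric", step = "numeric",
                        slice = "integer"),
         validity = function(object) {
           msg <- NULL
           n <- sqrt(sum(object@direction^2))
           if (abs(n - 1) > 1e-8)
             msg <- c(msg, "direction must be a unit vector")
           if (object@length <= 0 || object@step <= 0)
             msg <- c(msg, "length and step must be > 0")
           if (is.null(msg)) TRUE else msg
         })

#' Water-equivalent path length along a ray
#'
#' Cumulative WEPL (`wepl[i]` is the water-equivalent depth at physical depth
#' `depths[i]`) obtained by midpoint sampling of the RLSP map along a
#' \linkS4class{RayPath}; WEPL = physical length x RLSP accumulated along the
#' path.
#'
#' @slot depths sampled physical depths in mm (starting at 0).
#' @slot rlsp RLSP sampled at each depth (informative; accumulation uses
#'   interval midpoints).
#' @slot wepl cumulative water-equivalent depth in mm at each depth.
#' @slot ray the ray traced.
#' @slot tag source image tag, e.g. `"fbp"`, `"imar"`, `"gt"`.
#' @exportClass WEPLProfile
setClass("WEPLProfile",
         representation(depths = "numeric", rlsp = "numeric",
                        wepl = "numeric", ray = "RayPath", tag = "character"),
         validity = function(object) {
           msg <- NULL
           n <- length(object@depths)
           if (length(object@wepl) != n || length(object@rlsp) != n)
             msg <- c(msg, "depths, rlsp and wepl must have equal length")
           if (n > 1 && any(diff(object@wepl) < -1e-9))
             msg <- c(msg, "cumulative WEPL must be non-decreasing")
           if (is.null(msg)) TRUE else msg
         })

#' Per-depth WEPL deviation between two profiles on the same ray
#'
#' Difference test - ground truth (mm) at each sampled depth, with the signed
#' extremum (the deviation of largest magnitude) and its depth.
#'
#' @slot depths sampled depths (mm).
#' @slot delta per-depth WEPL difference (mm).
#' @slot extremum signed deviation of largest magnitude (mm).
#' @slot extremumDepth depth of the extremum (mm).
#' @exportClass DeltaWEPL
setClass("DeltaWEPL",
         representation(depths = "numeric", delta = "numeric",
                        extremum = "numeric", extremumDepth = "numeric"),
         validity = function(object) {
           if (length(object@depths) != length(object@delta))
             "depths and delta must have equal length" else TRUE
         })
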