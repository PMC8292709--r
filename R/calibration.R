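#' Construct a calibration curve
#'
#' @param hu,rlsp control points; HU strictly increasing, RLSP non-decreasing
#'   with the first value 0.
#' @param extrapolation `"clamp"` (default; hold endpoint values outside the
#'   control range) or `"linear"` (extend the end segments, floored at 0).
#' @return a \linkS4class{CalibrationCurve}.
#' @export
calibrationCurve <- function(hu, rlsp, extrapolation = c("clamp", "linear")) {
  new("CalibrationCurve", hu = as.numeric(hu), rlsp = as.numeric(rlsp),
      extrapolation = match.arg(extrapolation))
}

#' Stock six-point HU to RLSP calibration curve
#'
#' The piecewise-linear calibration used throughout the package: six control
#' points, five linear segments, spanning air (-1000 HU, RLSP 0) through
#' soft tissue (0 HU, RLSP 1) up to a dense-material anchor (3095 HU,
#' RLSP 2.602). Values beyond the last point clamp by default: clamping
#' bounds the WEPL error contribution of voxels whose CT numbers are not
#' physical (saturated metal), which is standard commissioning practice.
#'
#' @inheritParams calibrationCurve
#' @return a \linkS4class{CalibrationCurve} with exactly 6 control points.
#' @examples
#' defaultCalibration()
#' rlspAt(defaultCalibration(), c(-200, 0, 50))
#' @export
defaultCalibration <- function(extrapolation = c("clamp", "linear")) {
  calibrationCurve(hu = c(-1000, -200, -100, 0, 50, 3095),
                   rlsp = c(0, 0.8, 0.95, 1.0, 1.05, 2.602),
                   extrapolation = match.arg(extrapolation))
}

#' @rdname CalibrationCurve-class
setMethod("controlPoints", "CalibrationCurve", function(x) {
  data.frame(hu = x@hu, rlsp = x@rlsp)
})

#' Evaluate a calibration curve
#'
#' Exact linear interpolation within segments; outside the control range the
#' extrapolation policy applies (`"clamp"`: endpoint values; `"linear"`: end
#' segments extended, floored at 0 since stopping power cannot be negative).
#' The map is monotone non-decreasing over the whole real line.
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param hu numeric vector/array of CT numbers.
#' @return RLSP values, same shape as `hu`.
#' @export
rlspAt <- function(curve, hu) {
  stopifnot(is(curve, "CalibrationCurve"))
  shape <- dim(hu)
  x <- as.numeric(hu)
  out <- stats::approx(curve@hu, curve@rlsp, xout = x, rule = 2)$y
  if (curve@extrapolation == "linear") {
    n <- length(curve@hu)
    below <- x < curve@hu[1]
    above <- x > curve@hu[n]
    if (any(below)) {
      s <- (curve@rlsp[2] - curve@rlsp[1]) / (curve@hu[2] - curve@hu[1])
      out[below] <- pmax(0, curve@rlsp[1] + s * (x[below] - curve@hu[1]))
    }
    if (any(above)) {
      s <- (curve@rlsp[n] - curve@rlsp[n - 1]) /
        (curve@hu[n] - curve@hu[n - 1])
      out[above] <- curve@rlsp[n] + s * (x[above] - curve@hu[n])
    }
  }
  if (!is.null(shape)) dim(out) <- shape
  out
}

#' Structure override rule for RLSP assignment
#'
#' Assigns a fixed RLSP to all voxels of a named structure (resolved against
#' a \linkS4class{StructureSet} at application time) or an explicit mask.
#' The stock use is the departmental-protocol style override of rectal air to
#' water (`overrideRule("rectum_air", 1.0)`).
#'
#' @param structure structure name, or `NULL` when `mask` is given.
#' @param rlsp fixed RLSP value, >= 0.
#' @param mask explicit logical array, or `NULL`.
#' @return an override rule (list).
#' @export
overrideRule <- function(structure = NULL, rlsp, mask = NULL) {
  stopifnot(rlsp >= 0, !is.null(structure) || !is.null(mask))
  list(structure = structure, rlsp = rlsp, mask = mask)
}

#' Convert an HU image to an RLSP map
#'
#' Voxel-wise application of the calibration curve, followed by the override
#' rules in list order (later rules win on overlap). The union of all
#' override masks is recorded in the result's `overrideMask` slot as
#' provenance.
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param image an \linkS4class{HUImage}.
#' @param overrides list of [overrideRule()]s.
#' @param structures a \linkS4class{StructureSet} used to resolve named
#'   override rules (must share the image grid).
#' @return an \linkS4class{RLSPMap}.
#' @examples
#' img <- huImage(matrix(0, 8, 8))
#' applyCalibration(defaultCalibration(), img)
#' @export
applyCalibration <- function(curve, image, overrides = list(),
                             structures = NULL) {
  stopifnot(is(curve, "CalibrationCurve"), is(image, "HUImage"))
  v <- rlspAt(curve, gridValues(image))
  prov <- array(FALSE, dim(v))
  for (rule in overrides) {
    m <- rule$mask
    if (is.null(m)) {
      if (is.null(structures))
        stop("named override rules require a StructureSet")
      m <- structureMask(structures, rule$structure)
    }
    if (!identical(dim(m), dim(v)))
      stop("override mask grid does not match the image grid")
    v[m] <- rule$rlsp
    prov <- prov | m
  }
  rlspMap(v, gridSpacing(image), gridOrigin(image), overrideMask = prov)
}

#' Read/write calibration curves
#'
#' CSV (two columns `hu`, `rlsp`) or JSON (fields `hu`, `rlsp`,
#' `extrapolation`), chosen by file extension.
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param path file path ending in `.csv` or `.json`.
#' @return `readCalibrationCurve` returns the curve; the writer returns
#'   `path` invisibly.
#' @export
writeCalibrationCurve <- function(curve, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(controlPoints(curve), path, row.names = FALSE)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(hu = curve@hu, rlsp = curve@rlsp,
                              extrapolation = curve@extrapolation),
                         path, digits = NA)
  } else stop("unsupported extension (use .csv or .json)")
  invisible(path)
}

#' @rdname writeCalibrationCurve
#' @export
readCalibrationCurve <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path)
    calibrationCurve(df$hu, df$rlsp)
  } else if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    calibrationCurve(x$hu, x$rlsp, x$extrapolation)
  } else stop("unsupported extension (use .csv or .json)")
}
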