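#' Gamma-analysis parameters
#'
#' Constructor for \linkS4class{GammaParams}; defaults are the 1% / 2 mm
#' local-difference criteria with a 10% low-dose cutoff.
#'
#' @param ddPercent dose-difference criterion, % of local reference dose.
#' @param dtaMm distance-to-agreement, mm.
#' @param cutoff low-dose cutoff, fraction of the reference maximum.
#' @param normalization `"local"`.
#' @param searchFactor search radius in multiples of `dtaMm`.
#' @param subvoxel sub-voxel refinement: minimise gamma analytically along
#'   the lattice edges of the neighbourhood (`FALSE` searches voxel centres
#'   only, which is what the brute-force oracle enumerates).
#' @return a \linkS4class{GammaParams}.
#' @export
gammaParams <- function(ddPercent = 1, dtaMm = 2, cutoff = 0.10,
                        normalization = "local", searchFactor = 3,
                        subvoxel = TRUE) {
  new("GammaParams", ddPercent = ddPercent, dtaMm = dtaMm, cutoff = cutoff,
      normalization = normalization, searchFactor = searchFactor,
      subvoxel = subvoxel)
}

#' Gamma analysis of two dose grids
#'
#' For every reference voxel above the cutoff,
#' `gamma = min over points r within the search radius of
#' sqrt((D_e(r) - D_ref)^2 / (dd * D_ref)^2 + |r|^2 / DTA^2)` with local
#' (reference-voxel dose) normalisation; a voxel passes when `gamma < 1`.
#' The search visits voxel centres in order of increasing distance with
#' early termination, then refines below voxel resolution by minimising
#' gamma analytically along the axis-aligned lattice edges of the
#' neighbourhood, where the linearly interpolated evaluated dose makes
#' gamma-squared an exact quadratic; this resolves dose gradients several
#' criterion widths per voxel steep (a distal SOBP edge) that fixed-pitch
#' sub-voxel sampling cannot. The 3-D
#' global pass rate uses the full volumetric search; per-slice 2-D rates
#' restrict the search to the slice plane, and the worst slice is reported.
#' Note the comparison is asymmetric: the reference role belongs to the dose
#' optimised on the planning image.
#'
#' @param reference the reference \linkS4class{DoseGrid} (the planning
#'   image's dose); its maximum defines the cutoff.
#' @param evaluated the evaluated \linkS4class{DoseGrid} (recalculated dose).
#' @param params a \linkS4class{GammaParams}.
#' @return a \linkS4class{GammaResult}.
#' @examples
#' d <- doseGrid(array(100, c(8, 8, 1)), spacing = 2)
#' gammaIndex(d, d)@passRate3d
#' @export
gammaIndex <- function(reference, evaluated, params = gammaParams()) {
  stopifnot(is(reference, "DoseGrid"), is(evaluated, "DoseGrid"))
  if (!identical(gridDim(reference), gridDim(evaluated)) ||
      max(abs(gridSpacing(reference) - gridSpacing(evaluated))) > 1e-9)
    stop("dose grids are not congruent")
  rv <- gridValues(reference); ev <- gridValues(evaluated)
  cutoffAbs <- params@cutoff * max(rv)
  if (all(rv < cutoffAbs))
    stop("all reference voxels lie below the low-dose cutoff")
  d <- gridDim(reference); sp <- gridSpacing(reference)
  radius <- params@searchFactor * params@dtaMm
  g3 <- .cppGammaMap(as.vector(rv), as.vector(ev), as.integer(d), sp,
                     params@ddPercent / 100, params@dtaMm, cutoffAbs,
                     radius, params@subvoxel, FALSE)
  g2 <- .cppGammaMap(as.vector(rv), as.vector(ev), as.integer(d), sp,
                     params@ddPercent / 100, params@dtaMm, cutoffAbs,
                     radius, params@subvoxel, TRUE)
  g3 <- array(g3, d); g2 <- array(g2, d)
  sliceRates <- apply(g2, 3, function(s) {
    n <- sum(!is.na(s))
    if (n == 0) NA_real_ else 100 * sum(s < 1, na.rm = TRUE) / n
  })
  worst <- if (all(is.na(sliceRates))) NA_integer_ else
    which.min(sliceRates)
  new("GammaResult",
      passRate3d = 100 * mean(g3[!is.na(g3)] < 1),
      sliceRates = sliceRates,
      worstSlice = as.integer(worst),
      worstSliceRate = if (is.na(worst)) NA_real_ else sliceRates[worst],
      gammaMap = g3)
}

setMethod("show", "GammaResult", function(object) {
  cat(sprintf(
    "GammaResult: 3-D pass %.1f%%, worst 2-D slice %.1f%% (slice %d)\n",
    object@passRate3d, object@worstSliceRate, object@worstSlice))
})

#' Cumulative DVH and summary metrics
#'
#' Metrics are computed from the voxel dose values directly (the binned
#' curve is for export only): `D_mean` (% of prescription), `D_V98%` (dose
#' covering 98% of the volume, interpolated between order statistics),
#' `V_D95%` (% of volume receiving at least 95% of prescription), `D_1cc`
#' (dose exceeded by exactly 1 cc, interpolated; structures smaller than
#' 1 cc report the maximum dose with a warning), and `V_Dthr` (% of volume
#' at or above `thresholdFrac` of prescription, the fixed-absolute-dose
#' volume metric used for organs at risk).
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask logical structure mask on the dose grid.
#' @param prescription prescription dose (default: the grid's).
#' @param thresholdFrac absolute-dose threshold for `V_Dthr`, as a fraction
#'   of prescription.
#' @param binWidth DVH curve bin width, % of prescription.
#' @return list with `metrics` (named numeric) and `curve` (data.frame
#'   `dose_pct`, `volume_pct`).
#' @examples
#' d <- doseGrid(array(100, c(10, 10, 2)), spacing = 5)
#' m <- array(TRUE, c(10, 10, 2))
#' dvhMetrics(d, m)$metrics
#' @export
dvhMetrics <- function(dose, mask, prescription = NULL,
                       thresholdFrac = 0.5, binWidth = 0.1) {
  stopifnot(is(dose, "DoseGrid"), identical(dim(mask), gridDim(dose)))
  if (!any(mask)) stop("structure mask is empty")
  if (is.null(prescription)) prescription <- dose@prescription
  dv <- gridValues(dose)[mask]
  pct <- 100 * dv / prescription
  n <- length(pct)
  voxVol <- prod(gridSpacing(dose))
  sorted <- sort(pct, decreasing = TRUE)
  k1cc <- 1000 / voxVol
  d1cc <- if (n * voxVol < 1000) {
    warning("structure smaller than 1 cc; D_1cc reported as D_max")
    sorted[1]
  } else if (k1cc <= 1) sorted[1] else
    stats::approx(seq_len(n), sorted, xout = k1cc)$y
  metrics <- c(
    d_mean = mean(pct),
    d_v98 = unname(stats::quantile(pct, 0.02, type = 7)),
    v_d95 = 100 * mean(pct >= 95),
    d_1cc = d1cc,
    v_dthr = 100 * mean(pct >= 100 * thresholdFrac))
  grid <- seq(0, max(pct) + binWidth, by = binWidth)
  curve <- data.frame(dose_pct = grid,
                      volume_pct = vapply(grid, function(g)
                        100 * mean(pct >= g), numeric(1)))
  list(metrics = metrics, curve = curve)
}

#' ROI CT-number and noise statistics
#'
#' Per-slice and pooled mean CT number of an ROI, its difference to a
#' reference ROI placed on the same tissue unaffected by artifacts, and the
#' noise (SD of CT numbers inside the ROI), over a range of consecutive
#' slices.
#'
#' @param image an \linkS4class{HUImage}.
#' @param roi,reference logical masks on the image grid.
#' @param slices slice indices to analyse (default: all slices where both
#'   masks are present).
#' @return list with `perSlice` (data.frame) and `pooled` (named numeric:
#'   `mean`, `refMean`, `difference`, `noise`).
#' @export
roiStats <- function(image, roi, reference, slices = NULL) {
  stopifnot(is(image, "HUImage"), identical(dim(roi), gridDim(image)),
            identical(dim(reference), gridDim(image)))
  present <- which(apply(roi, 3, any) & apply(reference, 3, any))
  if (is.null(slices)) slices <- present
  if (length(slices) == 0L || !all(slices %in% present))
    stop("ROI or reference mask empty on a requested slice")
  v <- gridValues(image)
  per <- do.call(rbind, lapply(slices, function(z) {
    a <- v[, , z][roi[, , z]]
    b <- v[, , z][reference[, , z]]
    data.frame(slice = z, mean = mean(a), refMean = mean(b),
               difference = mean(a) - mean(b), noise = stats::sd(a))
  }))
  a <- unlist(lapply(slices, function(z) v[, , z][roi[, , z]]))
  b <- unlist(lapply(slices, function(z) v[, , z][reference[, , z]]))
  list(perSlice = per,
       pooled = c(mean = mean(a), refMean = mean(b),
                  difference = mean(a) - mean(b), noise = stats::sd(a)))
}

#' Signed metric differences between two plans
#'
#' Tabulates `A - B` per shared metric, the comparison layout used to report
#' optimised-vs-recalculated dose statistics.
#'
#' @param a,b named numeric vectors over the same metric set.
#' @param labels column labels for the two inputs.
#' @return data.frame with columns `metric`, the two labels, and `diff`.
#' @export
comparePlans <- function(a, b, labels = c("A", "B")) {
  if (!setequal(names(a), names(b)) || is.null(names(a)))
    stop("metric sets differ")
  b <- b[names(a)]
  out <- data.frame(metric = names(a), A = unname(a), B = unname(b),
                    diff = unname(a - b))
  names(out)[2:3] <- labels
  out
}

#' Circular ROI mask on the phantom grid
#'
#' Convenience builder for ROI analyses: a disc of the given diameter at an
#' in-plane position, replicated over the requested slices.
#'
#' @param image grid-defining object (any \linkS4class{GridVolume}).
#' @param center in-plane centre (x, y) in mm.
#' @param diameter disc diameter in mm (default 12, a cursor-sized ROI).
#' @param slices slice indices carrying the ROI (default: all).
#' @return logical array on the image grid.
#' @export
discROI <- function(image, center, diameter = 12, slices = NULL) {
  d <- gridDim(image); sp <- gridSpacing(image); o <- gridOrigin(image)
  if (is.null(slices)) slices <- seq_len(d[3])
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  X <- matrix(xs, d[1], d[2]); Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  disc <- (X - center[1])^2 + (Y - center[2])^2 <= (diameter / 2)^2
  out <- array(FALSE, d)
  for (z in slices) out[, , z] <- disc
  out
}
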