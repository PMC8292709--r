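#' Analytic SOBP depth-dose model
#'
#' @param plateau plateau level (arbitrary; plans are renormalised).
#' @param falloff distal 80-20% falloff distance, mm WEPL.
#' @param buildup proximal 20-80% buildup distance, mm WEPL.
#' @param entranceRatio entrance dose as a fraction of the plateau.
#' @return a \linkS4class{SobpModel}.
#' @export
sobpModel <- function(plateau = 1, falloff = 2, buildup = 4,
                      entranceRatio = 0.3) {
  new("SobpModel", plateau = plateau, falloff = falloff, buildup = buildup,
      entranceRatio = entranceRatio)
}

#' Depth dose of a spread-out Bragg peak template
#'
#' Dose as a function of cumulative water-equivalent depth `w` for a field of
#' distal range `R` and modulation `M`: entrance level, logistic buildup to
#' the plateau at `R - M`, flat plateau on `[R - M, R]`, logistic distal
#' falloff at `R`. Logistic scale `k` relates to the 80-20% distance `d` by
#' `k = d / (2 log 4)`.
#'
#' @param w water-equivalent depth(s), mm.
#' @param R distal range, mm WEPL.
#' @param M modulation width, mm WEPL.
#' @param model a \linkS4class{SobpModel}.
#' @return dose values (plateau units).
#' @examples
#' sobpDepthDose(c(0, 50, 100, 106), R = 100, M = 40)
#' @export
sobpDepthDose <- function(w, R, M, model = sobpModel()) {
  kd <- model@falloff / (2 * log(4))
  kp <- model@buildup / (2 * log(4))
  e <- model@entranceRatio
  prox <- 1 / (1 + exp(-(w - (R - M)) / kp))
  dist <- 1 / (1 + exp((w - R) / kd))
  model@plateau * (e + (1 - e) * prox) * dist
}

# raw (unnormalised) dose of one beam on one slice, on the image grid
.beamSliceDose <- function(rlsp, beam, model, z, depthStep = 1,
                           latStep = NULL) {
  sp <- gridSpacing(rlsp); o <- gridOrigin(rlsp); d <- gridDim(rlsp)
  dir <- .beamDir(beam@angle); perp <- .beamPerp(beam@angle)
  iso <- beam@iso
  sig <- max(beam@penumbraSigma, 1e-6)
  if (is.null(latStep)) latStep <- min(beam@raySpacing, min(sp[1:2]))
  lpad <- 3 * sig + 2 * latStep
  lpos <- seq(beam@latRange[1] - lpad, beam@latRange[2] + lpad,
              by = latStep)
  smax <- 0.5 * sqrt(sum((d[1:2] * sp[1:2])^2)) + 2 * depthStep +
    sqrt(sum(iso^2))
  spos <- seq(-smax, smax, by = depthStep)
  nL <- length(lpos); nS <- length(spos)
  qx <- outer(lpos * perp[1], spos * dir[1], "+") + iso[1]
  qy <- outer(lpos * perp[2], spos * dir[2], "+") + iso[2]
  r <- sampleBilinear(gridValues(rlsp)[, , z], sp[1:2], o[1:2],
                      cbind(as.vector(qx), as.vector(qy)))
  r <- matrix(r, nL, nS)
  wepl <- (t(apply(r, 1, cumsum)) - r / 2) * depthStep
  aper <- stats::pnorm((beam@latRange[2] - lpos) / sig) -
    stats::pnorm((beam@latRange[1] - lpos) / sig)
  doseLS <- aper * sobpDepthDose(wepl, beam@range, beam@modulation, model)
  # voxel (lateral, depth) coordinates in the beam frame
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1] - iso[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2] - iso[2]
  X <- matrix(xs, d[1], d[2]); Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  lv <- X * perp[1] + Y * perp[2]
  sv <- X * dir[1] + Y * dir[2]
  vals <- sampleBilinear(doseLS, c(latStep, depthStep),
                         c(lpos[1], spos[1]), cbind(as.vector(lv),
                                                    as.vector(sv)))
  matrix(beam@weight * pmax(vals, 0), d[1], d[2])
}

.computeDoseRaw <- function(rlsp, beams, model) {
  d <- gridDim(rlsp)
  out <- array(0, d)
  for (beam in beams)
    for (z in seq_len(d[3]))
      out[, , z] <- out[, , z] + .beamSliceDose(rlsp, beam, model, z)
  out
}

# WEPL and metal/target intersections along the bundle of one candidate angle
.scanAngle <- function(rlsp, ptv, metalMask, structures, angle, raySpacing,
                       step) {
  d <- gridDim(rlsp)
  slices <- which(apply(ptv, 3, any))
  proxW <- distW <- numeric(0)
  blocked <- FALSE
  for (z in slices) {
    rays <- rayBundle(structures, ".ptv", angle, slice = z,
                      raySpacing = raySpacing, step = step)
    for (ray in rays) {
      prof <- traceWEPL(rlsp, ray)
      pts <- .rayPoints(ray, prof@depths)
      mk <- sampleBilinear(ptv[, , z] * 1, gridSpacing(rlsp)[1:2],
                           gridOrigin(rlsp)[1:2], pts) >= 0.5
      if (!any(mk)) next
      i1 <- which(mk)[1]; i2 <- max(which(mk))
      proxW <- c(proxW, prof@wepl[i1])
      distW <- c(distW, prof@wepl[i2])
      if (!is.null(metalMask) && any(metalMask)) {
        mm <- sampleBilinear(metalMask[, , z] * 1, gridSpacing(rlsp)[1:2],
                             gridOrigin(rlsp)[1:2], pts) >= 0.5
        if (any(mm & seq_along(mm) <= i2)) blocked <- TRUE
      }
    }
  }
  list(prox = proxW, dist = distW, blocked = blocked)
}

#' Plan SOBP beams on an RLSP map
#'
#' For each requested gantry angle, spans a ray bundle over the PTV's
#' beam's-eye view, traces WEPL on the planning map, and freezes a
#' \linkS4class{BeamSpec}: distal range `R` = deepest distal PTV edge (WEPL)
#' plus the distal margin, modulation `M` covering from the shallowest
#' proximal edge minus the proximal margin up to `R`, and a lateral aperture
#' of the BEV extent plus the lateral margin. Any angle whose bundle crosses
#' metal before the distal PTV edge is rejected with an error (unless
#' `force = TRUE`); with bilateral implants this leaves the
#' anterior-posterior vertical beam. The plan's normalisation is frozen at
#' planning time so the mean PTV dose on the planning map equals the
#' prescription.
#'
#' @param rlsp the planning \linkS4class{RLSPMap}.
#' @param structures a \linkS4class{StructureSet} containing the target.
#' @param ptv name of the target structure.
#' @param angles gantry angles in degrees (90 = anterior-posterior).
#' @param prescription prescription dose (reported doses are % of it).
#' @param raySpacing lateral ray spacing, mm.
#' @param lateralMargin,distalMargin,proximalMargin field margins, mm.
#' @param penumbraSigma lateral penumbra sigma, mm.
#' @param model a \linkS4class{SobpModel}.
#' @param metal name of the metal structure used for the beam-blocking test
#'   (`NULL` to skip).
#' @param force plan through metal instead of rejecting blocked angles.
#' @param step WEPL tracing step, mm.
#' @return a \linkS4class{TreatmentPlan}.
#' @export
planBeams <- function(rlsp, structures, ptv, angles, prescription = 100,
                      raySpacing = 2, lateralMargin = 5, distalMargin = 3,
                      proximalMargin = 3, penumbraSigma = 2,
                      model = sobpModel(), metal = "metal", force = FALSE,
                      step = 0.5) {
  stopifnot(is(rlsp, "RLSPMap"), is(structures, "StructureSet"),
            length(angles) >= 1)
  ptvMask <- structureMask(structures, ptv)
  if (!any(ptvMask)) stop("PTV '", ptv, "' is empty")
  metalMask <- if (!is.null(metal) && metal %in% structureNames(structures))
    structureMask(structures, metal) else NULL
  # temporary structure alias so rayBundle can span the target
  structures@masks$.ptv <- ptvMask
  d <- gridDim(rlsp); sp <- gridSpacing(rlsp); o <- gridOrigin(rlsp)
  idx <- which(ptvMask, arr.ind = TRUE)
  iso <- c(o[1] + (mean(idx[, 1]) - 1) * sp[1],
           o[2] + (mean(idx[, 2]) - 1) * sp[2])
  beams <- list(); blockedAngles <- numeric(0)
  for (a in angles) {
    scan <- .scanAngle(rlsp, ptvMask, metalMask, structures, a, raySpacing,
                       step)
    if (length(scan$dist) == 0L)
      stop("no ray of angle ", a, " crosses the PTV")
    if (scan$blocked && !force) {
      blockedAngles <- c(blockedAngles, a)
      next
    }
    R <- max(scan$dist) + distalMargin
    M <- min(R - 1e-6, R - (min(scan$prox) - proximalMargin))
    perp <- .beamPerp(a)
    px <- o[1] + (idx[, 1] - 1) * sp[1] - iso[1]
    py <- o[2] + (idx[, 2] - 1) * sp[2] - iso[2]
    lat <- px * perp[1] + py * perp[2]
    beams[[length(beams) + 1L]] <-
      new("BeamSpec", angle = a, raySpacing = raySpacing, range = R,
          modulation = M, lateralMargin = lateralMargin,
          penumbraSigma = penumbraSigma, weight = 1 / length(angles),
          latRange = c(min(lat) - lateralMargin, max(lat) + lateralMargin),
          iso = iso)
  }
  if (length(blockedAngles)) {
    msg <- paste0("beam angle(s) ", paste(blockedAngles, collapse = ", "),
                  " blocked by metal before the distal PTV edge")
    if (length(beams) == 0L)
      msg <- paste0(msg, "; with bilateral implants only the ",
                    "anterior-posterior vertical beam (90 degrees) avoids ",
                    "the implants")
    stop(msg)
  }
  plan <- new("TreatmentPlan", beams = beams, prescription = prescription,
              scale = 1, model = model, gridDim = as.integer(d))
  raw <- .computeDoseRaw(rlsp, beams, model)
  m <- mean(raw[ptvMask])
  if (m <= 0) stop("planning produced zero dose in the PTV")
  plan@scale <- prescription / m
  plan
}

#' Compute dose for a frozen plan
#'
#' Deposits each beam's SOBP depth-dose as a function of cumulative WEPL on
#' the given RLSP map, applies the Gaussian-penumbra lateral aperture, sums
#' beams and applies the plan's frozen normalisation. Calling it on the
#' planning map reproduces the planning dose; [recalculateDose()] is the
#' same computation on another (congruent) map with all beam parameters and
#' the normalisation unchanged, mirroring the plan-on-A / recalculate-on-B
#' workflow.
#'
#' @param rlsp an \linkS4class{RLSPMap}.
#' @param plan a \linkS4class{TreatmentPlan}.
#' @return a \linkS4class{DoseGrid} (values in % of prescription when
#'   `prescription = 100`).
#' @export
computeDose <- function(rlsp, plan) {
  stopifnot(is(rlsp, "RLSPMap"), is(plan, "TreatmentPlan"))
  if (!identical(as.integer(gridDim(rlsp)), plan@gridDim))
    stop("RLSP grid is not congruent with the planning grid")
  raw <- .computeDoseRaw(rlsp, plan@beams, plan@model)
  doseGrid(raw * plan@scale, gridSpacing(rlsp), gridOrigin(rlsp),
           prescription = plan@prescription)
}

#' @rdname computeDose
#' @export
recalculateDose <- function(plan, rlsp) {
  computeDose(rlsp, plan)
}

setMethod("show", "TreatmentPlan", function(object) {
  cat(sprintf("TreatmentPlan: %d beam(s), prescription %g\n",
              length(object@beams), object@prescription))
  for (b in object@beams)
    cat(sprintf(
      "  angle %5.1f deg  R %.1f mm  M %.1f mm  aperture [%.1f, %.1f] mm\n",
      b@angle, b@range, b@modulation, b@latRange[1], b@latRange[2]))
})
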