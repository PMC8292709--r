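#' Construct a sampled ray
#'
#' @param start in-plane start point (x, y) in mm.
#' @param direction in-plane direction (normalised internally).
#' @param length total physical length in mm.
#' @param step sampling step in mm (default 0.5: sub-voxel accuracy at
#'   negligible cost).
#' @param slice slice index the ray lives in.
#' @return a \linkS4class{RayPath}.
#' @export
rayPath <- function(start, direction, length, step = 0.5, slice = 1L) {
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  stopifnot(n > 0)
  new("RayPath", start = as.numeric(start), direction = direction / n,
      length = as.numeric(length), step = as.numeric(step),
      slice = as.integer(slice))
}

# depths sampled along a ray: 0, step, ..., floor(length/step) * step
.rayDepths <- function(ray) {
  (0:floor(ray@length / ray@step)) * ray@step
}

.rayPoints <- function(ray, depths) {
  cbind(ray@start[1] + depths * ray@direction[1],
        ray@start[2] + depths * ray@direction[2])
}

.sampleAlongRay <- function(vol, ray, outside = 0) {
  d <- gridDim(vol); sp <- gridSpacing(vol); o <- gridOrigin(vol)
  z <- ray@slice
  if (z < 1 || z > d[3]) stop("ray slice outside the grid")
  depths <- .rayDepths(ray)
  pts <- .rayPoints(ray, depths)
  xmax <- o[1] + (d[1] - 1) * sp[1]
  ymax <- o[2] + (d[2] - 1) * sp[2]
  inGrid <- pts[, 1] >= o[1] - sp[1] / 2 & pts[, 1] <= xmax + sp[1] / 2 &
            pts[, 2] >= o[2] - sp[2] / 2 & pts[, 2] <= ymax + sp[2] / 2
  if (!any(inGrid)) stop("ray misses the grid entirely")
  mids <- .rayPoints(ray, depths[-1] - ray@step / 2)
  slice <- gridValues(vol)[, , z]
  list(depths = depths,
       at = sampleBilinear(slice, sp[1:2], o[1:2], pts, outside),
       mid = sampleBilinear(slice, sp[1:2], o[1:2], mids, outside))
}

#' Trace water-equivalent path length along a ray
#'
#' Accumulates WEPL = physical length x RLSP along the ray: the RLSP map is
#' sampled by bilinear interpolation at the midpoint of each `step`-long
#' interval and the cumulative sum of `step * RLSP` gives the
#' water-equivalent depth at each sampled depth. Samples outside the grid
#' contribute RLSP 0 (air). A ray that never enters the grid is an error.
#'
#' @param rlsp an \linkS4class{RLSPMap}.
#' @param ray a \linkS4class{RayPath}.
#' @param tag source-image tag carried in the profile (e.g. `"fbp"`).
#' @return a \linkS4class{WEPLProfile}.
#' @examples
#' m <- rlspMap(array(1, c(50, 50, 1)), spacing = c(4, 4, 4))
#' p <- traceWEPL(m, rayPath(c(-50, 0), c(1, 0), 100))
#' max(p@wepl)  # 100 mm of water for 100 mm at RLSP 1
#' @export
traceWEPL <- function(rlsp, ray, tag = "") {
  stopifnot(is(rlsp, "RLSPMap"), is(ray, "RayPath"))
  s <- .sampleAlongRay(rlsp, ray, outside = 0)
  wepl <- c(0, cumsum(s$mid * ray@step))
  new("WEPLProfile", depths = s$depths, rlsp = s$at, wepl = wepl,
      ray = ray, tag = tag)
}

#' CT-number line profile along a ray
#'
#' Samples HU at exactly the depths used by [traceWEPL()] on the same ray, so
#' CT-number and WEPL-deviation profiles overlay. Outside-grid samples return
#' -1000 (air).
#'
#' @param image an \linkS4class{HUImage}.
#' @param ray a \linkS4class{RayPath}.
#' @return data.frame with columns `depth_mm` and `hu`.
#' @export
lineProfile <- function(image, ray) {
  stopifnot(is(image, "HUImage"), is(ray, "RayPath"))
  s <- .sampleAlongRay(image, ray, outside = -1000)
  data.frame(depth_mm = s$depths, hu = s$at)
}

.sameRay <- function(a, b, tol = 1e-6) {
  max(abs(a@start - b@start)) < tol &&
    max(abs(a@direction - b@direction)) < tol &&
    abs(a@length - b@length) < tol && abs(a@step - b@step) < tol &&
    a@slice == b@slice
}

#' WEPL deviation between two profiles on the same ray
#'
#' Per-depth difference `test - gt` (mm), with the signed extremum (largest
#' magnitude, sign preserved) and the depth at which it occurs. Profiles must
#' come from the identical ray and sampling.
#'
#' @param test profile from the image under test (FBP or MAR-corrected).
#' @param gt profile from the ground-truth image.
#' @return a \linkS4class{DeltaWEPL}.
#' @export
deltaWEPL <- function(test, gt) {
  stopifnot(is(test, "WEPLProfile"), is(gt, "WEPLProfile"))
  if (!.sameRay(test@ray, gt@ray))
    stop("profiles were sampled on different rays")
  delta <- test@wepl - gt@wepl
  i <- which.max(abs(delta))
  new("DeltaWEPL", depths = test@depths, delta = delta,
      extremum = delta[i], extremumDepth = test@depths[i])
}

setMethod("show", "DeltaWEPL", function(object) {
  cat(sprintf("DeltaWEPL: extremum %+.2f mm at depth %.1f mm (%d samples)\n",
              object@extremum, object@extremumDepth, length(object@delta)))
})
setMethod("show", "WEPLProfile", function(object) {
  cat(sprintf("WEPLProfile%s: %d samples, total WEPL %.1f mm\n",
              if (nzchar(object@tag)) paste0(" [", object@tag, "]") else "",
              length(object@depths), max(object@wepl)))
})

# in-slice beam direction for a gantry angle in degrees:
# 90 degrees = anterior-posterior (vertical, travelling -y)
.beamDir <- function(angleDeg) {
  a <- angleDeg * pi / 180
  c(cos(a), -sin(a))
}

.beamPerp <- function(angleDeg) {
  a <- angleDeg * pi / 180
  c(sin(a), cos(a))
}

# entry/exit parameters of the line p + s*d through the grid bounding box
.clipToGrid <- function(p, d, sp, o, dims) {
  lo <- o[1:2] - sp[1:2] / 2
  hi <- o[1:2] + (dims[1:2] - 0.5) * sp[1:2]
  s0 <- -Inf; s1 <- Inf
  for (ax in 1:2) {
    if (abs(d[ax]) < 1e-12) {
      if (p[ax] < lo[ax] || p[ax] > hi[ax]) return(NULL)
    } else {
      t1 <- (lo[ax] - p[ax]) / d[ax]
      t2 <- (hi[ax] - p[ax]) / d[ax]
      s0 <- max(s0, min(t1, t2)); s1 <- min(s1, max(t1, t2))
    }
  }
  if (s0 >= s1) return(NULL)
  c(s0, s1)
}

#' Beam's-eye-view ray bundle over a structure
#'
#' One ray per lateral sampling position across the structure's
#' beam's-eye-view extent (plus `margin` on both sides), each entering at the
#' grid boundary and travelling along the beam direction. Used for WEPL
#' deviation summaries and by the dose engine.
#'
#' @param structures a \linkS4class{StructureSet}.
#' @param name structure whose BEV extent defines the bundle.
#' @param angle gantry angle in degrees (90 = anterior-posterior).
#' @param slice slice index (default: middle slice).
#' @param raySpacing lateral spacing between rays, mm.
#' @param margin lateral margin beyond the mask extent, mm.
#' @param step sampling step of each ray, mm.
#' @return list of \linkS4class{RayPath}.
#' @export
rayBundle <- function(structures, name, angle, slice = NULL, raySpacing = 2,
                      margin = 0, step = 0.5) {
  stopifnot(is(structures, "StructureSet"))
  mask <- structureMask(structures, name)
  d <- dim(mask); sp <- structures@spacing; o <- structures@origin
  if (is.null(slice)) slice <- as.integer(ceiling(d[3] / 2))
  m <- mask[, , slice]
  if (!any(m)) stop("structure '", name, "' is empty on slice ", slice)
  idx <- which(m, arr.ind = TRUE)
  px <- o[1] + (idx[, 1] - 1) * sp[1]
  py <- o[2] + (idx[, 2] - 1) * sp[2]
  dir <- .beamDir(angle); perp <- .beamPerp(angle)
  ctr <- o[1:2] + (d[1:2] - 1) / 2 * sp[1:2]
  lat <- (px - ctr[1]) * perp[1] + (py - ctr[2]) * perp[2]
  lmin <- min(lat) - margin; lmax <- max(lat) + margin
  nRays <- max(1L, ceiling((lmax - lmin) / raySpacing) + 1L)
  lpos <- if (nRays == 1L) (lmin + lmax) / 2 else
    seq(lmin, lmax, length.out = nRays)
  rays <- list()
  for (l in lpos) {
    p <- ctr + l * perp
    ss <- .clipToGrid(p, dir, sp, o, d)
    if (is.null(ss)) next
    rays[[length(rays) + 1L]] <-
      rayPath(p + ss[1] * dir, dir, ss[2] - ss[1], step, slice)
  }
  if (length(rays) == 0L) stop("no ray of the bundle crosses the grid")
  rays
}

#' Tabulate FBP/MAR/GT profiles along one ray
#'
#' Convenience assembly of the comparison profile along a single ray: CT
#' numbers of the three images, cumulative WEPL of the three RLSP maps, and
#' the WEPL deviations of FBP and the corrected image against ground truth.
#'
#' @param ray a \linkS4class{RayPath}.
#' @param gt,fbpImg,imarImg the three \linkS4class{HUImage}s.
#' @param gtR,fbpR,imarR the corresponding \linkS4class{RLSPMap}s.
#' @return data.frame with columns `depth_mm`, `hu_fbp`, `hu_imar`, `hu_gt`,
#'   `wepl_fbp`, `wepl_imar`, `wepl_gt`, `dwepl_fbp`, `dwepl_imar`.
#' @export
profileTable <- function(ray, gt, fbpImg, imarImg, gtR, fbpR, imarR) {
  pg <- traceWEPL(gtR, ray, "gt")
  pf <- traceWEPL(fbpR, ray, "fbp")
  pi <- traceWEPL(imarR, ray, "imar")
  data.frame(
    depth_mm = pg@depths,
    hu_fbp = lineProfile(fbpImg, ray)$hu,
    hu_imar = lineProfile(imarImg, ray)$hu,
    hu_gt = lineProfile(gt, ray)$hu,
    wepl_fbp = pf@wepl, wepl_imar = pi@wepl, wepl_gt = pg@wepl,
    dwepl_fbp = pf@wepl - pg@wepl, dwepl_imar = pi@wepl - pg@wepl)
}
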