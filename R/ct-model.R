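#' HU to linear attenuation conversion
#'
#' Standard linear HU definition: `mu = muWater * (1 + HU/1000)`, clamped at
#' 0 from below. `muToHu` is the inverse (no clamp).
#'
#' @param hu numeric array of CT numbers.
#' @param muWater linear attenuation of water per mm (default 0.019, a
#'   120 kVp-like value).
#' @return attenuation array (per mm), or HU array for `muToHu`.
#' @examples
#' huToMu(c(-1000, 0, 1000))
#' @export
huToMu <- function(hu, muWater = 0.019) {
  stopifnot(muWater > 0)
  pmax(muWater * (1 + hu / 1000), 0)
}

#' @rdname huToMu
#' @param mu attenuation array (per mm).
#' @export
muToHu <- function(mu, muWater = 0.019) {
  1000 * (mu / muWater - 1)
}

#' Parallel-beam forward projection
#'
#' Projects every slice of an image onto a parallel-beam sinogram: each
#' sample is the mm-weighted line integral along the corresponding ray
#' (midpoint quadrature at `step` mm with bilinear interpolation). View
#' angles are equispaced over [0, pi). HU input is converted to linear
#' attenuation first; `input = "raw"` integrates the voxel values as they
#' are (used e.g. to project a metal mask into its sinogram trace).
#'
#' @param image an \linkS4class{HUImage} (or any \linkS4class{GridVolume}
#'   with `input = "raw"`).
#' @param nAngles number of view angles over 180 degrees (>= 2).
#' @param binSpacing detector bin spacing in mm (default: the smaller
#'   in-plane voxel spacing).
#' @param nBins detector bin count; the default covers the grid diagonal.
#'   A span smaller than the diagonal is an error (truncated projections).
#' @param muWater water attenuation per mm for the HU conversion.
#' @param step ray sampling step in mm (default `binSpacing / 2`).
#' @param input `"hu"` (convert to attenuation) or `"raw"`.
#' @return a \linkS4class{Sinogram}.
#' @examples
#' img <- huImage(matrix(0, 32, 32), spacing = 4)
#' forwardProject(img, nAngles = 12)
#' @export
forwardProject <- function(image, nAngles = 360, binSpacing = NULL,
                           nBins = NULL, muWater = 0.019, step = NULL,
                           input = c("hu", "raw")) {
  stopifnot(is(image, "GridVolume"), nAngles >= 2)
  input <- match.arg(input)
  d <- gridDim(image); sp <- gridSpacing(image)
  if (is.null(binSpacing)) binSpacing <- min(sp[1:2])
  diag <- sqrt(sum((d[1:2] * sp[1:2])^2))
  if (is.null(nBins)) nBins <- as.integer(ceiling(diag / binSpacing) + 4L)
  if (nBins * binSpacing < diag)
    stop("detector span (", nBins * binSpacing,
         " mm) does not cover the grid diagonal (", round(diag, 1), " mm)")
  if (is.null(step)) step <- binSpacing / 2
  angles <- (seq_len(nAngles) - 1) * pi / nAngles
  vol <- gridValues(image)
  if (input == "hu") vol <- huToMu(vol, muWater)
  sino <- array(0, c(nBins, nAngles, d[3]))
  for (z in seq_len(d[3]))
    sino[, , z] <- .cppForwardProject(vol[, , z], sp[1:2], angles,
                                      as.integer(nBins), binSpacing, step)
  new("Sinogram", values = sino, angles = angles, binSpacing = binSpacing,
      metalTrace = array(FALSE, dim(sino)), imgDim = as.integer(d),
      imgSpacing = sp, imgOrigin = gridOrigin(image), muWater = muWater)
}

#' Mark the metal trace of a sinogram
#'
#' The metal trace is the set of sinogram samples whose rays intersect the
#' segmented metal; it is obtained by forward-projecting the image-domain
#' metal mask and thresholding the path length through metal above (close to)
#' zero.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param metalMask logical array on the sinogram's image grid.
#' @param tol minimum in-metal path length (mm) for a sample to count.
#' @return the sinogram with its `metalTrace` slot filled.
#' @export
markMetalTrace <- function(sino, metalMask, tol = 0.01) {
  stopifnot(is(sino, "Sinogram"),
            identical(dim(metalMask), as.integer(sino@imgDim)))
  maskImg <- huImage(array(as.numeric(metalMask), dim(metalMask)),
                     sino@imgSpacing, sino@imgOrigin)
  proj <- forwardProject(maskImg, nAngles = length(sino@angles),
                         binSpacing = sino@binSpacing,
                         nBins = dim(sino@values)[1],
                         muWater = sino@muWater, input = "raw")
  sino@metalTrace <- proj@values > tol
  sino
}

#' Corrupt a sinogram with metal-induced physics
#'
#' Applies, in order: (1) beam hardening as a quadratic penalty on the
#' metal-only line integral, `p' = p - beta * pMetal^2`; (2) Poisson counting
#' noise on `n0 * exp(-p')`; (3) a detector floor clamp at `epsilon` counts
#' followed by log conversion back to line integrals. With `beta = 0` and
#' `n0 = Inf` the input is returned bit-exactly. Together the two mechanisms
#' produce the characteristic dark bands between implants and noise streaks
#' through the metal shadow that the MAR stage corrects.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param beta beam-hardening strength (unitless, >= 0).
#' @param n0 incident photon count per ray (counts; `Inf` disables noise).
#' @param epsilon detector floor in counts (> 0).
#' @param seed integer seed for the Poisson draw.
#' @param metalSino \linkS4class{Sinogram} of metal-only line integrals
#'   (required when `beta > 0`); obtain it by forward-projecting the
#'   metal-only attenuation.
#' @return the corrupted \linkS4class{Sinogram}.
#' @export
corruptSinogram <- function(sino, beta = 0, n0 = Inf, epsilon = 0.5,
                            seed = 1, metalSino = NULL) {
  stopifnot(is(sino, "Sinogram"), beta >= 0, n0 > 0, epsilon > 0)
  if (beta == 0 && is.infinite(n0)) return(sino)
  p <- sino@values
  if (beta > 0) {
    if (is.null(metalSino))
      stop("beta > 0 requires 'metalSino' (metal-only line integrals)")
    stopifnot(identical(dim(metalSino@values), dim(p)))
    p <- p - beta * metalSino@values^2
  }
  if (is.finite(n0)) {
    counts <- .withSeed(seed, stats::rpois(length(p), n0 * exp(-p)))
    counts <- pmax(counts, epsilon)
    p <- array(log(n0 / counts), dim(p))
  }
  sino@values <- p
  sino
}

# frequency response of the band-limited ramp filter (Kak & Slaney kernel),
# optionally Hann-apodized, on a cyclic grid of length L
.rampResponse <- function(L, binSpacing, filter) {
  n <- c(0:(L / 2), -(L / 2 - 1):-1)
  h <- numeric(L)
  h[n == 0] <- 1 / (4 * binSpacing^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * binSpacing)^2
  H <- Re(stats::fft(h))
  if (filter == "hann") {
    k <- c(0:(L / 2), (L / 2 - 1):1)
    H <- H * 0.5 * (1 + cos(2 * pi * k / L))
  }
  H
}

#' Filtered back projection
#'
#' Reconstructs an HU image from a parallel-beam sinogram: ramp filtering of
#' each view (band-limited discrete ramp kernel, optionally Hann-apodized to
#' temper edge ringing), pixel-driven back projection, and conversion from
#' attenuation back to HU.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param filter `"hann"` (default) or `"ramp"`.
#' @return an \linkS4class{HUImage} on the sinogram's source grid.
#' @export
fbp <- function(sino, filter = c("hann", "ramp")) {
  stopifnot(is(sino, "Sinogram"))
  filter <- match.arg(filter)
  d <- dim(sino@values)
  nBins <- d[1]
  L <- 2^ceiling(log2(2 * nBins))
  H <- .rampResponse(L, sino@binSpacing, filter)
  dims <- sino@imgDim
  out <- array(0, dims)
  for (z in seq_len(d[3])) {
    p <- sino@values[, , z]
    pad <- matrix(0, L, d[2])
    pad[seq_len(nBins), ] <- p
    fq <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / L *
      sino@binSpacing
    mu <- .cppBackProject(fq[seq_len(nBins), , drop = FALSE], sino@angles,
                          sino@binSpacing, dims[1], dims[2],
                          sino@imgSpacing[1:2])
    out[, , z] <- muToHu(mu, sino@muWater)
  }
  huImage(out, sino@imgSpacing, sino@imgOrigin)
}
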