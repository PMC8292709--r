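# shared fixtures; expensive end-to-end objects are built once per test run
.fixtures <- new.env(parent = emptyenv())

smallDim <- c(64, 64, 2)
smallSpacing <- c(8, 8, 8)

smallPhantom <- function(cfg = "none", noise = FALSE, seed = 1) {
  buildPhantom(defaultPhantom(cfg, dim = smallDim, spacing = smallSpacing),
               defaultMaterials(noise = noise), seed = seed)
}

# mid-resolution bilateral scenario with the full corruption + MAR chain,
# plus the matching implant-free reference reconstruction
bilateralChain <- function() {
  if (!is.null(.fixtures$bilat)) return(.fixtures$bilat)
  dm <- c(128, 128, 2); sp <- c(4, 4, 4)
  nAng <- 180
  gt <- buildPhantom(defaultPhantom("none", dim = dm, spacing = sp),
                     defaultMaterials(), seed = 2)
  ph <- buildPhantom(defaultPhantom("bilateral", dim = dm, spacing = sp),
                     defaultMaterials(), seed = 2)
  gtSino <- corruptSinogram(forwardProject(gt$image, nAngles = nAng),
                            beta = 0, n0 = 1e7, epsilon = 5, seed = 11)
  gtImg <- fbp(gtSino)
  sino <- forwardProject(ph$image, nAngles = nAng)
  mu <- huToMu(gridValues(ph$image)) * structureMask(ph$structures, "metal")
  metalSino <- forwardProject(huImage(mu, gridSpacing(ph$image),
                                      gridOrigin(ph$image)),
                              nAngles = nAng, input = "raw")
  corrupted <- corruptSinogram(sino, beta = 0.01, n0 = 1e7, epsilon = 5,
                               seed = 3, metalSino = metalSino)
  fbpImg <- fbp(corrupted)
  imarImg <- imar(corrupted)
  curve <- defaultCalibration()
  .fixtures$bilat <- list(
    gt = gt, ph = ph, sino = sino, corrupted = corrupted,
    metalSino = metalSino, gtImg = gtImg, fbpImg = fbpImg,
    imarImg = imarImg, gtR = applyCalibration(curve, gtImg),
    fbpR = applyCalibration(curve, fbpImg),
    imarR = applyCalibration(curve, imarImg))
  .fixtures$bilat
}

# voxels further than k voxels from any in-plane material boundary
interiorMask <- function(lab, k = 2) {
  edge <- array(FALSE, dim(lab))
  for (di in -k:k) for (dj in -k:k) {
    ii <- pmin(pmax(seq_len(dim(lab)[1]) + di, 1), dim(lab)[1])
    jj <- pmin(pmax(seq_len(dim(lab)[2]) + dj, 1), dim(lab)[2])
    edge <- edge | (lab[ii, jj, , drop = FALSE] != lab)
  }
  !edge
}

# brute-force gamma oracle: exhaustive voxel-centre search, no early exit
gammaOracle <- function(ref, ev, spacing, ddFrac, dta, cutoffAbs, radius) {
  d <- dim(ref)
  out <- array(NA_real_, d)
  coords <- function(i) (i - 1) * spacing
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    D <- ref[i, j, k]
    if (D < cutoffAbs) next
    best <- Inf
    for (kk in seq_len(d[3])) for (jj in seq_len(d[2]))
      for (ii in seq_len(d[1])) {
        dr2 <- sum(((c(ii, jj, kk) - c(i, j, k)) * spacing)^2)
        if (dr2 > radius^2) next
        g2 <- dr2 / dta^2 + (ev[ii, jj, kk] - D)^2 / (ddFrac * D)^2
        if (g2 < best) best <- g2
      }
    out[i, j, k] <- sqrt(best)
  }
  out
}
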