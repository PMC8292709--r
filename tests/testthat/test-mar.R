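test_that("metal segmentation thresholds correctly", {
  v <- array(40, c(16, 16, 1))
  v[8, 8, 1] <- 8000
  img <- huImage(v, spacing = 4)
  m <- segmentMetal(img, 3000)
  expect_equal(sum(m), 1)
  expect_true(m[8, 8, 1])
  soft <- huImage(array(40, c(16, 16, 1)), spacing = 4)
  expect_warning(m2 <- segmentMetal(soft, 3000), "no voxel")
  expect_equal(sum(m2), 0)
})

test_that("bilateral implants segment into two components", {
  fx <- bilateralChain()
  m <- segmentMetal(fx$fbpImg, 3000)
  lab <- EBImage::bwlabel(m[, , 1])
  expect_equal(max(lab), 2)
})

test_that("the prior replaces tissue classes and caps below metal", {
  flat <- huImage(array(40, c(16, 16, 1)), spacing = 4)
  p <- buildPrior(flat, array(FALSE, c(16, 16, 1)), marParams())
  expect_equal(gridValues(p), array(40, c(16, 16, 1)))

  ph <- smallPhantom("unilateral", noise = FALSE)
  metal <- structureMask(ph$structures, "metal")
  prior <- buildPrior(ph$image, metal, marParams())
  pv <- gridValues(prior)
  expect_true(all(pv < 3000))
  expect_true(all(pv[metal] == 40))
  lab <- gridValues(ph$label)
  mats <- defaultMaterials(noise = FALSE)
  # air-class voxels -> air value, soft-class -> soft value, bone kept
  expect_true(all(pv[lab == which(mats$material == "air")] == -1000))
  expect_true(all(pv[lab == which(mats$material == "soft_tissue")] == 40))
  boneId <- which(mats$material == "bone_cortical")
  expect_true(all(pv[lab == boneId] == 1200))
})

test_that("NMAR with an empty metal trace is exactly FBP", {
  ph <- smallPhantom("none", noise = TRUE)
  sino <- forwardProject(ph$image, nAngles = 24)
  prior <- buildPrior(fbp(sino), array(FALSE, gridDim(ph$image)),
                      marParams())
  expect_identical(gridValues(nmar(sino, prior)),
                   gridValues(fbp(sino)))
})

test_that("NMAR with the exact ground-truth prior restores the image", {
  # noiseless corrupted acquisition of the implant phantom, in-painted
  # against the implant-free truth as prior: the normalized trace is flat,
  # so the output matches the implant-free reconstruction closely
  dm <- c(128, 128, 1); sp <- c(4, 4, 4)
  gt <- buildPhantom(defaultPhantom("none", dim = dm, spacing = sp),
                     defaultMaterials(noise = FALSE), seed = 1)
  ph <- buildPhantom(defaultPhantom("bilateral", dim = dm, spacing = sp),
                     defaultMaterials(noise = FALSE), seed = 1)
  nAng <- 180
  sino <- forwardProject(ph$image, nAngles = nAng)
  mu <- huToMu(gridValues(ph$image)) * structureMask(ph$structures, "metal")
  ms <- forwardProject(huImage(mu, sp, gridOrigin(ph$image)),
                       nAngles = nAng, input = "raw")
  corrupted <- corruptSinogram(sino, beta = 0.01, n0 = Inf, metalSino = ms)
  corrupted <- markMetalTrace(corrupted,
                              structureMask(ph$structures, "metal"))
  out <- nmar(corrupted, gt$image)
  ref <- fbp(forwardProject(gt$image, nAngles = nAng))
  body <- structureMask(ph$structures, "body")
  err <- gridValues(out)[body] - gridValues(ref)[body]
  expect_lt(sqrt(mean(err^2)), 5)
})

test_that("NMAR pulls the dark inter-implant band toward ground truth", {
  fx <- bilateralChain()
  mask <- segmentMetal(fx$fbpImg, 3000)
  sino <- markMetalTrace(fx$corrupted, mask)
  prior <- buildPrior(liPrecorrect(sino), mask, marParams())
  out <- nmar(sino, prior)
  band <- discROI(fx$fbpImg, c(0, -12), 30)
  gtMean <- mean(gridValues(fx$gtImg)[band])
  expect_lt(abs(mean(gridValues(out)[band]) - gtMean),
            abs(mean(gridValues(fx$fbpImg)[band]) - gtMean))
})

test_that("FSMAR is the identity when both inputs agree", {
  ph <- smallPhantom("unilateral", noise = TRUE)
  metal <- structureMask(ph$structures, "metal")
  out <- fsmar(ph$image, ph$image, metal)
  expect_equal(gridValues(out), gridValues(ph$image), tolerance = 1e-10)
  # constant images stay constant (DC preservation)
  const <- huImage(array(120, c(32, 32, 1)), spacing = 4)
  out2 <- fsmar(const, const, array(FALSE, c(32, 32, 1)))
  expect_equal(gridValues(out2), array(120, c(32, 32, 1)),
               tolerance = 1e-10)
})

test_that("FSMAR restores sharp edges far from metal", {
  n <- 64
  v <- matrix(0, n, n); v[, 33:n] <- 400  # step edge at the grid centre
  original <- huImage(v, spacing = 1)
  blurred <- huImage(EBImage::gblur(v, sigma = 4), spacing = 1)
  metal <- array(FALSE, c(n, n, 1)); metal[4, 4, 1] <- TRUE  # far corner
  out <- fsmar(original, blurred, metal, sigma = 4)
  # edge sharpness = jump between the two columns flanking the step, far
  # from the metal corner; the recombination recovers it within 10%
  sharp <- function(img) {
    m <- gridValues(img)[, , 1]
    mean(m[40:60, 33] - m[40:60, 32])
  }
  expect_gt(sharp(out), 0.9 * sharp(original))
  expect_lt(sharp(blurred), 0.2 * sharp(original))
})

test_that("one iMAR iteration equals one NMAR + FSMAR pass", {
  fx <- bilateralChain()
  p1 <- marParams(nIter = 1)
  got <- imar(fx$corrupted, p1)
  mask <- segmentMetal(fx$fbpImg, p1@metalThreshold)
  sino <- markMetalTrace(fx$corrupted, mask)
  prior <- buildPrior(liPrecorrect(sino), mask, p1)
  manual <- fsmar(fx$fbpImg, nmar(sino, prior), mask, p1@sigma,
                  p1@weightBand)
  mv <- gridValues(manual)
  mv[mask] <- gridValues(fx$fbpImg)[mask]  # metal reinsertion
  expect_equal(gridValues(got), mv, tolerance = 1e-12)
})

test_that("iMAR on a metal-free acquisition returns the FBP image", {
  ph <- smallPhantom("none", noise = TRUE)
  sino <- forwardProject(ph$image, nAngles = 24)
  expect_warning(out <- imar(sino), "no voxel")
  expect_identical(gridValues(out), gridValues(fbp(sino)))
})

test_that("iMAR reduces the inter-implant WEPL deviation versus FBP", {
  fx <- bilateralChain()
  rays <- rayBundle(fx$ph$structures, "ptv_prostate", 90)
  worst <- function(testR) {
    max(vapply(rays, function(r)
      abs(deltaWEPL(traceWEPL(testR, r), traceWEPL(fx$gtR, r))@extremum),
      numeric(1)))
  }
  expect_lt(worst(fx$imarR), worst(fx$fbpR))
})

test_that("iMAR leaves distant soft tissue and periprosthetic bone stable", {
  fx <- bilateralChain()
  lab <- gridValues(fx$ph$label)
  mats <- defaultMaterials()
  softId <- which(mats$material == "soft_tissue")
  sp <- gridSpacing(fx$fbpImg)
  dist <- marbench:::.metalDistance(
    structureMask(fx$ph$structures, "metal"), sp)
  d <- gridDim(fx$fbpImg)
  ys <- gridOrigin(fx$fbpImg)[2] + (seq_len(d[2]) - 1) * sp[2]
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  quiet <- (lab == softId) & dist > 50 & abs(Y + 10) > 45
  mad <- mean(abs(gridValues(fx$imarImg)[quiet] -
                    gridValues(fx$fbpImg)[quiet]))
  expect_lt(mad, 20)
  # periprosthetic bone error does not need to vanish, but must not worsen
  boneNear <- (lab %in% which(mats$material %in%
                                c("bone_cortical", "bone_trabecular"))) &
    dist < 15 & dist > 0
  gtv <- gridValues(fx$gtImg)
  errF <- mean(abs(gridValues(fx$fbpImg)[boneNear] - gtv[boneNear]))
  errI <- mean(abs(gridValues(fx$imarImg)[boneNear] - gtv[boneNear]))
  expect_lte(errI, errF * 1.05)
})

test_that("re-correcting an already corrected image is stable", {
  fx <- bilateralChain()
  # re-project the corrected image and run the chain again: the second
  # correction must be much smaller than the first (no oscillation)
  sino2 <- forwardProject(fx$imarImg, nAngles = length(fx$sino@angles))
  again <- imar(sino2, marParams())
  firstPass <- mean(abs(gridValues(fx$imarImg) - gridValues(fx$fbpImg)))
  secondPass <- mean(abs(gridValues(again) - gridValues(fx$imarImg)))
  expect_lt(secondPass, firstPass)
})
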