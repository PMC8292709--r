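test_that("HU to attenuation conversion follows the linear HU definition", {
  expect_equal(huToMu(0), 0.019)
  expect_equal(huToMu(-1000), 0)
  expect_equal(huToMu(1000), 2 * 0.019)
  expect_equal(huToMu(-2000), 0)  # clamped at zero
  expect_equal(muToHu(huToMu(c(-500, 40, 1200))), c(-500, 40, 1200))
})

test_that("forward projection integrates a uniform disk to its chord", {
  n <- 128; sp <- 2
  xs <- ((1:n) - (n + 1) / 2) * sp
  X <- matrix(xs, n, n); Y <- t(X)
  r <- 60; c0 <- 0.019
  disk <- ifelse(X^2 + Y^2 <= r^2, c0, 0)
  img <- huImage(muToHu(disk), spacing = sp)
  sino <- forwardProject(img, nAngles = 8)
  nBins <- dim(sino@values)[1]
  central <- sino@values[(nBins + 1) / 2, , 1]
  expect_equal(central, rep(2 * r * c0, 8), tolerance = 0.02)
})

test_that("the projector is linear and maps zero to zero", {
  a <- huImage(matrix(stats::rnorm(32 * 32, 0, 200), 32, 32), spacing = 4)
  b <- huImage(matrix(stats::rnorm(32 * 32, 0, 200), 32, 32), spacing = 4)
  ab <- huImage(gridValues(a) + gridValues(b) + 1000, spacing = 4)
  pa <- forwardProject(a, nAngles = 6)@values
  pb <- forwardProject(b, nAngles = 6)@values
  pab <- forwardProject(ab, nAngles = 6)@values
  # mu(a) + mu(b) = mu(a + b + 1000 HU), values kept above the clamp
  expect_equal(pab, pa + pb, tolerance = 1e-12)
  zero <- huImage(matrix(-1000, 32, 32), spacing = 4)
  expect_true(all(forwardProject(zero, nAngles = 6)@values == 0))
  expect_error(forwardProject(a, nAngles = 6, nBins = 10),
               "detector span")
})

test_that("corruption is the identity at null parameters, bit-exactly", {
  ph <- smallPhantom("none", noise = TRUE)
  sino <- forwardProject(ph$image, nAngles = 12)
  out <- corruptSinogram(sino, beta = 0, n0 = Inf)
  expect_identical(out@values, sino@values)
})

test_that("beam hardening only depresses samples crossing metal", {
  ph <- smallPhantom("unilateral", noise = FALSE)
  sino <- forwardProject(ph$image, nAngles = 24)
  mu <- huToMu(gridValues(ph$image)) *
    structureMask(ph$structures, "metal")
  ms <- forwardProject(huImage(mu, gridSpacing(ph$image),
                               gridOrigin(ph$image)),
                       nAngles = 24, input = "raw")
  out <- corruptSinogram(sino, beta = 0.01, n0 = Inf, metalSino = ms)
  onTrace <- ms@values > 0
  expect_true(all(out@values[onTrace] <= sino@values[onTrace]))
  expect_identical(out@values[!onTrace], sino@values[!onTrace])
  expect_error(corruptSinogram(sino, beta = 0.01, n0 = Inf), "metalSino")
})

test_that("photon counting noise is reproducible and Poisson-like", {
  vals <- array(1.5, c(40, 40, 1))  # ~2.2e3 counts per sample at n0 = 1e4
  sino <- forwardProject(huImage(matrix(0, 16, 16), spacing = 4),
                         nAngles = 40, nBins = 40)
  sino@values <- vals
  a <- corruptSinogram(sino, n0 = 1e4, seed = 7)
  b <- corruptSinogram(sino, n0 = 1e4, seed = 7)
  expect_identical(a@values, b@values)
  counts <- 1e4 * exp(-a@values)  # invert the log conversion
  expect_equal(stats::var(as.vector(counts)) / mean(counts), 1,
               tolerance = 0.1)  # 1600 draws
})

test_that("FBP round-trips the metal-free phantom within 40 HU", {
  ph <- buildPhantom(defaultPhantom("none", dim = c(128, 128, 1),
                                    spacing = c(4, 4, 4)),
                     defaultMaterials(noise = FALSE), seed = 1)
  rec <- fbp(forwardProject(ph$image, nAngles = 360))
  # exclude a 2-voxel rim around material boundaries
  body <- structureMask(ph$structures, "body") &
    interiorMask(gridValues(ph$label))
  err <- gridValues(rec)[body] - gridValues(ph$image)[body]
  expect_lt(sqrt(mean(err^2)), 40)
})

test_that("FBP interior error decreases monotonically with view count", {
  ph <- buildPhantom(defaultPhantom("none", dim = c(128, 128, 1),
                                    spacing = c(4, 4, 4)),
                     defaultMaterials(noise = FALSE), seed = 1)
  body <- structureMask(ph$structures, "body") &
    interiorMask(gridValues(ph$label))
  rmse <- vapply(c(45, 90, 180, 360), function(nv) {
    rec <- fbp(forwardProject(ph$image, nAngles = nv))
    sqrt(mean((gridValues(rec)[body] - gridValues(ph$image)[body])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("an all-zero sinogram reconstructs to air", {
  sino <- forwardProject(huImage(matrix(-1000, 32, 32), spacing = 4),
                         nAngles = 48)
  rec <- fbp(sino)
  expect_equal(gridValues(rec), array(-1000, c(32, 32, 1)),
               tolerance = 1e-8)
})

test_that("corrupted bilateral acquisition darkens the inter-implant band", {
  fx <- bilateralChain()
  region <- discROI(fx$fbpImg, c(0, -12), 30)
  gtMean <- mean(gridValues(fx$gt$image)[region])
  fbpMean <- mean(gridValues(fx$fbpImg)[region])
  expect_lt(fbpMean, gtMean - 50)  # dark streaks between the implants
})

test_that("projecting a rotated image shifts the view angles", {
  # 90-degree rotation of the grid equals a cyclic shift of half the views
  v <- matrix(stats::rnorm(64 * 64, 0, 150), 64, 64)
  img <- huImage(v, spacing = 4)
  rot <- huImage(t(v)[, 64:1], spacing = 4)  # rotate 90 deg CCW
  nA <- 8
  p0 <- forwardProject(img, nAngles = nA)@values[, , 1]
  p1 <- forwardProject(rot, nAngles = nA)@values[, , 1]
  shifted <- cbind(p1[nrow(p1):1, (nA / 2 + 1):nA], p1[, 1:(nA / 2)])
  expect_lt(max(abs(p0 - shifted)), 0.01 * max(abs(p0)))
})

test_that("sinograms round-trip through their file format", {
  ph <- smallPhantom("unilateral", noise = TRUE)
  sino <- forwardProject(ph$image, nAngles = 12)
  sino <- markMetalTrace(sino, structureMask(ph$structures, "metal"))
  f <- tempfile(fileext = ".rds")
  writeSinogram(sino, f)
  back <- readSinogram(f)
  expect_identical(back@values, sino@values)
  expect_identical(back@metalTrace, sino@metalTrace)
  expect_equal(back@angles, sino@angles)
  expect_equal(back@imgSpacing, sino@imgSpacing)
})
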