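test_that("identical and uniformly scaled doses pass gamma fully", {
  d <- doseGrid(array(stats::runif(8 * 8 * 2, 50, 100), c(8, 8, 2)),
                spacing = 2)
  r <- gammaIndex(d, d)
  expect_equal(r@passRate3d, 100)
  expect_equal(r@worstSliceRate, 100)
  scaled <- doseGrid(gridValues(d) * 1.005, spacing = 2)
  expect_equal(gammaIndex(d, scaled)@passRate3d, 100)
})

test_that("the gamma map matches an exhaustive brute-force oracle", {
  set.seed(9)
  for (dims in list(c(8, 8, 1), c(6, 6, 6), c(16, 16, 3))) {
    sp <- c(2, 2, 2)
    ref <- array(stats::runif(prod(dims), 10, 100), dims)
    ev <- ref * array(stats::runif(prod(dims), 0.96, 1.04), dims)
    dr <- doseGrid(ref, spacing = sp)
    de <- doseGrid(ev, spacing = sp)
    # voxel-centre search so the oracle space is identical
    params <- gammaParams(subvoxel = FALSE)
    got <- gammaIndex(dr, de, params)@gammaMap
    want <- gammaOracle(ref, ev, sp, ddFrac = 0.01, dta = 2,
                        cutoffAbs = 0.10 * max(ref), radius = 6)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("gamma respects the low-dose cutoff and asymmetry", {
  ref <- array(1, c(6, 6, 1)); ref[1:3, , ] <- 100
  ev <- ref; ev[4:6, , ] <- 3  # large relative error in low-dose region
  dr <- doseGrid(ref, spacing = 2); de <- doseGrid(ev, spacing = 2)
  r <- gammaIndex(dr, de)
  expect_true(all(is.na(r@gammaMap[4:6, , ])))  # below 10% of max
  expect_equal(r@passRate3d, 100)
  expect_error(gammaIndex(dr, doseGrid(ref, spacing = 3)), "congruent")
  # local normalization is asymmetric: a hot spike in the reference finds
  # no matching evaluated dose, but as evaluated it is simply not selected
  flat <- doseGrid(array(100, c(6, 6, 1)), spacing = 2)
  spikeVals <- array(100, c(6, 6, 1)); spikeVals[3, 3, 1] <- 105
  spike <- doseGrid(spikeVals, spacing = 2)
  expect_equal(gammaIndex(flat, spike)@passRate3d, 100)
  expect_lt(gammaIndex(spike, flat)@passRate3d, 100)
})

test_that("DVH metrics are exact on uniform and half-half doses", {
  m <- array(TRUE, c(10, 10, 10))
  u <- doseGrid(array(100, c(10, 10, 10)), spacing = 5)
  mu <- dvhMetrics(u, m)$metrics
  expect_equal(unname(mu), c(100, 100, 100, 100, 100))
  half <- array(0, c(10, 10, 10)); half[1:5, , ] <- 100
  h <- dvhMetrics(doseGrid(half, spacing = 5), m)$metrics
  expect_equal(unname(h["d_mean"]), 50)
  expect_equal(unname(h["v_d95"]), 50)
  expect_equal(unname(h["d_v98"]), 0)
})

test_that("DVH metrics agree with a sort-and-count oracle", {
  set.seed(4)
  dims <- c(10, 10, 10)
  vals <- array(stats::runif(1000, 0, 110), dims)
  dose <- doseGrid(vals, spacing = 5, prescription = 100)  # 0.125 cc voxels
  mask <- array(stats::runif(1000) < 0.8, dims)
  got <- dvhMetrics(dose, mask)$metrics
  pct <- sort(vals[mask], decreasing = TRUE)
  n <- length(pct)
  expect_equal(unname(got["d_mean"]), mean(pct))
  # dose covering 98% of the volume: between adjacent order statistics
  k <- 0.98 * n
  expect_gte(got["d_v98"], pct[ceiling(k) + 1] - 1e-9)
  expect_lte(got["d_v98"], pct[floor(k)] + 1e-9)
  expect_equal(unname(got["v_d95"]), 100 * sum(pct >= 95) / n)
  k1 <- 1000 / 125
  expect_gte(got["d_1cc"], pct[ceiling(k1)] - 1e-9)
  expect_lte(got["d_1cc"], pct[floor(k1)] + 1e-9)
  expect_equal(unname(got["v_dthr"]), 100 * sum(pct >= 50) / n)
})

test_that("the cumulative DVH curve is monotone from 100%", {
  set.seed(5)
  dose <- doseGrid(array(stats::runif(512, 0, 104), c(8, 8, 8)),
                   spacing = 5)
  res <- dvhMetrics(dose, array(TRUE, c(8, 8, 8)))
  expect_equal(res$curve$volume_pct[1], 100)
  expect_true(all(diff(res$curve$volume_pct) <= 0))
})

test_that("sub-1cc structures fall back to the maximum dose", {
  dose <- doseGrid(array(stats::runif(64, 0, 100), c(4, 4, 4)),
                   spacing = 2)  # 8 mm3 voxels, 512 mm3 total
  m <- array(TRUE, c(4, 4, 4))
  expect_warning(res <- dvhMetrics(dose, m), "1 cc")
  expect_equal(unname(res$metrics["d_1cc"]), max(gridValues(dose)))
})

test_that("ROI statistics report means, differences and noise", {
  v <- array(40, c(16, 16, 3))
  img <- huImage(v, spacing = 4)
  roi <- array(FALSE, dim(v)); roi[2:5, 2:5, ] <- TRUE
  ref <- array(FALSE, dim(v)); ref[10:13, 10:13, ] <- TRUE
  s <- roiStats(img, roi, ref)
  expect_equal(unname(s$pooled["difference"]), 0)
  expect_equal(unname(s$pooled["noise"]), 0)
  v2 <- v; v2[2:5, 2:5, ] <- 140
  s2 <- roiStats(huImage(v2, spacing = 4), roi, ref)
  expect_equal(unname(s2$pooled["difference"]), 100)
  expect_equal(nrow(s2$perSlice), 3)
})

test_that("measured ROI noise recovers a known Gaussian sigma", {
  v <- array(40, c(32, 32, 2))
  set.seed(11)
  noise <- array(stats::rnorm(length(v), 0, 20), dim(v))
  img <- huImage(v + noise, spacing = 4)
  roi <- array(TRUE, dim(v))   # 2048 voxels
  ref <- roi
  s <- roiStats(img, roi, ref)
  expect_equal(unname(s$pooled["noise"]), 20, tolerance = 2)
})

test_that("plan comparisons are antisymmetric and zero on identity", {
  a <- c(d_mean = 99.4, d_v98 = 95.2, v_d95 = 98.3)
  expect_true(all(comparePlans(a, a)$diff == 0))
  b <- c(d_mean = 99.0, d_v98 = 90.6, v_d95 = 94.9)
  expect_equal(comparePlans(a, b)$diff, -comparePlans(b, a)$diff)
  expect_error(comparePlans(a, b[1:2]), "metric sets")
})
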