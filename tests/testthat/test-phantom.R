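test_that("zero-noise phantom is piecewise constant at the material means", {
  ph <- smallPhantom("none", noise = FALSE)
  mats <- defaultMaterials(noise = FALSE)
  vals <- unique(as.vector(gridValues(ph$image)))
  expect_true(all(vals %in% mats$hu))
  # labels resolve and HU equals the mean of the labelled material everywhere
  lab <- gridValues(ph$label)
  expect_equal(gridValues(ph$image), array(mats$hu[lab], dim(lab)))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- smallPhantom("unilateral", noise = TRUE, seed = 42)
  b <- smallPhantom("unilateral", noise = TRUE, seed = 42)
  expect_identical(gridValues(a$image), gridValues(b$image))
  c <- smallPhantom("unilateral", noise = TRUE, seed = 43)
  expect_false(identical(gridValues(a$image), gridValues(c$image)))
})

test_that("no voxel reaches the metal threshold without implants", {
  ph <- smallPhantom("none", noise = TRUE)
  expect_true(all(gridValues(ph$image) < 3000))
  expect_equal(sum(structureMask(ph$structures, "metal")), 0)
})

test_that("bilateral metal volume doubles the unilateral volume", {
  uni <- smallPhantom("unilateral")
  bil <- smallPhantom("bilateral")
  nUni <- sum(structureMask(uni$structures, "metal"))
  nBil <- sum(structureMask(bil$structures, "metal"))
  expect_gt(nUni, 0)
  # voxel centres are symmetric about the midline, so mirroring is exact up
  # to one voxel of rasterization asymmetry
  expect_lte(abs(nBil - 2 * nUni), 1)
})

test_that("mirrorImplant reflects the implant and nothing else", {
  spec <- defaultPhantom("unilateral", dim = smallDim,
                         spacing = smallSpacing)
  bil <- mirrorImplant(spec)
  expect_identical(bil@implantConfig, "bilateral")
  imp0 <- Filter(function(s) s$role == "implant", spec@shapes)
  imp1 <- Filter(function(s) s$role == "implant", bil@shapes)
  expect_length(imp1, 2 * length(imp0))
  # reflected centroid x-offset is the negative of the original
  expect_equal(imp1[[2]]$center[1], -imp0[[1]]$center[1])
  expect_equal(imp1[[2]]$center[2], imp0[[1]]$center[2])
  # non-implant shapes untouched
  expect_identical(Filter(function(s) s$role != "implant", bil@shapes),
                   Filter(function(s) s$role != "implant", spec@shapes))
  # mirroring is only defined on unilateral configurations
  expect_error(mirrorImplant(bil), "unilateral")
})

test_that("structure masks are nonempty, and targets exclude metal", {
  ph <- smallPhantom("bilateral")
  s <- ph$structures
  for (nm in structureNames(s))
    if (nm != "metal") expect_gt(sum(structureMask(s, nm)), 0)
  metal <- structureMask(s, "metal")
  for (nm in c("ptv_prostate", "ptv_sarcoma", "bladder", "rectum"))
    expect_equal(sum(structureMask(s, nm) & metal), 0)
  # a target drawn over the implant is rejected
  spec <- defaultPhantom("unilateral", dim = smallDim,
                         spacing = smallSpacing)
  spec@structures$ptv_bad <- phantomShape("ellipse", "soft_tissue",
                                          c(100, -10), c(25, 25))
  expect_error(buildPhantom(spec, defaultMaterials(), seed = 1),
               "overlaps the metal")
})

test_that("material table invariants are enforced", {
  m <- defaultMaterials()
  m$hu[m$material == "air"] <- -900
  expect_error(materialTable(m), "air")
  m <- defaultMaterials()
  m$sd[2] <- -1
  expect_error(materialTable(m), "SD")
  m <- defaultMaterials()
  m$hu[m$material == "metal"] <- 2500
  expect_error(materialTable(m), "metal")
})

test_that("phantom specifications round-trip through YAML and JSON", {
  spec <- defaultPhantom("bilateral", dim = smallDim,
                         spacing = smallSpacing)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writePhantomSpec(spec, f, materials = defaultMaterials())
    back <- readPhantomSpec(f)
    expect_equal(back$spec@dim, spec@dim)
    expect_equal(back$spec@spacing, spec@spacing)
    expect_identical(back$spec@implantConfig, spec@implantConfig)
    expect_equal(back$materials, defaultMaterials())
    # the rebuilt spec rasterizes identically
    a <- buildPhantom(spec, defaultMaterials(), seed = 3)
    b <- buildPhantom(back$spec, back$materials, seed = 3)
    expect_identical(gridValues(a$label), gridValues(b$label))
  }
})

test_that("grid metadata round-trips through NIfTI bit-exactly", {
  ph <- smallPhantom("unilateral", noise = TRUE)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(ph$image, f)
  back <- readVolume(f, "HUImage")
  expect_identical(gridValues(back), gridValues(ph$image))
  expect_identical(gridSpacing(back), gridSpacing(ph$image))
  expect_identical(gridOrigin(back), gridOrigin(ph$image))
  sdir <- tempfile("structs")
  writeStructureSet(ph$structures, sdir)
  back2 <- readStructureSet(sdir)
  expect_identical(back2@masks, ph$structures@masks)
})
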