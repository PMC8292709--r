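#' Experiment configuration
#'
#' Assembles and validates the configuration of a full phantom experiment:
#' phantom geometry, acquisition corruption, MAR parameters, calibration,
#' plan definitions per scenario, gamma criteria and the global seed
#' (per-stage seeds are derived deterministically from it, so a rerun with
#' the same configuration is byte-identical).
#'
#' Scenario vocabulary: `"gt"` is the implant-free phantom whose FBP
#' reconstruction doubles as the ground-truth reference image;
#' `"unilateral"` and `"bilateral"` carry implants. Each plan entry names
#' its scenario, target, beam angles and organs at risk.
#'
#' @param outDir output directory for the report bundle.
#' @param phantomDim,spacing phantom grid (voxels) and spacing (mm).
#' @param nAngles CT views over 180 degrees.
#' @param beta,n0,epsilon corruption parameters (see [corruptSinogram()]);
#'   `corruption = FALSE` forces the identity acquisition (null experiment).
#' @param corruption logical master switch for the corruption model.
#' @param mar a \linkS4class{MARParams}.
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param gamma a \linkS4class{GammaParams}.
#' @param scenarios subset of `c("gt", "unilateral", "bilateral")`.
#' @param plans list of plan definitions (`name`, `scenario`, `ptv`,
#'   `angles`, `oars`); `NULL` for the stock set (prostate AP on gt,
#'   prostate lateral+oblique on unilateral, sarcoma AP+oblique on
#'   unilateral, prostate AP on bilateral).
#' @param prescription prescription dose.
#' @param thresholdFrac organ-at-risk absolute-dose volume threshold as a
#'   fraction of prescription.
#' @param roiCenter,roiRefCenter,roiDiameter in-plane ROI definition (mm)
#'   for the streak/reference CT-number analysis.
#' @param materials material table for the phantom.
#' @param seed global integer seed.
#' @return a validated config list (class `marbenchConfig`).
#' @export
experimentConfig <- function(outDir = tempfile("marbench"),
                             phantomDim = c(256, 256, 10),
                             spacing = c(2, 2, 2),
                             nAngles = 360,
                             beta = 0.01, n0 = 1e7, epsilon = 5,
                             corruption = TRUE,
                             mar = marParams(),
                             curve = defaultCalibration(),
                             gamma = gammaParams(),
                             scenarios = c("gt", "unilateral", "bilateral"),
                             plans = NULL,
                             prescription = 100,
                             thresholdFrac = 0.5,
                             roiCenter = c(0, -12),
                             roiRefCenter = c(0, 70),
                             roiDiameter = 12,
                             materials = defaultMaterials(),
                             seed = 1) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (is.null(plans)) {
    plans <- list(
      list(name = "prostate_gt", scenario = "gt", ptv = "ptv_prostate",
           angles = 90, oars = c("bladder", "rectum")),
      list(name = "prostate_unilateral", scenario = "unilateral",
           ptv = "ptv_prostate", angles = c(0, 45),
           oars = c("bladder", "rectum")),
      list(name = "sarcoma_unilateral", scenario = "unilateral",
           ptv = "ptv_sarcoma", angles = c(90, 60), oars = character(0)),
      list(name = "prostate_bilateral", scenario = "bilateral",
           ptv = "ptv_prostate", angles = 90,
           oars = c("bladder", "rectum")))
  }
  plans <- Filter(function(p) p$scenario %in% scenarios, plans)
  stopifnot(is(mar, "MARParams"), is(curve, "CalibrationCurve"),
            is(gamma, "GammaParams"), nAngles >= 2, prescription > 0,
            seed == round(seed))
  if (!corruption) { beta <- 0; n0 <- Inf }
  structure(list(outDir = outDir, phantomDim = phantomDim,
                 spacing = spacing, nAngles = nAngles, beta = beta, n0 = n0,
                 epsilon = epsilon, corruption = corruption, mar = mar,
                 curve = curve, gamma = gamma, scenarios = scenarios,
                 plans = plans, prescription = prescription,
                 thresholdFrac = thresholdFrac, roiCenter = roiCenter,
                 roiRefCenter = roiRefCenter, roiDiameter = roiDiameter,
                 materials = materials, seed = as.integer(seed)),
            class = "marbenchConfig")
}

# acquisition: forward project the truth image and corrupt the raw data
.acquire <- function(truth, metalMask, config, seedKey) {
  sino <- forwardProject(truth, nAngles = config$nAngles)
  if (config$beta > 0 || is.finite(config$n0)) {
    metalSino <- NULL
    if (config$beta > 0 && any(metalMask)) {
      mu <- huToMu(gridValues(truth)) * metalMask
      metalSino <- forwardProject(
        huImage(mu, gridSpacing(truth), gridOrigin(truth)),
        nAngles = config$nAngles, input = "raw")
    }
    beta <- if (any(metalMask)) config$beta else 0
    sino <- corruptSinogram(sino, beta = beta, n0 = config$n0,
                            epsilon = config$epsilon,
                            seed = .deriveSeed(config$seed, seedKey),
                            metalSino = metalSino)
  }
  sino
}

# soft-tissue voxels expected to be free of metal artifacts: > 50 mm from
# any implant and, for the bilateral case, outside the inter-implant streak
# corridor (the band of rays crossing both implants); for the unilateral
# case this is the contralateral half of the phantom
.quietSoftMask <- function(label, structures, materials, scenario) {
  softId <- which(materials$material == "soft_tissue")
  d <- gridDim(label); sp <- gridSpacing(label); o <- gridOrigin(label)
  soft <- gridValues(label) == softId
  metal <- structureMask(structures, "metal")
  far <- .metalDistance(metal, sp) > 50
  idx <- which(metal, arr.ind = TRUE)
  mx <- o[1] + (mean(idx[, 1]) - 1) * sp[1]
  my <- o[2] + (mean(idx[, 2]) - 1) * sp[2]
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  if (scenario == "bilateral") {
    soft & far & abs(Y - my) > 45
  } else {
    # mean metal x is on the implant side; keep the opposite half
    if (mx >= 0) soft & far & X < -40 else soft & far & X > 40
  }
}

# rectal override: the gas-holding rectum is overridden to water RLSP, the
# protocol-style fix for non-reproducible rectal filling; covering the whole
# structure (gas plus wall) also neutralises the partial-volume rim the
# reconstruction smears around the sharp air boundary
.rectalAirRule <- function(label, structures, materials) {
  if (!"rectum" %in% structureNames(structures)) return(list())
  list(overrideRule(rlsp = 1.0,
                    mask = structureMask(structures, "rectum")))
}

# shorten a ray so it ends at the beam-relevant depth: the distal edge of
# the target plus a margin (range deviations beyond the beam's stopping
# point do not affect the plan)
.truncateAtStructure <- function(ray, mask, spacing, origin, margin = 3) {
  depths <- .rayDepths(ray)
  pts <- .rayPoints(ray, depths)
  m <- sampleBilinear(mask[, , ray@slice] * 1, spacing[1:2], origin[1:2],
                      pts) >= 0.5
  if (!any(m)) return(ray)
  cut <- min(depths[max(which(m))] + margin, ray@length)
  rayPath(ray@start, ray@direction, cut, ray@step, ray@slice)
}

.weplSummary <- function(rays, testR, gtR) {
  deltas <- vapply(rays, function(ray) {
    deltaWEPL(traceWEPL(testR, ray), traceWEPL(gtR, ray))@extremum
  }, numeric(1))
  i <- which.max(abs(deltas))
  c(maxAbs = abs(deltas[i]), extremum = deltas[i])
}

.planAndCompare <- function(planningRlsp, refRlsp, structures, planDef,
                            config) {
  plan <- planBeams(planningRlsp, structures, planDef$ptv, planDef$angles,
                    prescription = config$prescription)
  opt <- computeDose(planningRlsp, plan)
  recalc <- recalculateDose(plan, refRlsp)
  gam <- gammaIndex(opt, recalc, config$gamma)
  dvhFor <- function(dose, structName) {
    dvhMetrics(dose, structureMask(structures, structName),
               thresholdFrac = config$thresholdFrac)$metrics
  }
  tabs <- list()
  tabs[[planDef$ptv]] <- comparePlans(dvhFor(opt, planDef$ptv),
                                      dvhFor(recalc, planDef$ptv),
                                      c("optimized", "recalculated"))
  for (oar in planDef$oars)
    tabs[[oar]] <- comparePlans(dvhFor(opt, oar), dvhFor(recalc, oar),
                                c("optimized", "recalculated"))
  list(plan = plan, optimized = opt, recalculated = recalc, gamma = gam,
       dvh = tabs)
}

#' Run the full phantom experiment
#'
#' Orchestrates phantom generation, CT acquisition with metal-induced
#' corruption, FBP and iterated-MAR reconstruction, HU-to-RLSP calibration
#' with the rectal-air-as-water override, WEPL deviation analysis along the
#' anterior-posterior ray bundle through the target, plan optimisation on
#' each reconstruction with recalculation on the ground-truth image, and
#' gamma / DVH / ROI comparison. Writes a report bundle (images, dose grids,
#' profile and table CSVs, manifest with checksums) to `config$outDir` and
#' returns the in-memory bundle.
#'
#' The ground-truth reference image is the FBP reconstruction of the
#' implant-free phantom, as an artifact-free scan would provide. For the
#' `"gt"` scenario itself the comparison reference is the noiseless phantom
#' truth, so its WEPL summary quantifies reconstruction fidelity rather
#' than artifact burden; the null-experiment control is an implant scenario
#' run with `corruption = FALSE`, whose deviations against the ground-truth
#' reconstruction should vanish.
#'
#' @param config an [experimentConfig()].
#' @return the report bundle (list), invisibly including `outDir`.
#' @export
runExperiment <- function(config = experimentConfig()) {
  stopifnot(inherits(config, "marbenchConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("images", "doses", "profiles", "tables"))
    dir.create(file.path(config$outDir, sub), showWarnings = FALSE)

  phSeed <- .deriveSeed(config$seed, "phantom")
  bundle <- list(config = config, scenarios = list())

  # implant-free phantom: truth + its reconstruction (the GT image)
  gtSpec <- defaultPhantom("none", dim = config$phantomDim,
                           spacing = config$spacing)
  gtPh <- buildPhantom(gtSpec, config$materials, phSeed)
  gtSino <- .acquire(gtPh$image, structureMask(gtPh$structures, "metal"),
                     config, "acquire_gt")
  gtImage <- fbp(gtSino)
  overrides <- .rectalAirRule(gtPh$label, gtPh$structures, config$materials)
  gtRlsp <- applyCalibration(config$curve, gtImage, overrides)
  truthRlsp <- applyCalibration(config$curve, gtPh$image, overrides)
  bundle$gt <- list(truth = gtPh$image, image = gtImage, rlsp = gtRlsp,
                    truthRlsp = truthRlsp, structures = gtPh$structures,
                    label = gtPh$label)
  writeVolume(gtPh$image, file.path(config$outDir, "images",
                                    "gt_truth.nii.gz"))
  writeVolume(gtImage, file.path(config$outDir, "images", "gt_fbp.nii.gz"))

  rows <- list()     # table-2-shaped records
  weplRows <- list() # per-scenario WEPL deviation summaries

  for (sc in config$scenarios) {
    hasMetal <- sc != "gt"
    if (hasMetal) {
      spec <- defaultPhantom(sc, dim = config$phantomDim,
                             spacing = config$spacing)
      ph <- buildPhantom(spec, config$materials, phSeed)
      sino <- .acquire(ph$image, structureMask(ph$structures, "metal"),
                       config, paste0("acquire_", sc))
      fbpImg <- fbp(sino)
      imarImg <- imar(sino, config$mar)
      refImg <- gtImage; refRlsp <- gtRlsp
    } else {
      ph <- gtPh; sino <- gtSino; fbpImg <- gtImage; imarImg <- NULL
      refImg <- gtPh$image; refRlsp <- truthRlsp
    }
    fbpRlsp <- applyCalibration(config$curve, fbpImg, overrides)
    imarRlsp <- if (hasMetal)
      applyCalibration(config$curve, imarImg, overrides) else NULL

    # WEPL deviation along the AP bundle through the central target,
    # truncated at the beam's distal edge where range accuracy matters
    rays <- rayBundle(ph$structures, "ptv_prostate", 90)
    ptvMask <- structureMask(ph$structures, "ptv_prostate")
    beamRays <- lapply(rays, .truncateAtStructure, mask = ptvMask,
                       spacing = gridSpacing(fbpImg),
                       origin = gridOrigin(fbpImg))
    wepl <- list(fbp = .weplSummary(beamRays, fbpRlsp, refRlsp))
    if (hasMetal) wepl$imar <- .weplSummary(beamRays, imarRlsp, refRlsp)
    weplRows[[sc]] <- wepl

    # representative profile lines (bundle edges and centre)
    sel <- unique(c(1L, ceiling(length(rays) / 2), length(rays)))
    for (i in seq_along(sel)) {
      tab <- profileTable(rays[[sel[i]]], refImg, fbpImg,
                          if (hasMetal) imarImg else fbpImg,
                          refRlsp, fbpRlsp,
                          if (hasMetal) imarRlsp else fbpRlsp)
      utils::write.csv(tab, file.path(config$outDir, "profiles",
                                      sprintf("%s_line%d.csv", sc, i)),
                       row.names = FALSE)
    }

    # plans attached to this scenario
    scPlans <- Filter(function(p) p$scenario == sc, config$plans)
    planResults <- list()
    for (pd in scPlans) {
      res <- list(fbp = .planAndCompare(fbpRlsp, refRlsp, ph$structures,
                                        pd, config))
      if (hasMetal)
        res$imar <- .planAndCompare(imarRlsp, refRlsp, ph$structures, pd,
                                    config)
      planResults[[pd$name]] <- res
      for (recon in names(res)) {
        r <- res[[recon]]
        rows[[length(rows) + 1L]] <- data.frame(
          plan = pd$name, recon = recon, structure = "(gamma)",
          metric = "gamma3d_pct", optimized = r$gamma@passRate3d,
          recalculated = NA, diff = NA)
        rows[[length(rows) + 1L]] <- data.frame(
          plan = pd$name, recon = recon, structure = "(gamma)",
          metric = "gamma2d_worst_pct", optimized = r$gamma@worstSliceRate,
          recalculated = NA, diff = NA)
        for (structName in names(r$dvh)) {
          t <- r$dvh[[structName]]
          rows[[length(rows) + 1L]] <- data.frame(
            plan = pd$name, recon = recon, structure = structName,
            metric = t$metric, optimized = t$optimized,
            recalculated = t$recalculated, diff = t$diff)
        }
        writeVolume(r$optimized,
                    file.path(config$outDir, "doses",
                              sprintf("%s_%s_opt.nii.gz", pd$name, recon)))
        writeVolume(r$recalculated,
                    file.path(config$outDir, "doses",
                              sprintf("%s_%s_recalc.nii.gz", pd$name,
                                      recon)))
      }
    }

    # ROI CT-number / noise analysis and far-field soft-tissue stability
    d <- gridDim(fbpImg)
    mid <- ceiling(d[3] / 2)
    roiSlices <- intersect(mid + (-2:2), seq_len(d[3]))
    roi <- discROI(fbpImg, config$roiCenter, config$roiDiameter, roiSlices)
    ref <- discROI(fbpImg, config$roiRefCenter, config$roiDiameter,
                   roiSlices)
    roiRes <- list(fbp = roiStats(fbpImg, roi, ref, roiSlices))
    contralateralMad <- NA_real_
    if (hasMetal) {
      roiRes$imar <- roiStats(imarImg, roi, ref, roiSlices)
      region <- .quietSoftMask(ph$label, ph$structures, config$materials, sc)
      contralateralMad <- mean(abs(gridValues(imarImg)[region] -
                                     gridValues(fbpImg)[region]))
    }

    if (hasMetal) {
      writeVolume(fbpImg, file.path(config$outDir, "images",
                                    sprintf("%s_fbp.nii.gz", sc)))
      writeVolume(imarImg, file.path(config$outDir, "images",
                                     sprintf("%s_imar.nii.gz", sc)))
    }
    bundle$scenarios[[sc]] <- list(
      truth = ph$image, structures = ph$structures, label = ph$label,
      fbp = fbpImg, imar = imarImg, fbpRlsp = fbpRlsp, imarRlsp = imarRlsp,
      wepl = wepl, plans = planResults, roi = roiRes,
      contralateralMad = contralateralMad)
  }

  table2 <- do.call(rbind, rows)
  utils::write.csv(table2, file.path(config$outDir, "tables", "table2.csv"),
                   row.names = FALSE)
  weplTab <- do.call(rbind, lapply(names(weplRows), function(sc) {
    do.call(rbind, lapply(names(weplRows[[sc]]), function(recon) {
      w <- weplRows[[sc]][[recon]]
      data.frame(scenario = sc, recon = recon, max_abs_dwepl_mm = w["maxAbs"],
                 extremum_mm = w["extremum"])
    }))
  }))
  utils::write.csv(weplTab, file.path(config$outDir, "tables", "wepl.csv"),
                   row.names = FALSE)
  bundle$table2 <- table2
  bundle$weplTable <- weplTab

  summary <- list(
    seed = config$seed,
    corruption = config$corruption,
    scenarios = config$scenarios,
    wepl = weplRows,
    contralateral_mad_hu = lapply(bundle$scenarios, `[[`,
                                  "contralateralMad"))
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  files <- list.files(config$outDir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$outDir, "manifest.json"))
  manifest <- data.frame(file = sub(paste0("^", config$outDir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       pretty = TRUE)
  bundle$outDir <- config$outDir
  invisible(bundle)
}

#' Render report figures from a bundle directory
#'
#' Regenerates the publication-style figures from the stored intermediates
#' (no recomputation): CT-number and WEPL-deviation profile overlays per
#' analysis line, and the optimised-minus-recalculated dose-difference map
#' for each plan. Styling is fixed and the files carry no timestamps, so
#' renders of the same bundle are identical.
#'
#' @param outDir a bundle directory written by [runExperiment()].
#' @return paths of the figures written, invisibly.
#' @export
renderReport <- function(outDir) {
  figDir <- file.path(outDir, "figures")
  dir.create(figDir, showWarnings = FALSE)
  written <- character(0)
  for (f in sort(list.files(file.path(outDir, "profiles"),
                            full.names = TRUE))) {
    tab <- utils::read.csv(f)
    out <- file.path(figDir, sub("\\.csv$", ".png", basename(f)))
    grDevices::png(out, width = 800, height = 600)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    graphics::matplot(tab$depth_mm, tab[c("hu_fbp", "hu_imar", "hu_gt")],
                      type = "l", lty = 1, col = c("red", "blue", "black"),
                      xlab = "depth (mm)", ylab = "CT number (HU)",
                      main = sub("\\.csv$", "", basename(f)))
    graphics::legend("topright", c("FBP", "MAR", "GT"), lty = 1,
                     col = c("red", "blue", "black"), bty = "n")
    graphics::matplot(tab$depth_mm, tab[c("dwepl_fbp", "dwepl_imar")],
                      type = "l", lty = 1, col = c("red", "blue"),
                      xlab = "depth (mm)", ylab = "dWEPL (mm)")
    graphics::abline(h = 0, col = "grey")
    grDevices::dev.off()
    written <- c(written, out)
  }
  doseFiles <- list.files(file.path(outDir, "doses"),
                          pattern = "_opt\\.nii\\.gz$", full.names = TRUE)
  for (f in sort(doseFiles)) {
    rec <- sub("_opt\\.nii\\.gz$", "_recalc.nii.gz", f)
    if (!file.exists(rec)) next
    opt <- readVolume(f, "DoseGrid"); rc <- readVolume(rec, "DoseGrid")
    mid <- ceiling(gridDim(opt)[3] / 2)
    diffSlice <- gridValues(opt)[, , mid] - gridValues(rc)[, , mid]
    out <- file.path(figDir, sub("_opt\\.nii\\.gz$", "_dosediff.png",
                                 basename(f)))
    grDevices::png(out, width = 600, height = 600)
    lim <- max(abs(diffSlice), 1e-6)
    graphics::image(diffSlice, zlim = c(-lim, lim),
                    col = grDevices::hcl.colors(64, "Blue-Red"),
                    main = sub("_opt\\.nii\\.gz$", "", basename(f)),
                    xlab = "optimized - recalculated dose", ylab = "")
    grDevices::dev.off()
    written <- c(written, out)
  }
  invisible(written)
}
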