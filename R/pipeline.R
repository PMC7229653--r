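## Pipeline driver: a validated configuration, a synthetic end-to-end run
## (simulate -> traction -> nuclear dynamics -> morphometry -> statistics),
## and a checksummed manifest for reproducibility checks.

#' Default pipeline configuration
#'
#' Returns the full configuration consumed by [runPipeline()]. Every key is
#' validated; unknown keys are rejected by name. Physical quantities are in
#' the units of the slot names (micrometres, minutes, pascals).
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return A named nested list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("simulate", "tfm", "nucdyn", "morphometry", "stats"),
    tfm = list(
      gridShape = c(32, 32), spacingUm = 4,
      youngModulusPa = 1000, poissonRatio = 0.45,
      magnitudePa = 100,
      beadDensityPerUm2 = 0.02, beadDiameterUm = 2,
      photonNoiseSd = 0.005, maxDisplacementUm = 2,
      intensityPercentileCut = 92, lambda = 1e-6
    ),
    nucdyn = list(
      alpha = 0.4, tauMin = 8, noiseSd = 0.1,
      nNuclei = 30, nFrames = 33, frameIntervalMin = 1, maxLagFrames = 31
    ),
    morphometry = list(
      nNuclei = 12, maxFoci = 8, minSeparationUm = 1.2,
      fociPixelSizeUm = 0.21,
      sproutLengthsUm = c(60, 80, 100, 120), coreRadiusUm = 40,
      sproutPixelSizeUm = 0.42,
      gelAreaFractions = c(1, 0.8, 0.56), gelInitialRadiusPx = 100
    ),
    stats = list(
      genes = c("Lmna", "Acta2", "Fn1"),
      log2FoldChanges = c(1, 0.8, 1.5),
      nReplicates = 3, ctNoiseSd = 0.1
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration against the schema of [defaultPipelineConfig()]:
#' unknown keys are rejected with the offending key named (fail-fast), missing
#' keys are filled from the defaults, and physical quantities must be
#' positive.
#'
#' @param config a (possibly partial) configuration list.
#' @return The completed configuration.
#' @export
validatePipelineConfig <- function(config) {
  def <- defaultPipelineConfig(if (!is.null(config$seed)) config$seed else 1)
  merge <- function(user, default, prefix) {
    unknown <- setdiff(names(user), names(default))
    if (length(unknown))
      stop("unknown config key: ", paste0(prefix, unknown[1]))
    out <- default
    for (k in names(user)) {
      out[[k]] <- if (is.list(default[[k]])) {
        if (!is.list(user[[k]]))
          stop("config key ", prefix, k, " must be a list")
        merge(user[[k]], default[[k]], paste0(prefix, k, "$"))
      } else user[[k]]
    }
    out
  }
  cfg <- merge(config, def, "")
  pos <- c("tfm$spacingUm", "tfm$youngModulusPa", "tfm$beadDensityPerUm2",
           "tfm$beadDiameterUm", "tfm$maxDisplacementUm",
           "nucdyn$tauMin", "nucdyn$frameIntervalMin",
           "morphometry$minSeparationUm", "morphometry$fociPixelSizeUm",
           "morphometry$coreRadiusUm", "morphometry$sproutPixelSizeUm",
           "morphometry$gelInitialRadiusPx")
  for (p in pos) {
    parts <- strsplit(p, "$", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || any(v <= 0))
      stop("config key ", p, " must be positive")
  }
  if (cfg$tfm$poissonRatio < 0 || cfg$tfm$poissonRatio >= 0.5)
    stop("config key tfm$poissonRatio must lie in [0, 0.5)")
  bad <- setdiff(cfg$stages, c("simulate", "tfm", "nucdyn", "morphometry",
                               "stats"))
  if (length(bad)) stop("unknown stage: ", bad[1])
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates synthetic fixtures and runs every requested stage in dependency
#' order: bead-pair simulation and the full traction workflow (detection,
#' linking, outlier filtering, gridding, FTTC inversion), nucleus time-lapse
#' simulation with decorrelation curves and the decay fit, morphometry
#' (foci counting, sprout metrics, gel contraction), and the statistics layer
#' (delta-delta-Ct, t tests with Bonferroni adjustment). All outputs are
#' written under `outDir` and listed, with MD5 checksums, in
#' `manifest.json`; identical configuration and seed give byte-identical
#' manifests.
#'
#' @param config configuration from [defaultPipelineConfig()] or a partial
#'   override; validated by [validatePipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config = list(), outDir) {
  cfg <- validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(rel) {
    written <<- c(written, rel)
    p <- file.path(outDir, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    p
  }
  saveJSON <- function(x, rel)
    jsonlite::write_json(x, put(rel), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      partial <- data.frame(path = sort(written),
                            md5 = unname(tools::md5sum(
                              file.path(outDir, sort(written)))))
      jsonlite::write_json(list(status = "failed", stage = name,
                                files = partial),
                           file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  substrate <- ElasticSubstrate(cfg$tfm$youngModulusPa, cfg$tfm$poissonRatio)
  truth <- tractionDipoleTruth(cfg$tfm$gridShape, cfg$tfm$spacingUm,
                               substrate, magnitudePa = cfg$tfm$magnitudePa)
  beadSim <- simulateBeadImages(truth, cfg$tfm$beadDensityPerUm2,
                                cfg$tfm$beadDiameterUm,
                                cfg$tfm$photonNoiseSd,
                                seed = cfg$seed + 11)
  nucSim <- NULL
  fociSim <- NULL
  sproutSim <- NULL
  gelSim <- simulateGelSeries(cfg$morphometry$gelAreaFractions,
                              cfg$morphometry$gelInitialRadiusPx)
  fciCounts <- withSeed(cfg$seed + 13,
                        sample(0:cfg$morphometry$maxFoci,
                               cfg$morphometry$nNuclei, replace = TRUE))
  fociSim <- simulateFoci(fciCounts, cfg$morphometry$minSeparationUm,
                          cfg$morphometry$fociPixelSizeUm,
                          seed = cfg$seed + 17)
  sproutSim <- simulateSprouts(cfg$morphometry$sproutLengthsUm,
                               cfg$morphometry$coreRadiusUm,
                               cfg$morphometry$sproutPixelSizeUm,
                               seed = cfg$seed + 19)
  lfc <- matrix(c(rep(0, length(cfg$stats$genes)),
                  cfg$stats$log2FoldChanges),
                ncol = 2,
                dimnames = list(cfg$stats$genes, c("FCG", "RF")))
  ctTab <- simulateCtTable(lfc, nReplicates = cfg$stats$nReplicates,
                           ctNoiseSd = cfg$stats$ctNoiseSd,
                           seed = cfg$seed + 23)

  if ("simulate" %in% cfg$stages) runStage("simulate", {
    norm01 <- function(m) (m - min(m)) / max(1e-12, diff(range(m)))
    writeStack(ImageFrameSeries(list(norm01(beadSim$reference),
                                     norm01(beadSim$deformed)),
                                pixelSizeUm = beadSim$pixelSizeUm),
               put("fixtures/beads.tif"))
    saveJSON(list(strain_energy_truth_note = "see tfm/summary.json",
                  grid_shape = dim(truth@tx),
                  spacing_um = truth@spacingUm,
                  max_traction_pa = max(sqrt(truth@tx^2 + truth@ty^2))),
             "fixtures/beads.truth.json")
    writeStack(ImageFrameSeries(lapply(gelSim$frames, identity),
                                pixelSizeUm = 1),
               put("fixtures/gel.tif"))
    saveJSON(list(normalized_areas = gelSim$truth), "fixtures/gel.truth.json")
    writeStack(ImageFrameSeries(norm01(fociSim$foci),
                                pixelSizeUm = fociSim$pixelSizeUm),
               put("fixtures/foci.tif"))
    writeMeasurementTable(fociSim$truth, put("fixtures/foci.truth.csv"))
    writeStack(ImageFrameSeries(sproutSim$image,
                                pixelSizeUm = sproutSim$pixelSizeUm),
               put("fixtures/sprouts.tif"))
    writeMeasurementTable(sproutSim$truth, put("fixtures/sprouts.truth.csv"))
    writeMeasurementTable(ctTab, put("fixtures/ct_table.csv"),
                          keyColumns = c("gene", "condition", "replicate"))
    for (f in c("fixtures/beads.meta.json", "fixtures/gel.meta.json",
                "fixtures/foci.meta.json", "fixtures/sprouts.meta.json"))
      written <- c(written, f)
  })

  tfmOut <- NULL
  if ("tfm" %in% cfg$stages) runStage("tfm", {
    diaPx <- cfg$tfm$beadDiameterUm / beadSim$pixelSizeUm
    ref <- detectBeads(beadSim$reference, diaPx,
                       cfg$tfm$intensityPercentileCut,
                       pixelSizeUm = beadSim$pixelSizeUm)
    def <- detectBeads(beadSim$deformed, diaPx,
                       cfg$tfm$intensityPercentileCut,
                       pixelSizeUm = beadSim$pixelSizeUm)
    links <- linkBeads(ref, def, cfg$tfm$maxDisplacementUm)
    links <- filterOutliers(links)
    extent <- (rev(cfg$tfm$gridShape) - 1) * cfg$tfm$spacingUm
    fld <- interpolateField(links, cfg$tfm$spacingUm, extentUm = extent)
    tr <- invertFTTC(fld, substrate, cfg$tfm$lambda)
    tfmOut <- tr
    xs <- (col(fld@ux) - 1) * fld@spacingUm
    ys <- (row(fld@ux) - 1) * fld@spacingUm
    writeMeasurementTable(
      data.frame(x_um = as.vector(xs), y_um = as.vector(ys),
                 ux_um = as.vector(fld@ux), uy_um = as.vector(fld@uy),
                 tx_Pa = as.vector(tr@tx), ty_Pa = as.vector(tr@ty)),
      put("tfm/traction_grid.csv"), keyColumns = c("y_um", "x_um"))
    saveJSON(list(strain_energy_pJ = strainEnergy(tr),
                  lambda = tr@lambda,
                  grid_shape = dim(tr@tx),
                  n_beads_linked = nrow(links),
                  max_traction_pa = max(tr@magnitude)),
             "tfm/summary.json")
  })

  if ("nucdyn" %in% cfg$stages) runStage("nucdyn", {
    ncfg <- cfg$nucdyn
    curves <- vector("list", ncfg$nNuclei)
    rows <- vector("list", ncfg$nNuclei)
    for (i in seq_len(ncfg$nNuclei)) {
      sim <- simulateNucleusSeries(ncfg$alpha, ncfg$tauMin, ncfg$noiseSd,
                                   ncfg$nFrames, ncfg$frameIntervalMin,
                                   seed = cfg$seed + 100 + i)
      curves[[i]] <- computePCCCurve(
        nucleusPixelSeries(sim$series, sim$mask, register = FALSE),
        ncfg$maxLagFrames, ncfg$frameIntervalMin)
      tb <- curveData(curves[[i]])
      tb$cell_id <- i
      rows[[i]] <- tb
    }
    writeMeasurementTable(do.call(rbind, rows)[, c("cell_id", "lag_min",
                                                   "pcc", "n_pairs")],
                          put("nucdyn/curves.csv"),
                          keyColumns = c("cell_id", "lag_min"))
    mc <- meanPCCCurve(curves)
    writeMeasurementTable(mc$table, put("nucdyn/mean_curve.csv"),
                          keyColumns = "lag_min")
    fit <- fitDecorrelation(mc$curve)
    saveJSON(list(alpha = fit@alpha, tau_min = fit@tauMin, eta = fit@eta,
                  rss = fit@rss, converged = fit@converged,
                  n_cells = ncfg$nNuclei),
             "nucdyn/fit.json")
  })

  if ("morphometry" %in% cfg$stages) runStage("morphometry", {
    labels <- segmentNuclei(fociSim$nucleus)
    counts <- countFoci(fociSim$foci, labels,
                        pixelSizeUm = fociSim$pixelSizeUm)
    writeMeasurementTable(counts, put("morphometry/foci_counts.csv"),
                          keyColumns = "nucleus_id")
    sm <- sproutMetrics(sproutSim$image, sproutSim$pixelSizeUm,
                        coreRemovalRadiusUm = 8)
    saveJSON(list(n_sprouts = sm$n_sprouts,
                  avg_sprout_length_um = sm$avg_sprout_length_um,
                  total_skeleton_length_um = sm$total_skeleton_length_um,
                  truth_mean_um = sproutSim$meanLengthUm),
             "morphometry/sprouts.json")
    gc <- gelContraction(gelSim$frames)
    writeMeasurementTable(gc, put("morphometry/gel_contraction.csv"),
                          keyColumns = "time_days")
  })

  if ("stats" %in% cfg$stages) runStage("stats", {
    dd <- deltaDeltaCt(ctTab, referenceCondition = "FCG")
    writeMeasurementTable(dd, put("stats/fold_changes.csv"),
                          keyColumns = c("gene", "condition"))
    groups <- withSeed(cfg$seed + 29, list(
      fcg = stats::rnorm(40, 10, 2), rf = stats::rnorm(40, 12, 2)))
    tt <- tTestTwoSided(groups$rf, groups$fcg, comparison = "RF vs FCG")
    tt$adjusted_p <- bonferroniAdjust(tt$p_value)
    tt$stars <- significanceStars(tt$adjusted_p)
    writeMeasurementTable(tt, put("stats/t_tests.csv"),
                          keyColumns = "comparison")
  })

  files <- sort(unique(written))
  manifest <- list(
    package = "mechq",
    version = as.character(utils::packageVersion("mechq")),
    seed = cfg$seed,
    stages = cfg$stages,
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(file.path(outDir, files))))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
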