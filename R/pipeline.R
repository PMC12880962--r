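# Configuration-driven orchestration: phantom -> segmentation -> skeleton
# graph -> morphometrics, plus the DWI/ADC, DCE and histology arms, each an
# optional stage of one reproducible run.

pipelineStageNames <- c("phantom", "segment", "graph", "morphometrics",
                        "adc", "dce", "histology")

knownKeys <- list(
  top = c("output_dir", "seed", "stages", pipelineStageNames),
  phantom = c("grid_shape", "spacing", "tree_depth", "root_radius",
              "radius_decay", "segment_length", "tortuosity_amplitude",
              "seed", "vessel_intensity", "parenchyma_intensity",
              "noise_sd"),
  segment = c("low", "high", "connectivity", "seeds"),
  graph = c("min_end_length", "iterations", "smoothing", "attach"),
  morphometrics = character(),
  adc = c("parenchyma_d", "vessel_d", "s0", "b_values", "directions",
          "noise_sd", "seed"),
  dce = c("velocity_cm_per_min", "frame_interval_s", "n_frames",
          "bolus_amplitude", "baseline", "kernel", "threshold_fraction",
          "roi_size", "noise_sd", "seed"),
  histology = c("dispersion", "n_biopsies", "seed", "compare_timepoint"))

checkKeys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
}

cfgGet <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order (phantom ->
#' segmentation -> skeleton graph -> morphometrics; the ADC, DCE and
#' histology arms branch off the phantom), writing every artifact plus the
#' resolved configuration and a log into `output_dir`. Identical
#' configuration and seeds give identical outputs. Unknown configuration
#' keys are rejected; a stage whose upstream artifact is missing fails
#' with an error naming the stage.
#'
#' @param config a YAML file path or an equivalent named list. Top-level
#'   keys: `output_dir`, `seed` (default for every stochastic stage),
#'   `stages` (character vector; default all), and one section per stage
#'   with that stage's parameters.
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths.
#' @examples
#' \dontrun{
#' res <- runPipeline(list(output_dir = tempfile(), seed = 1,
#'                         stages = c("phantom", "segment", "graph",
#'                                    "morphometrics")))
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  checkKeys(config, knownKeys$top, "top level")
  for (st in pipelineStageNames)
    if (!is.null(config[[st]]))
      checkKeys(config[[st]], knownKeys[[st]], sprintf("stage '%s'", st))
  outDir <- cfgGet(config, "output_dir", tempfile("perfusemri_run_"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfgGet(config, "stages", pipelineStageNames)
  bad <- setdiff(stages, pipelineStageNames)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- pipelineStageNames[pipelineStageNames %in% stages]
  globalSeed <- cfgGet(config, "seed", NULL)
  stageSeed <- function(cfg, offset) {
    s <- cfgGet(cfg, "seed", if (!is.null(globalSeed)) globalSeed + offset
                else NULL)
    if (is.null(s))
      stop("every stochastic stage needs a seed (stage or top-level)")
    as.integer(s)
  }
  logLines <- character()
  note <- function(fmt, ...) {
    logLines <<- c(logLines, sprintf(fmt, ...))
  }
  art <- list()
  res <- list()
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop(sprintf("stage '%s' requires the '%s' artifact; run its upstream stage",
                   stage, what))
    res[[what]]
  }

  if ("phantom" %in% stages) {
    pc <- cfgGet(config, "phantom", list())
    spec <- PhantomSpec(
      gridShape = unlist(cfgGet(pc, "grid_shape", c(140, 140, 120))),
      spacing = unlist(cfgGet(pc, "spacing", c(0.83, 0.83, 0.83))),
      treeDepth = cfgGet(pc, "tree_depth", 4),
      rootRadius = cfgGet(pc, "root_radius", 4),
      radiusDecay = cfgGet(pc, "radius_decay", 0.75),
      segmentLength = cfgGet(pc, "segment_length", 16),
      tortuosityAmplitude = cfgGet(pc, "tortuosity_amplitude", 0.8),
      seed = stageSeed(pc, 0L))
    res$spec <- spec
    res$tree <- generateVesselTree(spec)
    res$mask <- rasterizeTree(res$tree, spec)
    res$t2 <- simulateT2Volume(res$mask,
      vesselIntensity = cfgGet(pc, "vessel_intensity", 200),
      parenchymaIntensity = cfgGet(pc, "parenchyma_intensity", 100),
      noiseSd = cfgGet(pc, "noise_sd", 5), seed = stageSeed(pc, 1L))
    art$tree <- writeSpatialGraph(res$tree, file.path(outDir, "tree.json"))
    art$mask <- writeVolume(res$mask, file.path(outDir, "mask.nii.gz"))
    art$t2 <- writeVolume(res$t2, file.path(outDir, "t2.nii.gz"))
    note("phantom: %d segments, %d foreground voxels",
         length(graphSegments(res$tree)), sum(voxelData(res$mask)))
  }

  if ("segment" %in% stages) {
    sc <- cfgGet(config, "segment", list())
    t2 <- need("t2", "segment")
    tree <- need("tree", "segment")
    seeds <- cfgGet(sc, "seeds", NULL)
    if (is.null(seeds)) {
      inletPos <- unlist(graphNodes(tree)[graphNodes(tree)$id ==
                                            inletNode(tree), c("x", "y", "z")])
      seeds <- matrix(worldToVoxel(t2, inletPos), ncol = 3)
    } else seeds <- matrix(unlist(seeds), ncol = 3, byrow = TRUE)
    res$segMask <- regionGrow(t2, seeds,
      low = cfgGet(sc, "low", 150), high = cfgGet(sc, "high", Inf),
      connectivity = cfgGet(sc, "connectivity", 26))
    art$segMask <- writeVolume(res$segMask,
                               file.path(outDir, "segmentation.nii.gz"))
    note("segment: %d voxels segmented", sum(voxelData(res$segMask)))
  }

  if ("graph" %in% stages) {
    gc_ <- cfgGet(config, "graph", list())
    mask <- if (!is.null(res$segMask)) res$segMask else need("mask", "graph")
    res$graph <- extractVesselGraph(mask,
      minEndLength = cfgGet(gc_, "min_end_length", 2),
      iterations = cfgGet(gc_, "iterations", 10),
      smoothing = cfgGet(gc_, "smoothing", 0.5),
      attach = cfgGet(gc_, "attach", 0.25))
    art$graph <- writeSpatialGraph(res$graph, file.path(outDir, "graph.json"))
    art$segments <- writeSegmentCsv(res$graph,
                                    file.path(outDir, "segments.csv"))
    note("graph: %d nodes, %d segments", nrow(graphNodes(res$graph)),
         length(graphSegments(res$graph)))
  }

  if ("morphometrics" %in% stages) {
    g <- need("graph", "morphometrics")
    s <- networkSummary(g)
    res$morphometrics <- s
    out <- s[setdiff(names(s), "segments")]
    if (!is.null(res$mask)) out$mask_volume_mm3 <- maskVolumeMm3(res$mask)
    jsonlite::write_json(out, file.path(outDir, "morphometrics.json"),
                         auto_unbox = TRUE, digits = NA)
    art$morphometrics <- file.path(outDir, "morphometrics.json")
    note("morphometrics: total length %.1f mm", s$total_length_mm)
  }

  if ("adc" %in% stages) {
    ac <- cfgGet(config, "adc", list())
    mask <- need("mask", "adc")
    Dp <- cfgGet(ac, "parenchyma_d", 0.55e-3)
    Dv <- cfgGet(ac, "vessel_d", 2.5e-3)
    Dmap <- array(Dp, dim(voxelData(mask)))
    Dmap[voxelData(mask)] <- Dv
    dwi <- simulateDwi(Dmap, S0 = cfgGet(ac, "s0", 100),
      bValues = unlist(cfgGet(ac, "b_values", c(90, 500, 1500, 2000))),
      directions = cfgGet(ac, "directions", 3),
      noiseSd = cfgGet(ac, "noise_sd", 1), seed = stageSeed(ac, 2L),
      spacing = spacingMm(mask))
    res$adc <- computeAdcMap(dwi)
    res$adcStats <- parenchymaStats(res$adc, vesselMask = mask,
                                    bMinVolume = dwi$volumes[[1]][[1]])
    art$adc <- writeVolume(
      ImageVolume(ifelse(is.na(voxelData(res$adc)), 0, voxelData(res$adc)),
                  spacing = spacingMm(res$adc)),
      file.path(outDir, "adc.nii.gz"))
    jsonlite::write_json(
      list(mean_mm2_per_s = res$adcStats$mean, sd_mm2_per_s = res$adcStats$sd,
           n_voxels = res$adcStats$n),
      file.path(outDir, "adc_stats.json"), auto_unbox = TRUE, digits = NA)
    art$adcStats <- file.path(outDir, "adc_stats.json")
    note("adc: parenchymal mean %.4g mm^2/s", res$adcStats$mean)
  }

  if ("dce" %in% stages) {
    dc <- cfgGet(config, "dce", list())
    tree <- need("tree", "dce")
    mask <- need("mask", "dce")
    vel <- cfgGet(dc, "velocity_cm_per_min", 30)
    dt <- cfgGet(dc, "frame_interval_s", 10)
    res$dce <- simulateDce(tree, mask, velocityCmPerMin = vel,
      frameIntervalS = dt, nFrames = cfgGet(dc, "n_frames", 24),
      bolusAmplitude = cfgGet(dc, "bolus_amplitude", 100),
      baseline = cfgGet(dc, "baseline", 20),
      kernel = cfgGet(dc, "kernel", "step"),
      noiseSd = cfgGet(dc, "noise_sd", 0), seed = stageSeed(dc, 3L))
    res$ttp <- ttpMap(res$dce)
    ttpOut <- voxelData(res$ttp)
    ttpOut[is.na(ttpOut)] <- -1
    art$ttp <- writeVolume(ImageVolume(ttpOut, spacing = spacingMm(res$ttp)),
                           file.path(outDir, "ttp.nii.gz"))
    rootSeg <- graphSegments(tree)[[1]]
    res$front <- trackBolusFront(res$dce, inletPath(tree),
      thresholdFraction = cfgGet(dc, "threshold_fraction", 0.5))
    write.csv(res$front, file.path(outDir, "front.csv"), row.names = FALSE)
    est <- estimateVelocity(res$front)
    dCm <- 2 * mean(rootSeg$radius) / 10
    res$flow <- list(location_label = "inlet", diameter_cm = dCm,
                     velocity_cm_per_min = est$velocity_cm_per_min,
                     sd_cm_per_min = est$sd_cm_per_min,
                     flow_mL_per_min = volumetricFlow(dCm,
                       max(0, est$velocity_cm_per_min)))
    jsonlite::write_json(res$flow, file.path(outDir, "flow.json"),
                         auto_unbox = TRUE, digits = NA)
    art$flow <- file.path(outDir, "flow.json")
    note("dce: estimated velocity %.2f cm/min, flow %.3f mL/min",
         est$velocity_cm_per_min, res$flow$flow_mL_per_min)
  }

  if ("histology" %in% stages) {
    hc <- cfgGet(config, "histology", list())
    res$histology <- simulateHistology(
      dispersion = cfgGet(hc, "dispersion", 0.3),
      nBiopsies = cfgGet(hc, "n_biopsies", 4),
      seed = stageSeed(hc, 4L))
    art$histology <- writeHistologyCsv(res$histology,
                                       file.path(outDir, "histology.csv"))
    summ <- summarizeGroups(res$histology)
    cmp <- compareGroups(res$histology,
                         cfgGet(hc, "compare_timepoint", "30 min"))
    jsonlite::write_json(list(summary = summ, comparison = cmp),
                         file.path(outDir, "histology_report.json"),
                         auto_unbox = TRUE, digits = NA)
    art$histologyReport <- file.path(outDir, "histology_report.json")
    note("histology: 30-min comparison p = %.4f", cmp$p)
  }

  yaml::write_yaml(config, file.path(outDir, "config_resolved.yaml"))
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(list(results = res, artifacts = art, output_dir = outDir,
                 log = logLines))
}
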