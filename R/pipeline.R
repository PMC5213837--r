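#' @include io.R synth-scene.R curvature.R modstats.R
NULL

#' Default pipeline configuration
#'
#' All analysis defaults equal the standard parameterization used
#' throughout the package: streamline length window (10, 300) mm, turning
#' angle 60 degrees, box sizes 2..10, gamma grid 0.6..1.4 step 0.02 with
#' 25 runs, consensus threshold 0.5, and 5 random comparison networks.
#' The `simulate` block holds the synthetic-scene study conditions (see
#' [makeSyntheticScene()]).
#'
#' @param outDir Output directory.
#' @param masterSeed Master seed; all stage seeds derive from it.
#' @return Named list (a pipeline config).
#' @export
defaultPipelineConfig <- function(outDir = "triconnectome-out",
                                  masterSeed = 1L) {
  list(
    paths = list(out_dir = outDir, mesh = NULL, labels = NULL,
                 streamlines = NULL),
    simulate = list(n_subdivisions = 3L, radius = 50, bump_amplitude = 5,
                    bump_frequency = 6L, n_areas = 4L,
                    modules_per_area = 5L, n_streamlines = 5000L,
                    targeting_fidelity = 0.9, endpoint_noise_sd = 0.5,
                    step = 0.625, invalid_fraction = 0.05,
                    pair_rule = "random"),
    filter = list(min_length = 10, max_length = 300, max_angle = 60),
    boxcover = list(ell_min = 2L, ell_max = 10L),
    modularity = list(gamma_min = 0.6, gamma_max = 1.4, gamma_step = 0.02,
                      n_runs = 25L, tau = 0.5, n_random = 5L),
    master_seed = as.integer(masterSeed),
    log_level = "info")
}

#' Read, validate and write pipeline configs (YAML)
#'
#' Unset fields are filled from [defaultPipelineConfig()]; field types and
#' ranges are validated (positive lengths, `gamma_min < gamma_max`,
#' probabilities in [0, 1]).
#'
#' @param path YAML file path.
#' @param config A config list.
#' @return `readPipelineConfig` returns the validated config list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  merged <- utils::modifyList(def, raw)
  validatePipelineConfig(merged)
  merged
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validatePipelineConfig <- function(cfg) {
  f <- cfg$filter
  stopIfNot(is.numeric(f$min_length) && f$min_length >= 0,
            "filter$min_length must be a nonnegative number")
  stopIfNot(f$max_length > f$min_length,
            "filter$max_length must exceed min_length")
  stopIfNot(f$max_angle > 0 && f$max_angle <= 180,
            "filter$max_angle must lie in (0, 180]")
  b <- cfg$boxcover
  stopIfNot(b$ell_min >= 2 && b$ell_max >= b$ell_min,
            "boxcover ell range must satisfy 2 <= ell_min <= ell_max")
  m <- cfg$modularity
  stopIfNot(m$gamma_min < m$gamma_max && m$gamma_step > 0,
            "modularity gamma grid must have gamma_min < gamma_max, step > 0")
  stopIfNot(m$n_runs >= 1 && m$n_random >= 0,
            "modularity n_runs must be >= 1 and n_random >= 0")
  stopIfNot(m$tau >= 0 && m$tau <= 1, "modularity tau must lie in [0, 1]")
  s <- cfg$simulate
  stopIfNot(s$targeting_fidelity >= 0 && s$targeting_fidelity <= 1,
            "simulate$targeting_fidelity must lie in [0, 1]")
  stopIfNot(is.numeric(cfg$master_seed), "master_seed must be an integer")
  invisible(TRUE)
}

pipelineLog <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[triconnectome] ", ...)
}

writeJSONOut <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# ---- pipeline -----------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes the stages simulate, build, boxcover, modules and modstats in
#' order, writing every stage's outputs plus a manifest
#' (`manifest.json`: parameters, derived seeds, input checksums, per-stage
#' wall time) under `config$paths$out_dir`. With `resume = TRUE`, stages
#' whose manifest entry is complete and whose outputs still exist are
#' skipped. All numeric outputs are deterministic functions of the config
#' and `master_seed`.
#'
#' When `config$paths$mesh` is set, the mesh (OFF or PLY by extension),
#' labels TSV and streamlines (TCK or `.txt` polylines) are read instead
#' of simulated.
#'
#' @param config Config list (see [defaultPipelineConfig()]).
#' @param resume Skip completed stages recorded in the manifest.
#' @param upTo Last stage to execute (`"simulate"`, `"build"`,
#'   `"boxcover"`, `"modules"` or `"modstats"`, the default - i.e. run
#'   everything).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, resume = FALSE, upTo = "modstats") {
  stopIfNot(upTo %in% c("simulate", "build", "boxcover", "modules",
                        "modstats"), "unknown upTo stage")
  validatePipelineConfig(config)
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(out, "manifest.json")
  manifest <- if (resume && file.exists(manifestPath)) {
    jsonlite::read_json(manifestPath)
  } else {
    list(package = "triconnectome",
         version = as.character(utils::packageVersion("triconnectome")),
         master_seed = config$master_seed, stages = list())
  }
  seed <- config$master_seed

  outputsOf <- list(
    simulate = c("mesh.off", "labels.tsv", "streamlines.tck",
                 "scene.json"),
    build = c("network.mtx", "nodes.tsv", "rejections.json",
              "classification.tsv"),
    boxcover = c("boxcount.tsv", "fractal_fit.json"),
    modules = c("partition.tsv", "gamma_scan.tsv", "modules.json"),
    modstats = c("module_pairs.tsv", "targeting.json",
                 "density_histogram.tsv"))
  stageDone <- function(st) {
    e <- manifest$stages[[st]]
    !is.null(e) && identical(e$status, "complete") &&
      all(file.exists(file.path(out, unlist(outputsOf[[st]]))))
  }
  runStage <- function(st, fun, load = NULL) {
    if (resume && stageDone(st)) {
      pipelineLog(config, "stage ", st, ": complete, skipped (resume)")
      if (!is.null(load)) load()
      return(invisible())
    }
    pipelineLog(config, "stage ", st, ": start (seed ",
                deriveSeed(seed, st), ")")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage %s failed: %s", st, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[st]] <<- list(
      status = "complete",
      seed = deriveSeed(seed, st),
      outputs = as.list(unlist(outputsOf[[st]])),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    writeJSONOut(manifest, manifestPath)
    invisible()
  }

  env <- new.env()

  loadSimulate <- function() {
    lab <- readLabelsTSV(file.path(out, "labels.tsv"))
    mesh <- readMeshOFF(file.path(out, "mesh.off"),
                        areaLabels = lab$area)
    env$mesh <- mesh
    env$planted <- if (!is.null(lab$module)) lab$module else NULL
    env$streamlines <- readTCK(file.path(out, "streamlines.tck"))
  }
  loadBuild <- function() {
    nodes <- readNodeTableTSV(file.path(out, "nodes.tsv"))
    env$network <- readNetworkMM(
      file.path(out, "network.mtx"),
      nodes = data.frame(area = nodes$area, x = nodes$x, y = nodes$y,
                         z = nodes$z, stringsAsFactors = FALSE))
    cls <- utils::read.table(file.path(out, "classification.tsv"),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    env$classification <- list(classOfTriangle = cls$class,
                               meanCurvature = cls$H,
                               gaussianCurvature = cls$K)
  }
  loadModules <- function() {
    part <- utils::read.table(file.path(out, "partition.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    env$modules <- list(
      modules = data.frame(node = part$node + 1L, area = part$area,
                           module = part$module,
                           stringsAsFactors = FALSE),
      unassigned = part$node[is.na(part$module)] + 1L,
      scans = NULL)
  }

  runStage("simulate", function() {
    if (!is.null(config$paths$mesh)) {
      meshPath <- config$paths$mesh
      mesh <- if (grepl("\\.ply$", meshPath, ignore.case = TRUE))
        readMeshPLY(meshPath) else readMeshOFF(meshPath)
      lab <- readLabelsTSV(config$paths$labels)
      mesh@areaLabels <- lab$area
      sl <- if (grepl("\\.tck$", config$paths$streamlines,
                      ignore.case = TRUE))
        readTCK(config$paths$streamlines)
      else readPolylines(config$paths$streamlines)
      env$scene <- NULL
      env$mesh <- mesh
      env$streamlines <- sl
      env$planted <- if (!is.null(lab$module)) lab$module else NULL
      manifest$inputs <<- as.list(tools::md5sum(
        c(meshPath, config$paths$labels, config$paths$streamlines)))
    } else {
      s <- config$simulate
      scene <- makeSyntheticScene(
        nSubdivisions = s$n_subdivisions, radius = s$radius,
        bumpAmplitude = s$bump_amplitude,
        bumpFrequency = s$bump_frequency, nAreas = s$n_areas,
        modulesPerArea = s$modules_per_area,
        nStreamlines = s$n_streamlines,
        targetingFidelity = s$targeting_fidelity,
        endpointNoiseSd = s$endpoint_noise_sd, step = s$step,
        invalidFraction = s$invalid_fraction, pairRule = s$pair_rule,
        seed = deriveSeed(seed, "simulate"))
      env$scene <- scene
      env$mesh <- scene@mesh
      env$streamlines <- scene@streamlines
      env$planted <- scene@plantedModules
    }
    writeMeshOFF(env$mesh, file.path(out, "mesh.off"))
    writeLabelsTSV(areaLabels(env$mesh), file.path(out, "labels.tsv"),
                   module = env$planted)
    writeTCK(env$streamlines, file.path(out, "streamlines.tck"))
    writeJSONOut(list(params = config$simulate,
                      seed = deriveSeed(seed, "simulate"),
                      n_streamlines = nStreamlines(env$streamlines),
                      simulated = is.null(config$paths$mesh)),
                 file.path(out, "scene.json"))
  }, load = loadSimulate)
  if (upTo == "simulate") return(invisible(manifest))

  runStage("build", function() {
    f <- config$filter
    filt <- filterStreamlines(env$streamlines, minLength = f$min_length,
                              maxLength = f$max_length,
                              maxAngle = f$max_angle)
    centers <- triangleCenters(env$mesh)
    snap <- mapEndpoints(filt$kept, centers)
    adj <- triangleAdjacency(env$mesh)
    asm <- assembleNetwork(adj, snap$edges, nTriangles(env$mesh),
                           area = areaLabels(env$mesh), centers = centers)
    env$network <- asm$network
    env$filt <- filt
    env$snap <- snap
    cls <- classifySurface(env$mesh)
    env$classification <- cls
    writeNetworkMM(env$network, file.path(out, "network.mtx"))
    writeNodeTableTSV(env$network, file.path(out, "nodes.tsv"))
    writeJSONOut(list(counts = as.list(filt$counts),
                      n_self_loops = snap$nSelfLoops,
                      n_unsnapped = snap$nUnsnapped,
                      n_overlap_local_longrange = asm$nOverlap,
                      N = nNodes(env$network), k = nEdges(env$network)),
                 file.path(out, "rejections.json"))
    df <- data.frame(triangle_id = seq_len(nTriangles(env$mesh)) - 1L,
                     class = cls$classOfTriangle,
                     H = sprintf("%.10g", cls$meanCurvature),
                     K = sprintf("%.10g", cls$gaussianCurvature))
    utils::write.table(df, file.path(out, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, load = loadBuild)
  if (upTo == "build") return(invisible(manifest))

  runStage("boxcover", function() {
    b <- config$boxcover
    curve <- boxcountCurve(env$network, ellRange = b$ell_min:b$ell_max,
                           seed = deriveSeed(seed, "boxcover"))
    fit <- fitFractalDimension(curve, nNodes(env$network))
    env$fit <- fit
    utils::write.table(
      data.frame(ell_B = curve$ell, N_B = curve$nB,
                 N_B_over_N = sprintf("%.10g", curve$nBOverN)),
      file.path(out, "boxcount.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeJSONOut(list(d_B = fit@dB, stderr = fit@stderr,
                      r_squared = fit@rSquared,
                      fit_range = fit@fitRange, N = fit@nNodes),
                 file.path(out, "fractal_fit.json"))
  })
  if (upTo == "boxcover") return(invisible(manifest))

  runStage("modules", function() {
    m <- config$modularity
    grid <- seq(m$gamma_min, m$gamma_max, by = m$gamma_step)
    wam <- withinAreaModules(env$network, gammaGrid = grid,
                             nRuns = m$n_runs,
                             seed = deriveSeed(seed, "modules"),
                             tau = m$tau)
    env$modules <- wam
    utils::write.table(
      data.frame(node = wam$modules$node - 1L, area = wam$modules$area,
                 module = wam$modules$module),
      file.path(out, "partition.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    scanTab <- do.call(rbind, lapply(names(wam$scans), function(a) {
      s <- wam$scans[[a]]
      data.frame(area = a, gamma = s@gammaGrid,
                 Q_net_mean = sprintf("%.10g", s@QNet),
                 Q_rand_mean = sprintf("%.10g", s@QRand),
                 Q_MAX = sprintf("%.10g", s@QMax))
    }))
    utils::write.table(scanTab, file.path(out, "gamma_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeJSONOut(list(
      gamma_star = lapply(wam$scans, function(s) s@gammaStar),
      module_counts = lapply(wam$scans, function(s)
        length(unique(s@consensus@membership))),
      n_unassigned = length(wam$unassigned)),
      file.path(out, "modules.json"))
  }, load = loadModules)
  if (upTo == "modules") return(invisible(manifest))

  runStage("modstats", function() {
    m <- config$modularity
    grid <- seq(m$gamma_min, m$gamma_max, by = m$gamma_step)
    cmp <- compareToRandom(env$network, dataModules = env$modules,
                           gammaGrid = grid, nRuns = m$n_runs,
                           tau = m$tau, nRandom = m$n_random,
                           seed = deriveSeed(seed, "modstats"))
    tab <- modulePairTable(cmp$dataStats)
    tab$density <- sprintf("%.10g", tab$density)
    utils::write.table(tab, file.path(out, "module_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cent <- moduleCentroids(env$network, env$modules$modules$module)
    dassoc <- distanceAssociation(modulePairTable(cmp$dataStats), cent,
                                  nPermutations = 2000L,
                                  seed = deriveSeed(seed, "distperm"))
    gpref <- gyralPreference(modulePairTable(cmp$dataStats),
                             env$classification$classOfTriangle,
                             env$modules$modules$module)
    writeJSONOut(list(
      summary = cmp$summary,
      effect_size_measures = list(distance = "rank-biserial",
                                  curvature_class = "cramers_v"),
      distance_association = list(effect_size = dassoc$effectSize,
                                  p_value = dassoc$pValue,
                                  n_permutations = dassoc$nPermutations),
      curvature_preference = list(effect_size = gpref$effectSize,
                                  table = as.list(as.data.frame(gpref$table))),
      seeds = list(modstats = deriveSeed(seed, "modstats"))),
      file.path(out, "targeting.json"))
    hist <- densityHistogram(cmp$data$nonzeroDensities)
    utils::write.table(
      data.frame(bin_low = sprintf("%.10g", hist$binLow),
                 bin_high = sprintf("%.10g", hist$binHigh),
                 count = hist$count),
      file.path(out, "density_histogram.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  })

  pipelineLog(config, "pipeline complete: ", out)
  invisible(manifest)
}
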