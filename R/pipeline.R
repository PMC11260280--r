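## End-to-end analysis pipeline: cohort (synthetic or from disk) ->
## correspondence -> crop -> rigid GPA -> three shape models (femur,
## tibia, tibiofemoral joint) -> group statistics -> outcome prediction.
## All numeric outputs are deterministic given the configuration; stage
## timings go to the log and manifest only, so repeated runs produce
## byte-identical numeric files.

#' Pipeline configuration
#'
#' @param outDir report directory (created if missing).
#' @param cohort a [cohortSpec()] describing the synthetic cohort, or
#'   NULL when loading data from disk via `inputDir`.
#' @param inputDir directory with `femur/`, `tibia/` mesh subdirectories
#'   (PLY), `records.csv`, and `femur_template.ply` / `tibia_template.ply`
#'   plus mask JSONs; only used when `cohort` is NULL.
#' @param varianceThreshold cumulative explained-variance ratio used to
#'   retain modes (default 0.98).
#' @param sigLevel significance level (0.05).
#' @param koosSplit KOOS pain split between groups (75).
#' @param nBoot bootstrap iterations for prediction CIs (1000).
#' @param bootSeed bootstrap seed.
#' @param registration a [registrationParams()].
#' @param maxGenModes cap on the generalization-curve mode count.
#' @param predictorModes predictor mode count for the classifiers;
#'   `NULL` uses each model's `varianceThreshold` mode count.
#' @param ridge ridge penalty for the logistic classifiers.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(outDir, cohort = cohortSpec(), inputDir = NULL,
                           varianceThreshold = 0.98, sigLevel = 0.05,
                           koosSplit = 75, nBoot = 1000, bootSeed = 1,
                           registration = registrationParams(),
                           maxGenModes = 20, predictorModes = NULL,
                           ridge = 1e-4) {
  if (varianceThreshold <= 0 || varianceThreshold >= 1)
    stop("varianceThreshold must lie in (0, 1)")
  if (sigLevel <= 0 || sigLevel >= 1) stop("sigLevel must lie in (0, 1)")
  cfg <- list(outDir = outDir, cohort = cohort, inputDir = inputDir,
              varianceThreshold = varianceThreshold, sigLevel = sigLevel,
              koosSplit = koosSplit, nBoot = nBoot, bootSeed = bootSeed,
              registration = registration, maxGenModes = maxGenModes,
              predictorModes = predictorModes, ridge = ridge)
  class(cfg) <- "pipelineConfig"
  cfg
}

.writeCSV <- function(x, path) {
  write.csv(format(as.data.frame(x), digits = 12, trim = TRUE,
                   scientific = FALSE), path, row.names = FALSE, quote = FALSE)
}

.loadInputs <- function(cfg, log) {
  if (!is.null(cfg$cohort)) {
    log("cohort: generating synthetic cohort (seed ", cfg$cohort$seed, ")")
    return(generateCohort(cfg$cohort))
  }
  if (is.null(cfg$inputDir)) stop("config needs either a cohort spec or inputDir")
  log("cohort: loading from ", cfg$inputDir)
  records <- readRecords(file.path(cfg$inputDir, "records.csv"))
  readBone <- function(bone) {
    dirp <- file.path(cfg$inputDir, bone)
    files <- sort(list.files(dirp, pattern = "\\.(ply|stl|obj)$",
                             full.names = TRUE))
    lapply(files, readMesh)
  }
  mkTpl <- function(bone) {
    mesh <- readMesh(file.path(cfg$inputDir, sprintf("%s_template.ply", bone)))
    maskFile <- file.path(cfg$inputDir, sprintf("%s_mask.json", bone))
    include <- if (file.exists(maskFile)) {
      mk <- jsonlite::read_json(maskFile, simplifyVector = TRUE)
      seq_len(nrow(mesh@vertices)) %in% mk$include
    } else rep(TRUE, nrow(mesh@vertices))
    list(mesh = mesh, mask = VertexMask(include, templateId = mesh@name))
  }
  list(femur = readBone("femur"), tibia = readBone("tibia"),
       records = records, groundTruth = NULL,
       templates = list(femur = mkTpl("femur"), tibia = mkTpl("tibia")),
       spec = NULL)
}

.registerAll <- function(template, targets, params, log, stage) {
  lapply(targets, function(tg) {
    res <- registerTemplate(template, tg, params, details = TRUE)
    log(sprintf("%s: %s mean %.3f mm max %.3f mm (rigid iters %d)",
                stage, tg@name, res$meanDistance, res$maxDistance,
                res$rigidIterations))
    res$shape
  })
}

#' Run the full morphology-outcome analysis pipeline
#'
#' Executes correspondence, cropping, rigid alignment, shape-model
#' construction for femur, tibia and the combined tibiofemoral joint,
#' group statistics, and leave-one-out outcome prediction, writing a
#' report bundle of CSV/JSON files plus PLY mode-shape meshes to the
#' configured output directory. Any stage failure halts the pipeline with
#' a stage-attributed error.
#'
#' @param config a [pipelineConfig()], or the path to a YAML file with
#'   the same fields.
#' @return invisibly, a list with the three shape models, PC weights,
#'   statistics tables and [PredictionResult-class]s.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- .configFromYAML(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(config$outDir, "log.txt")
  cat("", file = logFile)
  t0 <- Sys.time()
  log <- function(...) cat(paste0(...), "\n", file = logFile, append = TRUE,
                           sep = "")
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log(sprintf("stage %s done in %.1f s", name,
                as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    out
  }

  inputs <- stage("input", .loadInputs(config, log))
  records <- inputs$records
  n <- nrow(records)
  .writeCSV(records, file.path(config$outDir, "records.csv"))

  corrF <- stage("correspond_femur",
    .registerAll(inputs$templates$femur$mesh, inputs$femur,
                 config$registration, log, "correspond femur"))
  corrT <- stage("correspond_tibia",
    .registerAll(inputs$templates$tibia$mesh, inputs$tibia,
                 config$registration, log, "correspond tibia"))

  cropF <- stage("crop", lapply(corrF, cropRegion,
                                mask = inputs$templates$femur$mask))
  cropT <- lapply(corrT, cropRegion, mask = inputs$templates$tibia$mask)

  alignedF <- stage("align_femur", gpaRigid(cropF))
  alignedT <- stage("align_tibia", gpaRigid(cropT))
  joint <- stage("assemble_joint", gpaRigid(assembleJoint(alignedF, alignedT)))

  sets <- list(femur = alignedF, tibia = alignedT, joint = joint)
  models <- list(); weights <- list(); predictions <- list()
  for (nm in names(sets)) {
    model <- stage(paste0("ssm_", nm), buildShapeModel(sets[[nm]]))
    models[[nm]] <- model
    comp <- modelCompactness(model)
    .writeCSV(comp, file.path(config$outDir, sprintf("compactness_%s.csv", nm)))
    gen <- stage(paste0("generalization_", nm),
      generalizationLOO(sets[[nm]], maxModes = min(config$maxGenModes, n - 2L)))
    .writeCSV(gen, file.path(config$outDir, sprintf("generalization_%s.csv", nm)))
    for (m in 1:3) {
      shp <- modeShapes(model, m, c(-2, 2))
      writeMesh(asTriangleMesh(shp[[1L]]),
                file.path(config$outDir, sprintf("mode%d_minus2sd_%s.ply", m, nm)))
      writeMesh(asTriangleMesh(shp[[2L]]),
                file.path(config$outDir, sprintf("mode%d_plus2sd_%s.ply", m, nm)))
    }
    W <- do.call(rbind, lapply(sets[[nm]]@shapes, function(s)
      projectShape(model, s)))
    weights[[nm]] <- W
    wdf <- data.frame(patient_id = records$patient_id, group = records$group,
                      W[, 1:min(10, ncol(W)), drop = FALSE])
    names(wdf)[-(1:2)] <- sprintf("pc%d", 1:min(10, ncol(W)))
    .writeCSV(wdf, file.path(config$outDir, sprintf("weights_%s.csv", nm)))
    k <- if (is.null(config$predictorModes))
      modesForVariance(model, config$varianceThreshold) else config$predictorModes
    log(sprintf("ssm_%s: %d modes at %.0f%% variance; predictors = %d",
                nm, modesForVariance(model, config$varianceThreshold),
                100 * config$varianceThreshold, k))
    predictions[[nm]] <- stage(paste0("predict_", nm),
      predictOutcome(W, as.integer(records$group == "R"),
                     nModes = min(k, ncol(W)), ridge = config$ridge,
                     nBoot = config$nBoot, seed = config$bootSeed,
                     modelName = nm))
    .writeCSV(predictionMetrics(predictions[[nm]]),
              file.path(config$outDir, sprintf("prediction_metrics_%s.csv", nm)))
    .writeCSV(data.frame(patient_id = records$patient_id,
                         label = predictions[[nm]]@labels,
                         probability = predictions[[nm]]@probabilities,
                         predicted = predictions[[nm]]@predicted),
              file.path(config$outDir, sprintf("prediction_patients_%s.csv", nm)))
    .writeCSV(rocCurve(predictions[[nm]]@probabilities, predictions[[nm]]@labels),
              file.path(config$outDir, sprintf("roc_%s.csv", nm)))
  }

  demo <- stage("stats", compareDemographics(records))
  .writeCSV(demo, file.path(config$outDir, "table1_demographics.csv"))
  welch <- do.call(rbind, lapply(names(weights), function(nm) {
    do.call(rbind, lapply(1:3, function(m) {
      wt <- welchTest(weights[[nm]][records$group == "R", m],
                      weights[[nm]][records$group == "MPMS", m])
      data.frame(model = nm, mode = m, t = wt$t, df = wt$df, p = wt$p,
                 significant = wt$p < config$sigLevel)
    }))
  }))
  .writeCSV(welch, file.path(config$outDir, "welch_pc_weights.csv"))
  vars <- morphologyVariables(records, femur = weights$femur,
                              tibia = weights$tibia, joint = weights$joint)
  cm <- correlationMatrix(vars)
  .writeCSV(cbind(variable = rownames(cm$r), as.data.frame(round(cm$r, 4))),
            file.path(config$outDir, "correlation_r.csv"))
  .writeCSV(cbind(variable = rownames(cm$masked),
                  as.data.frame(round(cm$masked, 4))),
            file.path(config$outDir, "correlation_masked.csv"))

  manifest <- list(
    package = "kneeSSM",
    version = as.character(utils::packageVersion("kneeSSM")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    n_patients = n,
    seeds = list(cohort = if (!is.null(inputs$spec)) inputs$spec$seed else NULL,
                 bootstrap = config$bootSeed),
    config_hash = .hashConfig(config),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log("pipeline complete")
  invisible(list(models = models, weights = weights,
                 predictions = predictions, demographics = demo,
                 welch = welch, correlations = cm, records = records,
                 sets = sets, inputs = inputs))
}

.hashConfig <- function(config) {
  cfg <- config
  cfg$outDir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

.configFromYAML <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohortSpec, y$cohort) else NULL
  reg <- if (!is.null(y$registration)) do.call(registrationParams, y$registration)
         else registrationParams()
  args <- y[setdiff(names(y), c("cohort", "registration"))]
  do.call(pipelineConfig, c(args, list(cohort = cohort, registration = reg)))
}
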