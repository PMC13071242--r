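# End-to-end pipeline: fixtures/input -> featurize -> select -> split ->
# train -> evaluate -> predict, with a JSON run manifest and per-stage
# caching keyed by config/input fingerprints.

.allowedTopKeys <- c("seed", "outDir", "stages", "soap", "fixtures", "input",
                     "select", "split", "train", "predict")
.allStages <- c("fixtures", "featurize", "select", "split", "train",
                "evaluate", "predict")

.subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647)
}

.fingerprint <- function(obj, files = character(0)) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  hashes <- unname(tools::md5sum(c(tmp, files[file.exists(files)])))
  paste(hashes, collapse = "+")
}

.validateConfig <- function(cfg) {
  bad <- setdiff(names(cfg), .allowedTopKeys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.allowedTopKeys, collapse = ", "))
  stages <- cfg$stages
  if (is.null(stages)) stages <- .allStages
  badStage <- setdiff(stages, .allStages)
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  model <- cfg$train$model
  if (!is.null(model) && !model %in% registeredModels())
    stop("unknown model '", model, "'; registered: ",
         paste(registeredModels(), collapse = ", "))
  if (is.null(cfg$fixtures) && is.null(cfg$input) &&
      any(c("fixtures", "featurize") %in% stages))
    stop("config needs either a 'fixtures' or an 'input' section")
  if (!is.null(cfg$predict) && "predict" %in% stages) {
    lookupSolvent(cfg$predict$solvent %||% stop("predict.solvent missing"))
  }
  stages
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default-filled pipeline settings; the descriptor defaults are the
# zinc-complex settings used throughout the package
.pipelineDefaults <- function(cfg) {
  soap <- cfg$soap
  cfg$soap <- list(
    rCut = soap$rCut %||% 6, nMax = soap$nMax %||% 8L,
    lMax = soap$lMax %||% 6L, sigmaAtom = soap$sigmaAtom %||% 1.0,
    rbf = soap$rbf %||% "gto", cutoffWidth = soap$cutoffWidth %||% 0.5,
    species = soap$species %||% NULL)
  sel <- cfg$select
  cfg$select <- list(k = sel$k %||% 3L, perCluster = sel$perCluster %||% 15L,
                     pcaComponents = sel$pcaComponents %||% 10L,
                     pooling = sel$pooling %||% "mean")
  cfg$split <- list(testFraction = cfg$split$testFraction %||% 0.2)
  tr <- cfg$train
  cfg$train <- list(model = tr$model %||% "gbt", folds = tr$folds %||% 5L,
                    grid = tr$grid %||% NULL)
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Run the shift-prediction pipeline from a config
#'
#' Executes the requested stages in order: \code{fixtures} (or external
#' input), \code{featurize}, \code{select}, \code{split}, \code{train},
#' \code{evaluate}, \code{predict}.  Stage outputs land in
#' \code{cfg$outDir}; a JSON manifest records the config snapshot, input
#' fingerprints, per-stage outputs and timings.  Deterministic stages are
#' cached: a rerun with an unchanged config and inputs skips any stage whose
#' fingerprint matches the previous manifest.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized top-level keys: \code{seed}, \code{outDir}, \code{stages},
#'   \code{soap}, \code{fixtures} (\code{nMolecules}, \code{atomsRange},
#'   \code{solvents}, \code{noiseSigma}), \code{input} (\code{xyz},
#'   \code{shifts}), \code{select} (\code{k}, \code{perCluster},
#'   \code{pcaComponents}), \code{split} (\code{testFraction}), \code{train}
#'   (\code{model}, \code{folds}, \code{grid}), \code{predict}
#'   (\code{solvent}).
#' @param seed Optional integer overriding \code{cfg$seed}.
#' @return The run manifest (named list), invisibly written to
#'   \code{outDir/manifest.json}.
#' @export
runPipeline <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- .validateConfig(cfg)
  cfg <- .pipelineDefaults(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outDir <- cfg$outDir %||% stop("config needs an outDir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  manifestPath <- file.path(outDir, "manifest.json")
  oldManifest <- if (file.exists(manifestPath))
    jsonlite::fromJSON(manifestPath, simplifyVector = FALSE) else NULL
  manifest <- list(
    config = cfg,
    versions = list(
      SoapShift = as.character(utils::packageVersion("SoapShift")),
      R = R.version.string),
    stages = list())

  cached <- function(stage, fp) {
    old <- oldManifest$stages[[stage]]
    !is.null(old) && identical(old$fingerprint, fp) &&
      all(file.exists(unlist(old$outputs)))
  }
  record <- function(stage, fp, outputs, seconds, skipped = FALSE) {
    manifest$stages[[stage]] <<- list(fingerprint = fp, outputs = outputs,
                                      seconds = round(seconds, 3),
                                      cached = skipped)
  }

  state <- new.env(parent = emptyenv())
  xyzPath <- file.path(outDir, "structures.xyz")
  shiftPath <- file.path(outDir, "shifts.csv")

  # -- fixtures / input -------------------------------------------------------
  if ("fixtures" %in% stages && !is.null(cfg$fixtures)) {
    fx <- cfg$fixtures
    fp <- .fingerprint(list(fx = fx, seed = cfg$seed))
    t0 <- proc.time()[3]
    if (cached("fixtures", fp)) {
      record("fixtures", fp, list(xyzPath, shiftPath), 0, TRUE)
    } else {
      structures <- makeToyComplexes(
        fx$nMolecules %||% 50L,
        as.integer(fx$atomsRange %||% c(8L, 14L)),
        seed = .subSeed(cfg$seed, 1L))
      params <- fixtureParams(noiseSigma = fx$noiseSigma %||% 0.05)
      tab <- makeFixtureShiftTable(
        structures,
        solvents = fx$solvents %||% c("acetone", "chloroform", "DMSO",
                                      "MeOH", "THF"),
        params = params, noiseSeed = .subSeed(cfg$seed, 2L))
      writeXYZ(structures, xyzPath)
      writeShiftTable(tab, shiftPath)
      record("fixtures", fp, list(xyzPath, shiftPath), proc.time()[3] - t0)
    }
  } else if (!is.null(cfg$input)) {
    xyzPath <- cfg$input$xyz
    shiftPath <- cfg$input$shifts
  }
  state$structures <- filterNeutralZinc(readXYZ(xyzPath))
  state$records <- loadShiftTable(shiftPath, state$structures)

  # -- featurize --------------------------------------------------------------
  species <- cfg$soap$species %||%
    unique(unlist(lapply(state$structures, function(s) s@elements)))
  soapCfg <- soapConfig(species, rCut = cfg$soap$rCut, nMax = cfg$soap$nMax,
                        lMax = cfg$soap$lMax, sigmaAtom = cfg$soap$sigmaAtom,
                        rbf = cfg$soap$rbf,
                        cutoffWidth = cfg$soap$cutoffWidth)
  descPath <- file.path(outDir, "descriptors.csv")
  if ("featurize" %in% stages) {
    fp <- .fingerprint(cfg$soap, c(xyzPath, shiftPath))
    t0 <- proc.time()[3]
    state$descriptors <- computeSoap(state$structures, soapCfg,
                                     centers = "hydrogen")
    record("featurize", fp, list(), proc.time()[3] - t0)
  }

  # -- select (representative sampling + validation) -------------------------
  if ("select" %in% stages) {
    sel <- cfg$select
    fp <- .fingerprint(list(sel = sel, seed = cfg$seed), xyzPath)
    t0 <- proc.time()[3]
    M <- do.call(rbind, lapply(state$structures, moleculeDescriptor,
                               config = soapCfg, pooling = sel$pooling))
    ids <- vapply(state$structures, function(s) s@moleculeId, "")
    km <- kmeansFit(M, sel$k, seed = .subSeed(cfg$seed, 3L))
    picked <- selectRepresentatives(km, ids, sel$perCluster,
                                    seed = .subSeed(cfg$seed, 4L))
    ncomp <- min(sel$pcaComponents, nrow(M) - 1L, ncol(M))
    pca <- pcaProject(M, ncomp)
    rep_scores <- pcaTransform(pca, M[ids %in% picked, , drop = FALSE])
    report <- ksValidate(rep_scores, pca$scores)
    report$diversityRatio <- diversityRatio(
      M[ids %in% picked, , drop = FALSE], M,
      seed = .subSeed(cfg$seed, 5L))
    selPath <- file.path(outDir, "selection.json")
    jsonlite::write_json(
      list(selected = picked, clusterSizes = tabulate(km@labels + 1L, km@k),
           ks = report$ksStats, nSignificant = report$nSignificant,
           diversityRatio = report$diversityRatio,
           diversityDefinition = report$diversityDefinition),
      selPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    state$selected <- picked
    record("select", fp, list(selPath), proc.time()[3] - t0)
  }

  # -- split / train / evaluate ----------------------------------------------
  if (any(c("split", "train", "evaluate") %in% stages)) {
    state$features <- assembleFeatures(state$descriptors, state$records)
    state$plan <- moleculeLevelSplit(state$features,
                                     cfg$split$testFraction,
                                     seed = .subSeed(cfg$seed, 6L))
  }
  if (any(c("train", "evaluate") %in% stages)) {
    t0 <- proc.time()[3]
    state$model <- tuneAndTrain(cfg$train$model, state$features, state$plan,
                                folds = cfg$train$folds,
                                grid = cfg$train$grid,
                                seed = .subSeed(cfg$seed, 7L),
                                config = soapCfg)
    fitSeconds <- proc.time()[3] - t0
    reportPath <- file.path(outDir, "report.json")
    if ("evaluate" %in% stages) {
      rep <- evaluateBySolvent(state$features, state$plan, state$model,
                               fitSeconds = fitSeconds)
      jsonlite::write_json(
        list(model = rep@modelName, maePpm = rep@maePpm,
             rmsePpm = rep@rmsePpm, r2 = rep@r2,
             fitSeconds = rep@fitSeconds, bestParams = state$model@bestParams,
             cvMae = state$model@cvMae,
             trainMolecules = length(state$plan@trainMolecules),
             testMolecules = length(state$plan@testMolecules),
             perSolvent = rep@perSolvent,
             seeds = list(pipeline = cfg$seed,
                          split = .subSeed(cfg$seed, 6L),
                          train = .subSeed(cfg$seed, 7L))),
        reportPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      state$report <- rep
      record("evaluate",
             .fingerprint(list(cfg$train, cfg$split, seed = cfg$seed)),
             list(reportPath), fitSeconds)
    }
  }

  # -- predict ----------------------------------------------------------------
  if ("predict" %in% stages && !is.null(cfg$predict)) {
    t0 <- proc.time()[3]
    preds <- predictShifts(state$model, state$structures,
                           cfg$predict$solvent)
    predPath <- file.path(outDir, "predictions.csv")
    writeShiftTable(preds, predPath)
    record("predict", .fingerprint(cfg$predict), list(predPath),
           proc.time()[3] - t0)
  }

  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$state <- state
  invisible(manifest)
}
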