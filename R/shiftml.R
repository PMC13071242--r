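# Shift regression: TMS referencing, feature assembly (SOAP + dielectric),
# leakage-free molecule-level splitting, grouped cross-validation over a
# registry of regression backends, and evaluation overall and per solvent.

#' Convert isotropic shieldings to TMS-referenced chemical shifts
#'
#' delta = sigma(TMS) - sigma, with the TMS reference shielding computed (or
#' supplied) per solvent because the reference is solvent-dependent at any
#' fixed level of theory.
#'
#' @param sigmaPpm Numeric vector of isotropic shieldings, ppm.
#' @param sigmaTmsPpm TMS reference shielding(s), ppm; scalar or vector
#'   recycled against \code{sigmaPpm}.
#' @return Chemical shifts delta, ppm.
#' @examples
#' shieldingToShift(24.50, 31.70)  # 7.20
#' @export
shieldingToShift <- function(sigmaPpm, sigmaTmsPpm) {
  if (!all(is.finite(sigmaPpm)) || !all(is.finite(sigmaTmsPpm)))
    stop("shieldings must be finite")
  sigmaTmsPpm - sigmaPpm
}

#' Reference a shift table against per-solvent TMS shieldings
#'
#' Fills \code{deltaPpm} for records carrying only \code{sigmaPpm}.
#'
#' @param records Shift records (see \code{\link{loadShiftTable}}).
#' @param tmsBySolvent Named numeric vector: canonical solvent name ->
#'   sigma(TMS) in ppm.
#' @return The records with \code{deltaPpm} populated.
#' @export
referenceShifts <- function(records, tmsBySolvent) {
  need <- is.na(records$deltaPpm)
  if (!any(need)) return(records)
  missing <- setdiff(unique(records$solvent[need]), names(tmsBySolvent))
  if (length(missing))
    stop("no TMS reference shielding supplied for solvent(s): ",
         paste(missing, collapse = ", "))
  records$deltaPpm[need] <- shieldingToShift(
    records$sigmaPpm[need], tmsBySolvent[records$solvent[need]])
  records
}

#' Assemble the regression design matrix
#'
#' One row per (hydrogen, solvent) record: the atom's SOAP descriptor entries
#' followed by a single \code{epsilon} column carrying the solvent's
#' dielectric constant — the model's only solvent feature.  Rows are sorted
#' deterministically by (molecule, atom, solvent).
#'
#' @param descriptors A \linkS4class{SoapDescriptors} with hydrogen centers
#'   covering every record.
#' @param records Shift records (\code{\link{loadShiftTable}} /
#'   \code{\link{referenceShifts}}); \code{deltaPpm} becomes the target
#'   (may be NA for prediction-only sets).
#' @param registry Solvent registry for epsilon lookup of any record whose
#'   \code{epsilon} is missing.
#' @return A \linkS4class{FeatureSet}.
#' @export
assembleFeatures <- function(descriptors, records,
                             registry = solventRegistry()) {
  info <- centerInfo(descriptors)
  key <- paste(info$moleculeId, info$atomIndex)
  ord <- order(records$moleculeId, records$atomIndex, records$solvent)
  records <- records[ord, , drop = FALSE]
  rowDesc <- match(paste(records$moleculeId, records$atomIndex), key)
  if (anyNA(rowDesc)) {
    bad <- which(is.na(rowDesc))[1L]
    stop("no descriptor for (", records$moleculeId[bad], ", atom ",
         records$atomIndex[bad], ")")
  }
  eps <- records$epsilon
  fill <- is.na(eps)
  if (any(fill))
    eps[fill] <- vapply(records$solvent[fill],
                        function(s) lookupSolvent(s, registry)$epsilon, 0)
  X <- cbind(descriptorValues(descriptors)[rowDesc, , drop = FALSE], eps)
  colnames(X) <- c(paste0("soap", seq_len(ncol(X) - 1L)), "epsilon")
  y <- if ("deltaPpm" %in% names(records)) records$deltaPpm
       else rep(NA_real_, nrow(records))
  rowInfo <- data.frame(moleculeId = records$moleculeId,
                        atomIndex = records$atomIndex,
                        solvent = records$solvent, epsilon = eps,
                        stringsAsFactors = FALSE)
  rownames(rowInfo) <- NULL
  new("FeatureSet", X = X, y = y, groups = records$moleculeId,
      rowInfo = rowInfo)
}

#' Molecule-level train/test split
#'
#' Molecules are shuffled by \code{seed} and
#' \code{round(testFraction * nMolecules)} of them (round half away from
#' zero) are assigned to the test side; every record follows its molecule, so
#' no hydrogen of a test complex is ever seen in training.  With 45 molecules
#' in 5 solvents and \code{testFraction = 0.2} this yields 9 test molecules,
#' i.e. 180 training and 45 test complex-solvent combinations.
#'
#' @param featureSet A \linkS4class{FeatureSet}.
#' @param testFraction Test proportion of molecules, in (0, 1).
#' @param seed Integer seed.
#' @return A \linkS4class{SplitPlan}.
#' @export
moleculeLevelSplit <- function(featureSet, testFraction = 0.2, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  mols <- unique(featureSet@groups)
  if (length(mols) < 2L)
    stop("cannot split a single molecule at the molecule level")
  nTest <- floor(testFraction * length(mols) + 0.5)
  nTest <- min(max(nTest, 1L), length(mols) - 1L)
  shuffled <- .withSeed(seed, sample(mols))
  testMols <- sort(shuffled[seq_len(nTest)])
  trainMols <- sort(setdiff(mols, testMols))
  new("SplitPlan",
      trainMolecules = trainMols, testMolecules = testMols,
      trainRows = which(featureSet@groups %in% trainMols),
      testRows = which(featureSet@groups %in% testMols),
      seed = as.integer(seed), testFraction = testFraction)
}

# ---- model registry ---------------------------------------------------------

# Each backend: does it want standardized columns, its default tuning grid,
# and fit/predict closures.  Hyperparameter grids are this package's own
# documented defaults (small, reproducible); chosen values are recorded on
# the fitted ShiftModel.
.modelRegistry <- function() {
  list(
    `gbt` = list(
      standardize = FALSE,
      grid = list(nrounds = c(150L, 300L), maxDepth = 4L, eta = 0.1,
                  colsampleBytree = 0.25),
      fit = function(X, y, p, seed) {
        cs <- if (is.null(p$colsampleBytree)) 1 else p$colsampleBytree
        xgboost::xgboost(x = X, y = y, objective = "reg:squarederror",
                         nrounds = p$nrounds, max_depth = p$maxDepth,
                         learning_rate = p$eta, colsample_bytree = cs,
                         tree_method = "hist", nthreads = 1L,
                         seed = seed, verbosity = 0L)
      },
      predict = function(fit, X) predict(fit, X)
    ),
    `random-forest` = list(
      standardize = FALSE,
      grid = list(numTrees = 300L),
      fit = function(X, y, p, seed) {
        ranger::ranger(x = X, y = y, num.trees = p$numTrees,
                       seed = seed, num.threads = 1)
      },
      predict = function(fit, X) predict(fit, data = X)$predictions
    ),
    `svr` = list(
      standardize = TRUE,
      grid = list(cost = c(1, 10), gamma = NA),  # NA -> 1/ncol(X)
      fit = function(X, y, p, seed) {
        g <- if (is.na(p$gamma)) 1 / ncol(X) else p$gamma
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = p$cost, gamma = g, scale = FALSE)
      },
      predict = function(fit, X) as.numeric(predict(fit, X))
    ),
    `gaussian-process` = list(
      standardize = TRUE,
      grid = list(sigma = NA, noiseVar = c(0.01, 0.1)),  # NA -> 1/ncol(X)
      fit = function(X, y, p, seed) {
        s <- if (is.na(p$sigma)) 1 / ncol(X) else p$sigma
        kernlab::gausspr(x = X, y = y, kernel = "rbfdot",
                         kpar = list(sigma = s), var = p$noiseVar,
                         scaled = FALSE)
      },
      predict = function(fit, X) as.numeric(kernlab::predict(fit, X))
    ),
    `kernel-ridge` = list(
      standardize = TRUE,
      grid = list(lambda = c(1e-3, 1e-1), gamma = NA),  # NA -> 1/ncol(X)
      fit = function(X, y, p, seed) {
        g <- if (is.na(p$gamma)) 1 / ncol(X) else p$gamma
        K <- .rbfKernel(X, X, g)
        alpha <- solve(K + p$lambda * diag(nrow(X)), y)
        list(Xtrain = X, alpha = alpha, gamma = g)
      },
      predict = function(fit, X) {
        as.numeric(.rbfKernel(X, fit$Xtrain, fit$gamma) %*% fit$alpha)
      }
    ),
    `decision-tree` = list(
      standardize = FALSE,
      grid = list(cp = c(0.001, 0.01)),
      fit = function(X, y, p, seed) {
        df <- as.data.frame(X)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "anova",
                     control = rpart::rpart.control(cp = p$cp, xval = 0))
      },
      predict = function(fit, X) as.numeric(predict(fit, as.data.frame(X)))
    )
  )
}

.rbfKernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * tcrossprod(A, B) +
    outer(rep(1, nrow(A)), rowSums(B^2))
  exp(-gamma * pmax(d2, 0))
}

#' Names of the registered regression backends
#'
#' @return Character vector of model names accepted by
#'   \code{\link{tuneAndTrain}}.
#' @export
registeredModels <- function() names(.modelRegistry())

.expandGrid <- function(grid) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# Molecule-grouped fold assignment: molecules shuffled by seed, dealt
# round-robin so fold sizes differ by at most one molecule.
.groupedFolds <- function(groups, folds, seed) {
  mols <- unique(groups)
  if (folds < 2L) stop("folds must be >= 2")
  shuffled <- .withSeed(seed, sample(mols))
  fold_of_mol <- stats::setNames(rep(seq_len(folds),
                                     length.out = length(shuffled)), shuffled)
  unname(fold_of_mol[groups])
}

#' Tune and train a shift-regression backend
#'
#' Grid search minimizing mean cross-validation MAE on the training rows of
#' the split, with molecule-grouped folds so no molecule straddles a fold
#' boundary (the same anti-leakage principle as the outer split; set
#' \code{grouped = FALSE} only for ablation).  Kernel-family backends
#' (svr, gaussian-process, kernel-ridge) receive column standardization
#' fitted on the training folds only.  The best parameter combination is
#' refitted on all training rows.
#'
#' @param modelName One of \code{\link{registeredModels}()}.
#' @param featureSet A \linkS4class{FeatureSet} with known targets.
#' @param plan A \linkS4class{SplitPlan} on the same feature set.
#' @param folds Number of CV folds (default 5).
#' @param grid Named list of parameter vectors overriding the backend's
#'   default grid (crossed with \code{expand.grid}).
#' @param seed Integer seed (drives fold assignment and stochastic backends).
#' @param grouped Keep molecules intact across folds (default TRUE).
#' @param config Optional \linkS4class{SoapConfig} the features were built
#'   with; stored on the model so \code{\link{predictShifts}} can featurize
#'   new structures identically.
#' @return A \linkS4class{ShiftModel}.
#' @export
tuneAndTrain <- function(modelName, featureSet, plan, folds = 5L,
                         grid = NULL, seed = 1L, grouped = TRUE,
                         config = NULL) {
  registry <- .modelRegistry()
  if (!modelName %in% names(registry))
    stop("unknown model '", modelName, "'; registered: ",
         paste(names(registry), collapse = ", "))
  backend <- registry[[modelName]]
  if (is.null(grid)) grid <- backend$grid
  combos <- .expandGrid(grid)
  if (!length(combos)) stop("empty parameter grid")

  rows <- plan@trainRows
  X <- featureSet@X[rows, , drop = FALSE]
  y <- featureSet@y[rows]
  if (anyNA(y)) stop("training rows contain NA targets")
  groups <- featureSet@groups[rows]
  folds <- min(as.integer(folds), length(unique(groups)))
  foldId <- if (grouped) .groupedFolds(groups, folds, seed)
            else .withSeed(seed, sample(rep(seq_len(folds),
                                            length.out = length(y))))

  cvMae <- vapply(combos, function(p) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- foldId != f; va <- !tr
      Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
      if (backend$standardize) {
        st <- .fitStandardizer(Xtr)
        Xtr <- .applyStandardizer(st, Xtr)
        Xva <- .applyStandardizer(st, Xva)
      }
      fit <- backend$fit(Xtr, y[tr], p, seed)
      mean(abs(y[va] - backend$predict(fit, Xva)))
    }, 0)
    mean(errs)
  }, 0)
  best <- combos[[which.min(cvMae)]]

  center <- numeric(0); scl <- numeric(0)
  Xfull <- X
  if (backend$standardize) {
    st <- .fitStandardizer(X)
    center <- st$center; scl <- st$scale
    Xfull <- .applyStandardizer(st, X)
  }
  fit <- backend$fit(Xfull, y, best, seed)
  if (is.null(config))
    config <- soapConfig("H", rCut = 1, nMax = 1L, lMax = 0L,
                         sigmaAtom = 1, cutoffWidth = 0)
  new("ShiftModel", modelName = modelName, fit = fit, bestParams = best,
      cvMae = min(cvMae), standardize = backend$standardize,
      center = center, scale = scl, config = config,
      seed = as.integer(seed))
}

.fitStandardizer <- function(X) {
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = center, scale = scl)
}

.applyStandardizer <- function(st, X) {
  sweep(sweep(X, 2L, st$center), 2L, st$scale, `/`)
}

#' Predict with a fitted ShiftModel on a raw feature matrix
#'
#' @param object A \linkS4class{ShiftModel}.
#' @param newdata Numeric matrix with the training feature layout
#'   (SOAP entries + epsilon).
#' @param ... Ignored.
#' @return Numeric vector of predicted shifts, ppm.
#' @export
setMethod("predict", "ShiftModel", function(object, newdata, ...) {
  backend <- .modelRegistry()[[object@modelName]]
  X <- as.matrix(newdata)
  if (object@standardize)
    X <- .applyStandardizer(list(center = object@center,
                                 scale = object@scale), X)
  backend$predict(object@fit, X)
})

#' Regression metrics: MAE, RMSE, R-squared
#'
#' R-squared is 1 - SSres/SStot about the mean of \code{yTrue}; for a
#' constant \code{yTrue} it is undefined and returned as NaN with a warning.
#'
#' @param yTrue,yPred Equal-length numeric vectors.
#' @return Named list: \code{mae}, \code{rmse}, \code{r2}.
#' @examples
#' regressionMetrics(c(0, 2), c(1, 1))  # mae 1, rmse 1, r2 0
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) == 0L)
    stop("yTrue and yPred must have equal nonzero length")
  e <- yTrue - yPred
  sstot <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sstot == 0) {
    warning("constant yTrue: R-squared is undefined")
    NaN
  } else 1 - sum(e^2) / sstot
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2)
}

#' ModelReport: held-out evaluation, overall and per solvent
#'
#' @slot modelName Backend name.
#' @slot maePpm,rmsePpm,r2 Overall test metrics.
#' @slot fitSeconds Wall-clock seconds of the final refit (NA if unknown).
#' @slot perSolvent \code{data.frame} (solvent, mae, rmse, r2, n) sorted by
#'   increasing MAE; \code{n} sums to the test rows.
#' @export
setClass("ModelReport",
  representation(modelName = "character", maePpm = "numeric",
                 rmsePpm = "numeric", r2 = "numeric", fitSeconds = "numeric",
                 perSolvent = "data.frame"))

#' @noRd
#' @export
setMethod("show", "ModelReport", function(object) {
  cat("ModelReport <", object@modelName, ">: MAE ",
      signif(object@maePpm, 4), " ppm, RMSE ", signif(object@rmsePpm, 4),
      " ppm, R2 ", signif(object@r2, 4), "\n", sep = "")
  print(object@perSolvent, row.names = FALSE)
})

#' Evaluate a fitted model on the held-out test rows, stratified by solvent
#'
#' @param featureSet The \linkS4class{FeatureSet} used for training.
#' @param plan The \linkS4class{SplitPlan}.
#' @param model A fitted \linkS4class{ShiftModel}.
#' @param fitSeconds Optional wall-clock fit time to record.
#' @return A \linkS4class{ModelReport}; the per-solvent table is sorted by
#'   increasing MAE and only solvents present in the test rows appear.
#' @export
evaluateBySolvent <- function(featureSet, plan, model, fitSeconds = NA_real_) {
  rows <- plan@testRows
  if (!length(rows)) stop("the split has no test rows")
  yTrue <- featureSet@y[rows]
  yPred <- predict(model, featureSet@X[rows, , drop = FALSE])
  overall <- regressionMetrics(yTrue, yPred)
  solv <- featureSet@rowInfo$solvent[rows]
  per <- do.call(rbind, lapply(unique(solv), function(s) {
    sel <- solv == s
    m <- suppressWarnings(regressionMetrics(yTrue[sel], yPred[sel]))
    data.frame(solvent = s, mae = m$mae, rmse = m$rmse, r2 = m$r2,
               n = sum(sel), stringsAsFactors = FALSE)
  }))
  per <- per[order(per$mae), , drop = FALSE]
  rownames(per) <- NULL
  new("ModelReport", modelName = model@modelName, maePpm = overall$mae,
      rmsePpm = overall$rmse, r2 = overall$r2, fitSeconds = fitSeconds,
      perSolvent = per)
}

#' Predict 1H shifts for structures in a solvent
#'
#' Featurizes every hydrogen of every structure with the model's SOAP config,
#' appends the solvent's dielectric constant, and predicts.  Any registered
#' solvent works, including solvents absent from training: the dielectric
#' constant is the only solvent input, which is what makes the model
#' transferable to unseen solvents.
#'
#' @param model A \linkS4class{ShiftModel} whose \code{config} slot holds the
#'   training \linkS4class{SoapConfig} (set by \code{\link{runPipeline}} or
#'   manually after \code{\link{tuneAndTrain}}).
#' @param structures A \linkS4class{MolecularStructure} or list of them.
#' @param solvent Solvent name resolvable in the registry.
#' @param registry Solvent registry.
#' @return A \code{data.frame} of shift records (\code{moleculeId},
#'   \code{atomIndex}, \code{solvent}, \code{epsilon}, \code{deltaPpm}),
#'   one row per hydrogen; empty for structures without hydrogens.
#' @export
predictShifts <- function(model, structures, solvent,
                          registry = solventRegistry()) {
  if (is(structures, "MolecularStructure")) structures <- list(structures)
  sol <- lookupSolvent(solvent, registry)
  desc <- computeSoap(structures, model@config, centers = "hydrogen")
  info <- centerInfo(desc)
  if (nrow(info) == 0L)
    return(data.frame(moleculeId = character(0), atomIndex = integer(0),
                      solvent = character(0), epsilon = numeric(0),
                      deltaPpm = numeric(0)))
  X <- cbind(descriptorValues(desc), sol$epsilon)
  colnames(X) <- c(paste0("soap", seq_len(ncol(X) - 1L)), "epsilon")
  data.frame(moleculeId = info$moleculeId, atomIndex = info$atomIndex,
             solvent = sol$name, epsilon = sol$epsilon,
             deltaPpm = predict(model, X), stringsAsFactors = FALSE)
}
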