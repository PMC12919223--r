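#' @importFrom xgboost xgb.DMatrix xgb.train xgb.save xgb.load
NULL

BLOCK_ORDER <- c("DX_presence", "RX_presence", "PROC_presence",
                 "DX_or", "RX_or", "PROC_or")

defaultBaseParams <- function() {
  list(objective = "binary:logistic", max_depth = 5, eta = 0.1,
       nthread = 1, nrounds = 100)
}

defaultMetaParams <- function() {
  list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
       nthread = 1, nrounds = 100)
}

fitBooster <- function(X, y, params, seed) {
  nrounds <- params$nrounds
  params$nrounds <- NULL
  if (is.null(params$scale_pos_weight))
    params$scale_pos_weight <- sum(y == 0) / max(1, sum(y == 1))
  set.seed(seed)
  dtrain <- xgb.DMatrix(X, label = y)
  xgb.train(params = params, data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Train one base learner with out-of-fold scores
#'
#' Fits a gradient-boosted tree classifier on one feature block and
#' produces out-of-fold scores by K-fold cross-fitting: each patient's
#' score comes from the model trained without their fold, so the meta
#' learner never sees in-fold leakage. The returned model is refit on
#' the full block for prediction time.
#'
#' @param X patients x features matrix (dense or \code{dgCMatrix}).
#' @param y 0/1 labels.
#' @param params named list of booster hyperparameters plus
#'   \code{nrounds}; unset entries fall back to shallow-tree defaults
#'   with class weighting.
#' @param nfolds number of cross-fitting folds (default 5).
#' @param seed RNG seed controlling fold assignment and training.
#' @return list(model, oof) with out-of-fold scores aligned to rows of
#'   \code{X}.
#' @export
trainBase <- function(X, y, params = list(), nfolds = 5L, seed = 1L) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  stopifnot(nrow(X) == length(y), nfolds >= 2L)
  params <- modifyList(defaultBaseParams(), params)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfolds), length(y)))
  oof <- numeric(length(y))
  for (k in seq_len(nfolds)) {
    inTrain <- fold != k
    m <- fitBooster(X[inTrain, , drop = FALSE], y[inTrain], params, seed + k)
    oof[!inTrain] <- predict(m, xgb.DMatrix(X[!inTrain, , drop = FALSE]))
  }
  model <- fitBooster(X, y, params, seed)
  list(model = model, oof = oof)
}

metaDesign <- function(baseScores, sex, age) {
  Z <- cbind(as.matrix(baseScores),
             sex_female = as.numeric(sex == "female"),
             age_at_index = as.numeric(age))
  colnames(Z)[seq_along(BLOCK_ORDER)] <- BLOCK_ORDER
  Z
}

#' Train the meta classifier over base scores, sex and age
#'
#' @param baseScores patients x 6 matrix of out-of-fold base scores in
#'   block order (DX/RX/PROC presence, then DX/RX/PROC odds-ratio).
#' @param sex character vector "male"/"female".
#' @param age numeric ages at index.
#' @param y 0/1 labels.
#' @param method \code{"xgboost"} (small boosted trees, default) or
#'   \code{"logistic"}.
#' @param params meta booster hyperparameters (xgboost method).
#' @param seed RNG seed.
#' @return list(metaModel, metaMethod).
#' @export
trainMeta <- function(baseScores, sex, age, y, method = c("xgboost", "logistic"),
                      params = list(), seed = 1L) {
  method <- match.arg(method)
  y <- as.integer(as.logical(y))
  if (nrow(as.matrix(baseScores)) != length(y))
    stop("misaligned rows between base scores and labels")
  Z <- metaDesign(baseScores, sex, age)
  if (method == "xgboost") {
    params <- modifyList(defaultMetaParams(), params)
    model <- fitBooster(Z, y, params, seed)
  } else {
    df <- data.frame(y = y, Z)
    model <- coef(glm(y ~ ., data = df, family = binomial()))
  }
  list(metaModel = model, metaMethod = method)
}

predictMeta <- function(metaModel, metaMethod, Z) {
  if (metaMethod == "xgboost") {
    predict(metaModel, xgb.DMatrix(Z))
  } else {
    eta <- metaModel[1] + as.numeric(Z %*% metaModel[-1])
    plogis(eta)
  }
}

seBlocks <- function(se) {
  blocks <- SummarizedExperiment::rowData(se)$block
  X <- SummarizedExperiment::assay(se, "X")
  lapply(setNames(BLOCK_ORDER, BLOCK_ORDER), function(b) {
    Matrix::t(X[blocks == b, , drop = FALSE])  # patients x features
  })
}

#' Train the full stacked risk-score ensemble
#'
#' Six base learners (one per feature block) are cross-fitted for
#' out-of-fold scores; the meta classifier combines the six scores with
#' sex and age. The training manifest (per-block feature fingerprints,
#' seed, training-split fingerprint) is stored and enforced at
#' prediction time.
#'
#' @param se a feature \code{SummarizedExperiment} from
#'   \code{\link{assembleFeatures}} whose \code{colData} carries
#'   \code{label}.
#' @param seed master RNG seed for fold assignment and training.
#' @param baseParams,metaParams hyperparameter overrides.
#' @param metaMethod \code{"xgboost"} or \code{"logistic"}.
#' @param nfolds cross-fitting folds.
#' @return A \linkS4class{RiskEnsemble}.
#' @export
trainEnsemble <- function(se, seed = 1L, baseParams = list(),
                          metaParams = list(),
                          metaMethod = c("xgboost", "logistic"),
                          nfolds = 5L) {
  metaMethod <- match.arg(metaMethod)
  cd <- SummarizedExperiment::colData(se)
  if (is.null(cd$label)) stop("colData(se)$label is required for training")
  y <- as.integer(cd$label)
  blocks <- seBlocks(se)
  baseModels <- list()
  oof <- matrix(NA_real_, ncol(se), length(BLOCK_ORDER),
                dimnames = list(NULL, BLOCK_ORDER))
  for (i in seq_along(BLOCK_ORDER)) {
    b <- BLOCK_ORDER[i]
    fit <- trainBase(blocks[[b]], y, baseParams, nfolds = nfolds,
                     seed = seed + 100L * i)
    baseModels[[b]] <- fit$model
    oof[, b] <- fit$oof
  }
  meta <- trainMeta(oof, cd$sex, cd$age_at_index, y, method = metaMethod,
                    params = metaParams, seed = seed + 999L)
  manifest <- list(format_version = 1L,
                   blocks = featureManifest(se),
                   split = splitFingerprint(cd$patient_id),
                   seed = as.integer(seed),
                   metaMethod = metaMethod,
                   package_version = as.character(utils::packageVersion("adscreen")))
  new("RiskEnsemble", baseModels = baseModels, metaModel = meta$metaModel,
      metaMethod = metaMethod, manifest = manifest)
}

#' Predict risk scores from a feature bundle
#'
#' Pure function of (model, features): applies the six base learners
#' and the meta classifier. The feature manifest must match the
#' training manifest block for block; a mismatch is refused with the
#' offending block named.
#'
#' @param model a \linkS4class{RiskEnsemble}.
#' @param se a feature \code{SummarizedExperiment}.
#' @return data.frame(patient_id, score) with scores in [0, 1].
#' @export
predictRisk <- function(model, se) {
  stopifnot(is(model, "RiskEnsemble"))
  mf <- featureManifest(se)
  for (b in BLOCK_ORDER) {
    if (!identical(mf[[b]], model@manifest$blocks[[b]]))
      stop("feature manifest mismatch in block ", b,
           ": bundle was not assembled with the training vocabularies")
  }
  blocks <- seBlocks(se)
  baseScores <- matrix(NA_real_, ncol(se), length(BLOCK_ORDER),
                       dimnames = list(NULL, BLOCK_ORDER))
  for (b in BLOCK_ORDER)
    baseScores[, b] <- predict(model@baseModels[[b]], xgb.DMatrix(blocks[[b]]))
  cd <- SummarizedExperiment::colData(se)
  Z <- metaDesign(baseScores, cd$sex, cd$age_at_index)
  score <- predictMeta(model@metaModel, model@metaMethod, Z)
  stopifnot(all(score >= 0 & score <= 1))
  data.frame(patient_id = cd$patient_id, score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' Save / load a risk ensemble as a model directory
#'
#' One booster file per base model (xgboost JSON), the meta model
#' (booster JSON or logistic coefficients), and a \code{manifest.json}
#' carrying the training fingerprint. The round trip is lossless:
#' reloaded models produce identical scores. Directories with a
#' tampered or unsupported manifest are refused.
#'
#' @param model a \linkS4class{RiskEnsemble}.
#' @param dir model directory (created if needed).
#' @return \code{saveModel}: \code{dir} invisibly; \code{loadModel}:
#'   a \linkS4class{RiskEnsemble}.
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "RiskEnsemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in BLOCK_ORDER)
    xgb.save(model@baseModels[[b]], file.path(dir, paste0("base_", b, ".json")))
  if (model@metaMethod == "xgboost") {
    xgb.save(model@metaModel, file.path(dir, "meta.json"))
  } else {
    jsonlite::write_json(as.list(model@metaModel),
                         file.path(dir, "meta_coefficients.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(model@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("not a model directory: manifest.json missing")
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format_version), 1L))
    stop("unsupported model format version: ", manifest$format_version)
  need <- file.path(dir, paste0("base_", BLOCK_ORDER, ".json"))
  if (!all(file.exists(need))) stop("model directory is missing base model files")
  baseModels <- lapply(setNames(need, BLOCK_ORDER), xgb.load)
  metaMethod <- manifest$metaMethod
  if (identical(metaMethod, "xgboost")) {
    metaModel <- xgb.load(file.path(dir, "meta.json"))
  } else {
    co <- jsonlite::fromJSON(file.path(dir, "meta_coefficients.json"))
    metaModel <- setNames(as.numeric(co), names(co))
  }
  manifest$blocks <- as.list(manifest$blocks)
  manifest$format_version <- as.integer(manifest$format_version)
  manifest$seed <- as.integer(manifest$seed)
  new("RiskEnsemble", baseModels = baseModels, metaModel = metaModel,
      metaMethod = metaMethod, manifest = manifest)
}
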