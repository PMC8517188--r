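# GPR regression (gradient-boosted trees) and pass/fail classification
# (ridge) under the repeated 70/30 train/test protocol.

#' Binary pass/fail labels from GPR values
#'
#' @param gprValues numeric GPR in [0, 100]
#' @param crit a \linkS4class{GammaCriterion} (its action limit is used;
#'   boundary inclusive)
#' @return factor with levels fail, pass
#' @export
makeLabels <- function(gprValues, crit) {
  stopifnot(all(gprValues >= 0), all(gprValues <= 100))
  factor(ifelse(gprValues >= crit@actionLimit, "pass", "fail"),
         levels = c("fail", "pass"))
}

#' Absolute prediction error
#'
#' \eqn{APE = |GPR_{pred} - GPR_{meas}| / GPR_{meas} \times 100\%}.
#'
#' @param pred predicted GPR (\%)
#' @param meas measured GPR (\%), must be > 0
#' @return APE in percent (vectorized)
#' @export
apePercent <- function(pred, meas) {
  if (any(meas <= 0)) stop("measured GPR must be > 0")
  abs(pred - meas) / meas * 100
}

#' Area under the ROC curve from continuous decision scores
#'
#' @param scores numeric decision scores (larger = more "pass")
#' @param labels factor with levels fail, pass (or coercible)
#' @return AUC in [0, 1]
#' @export
aucScore <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("fail", "pass"))
  as.numeric(pROC::auc(labels, as.numeric(scores),
                       levels = c("fail", "pass"), direction = "<",
                       quiet = TRUE))
}

# Paper-style default gradient-boosting configuration.
defaultGbrParams <- function() {
  list(eta = 0.12, nrounds = 58L, max_depth = 3L, subsample = 1,
       alpha = 0.12)
}

fitGbr <- function(X, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  max_depth = params$max_depth, subsample = params$subsample,
                  alpha = params$alpha, nthread = 1,
                  seed = as.integer(seed %% 2147483647)),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

#' Train the GPR regressor (gradient-boosted trees)
#'
#' Hyperparameters (learning rate, number of trees, depth, subsample, L1
#' regularization alpha) are tuned by randomized search (default 60 draws)
#' scored by cross-validated mean absolute error; the search space is
#' centered on the no-search default configuration (alpha 0.12, learning
#' rate 0.12, 58 trees, depth 3), which is itself always a candidate.
#' \code{search = FALSE} fits that default directly.
#'
#' @param train feature table (training cohort, selected features)
#' @param gprValues training GPR values (\%)
#' @param seed integer seed
#' @param nDraws randomized-search draws (default 60)
#' @param cvFolds cross-validation folds (default 5)
#' @param search tune hyperparameters (default TRUE)
#' @return list(model, params, cvMae); predict with
#'   \code{predictGpr(fit, newdata)}
#' @export
trainRegressor <- function(train, gprValues, seed = 1, nDraws = 60,
                           cvFolds = 5, search = TRUE) {
  X <- asFeatureMatrix(train)
  y <- as.numeric(gprValues)
  if (nrow(X) < 2 * cvFolds) stop("too few training rows for ", cvFolds,
                                  "-fold cross-validation")
  candidates <- list(defaultGbrParams())
  if (search) {
    set.seed(subSeed(seed, 17))
    for (i in seq_len(nDraws - 1L))
      candidates[[i + 1L]] <- list(
        eta = exp(stats::runif(1, log(0.03), log(0.4))),
        nrounds = sample(20:150, 1),
        max_depth = sample(2:5, 1),
        subsample = stats::runif(1, 0.6, 1),
        alpha = exp(stats::runif(1, log(0.01), log(1.5))))
  }
  set.seed(subSeed(seed, 29))
  folds <- sample(rep(seq_len(cvFolds), length.out = nrow(X)))
  cvMae <- vapply(candidates, function(p) {
    errs <- vapply(seq_len(cvFolds), function(fold) {
      tr <- folds != fold
      fit <- fitGbr(X[tr, , drop = FALSE], y[tr], p, subSeed(seed, 31 + fold))
      mean(abs(stats::predict(fit, as.matrix(X[!tr, , drop = FALSE])) - y[!tr]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- candidates[[which.min(cvMae)]]
  list(model = fitGbr(X, y, best, subSeed(seed, 43)), params = best,
       cvMae = min(cvMae), featureNames = colnames(X))
}

#' Predict GPR from a trained regressor
#'
#' @param fit result of \code{\link{trainRegressor}}
#' @param newdata feature table with the model's features
#' @return predicted GPR (\%)
#' @export
predictGpr <- function(fit, newdata) {
  X <- as.matrix(newdata[, fit$featureNames, drop = FALSE])
  stats::predict(fit$model, X)
}

#' Train the pass/fail ridge classifier
#'
#' Linear least squares on +/-1 class targets with L2 regularization,
#' fitted with glmnet (alpha = 0, standardized features). The
#' regularization strength is chosen by cross-validated AUC over a log
#' grid of sklearn-style alpha values (the grid includes 1.0 and 31.6;
#' glmnet's lambda = alpha / n). Decision scores are the linear predictor.
#'
#' @param train feature table (training cohort, selected features)
#' @param labels factor with levels fail, pass; both classes required
#' @param seed integer seed
#' @param alphaGrid ridge penalty grid (default 10^seq(-2, 3, 0.25))
#' @param cvFolds cross-validation folds (default 5)
#' @return list(model, alpha, lambda, cvAuc, featureNames); score with
#'   \code{decisionScores(fit, newdata)}
#' @export
trainClassifier <- function(train, labels, seed = 1,
                            alphaGrid = 10^seq(-2, 3, by = 0.25),
                            cvFolds = 5) {
  X <- asFeatureMatrix(train)
  labels <- factor(as.character(labels), levels = c("fail", "pass"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("training labels contain a single class")
  y <- ifelse(labels == "pass", 1, -1)
  n <- nrow(X)
  lambdaGrid <- sort(alphaGrid / n, decreasing = TRUE)
  set.seed(subSeed(seed, 53))
  folds <- sample(rep(seq_len(cvFolds), length.out = n))
  aucByLambda <- matrix(NA_real_, cvFolds, length(lambdaGrid))
  for (fold in seq_len(cvFolds)) {
    tr <- folds != fold
    if (length(unique(y[tr])) < 2L || !any(!tr)) next
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "gaussian",
                          alpha = 0, lambda = lambdaGrid)
    sc <- stats::predict(fit, X[!tr, , drop = FALSE])
    lab <- labels[!tr]
    if (nlevels(droplevels(lab)) < 2L) next
    for (j in seq_len(ncol(sc)))
      aucByLambda[fold, j] <- aucScore(sc[, j], lab)
  }
  meanAuc <- colMeans(aucByLambda, na.rm = TRUE)
  jBest <- which.max(meanAuc)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 0,
                        lambda = lambdaGrid)
  list(model = fit, lambda = lambdaGrid[jBest],
       alpha = lambdaGrid[jBest] * n, cvAuc = meanAuc[jBest],
       featureNames = colnames(X))
}

#' Decision scores of a trained classifier
#'
#' @param fit result of \code{\link{trainClassifier}}
#' @param newdata feature table with the model's features
#' @return numeric scores (larger = more "pass")
#' @export
decisionScores <- function(fit, newdata) {
  X <- as.matrix(newdata[, fit$featureNames, drop = FALSE])
  as.numeric(stats::predict(fit$model, X, s = fit$lambda))
}

#' Evaluation protocol settings
#'
#' @param trainFrac training fraction of the 70/30 split (default 0.7)
#' @param nRepeats repeated splits (default 20 for classification; the
#'   regression protocol conventionally uses 1)
#' @param cvFolds tuning folds (default 5)
#' @param k selected features per model (default 10)
#' @param nIter stability-selection iterations (default 100)
#' @param downsample downsample the training majority class
#'   (classification, default TRUE)
#' @param search randomized hyperparameter search for the regressor
#' @param nDraws randomized-search draws (default 60)
#' @return list of settings for \code{\link{evaluateClassification}} /
#'   \code{\link{evaluateRegression}}
#' @export
evalProtocol <- function(trainFrac = 0.7, nRepeats = 20, cvFolds = 5,
                         k = 10, nIter = 100, downsample = TRUE,
                         search = TRUE, nDraws = 60) {
  list(trainFrac = trainFrac, nRepeats = nRepeats, cvFolds = cvFolds,
       k = k, nIter = nIter, downsample = downsample, search = search,
       nDraws = nDraws)
}

# 70/30 split with a guard against single-class test cohorts; redraws are
# counted in the result attribute.
splitCohort <- function(n, trainFrac, labels = NULL, seed) {
  redraws <- 0L
  repeat {
    set.seed(subSeed(seed, 61 + redraws))
    tr <- sort(sample.int(n, round(trainFrac * n)))
    te <- setdiff(seq_len(n), tr)
    if (is.null(labels)) break
    if (length(unique(labels[tr])) == 2L && length(unique(labels[te])) == 2L)
      break
    redraws <- redraws + 1L
    if (redraws > 50L) stop("could not draw a split with both classes in both cohorts")
  }
  list(train = tr, test = te, redraws = redraws)
}

downsampleMajority <- function(idx, labels, seed) {
  lab <- labels[idx]
  tab <- table(lab)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (minority == majority) return(idx)
  set.seed(subSeed(seed, 71))
  keepMaj <- sample(idx[lab == majority], tab[[minority]])
  sort(c(idx[lab == minority], keepMaj))
}

#' Repeated train/test evaluation of pass/fail classification
#'
#' For each repeat and gamma criterion: a 70/30 split, optional
#' downsampling of the training majority class, stability feature
#' selection (on training data only), ridge classification and AUC on both
#' cohorts, for each feature modality (e.g. conventional, planomics,
#' hybrid). Test labels never enter selection or tuning.
#'
#' @param featureSets named list of feature tables over the same plans
#'   (rows aligned), e.g. list(CF = , PF = , HF = )
#' @param gprTable data.frame with one GPR column per criterion name
#' @param criteria named list of \linkS4class{GammaCriterion}; names must
#'   match \code{gprTable} columns (default \code{\link{defaultCriteria}})
#' @param protocol settings from \code{\link{evalProtocol}}
#' @param seed integer seed
#' @return data.frame with one row per (repeat, criterion, feature set):
#'   aucTrain, aucTest, alpha, nFail/nPass in the training cohort and the
#'   selected features (";"-separated)
#' @export
evaluateClassification <- function(featureSets, gprTable,
                                   criteria = defaultCriteria(),
                                   protocol = evalProtocol(), seed = 1) {
  n <- nrow(featureSets[[1]])
  out <- list()
  for (r in seq_len(protocol$nRepeats)) {
    for (cn in names(criteria)) {
      labs <- makeLabels(gprTable[[cn]], criteria[[cn]])
      sp <- splitCohort(n, protocol$trainFrac, labs,
                        subSeed(seed, 1000 * r + match(cn, names(criteria))))
      trIdx <- sp$train
      if (protocol$downsample)
        trIdx <- downsampleMajority(trIdx, labs,
                                    subSeed(seed, 2000 * r + match(cn, names(criteria))))
      for (sn in names(featureSets)) {
        tab <- featureSets[[sn]]
        sel <- selectFeatures(tab[trIdx, , drop = FALSE], labs[trIdx],
                              k = protocol$k, nIter = protocol$nIter,
                              seed = subSeed(seed, 3000 * r +
                                               17 * match(cn, names(criteria)) +
                                               match(sn, names(featureSets))))
        fit <- trainClassifier(tab[trIdx, sel$selected, drop = FALSE],
                               labs[trIdx],
                               seed = subSeed(seed, 4000 * r),
                               cvFolds = protocol$cvFolds)
        out[[length(out) + 1L]] <- data.frame(
          repeatIdx = r, criterion = cn, featureSet = sn,
          aucTrain = aucScore(decisionScores(fit, tab[trIdx, , drop = FALSE]),
                              labs[trIdx]),
          aucTest = aucScore(decisionScores(fit, tab[sp$test, , drop = FALSE]),
                             labs[sp$test]),
          alpha = fit$alpha,
          nTrainFail = sum(labs[trIdx] == "fail"),
          nTrainPass = sum(labs[trIdx] == "pass"),
          redraws = sp$redraws,
          selected = paste(sel$selected, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Repeated train/test evaluation of GPR regression
#'
#' As \code{\link{evaluateClassification}}, but fitting the
#' gradient-boosting regressor and reporting the absolute prediction
#' error: mean and SD of APE (percent of measured GPR) plus the mean
#' absolute error in percentage points, for both cohorts.
#'
#' @inheritParams evaluateClassification
#' @return data.frame with one row per (repeat, criterion, feature set)
#' @export
evaluateRegression <- function(featureSets, gprTable,
                               criteria = defaultCriteria(),
                               protocol = evalProtocol(nRepeats = 1),
                               seed = 1) {
  n <- nrow(featureSets[[1]])
  out <- list()
  for (r in seq_len(protocol$nRepeats)) {
    sp <- splitCohort(n, protocol$trainFrac, NULL, subSeed(seed, 5000 + r))
    for (cn in names(criteria)) {
      y <- gprTable[[cn]]
      for (sn in names(featureSets)) {
        tab <- featureSets[[sn]]
        sel <- selectFeatures(tab[sp$train, , drop = FALSE], y[sp$train],
                              k = protocol$k, nIter = protocol$nIter,
                              seed = subSeed(seed, 6000 * r +
                                               17 * match(cn, names(criteria)) +
                                               match(sn, names(featureSets))))
        fit <- trainRegressor(tab[sp$train, sel$selected, drop = FALSE],
                              y[sp$train], seed = subSeed(seed, 7000 * r),
                              nDraws = protocol$nDraws,
                              cvFolds = protocol$cvFolds,
                              search = protocol$search)
        apTr <- apePercent(predictGpr(fit, tab[sp$train, , drop = FALSE]),
                           y[sp$train])
        apTe <- apePercent(predictGpr(fit, tab[sp$test, , drop = FALSE]),
                           y[sp$test])
        out[[length(out) + 1L]] <- data.frame(
          repeatIdx = r, criterion = cn, featureSet = sn,
          apeTrainMean = mean(apTr), apeTrainSD = stats::sd(apTr),
          apeTestMean = mean(apTe), apeTestSD = stats::sd(apTe),
          maeTrainPts = mean(abs(predictGpr(fit, tab[sp$train, , drop = FALSE]) -
                                   y[sp$train])),
          maeTestPts = mean(abs(predictGpr(fit, tab[sp$test, , drop = FALSE]) -
                                  y[sp$test])),
          selected = paste(sel$selected, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
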