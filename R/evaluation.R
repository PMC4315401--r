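#' Rank-based AUC for presence vs background scores
#'
#' The Mann-Whitney estimate of the probability that a random presence
#' outranks a random background point, with ties contributing 1/2.
#'
#' @param presence,background numeric score vectors (each non-empty).
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8), c(0.1, 0.2))  # 1
#' @export
aucScore <- function(presence, background) {
  if (!length(presence) || !length(background))
    stop("both score groups must be non-empty")
  r <- rank(c(presence, background))
  m <- length(presence)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(background))
}

splitPresences <- function(presences, trainFraction) {
  m <- length(presences)
  nTrain <- min(max(round(trainFraction * m), 1L), m - 1L)
  idx <- sample.int(m)
  list(train = presences[idx[seq_len(nTrain)]],
       test = presences[idx[(nTrain + 1):m]])
}

#' Replicated train/test evaluation
#'
#' Repeatedly splits the presences into training and test fractions
#' (background shared across replicates), fits the model on the
#' training split, and scores training and test AUC against the
#' background. The cell-wise mean of the replicate suitability maps is
#' retained as the averaged model for downstream thresholding.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param presences presence cell indices.
#' @param background background cell indices.
#' @param replicates number of replicate runs (default 30).
#' @param trainFraction presence fraction used for training (default
#'   0.75).
#' @param seed master seed; replicate seeds are drawn from it.
#' @param ... passed to [fitMaxent()].
#' @return List of class data: \code{replicates} (data.frame seed,
#'   trainAUC, testAUC), \code{summary} (means and SDs; SDs are NA with
#'   a single replicate), \code{meanMap} (averaged
#'   \linkS4class{SuitabilityMap}), \code{models}.
#' @export
replicateEvaluation <- function(stack, presences, background,
                                replicates = 30, trainFraction = 0.75,
                                seed = 1, ...) {
  stopifnot(replicates >= 1, trainFraction > 0, trainFraction < 1)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max, replicates)
  rows <- vector("list", replicates)
  models <- vector("list", replicates)
  mapSum <- NULL
  for (i in seq_len(replicates)) {
    set.seed(repSeeds[i])
    sp <- splitPresences(presences, trainFraction)
    model <- fitMaxent(stack, sp$train, background, ...)
    sTrain <- predictAtCells(model, stack, sp$train)
    sTest <- predictAtCells(model, stack, sp$test)
    sBg <- predictAtCells(model, stack, background)
    rows[[i]] <- data.frame(seed = repSeeds[i],
                            trainAUC = aucScore(sTrain, sBg),
                            testAUC = aucScore(sTest, sBg))
    models[[i]] <- model
    m <- predictSuitability(model, stack, replicate = i)
    mapSum <- if (is.null(mapSum)) m@values else mapSum + m@values
  }
  reps <- do.call(rbind, rows)
  g <- stackGeometry(stack)
  meanMap <- new("SuitabilityMap", values = mapSum / replicates,
                 xmin = g$xmin, ymax = g$ymax, cellsize = g$cellsize,
                 replicate = 0L)
  list(replicates = reps,
       summary = list(
         meanTrainAUC = mean(reps$trainAUC),
         sdTrainAUC = if (replicates > 1) stats::sd(reps$trainAUC) else NA_real_,
         meanTestAUC = mean(reps$testAUC),
         sdTestAUC = if (replicates > 1) stats::sd(reps$testAUC) else NA_real_),
       meanMap = meanMap, models = models, seed = seed)
}

#' Jackknife AUC variable importance
#'
#' For each variable, fits a model with that variable alone and with
#' all variables but it, under one fixed train/test split, and reports
#' the test AUC of each alongside the full-model AUC.
#'
#' @inheritParams replicateEvaluation
#' @param variables layer names to jackknife (default all).
#' @return data.frame (variable, aucOnly, aucWithout) with the full
#'   model's test AUC in \code{attr(, "aucFull")}.
#' @export
jackknifeAUC <- function(stack, presences, background,
                         variables = layerNames(stack),
                         trainFraction = 0.75, seed = 1, ...) {
  if (length(variables) < 2)
    stop("jackknife needs at least 2 variables")
  set.seed(seed)
  sp <- splitPresences(presences, trainFraction)
  testAUC <- function(st) {
    model <- fitMaxent(st, sp$train, background, ...)
    aucScore(predictAtCells(model, st, sp$test),
             predictAtCells(model, st, background))
  }
  out <- data.frame(variable = variables,
                    aucOnly = NA_real_, aucWithout = NA_real_)
  for (i in seq_along(variables)) {
    v <- variables[i]
    out$aucOnly[i] <- testAUC(subsetStack(stack, v))
    out$aucWithout[i] <- testAUC(subsetStack(stack, setdiff(variables, v)))
  }
  attr(out, "aucFull") <- testAUC(subsetStack(stack, variables))
  attr(out, "seed") <- seed
  out
}

#' Permutation importance of model variables
#'
#' Shuffles each variable's raw values across the combined
#' presence-plus-background evaluation points, re-extracts the
#' features, and measures the drop in AUC. Negative drops are floored
#' at zero and the result is normalised to sum to 100% (all zeros when
#' no permutation hurts).
#'
#' @param model a \linkS4class{MaxentModel}.
#' @inheritParams replicateEvaluation
#' @return Named numeric vector of percentages.
#' @export
permutationImportance <- function(model, stack, presences, background,
                                  seed = 1) {
  set.seed(seed)
  vars <- unique(stats::na.omit(c(model@features@defs$layer,
                                  model@features@defs$layer2)))
  cells <- c(presences, background)
  X <- extractPredictors(stack, cells)
  ip <- seq_along(presences); ib <- length(presences) + seq_along(background)
  score <- function(X) {
    eta <- as.numeric(featureMatrix(model@features, X) %*% model@lambda)
    aucScore(eta[ip], eta[ib])
  }
  auc0 <- score(X)
  drops <- vapply(vars, function(v) {
    Xp <- X
    Xp[, v] <- X[sample.int(nrow(X)), v]
    max(0, auc0 - score(Xp))
  }, 0)
  if (sum(drops) > 0) drops <- 100 * drops / sum(drops)
  drops
}

#' Prune uninformative variables and refit
#'
#' Removes variables whose permutation importance falls below the
#' threshold (default 1%) and refits the model on the remaining stack.
#'
#' @inheritParams replicateEvaluation
#' @param threshold importance threshold in percent.
#' @param seed seed for the permutation importance.
#' @return List: \code{stack} (pruned), \code{model} (refitted),
#'   \code{importance} (initial), \code{dropped} (variable names),
#'   \code{initialModel}.
#' @export
pruneAndRefit <- function(stack, presences, background, threshold = 1,
                          seed = 1, ...) {
  model <- fitMaxent(stack, presences, background, ...)
  imp <- permutationImportance(model, stack, presences, background, seed)
  keep <- names(imp)[imp >= threshold]
  dropped <- setdiff(names(imp), keep)
  if (!length(keep))
    stop("pruning at ", threshold, "% would remove every variable")
  pruned <- subsetStack(stack, keep)
  refit <- if (length(dropped))
    fitMaxent(pruned, presences, background, ...) else model
  list(stack = pruned, model = refit, importance = imp, dropped = dropped,
       initialModel = model)
}

#' Partial response curve of one variable
#'
#' Sweeps a variable across its background range while holding the
#' other variables at their background means (categorical layers at
#' their mode), and evaluates the logistic output of each replicate
#' model; reports mean and SD across models (SD is NA with one model).
#'
#' @param models a \linkS4class{MaxentModel} or list of them.
#' @inheritParams replicateEvaluation
#' @param variable layer name to sweep.
#' @param gridPoints number of evaluation points (default 100).
#' @return data.frame (value, mean, sd).
#' @export
responseCurve <- function(models, stack, background, variable,
                          gridPoints = 100) {
  if (is(models, "MaxentModel")) models <- list(models)
  if (!variable %in% layerNames(stack)) stop("unknown variable: ", variable)
  X <- extractPredictors(stack, background)
  base <- vapply(layerNames(stack), function(l) {
    if (stack@kind[[l]] == "categorical") {
      tab <- table(X[, l])
      as.numeric(names(tab)[which.max(tab)])
    } else mean(X[, l])
  }, 0)
  v <- seq(min(X[, variable]), max(X[, variable]), length.out = gridPoints)
  Xs <- matrix(rep(base, each = gridPoints), gridPoints,
               dimnames = list(NULL, layerNames(stack)))
  Xs[, variable] <- v
  P <- vapply(models, function(m) {
    eta <- as.numeric(featureMatrix(m@features, Xs) %*% m@lambda)
    qeH <- exp(eta - m@logZ + m@H)
    qeH / (1 + qeH)
  }, numeric(gridPoints))
  P <- matrix(P, gridPoints)
  data.frame(value = v, mean = rowMeans(P),
             sd = if (length(models) > 1) apply(P, 1, stats::sd)
                  else NA_real_)
}
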