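.checkDataset <- function(data, features = NULL) {
  data <- as.data.frame(data)
  if (!"label" %in% names(data))
    stop("dataset needs a 'label' column")
  lab <- as.character(data$label)
  if (!all(lab %in% c(POSITIVE_CLASS, NEGATIVE_CLASS)))
    stop("labels must be '", POSITIVE_CLASS, "' or '", NEGATIVE_CLASS, "'")
  if (is.null(features))
    features <- intersect(FEATURE_LETTERS, names(data))
  if (!length(features)) stop("no feature columns found")
  x <- data[, features, drop = FALSE]
  if (any(!vapply(x, is.numeric, logical(1))) || anyNA(x) ||
      any(!is.finite(as.matrix(x))))
    stop("feature columns must be numeric with no missing values")
  list(x = x, y = lab, features = features)
}

# Stratified fold ids, invariant under row permutation: rows are put into a
# canonical order (by class, then feature values) before the seeded shuffle,
# so the same rows always land in the same folds regardless of input order.
.stratifiedFolds <- function(x, y, k, seed) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    canon <- idx[do.call(order, c(as.list(x[idx, , drop = FALSE]),
                                  list(idx)))]
    set.seed(seed + match(cls, c(NEGATIVE_CLASS, POSITIVE_CLASS)))
    folds[canon] <- sample(rep(seq_len(k), length.out = length(canon)))
  }
  folds
}

#' Stratified five-fold cross-validation, pooled metrics
#'
#' Splits the data into five stratified folds (fixed seed), trains on four,
#' predicts the held-out fold, pools the out-of-fold predictions over the
#' five folds and computes one [classificationMetrics()] set on the pooled
#' predictions. Deterministic given data and seed, and invariant under row
#' permutation of the input.
#'
#' @param data data.frame with feature columns and a `label` column of
#'   `"CWM"`/`"FWM"` values; both classes need at least `k` rows.
#' @param model a [modelSpec()].
#' @param seed integer seed controlling the fold split and stochastic fits.
#' @param features feature columns to use (default: all of `A`..`F` present).
#' @param k number of folds (default 5).
#' @return one-row data.frame of metrics, with the pooled confusion counts
#'   and per-row out-of-fold predictions attached as attributes
#'   `"confusion"` and `"predictions"`.
#' @export
fiveFoldCv <- function(data, model, seed = 1L, features = NULL, k = 5L) {
  d <- .checkDataset(data, features)
  tab <- table(d$y)
  if (any(tab < k))
    stop("each class needs at least ", k, " rows for ", k, "-fold CV")
  folds <- .stratifiedFolds(d$x, d$y, k, seed)
  pred <- rep(NA_character_, length(d$y))
  score <- rep(NA_real_, length(d$y))
  for (f in seq_len(k)) {
    test <- folds == f
    spec <- model
    spec$seed <- seed + 101L * f
    fit <- fitClassifier(spec, d$x[!test, , drop = FALSE], d$y[!test])
    out <- predictClassifier(fit, d$x[test, , drop = FALSE])
    pred[test] <- out$label
    score[test] <- out$score
  }
  cm <- confusionCounts(d$y, pred)
  met <- classificationMetrics(cm, scores = score, truth = d$y)
  attr(met, "confusion") <- cm
  attr(met, "predictions") <- data.frame(truth = d$y, label = pred,
                                         score = score)
  met
}

#' Enumerate feature combinations
#'
#' All non-empty subsets of the feature letters, ordered by decreasing
#' subset size and lexicographically within each size, so six features give
#' 63 combinations starting with `"ABCDEF"` and ending with `"F"`.
#'
#' @param features character vector of 1 to 12 single-letter feature codes.
#' @return character vector of letter-code strings.
#' @examples
#' head(enumerateCombinations())
#' @export
enumerateCombinations <- function(features = FEATURE_LETTERS) {
  features <- sort(unique(as.character(features)))
  if (!length(features) || length(features) > 12L)
    stop("need between 1 and 12 feature letters")
  unlist(lapply(rev(seq_along(features)), function(k) {
    apply(utils::combn(features, k), 2, paste, collapse = "")
  }))
}

#' Evaluate every feature combination under several classifiers
#'
#' For each combination, restricts the dataset to those feature columns,
#' runs [fiveFoldCv()] for every model, and records the per-model metrics
#' together with their model-averaged values (arithmetic mean of the
#' per-model values for each criterion; undefined (`NA`) values are dropped
#' from the average with their count recorded in the `n_undefined` column).
#'
#' @param data labeled feature data.frame (columns `A`..`F` or a subset,
#'   plus `label`).
#' @param models named list of [modelSpec()] objects (default: all seven
#'   families).
#' @param seed integer seed.
#' @param features which feature letters to enumerate over (default: those
#'   present in `data`).
#' @return data.frame in long layout: columns `combination`, `model` (one of
#'   the model names or `"average"`), `acc`, `sn`, `ppv`, `fscore`, `auc`,
#'   `n_undefined`.
#' @export
evaluateCombinations <- function(data, models = defaultModelSpecs(),
                                 seed = 1L, features = NULL) {
  if (is.null(features))
    features <- intersect(FEATURE_LETTERS, names(as.data.frame(data)))
  combos <- enumerateCombinations(features)
  out <- vector("list", length(combos))
  for (ci in seq_along(combos)) {
    letters_i <- strsplit(combos[ci], "")[[1]]
    rows <- vector("list", length(models))
    for (mi in seq_along(models)) {
      met <- fiveFoldCv(data, models[[mi]], seed = seed,
                        features = letters_i)
      rows[[mi]] <- cbind(combination = combos[ci],
                          model = names(models)[mi], met,
                          n_undefined = sum(is.na(unlist(met))))
    }
    per <- do.call(rbind, rows)
    avg <- vapply(METRIC_NAMES, function(m) mean(per[[m]], na.rm = TRUE),
                  numeric(1))
    rows[[length(models) + 1L]] <- cbind(
      combination = combos[ci], model = "average",
      as.data.frame(as.list(avg)),
      n_undefined = sum(is.na(per[, METRIC_NAMES])))
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Tolerance-aware ranking of feature combinations
#'
#' For one criterion, the "best set" is every combination whose
#' model-averaged value is within `tolerance` of the maximum (default
#' 0.001, i.e. values are considered tied when they differ by at most
#' 0.001). The overall winner across several criteria is the combination
#' appearing in the most best sets; ties are broken toward the larger
#' combination (more features), then lexicographically.
#'
#' @param reports output of [evaluateCombinations()] (only the `"average"`
#'   rows are used), or any data.frame with `combination` and criterion
#'   columns.
#' @param criterion one of `"acc"`, `"sn"`, `"ppv"`, `"fscore"`, `"auc"`.
#' @param tolerance numeric tie tolerance (default 0.001).
#' @return character vector: the best set for `criterion`, ordered by
#'   decreasing value.
#' @export
rankCombinations <- function(reports, criterion = "acc", tolerance = 0.001) {
  criterion <- match.arg(criterion, METRIC_NAMES)
  avg <- .averageRows(reports)
  if (!nrow(avg)) stop("no combination reports to rank")
  v <- avg[[criterion]]
  best <- avg$combination[v >= max(v, na.rm = TRUE) - tolerance & !is.na(v)]
  best[order(-v[match(best, avg$combination)])]
}

.averageRows <- function(reports) {
  reports <- as.data.frame(reports)
  if ("model" %in% names(reports))
    reports <- reports[reports$model == "average", , drop = FALSE]
  reports
}

#' @rdname rankCombinations
#' @param criteria criteria to vote over (default all five).
#' @return `selectBestCombination()`: a list with `winner` (single
#'   combination string), `wins` (named count of best-set appearances per
#'   combination) and `bestSets` (per-criterion best sets).
#' @export
selectBestCombination <- function(reports, criteria = METRIC_NAMES,
                                  tolerance = 0.001) {
  bestSets <- lapply(criteria, function(cr)
    rankCombinations(reports, cr, tolerance))
  names(bestSets) <- criteria
  all_combos <- unique(.averageRows(reports)$combination)
  wins <- vapply(all_combos, function(cb)
    sum(vapply(bestSets, function(bs) cb %in% bs, logical(1))), integer(1))
  top <- names(wins)[wins == max(wins)]
  top <- top[order(-nchar(top), top)]
  list(winner = top[1], wins = sort(wins, decreasing = TRUE),
       bestSets = bestSets)
}

#' Compare classifier families on one feature combination
#'
#' Cross-validates every model on the fixed combination and appends the
#' average performance: the mean of the five criteria (ACC, SN, PPV,
#' F-score, AUC) for that model. The winner is the model with the highest
#' average performance.
#'
#' @param data labeled feature data.frame.
#' @param combination letter-code string, e.g. `"ABCDEF"`.
#' @param models named list of [modelSpec()] objects.
#' @param seed integer seed.
#' @return data.frame with one row per model: `model`, the five metrics and
#'   `average_performance`; the winning model name is attached as attribute
#'   `"winner"`.
#' @export
compareModels <- function(data, combination = "ABCDEF",
                          models = defaultModelSpecs(), seed = 1L) {
  letters_i <- strsplit(combination, "")[[1]]
  rows <- lapply(seq_along(models), function(mi) {
    met <- fiveFoldCv(data, models[[mi]], seed = seed, features = letters_i)
    cbind(model = names(models)[mi], met)
  })
  out <- do.call(rbind, rows)
  out$average_performance <- averagePerformance(out)
  rownames(out) <- NULL
  attr(out, "winner") <- out$model[which.max(out$average_performance)]
  out
}

#' Average performance of a metric row
#'
#' Mean of the five criteria (`acc`, `sn`, `ppv`, `fscore`, `auc`) for each
#' row of a metric table; `NA` criteria are dropped from the mean.
#'
#' @param metrics data.frame with the five metric columns.
#' @return numeric vector, one value per row.
#' @export
averagePerformance <- function(metrics) {
  rowMeans(as.data.frame(metrics)[, METRIC_NAMES, drop = FALSE],
           na.rm = TRUE)
}

#' Train the final predictor on all rows
#'
#' Fits the chosen model family on the full labeled dataset restricted to
#' the chosen combination, and wraps it in a versioned artifact that
#' [saveModel()] / [loadModel()] round-trip bit-identically.
#'
#' @param data labeled feature data.frame.
#' @param model a [modelSpec()] (default: the EL family).
#' @param combination letter-code string.
#' @param seed integer seed.
#' @return object of class `"conswatModel"` with elements `version`,
#'   `family`, `combination`, `seed`, `classifier`.
#' @export
trainFinal <- function(data, model = modelSpec("EL"),
                       combination = "ABCDEF", seed = 1L) {
  letters_i <- strsplit(combination, "")[[1]]
  d <- .checkDataset(data, letters_i)
  spec <- model
  spec$seed <- seed
  fit <- fitClassifier(spec, d$x, d$y)
  structure(list(version = "conswat-model-1", family = model$family,
                 combination = combination, seed = as.integer(seed),
                 classifier = fit),
            class = "conswatModel")
}

#' @rdname trainFinal
#' @param object a `"conswatModel"` artifact.
#' @param path file path for the persisted artifact (RDS).
#' @export
saveModel <- function(object, path) {
  stopifnot(inherits(object, "conswatModel"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname trainFinal
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model artifact not found: ", path)
  object <- readRDS(path)
  if (!inherits(object, "conswatModel") ||
      !identical(object$version, "conswat-model-1"))
    stop("not a compatible conswat model artifact: ", path)
  object
}

#' Predict water conservation from a feature table
#'
#' Applies a trained artifact to new feature rows. Columns must include the
#' artifact's combination letters and contain no missing values. The label
#' is `"CWM"` when the positive-class score is at least 0.5.
#'
#' @param object a `"conswatModel"` from [trainFinal()] / [loadModel()].
#' @param newdata data.frame with the feature columns (e.g. from
#'   [featurizeStructure()] or a features TSV).
#' @return `newdata` with `pred_label` and `pred_score` columns appended.
#' @export
predictWaters <- function(object, newdata) {
  stopifnot(inherits(object, "conswatModel"))
  newdata <- as.data.frame(newdata)
  letters_i <- strsplit(object$combination, "")[[1]]
  missing <- setdiff(letters_i, names(newdata))
  if (length(missing))
    stop("feature column(s) missing from input: ",
         paste(missing, collapse = ", "))
  x <- newdata[, letters_i, drop = FALSE]
  if (anyNA(x) || any(!is.finite(as.matrix(x))))
    stop("feature columns contain missing or non-finite values")
  out <- predictClassifier(object$classifier, x)
  newdata$pred_label <- out$label
  newdata$pred_score <- out$score
  newdata
}
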