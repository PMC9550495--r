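MODEL_FAMILIES <- c("SVM", "KNN", "DT", "LR", "DA", "NB", "EL")

# Families whose decision function is scale-sensitive get a z-score
# standardization fitted on the training fold only.
SCALED_FAMILIES <- c("SVM", "KNN", "LR", "DA")

#' Classifier specifications
#'
#' The seven classifier families evaluated by the framework, with fixed,
#' documented default hyperparameters (all overridable through `hyper`):
#' SVM (RBF kernel, cost 1, gamma 1/p), KNN (k = 5, Euclidean), DT (CART,
#' Gini, unpruned), LR (binomial logistic regression), DA (linear
#' discriminant analysis), NB (Gaussian naive Bayes) and EL (ensemble
#' learning realized as 100 bagged decision trees, i.e. a random forest with
#' `mtry` equal to the number of features so every tree sees all features).
#'
#' @param family one of `"SVM"`, `"KNN"`, `"DT"`, `"LR"`, `"DA"`, `"NB"`,
#'   `"EL"`.
#' @param hyper named list of hyperparameter overrides.
#' @param seed integer seed used when fitting stochastic families.
#' @return object of class `"modelSpec"`.
#' @examples
#' modelSpec("EL")
#' @export
modelSpec <- function(family, hyper = list(), seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  structure(list(family = family, hyper = hyper, seed = as.integer(seed)),
            class = "modelSpec")
}

#' @rdname modelSpec
#' @param seed integer seed shared by all seven specs.
#' @export
defaultModelSpecs <- function(seed = 1L) {
  specs <- lapply(MODEL_FAMILIES, modelSpec, seed = seed)
  names(specs) <- MODEL_FAMILIES
  specs
}

#' @export
print.modelSpec <- function(x, ...) {
  cat("modelSpec:", x$family,
      if (length(x$hyper)) paste0("(",
        paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
        ")") else "(defaults)", "\n")
  invisible(x)
}

.hyperOr <- function(spec, name, default) {
  if (!is.null(spec$hyper[[name]])) spec$hyper[[name]] else default
}

# Fit one classifier on a feature matrix x (data.frame, numeric columns)
# and factor y with levels c(FWM, CWM). Returns an object predictClassifier
# understands. Standardization, when applicable, is fitted here and stored.
fitClassifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "modelSpec"))
  x <- as.data.frame(x)
  y <- factor(as.character(y), levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
  scaler <- NULL
  if (spec$family %in% SCALED_FAMILIES) {
    mu <- vapply(x, mean, numeric(1))
    sd <- vapply(x, stats::sd, numeric(1))
    sd[!is.finite(sd) | sd == 0] <- 1
    scaler <- list(mu = mu, sd = sd)
    x <- .applyScaler(x, scaler)
  }
  set.seed(spec$seed)
  fit <- switch(spec$family,
    SVM = e1071::svm(x = x, y = y, kernel = "radial",
                     cost = .hyperOr(spec, "cost", 1),
                     gamma = .hyperOr(spec, "gamma", 1 / ncol(x)),
                     probability = TRUE, scale = FALSE),
    KNN = list(train = x, y = y, k = .hyperOr(spec, "k", 5L)),
    DT = rpart::rpart(y ~ ., data = cbind(x, y = y), method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = .hyperOr(spec, "cp", 0.01),
                        minsplit = .hyperOr(spec, "minsplit", 20L))),
    LR = suppressWarnings(
      stats::glm(y ~ ., data = cbind(x, y = y), family = stats::binomial())),
    DA = MASS::lda(y ~ ., data = cbind(x, y = y)),
    NB = e1071::naiveBayes(x = x, y = y),
    EL = randomForest::randomForest(
      x = x, y = y, ntree = .hyperOr(spec, "ntree", 100L),
      mtry = .hyperOr(spec, "mtry", ncol(x)),
      nodesize = .hyperOr(spec, "nodesize", 1L)))
  structure(list(family = spec$family, fit = fit, scaler = scaler,
                 features = colnames(x), seed = spec$seed),
            class = "conswatClassifier")
}

.applyScaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  as.data.frame(sweep(sweep(as.matrix(x), 2, scaler$mu), 2, scaler$sd, "/"))
}

# Predict labels + positive-class probability scores. Every family returns a
# probability in [0, 1]; the label is score >= 0.5 except KNN/DT-style
# majority votes, where score and label agree by construction.
predictClassifier <- function(object, newx) {
  stopifnot(inherits(object, "conswatClassifier"))
  newx <- as.data.frame(newx)[, object$features, drop = FALSE]
  newx <- .applyScaler(newx, object$scaler)
  score <- switch(object$family,
    SVM = {
      pr <- stats::predict(object$fit, newx, probability = TRUE)
      attr(pr, "probabilities")[, POSITIVE_CLASS]
    },
    KNN = {
      set.seed(object$seed)  # random tie-breaks in the vote
      pred <- class::knn(object$fit$train, newx, object$fit$y,
                         k = object$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == POSITIVE_CLASS, p, 1 - p)
    },
    DT = stats::predict(object$fit, newx, type = "prob")[, POSITIVE_CLASS],
    LR = as.numeric(stats::predict(object$fit, newx, type = "response")),
    DA = stats::predict(object$fit, newx)$posterior[, POSITIVE_CLASS],
    NB = stats::predict(object$fit, newx, type = "raw")[, POSITIVE_CLASS],
    EL = stats::predict(object$fit, newx, type = "prob")[, POSITIVE_CLASS])
  score <- as.numeric(score)
  label <- ifelse(score >= 0.5, POSITIVE_CLASS, NEGATIVE_CLASS)
  data.frame(label = label, score = score, stringsAsFactors = FALSE)
}
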