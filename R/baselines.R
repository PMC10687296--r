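# Comparison models: gain-ratio attribute scoring (implemented here) and
# thin wrappers over established regressors behind one fit/predict
# contract -- decision trees (rpart), support vector regression (e1071) and
# a Gaussian-kernel RBF regressor (kernlab::gausspr; used in place of the
# symmetric-fuzzy-means-trained RBF network, which is out of scope).

shannon_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gain ratio of a categorical attribute
#'
#' Information gain of `target` given `feature` divided by the feature's
#' split information (its own entropy), both in bits.  The normalisation
#' corrects information gain's bias toward attributes with many distinct
#' values.  A feature with zero split information (a single category) has
#' no splitting power; the ratio is defined as 0 with a warning.
#'
#' @param feature Categorical vector (factor, character or discrete).
#' @param target Categorical vector of the same length.
#' @return Gain ratio in `[0, 1]`.
#' @examples
#' gain_ratio(c("a", "a", "b", "b"), c(1, 1, 0, 0))   # 1: perfect split
#' gain_ratio(c("a", "a", "b", "b"), c(1, 0, 1, 0))   # 0: independent
#' @export
gain_ratio <- function(feature, target) {
  if (length(feature) != length(target) || length(feature) < 2L)
    stop("feature and target must have equal length >= 2", call. = FALSE)
  h_target <- shannon_entropy(target)
  split_info <- shannon_entropy(feature)
  if (split_info == 0) {
    warning("zero split information: single-valued feature; gain ratio 0")
    return(0)
  }
  groups <- split(target, feature)
  h_cond <- sum(vapply(groups, function(g)
    length(g) / length(target) * shannon_entropy(g), numeric(1L)))
  gain <- h_target - h_cond
  max(0, gain / split_info)
}

BASELINE_IDS <- c("DT-GE", "DT-RE", "DT-AG", "SVR-LNR", "SVR-POLY",
                  "RBF-S", "RBF-N")

#' Baseline model specification
#'
#' @param model_id One of `"DT-GE"`, `"DT-RE"`, `"DT-AG"` (decision tree;
#'   the suffix names the stratification of the training table it is meant
#'   for), `"SVR-LNR"`, `"SVR-POLY"` (support vector regression with linear
#'   or polynomial kernel), `"RBF-S"`, `"RBF-N"` (Gaussian RBF regressor on
#'   z-standardized or min-max-normalized features).
#' @param hyperparameters Named list passed to the underlying fitter;
#'   library defaults when empty.
#' @return An object of class `"baseline_spec"`.
#' @export
baseline_spec <- function(model_id, hyperparameters = list()) {
  if (!model_id %in% BASELINE_IDS)
    stop("unknown baseline model id: ", model_id, call. = FALSE)
  structure(list(model_id = model_id,
                 hyperparameters = hyperparameters),
            class = "baseline_spec")
}

scale_features <- function(X, centre, scale) {
  sweep(sweep(X, 2L, centre, "-"), 2L, scale, "/")
}

#' Fit a baseline model
#'
#' Uniform contract: the model is fitted to the dataset's feature matrix
#' with the percent-scale prevalence as response; predictions are on the
#' percent scale.  Refitting with the same seed reproduces the model.
#'
#' @param spec A [baseline_spec()] (or a model id string).
#' @param dataset An `"ann_dataset"`.
#' @param rows Training row indices (default all).
#' @param seed Integer seed (some fitters draw random numbers).
#' @return An object of class `"baseline_fit"` with a `predict` method
#'   taking the dataset and optional row indices.
#' @export
fit_baseline <- function(spec, dataset, rows = NULL, seed = 1L) {
  if (is.character(spec)) spec <- baseline_spec(spec)
  stopifnot(inherits(spec, "baseline_spec"),
            inherits(dataset, "ann_dataset"))
  if (is.null(rows)) rows <- seq_len(nrow(dataset$X))
  X <- dataset$X[rows, , drop = FALSE]
  y <- dataset$y[rows]
  hp <- spec$hyperparameters
  id <- spec$model_id
  set.seed(as.integer(seed))

  if (length(unique(y)) == 1L) {
    # degenerate constant target: every sane regressor predicts the
    # constant; several library fitters reject it, so short-circuit
    return(structure(list(spec = spec, model = NULL, pre = NULL,
                          constant = y[1L]),
                     class = "baseline_fit"))
  }

  pre <- NULL
  if (id %in% c("RBF-S", "RBF-N")) {
    # drop constant columns before scaling, then standardize or normalize
    keep <- which(apply(X, 2L, function(v) length(unique(v)) > 1L))
    Xk <- X[, keep, drop = FALSE]
    if (id == "RBF-S") {
      centre <- colMeans(Xk); scl <- apply(Xk, 2L, stats::sd)
    } else {
      centre <- apply(Xk, 2L, min)
      scl <- apply(Xk, 2L, max) - centre
    }
    scl[scl == 0] <- 1
    pre <- list(keep = keep, centre = centre, scale = scl)
    X <- scale_features(Xk, centre, scl)
  }

  model <- switch(
    id,
    `DT-GE` = , `DT-RE` = , `DT-AG` = {
      df <- data.frame(y = y, X)
      ctrl <- do.call(rpart::rpart.control,
                      c(list(minsplit = 2L, cp = 0.001), hp))
      rpart::rpart(y ~ ., data = df, method = "anova", control = ctrl)
    },
    `SVR-LNR` = do.call(e1071::svm,
                        c(list(x = X, y = y, kernel = "linear"), hp)),
    `SVR-POLY` = do.call(e1071::svm,
                         c(list(x = X, y = y, kernel = "polynomial"), hp)),
    `RBF-S` = , `RBF-N` = do.call(kernlab::gausspr,
                                  c(list(x = X, y = y), hp)))

  structure(list(spec = spec, model = model, pre = pre),
            class = "baseline_fit")
}

#' @rdname fit_baseline
#' @param object A `"baseline_fit"`.
#' @param ... Unused.
#' @export
predict.baseline_fit <- function(object, dataset, rows = NULL, ...) {
  stopifnot(inherits(dataset, "ann_dataset"))
  if (is.null(rows)) rows <- seq_len(nrow(dataset$X))
  X <- dataset$X[rows, , drop = FALSE]
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(X)))
  id <- object$spec$model_id
  if (!is.null(object$pre)) {
    X <- scale_features(X[, object$pre$keep, drop = FALSE],
                        object$pre$centre, object$pre$scale)
  }
  if (id %in% c("DT-GE", "DT-RE", "DT-AG")) {
    as.numeric(stats::predict(object$model,
                              newdata = as.data.frame(X)))
  } else if (id %in% c("SVR-LNR", "SVR-POLY")) {
    as.numeric(stats::predict(object$model, X))
  } else {
    as.numeric(kernlab::predict(object$model, X))
  }
}
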