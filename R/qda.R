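#' Quadratic discriminant analysis with leave-one-out validation
#'
#' QDA classifies plots into the presence (1) and absence (0) groups by
#' maximizing the Gaussian posterior with group-specific covariance matrices,
#' \deqn{\delta_g(x) = -\tfrac12 \log|\Sigma_g|
#'   - \tfrac12 (x-\mu_g)^T \Sigma_g^{-1} (x-\mu_g) + \log \pi_g,}
#' with prior probabilities equal to the relative group sizes (the study's
#' convention). Performance is summarized by specificity (probability of
#' correctly classifying an absence), sensitivity (correctly classifying a
#' presence) and the overall error rate, each for resubstitution and for the
#' leave-one-out jackknife (each object classified by a model fitted without
#' it, priors recomputed from the remaining objects).
#'
#' @name qda_analysis
NULL

#' Fit a QDA classifier
#'
#' Thin wrapper over [MASS::qda()] with priors equal to relative group sizes
#' by default. A group whose covariance matrix is singular (too few objects
#' or constant features) raises an explicit error; there is no silent
#' regularization.
#'
#' @param features numeric matrix or data frame (objects x features).
#' @param labels 0/1 group labels.
#' @param priors `"proportions"` (default) or a numeric vector of two priors
#'   summing to 1, ordered (group 0, group 1).
#' @return Object of class `vole_qda` wrapping the `MASS::qda` fit.
#' @export
qda_fit <- function(features, labels, priors = "proportions") {
  x <- as.matrix(features)
  g <- factor(labels, levels = c(0, 1))
  stopifnot(nrow(x) == length(g), !anyNA(x))
  p <- ncol(x)
  if (any(table(g) < p + 1))
    stop("each group needs at least p + 1 objects for a non-singular covariance")
  pr <- if (identical(priors, "proportions")) as.vector(table(g)) / length(g)
        else priors
  fit <- tryCatch(MASS::qda(x, g, prior = pr),
                  error = function(e) stop("singular group covariance: ",
                                           conditionMessage(e), call. = FALSE))
  structure(list(fit = fit, priors = pr), class = "vole_qda")
}

#' Classify objects with a fitted QDA model
#'
#' @param model a `vole_qda` from [qda_fit()].
#' @param features matrix/data frame of objects to classify.
#' @return Integer vector of predicted labels (0/1).
#' @export
qda_predict <- function(model, features) {
  as.integer(as.character(stats::predict(model$fit, as.matrix(features))$class))
}

#' Specificity, sensitivity and error rate of a classification
#'
#' @param truth,predicted 0/1 vectors.
#' @return Named vector: `specificity` P(correct | group 0), `sensitivity`
#'   P(correct | group 1), `error_rate` overall misclassification.
#' @export
classification_outcome <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  c(specificity = mean(predicted[truth == 0] == 0),
    sensitivity = mean(predicted[truth == 1] == 1),
    error_rate = mean(predicted != truth))
}

#' Resubstitution and leave-one-out QDA performance
#'
#' Resubstitution classifies the training objects with the full model.
#' Leave-one-out refits the classifier n times, each time without one object,
#' recomputing the group priors from the n - 1 remaining objects, and
#' classifies the held-out object. A fold whose reduced training set yields a
#' singular group covariance is flagged and its object counted as
#' misclassified (with a warning).
#'
#' @param features matrix/data frame (objects x features).
#' @param labels 0/1 labels.
#' @param priors as in [qda_fit()]; `"proportions"` recomputes per fold.
#' @return List with `resubstitution` and `loo` (each a
#'   [classification_outcome()] vector), `loo_predicted`, and
#'   `singular_folds` (indices).
#' @export
qda_loo <- function(features, labels, priors = "proportions") {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  model <- qda_fit(x, labels, priors)
  resub <- classification_outcome(labels, qda_predict(model, x))
  n <- nrow(x)
  pred <- integer(n)
  singular <- integer(0)
  for (i in seq_len(n)) {
    fold <- tryCatch(qda_fit(x[-i, , drop = FALSE], labels[-i], priors),
                     error = function(e) NULL)
    if (is.null(fold)) {
      singular <- c(singular, i)
      pred[i] <- 1L - labels[i]       # counted as misclassified
    } else {
      pred[i] <- qda_predict(fold, x[i, , drop = FALSE])
    }
  }
  if (length(singular))
    warning(sprintf("%d leave-one-out fold(s) had singular covariance; objects counted as misclassified",
                    length(singular)))
  list(resubstitution = resub,
       loo = classification_outcome(labels, pred),
       loo_predicted = pred, singular_folds = singular)
}

#' QDA performance table over predictor sets
#'
#' Runs [qda_loo()] for each named set of predictor columns and collects
#' specificity, sensitivity and error rate, resubstitution first with the
#' leave-one-out value alongside.
#'
#' @param data data frame holding the predictors and the response.
#' @param response name of the 0/1 response column.
#' @param predictor_sets named list of character vectors of column names.
#' @return `data.frame` with one row per predictor set.
#' @export
qda_table <- function(data, response, predictor_sets) {
  rows <- lapply(names(predictor_sets), function(nm) {
    vars <- predictor_sets[[nm]]
    r <- qda_loo(data[, vars, drop = FALSE], data[[response]])
    data.frame(predictors = nm,
               specificity = r$resubstitution["specificity"],
               specificity_loo = r$loo["specificity"],
               sensitivity = r$resubstitution["sensitivity"],
               sensitivity_loo = r$loo["sensitivity"],
               error_rate = r$resubstitution["error_rate"],
               error_rate_loo = r$loo["error_rate"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
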