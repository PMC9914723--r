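#' Stratified case-level train/test split
#'
#' Splits at the subject level so the two lateralities of one subject never
#' straddle the split, stratified by label so class proportions are
#' preserved (to rounding). Reproducible under a fixed seed.
#'
#' @param records tibble with columns `id`, `label`, and optionally
#'   `subject` (defaults to one subject per case).
#' @param train_fraction fraction of subjects assigned to training.
#' @param seed RNG seed.
#' @return `list(train = ids, test = ids)`.
#' @export
split_cases <- function(records, train_fraction = 0.70, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!"subject" %in% names(records))
    records$subject <- seq_len(nrow(records))
  subj <- records |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(label = dplyr::first(.data$label), .groups = "drop")
  if (any(table(subj$label) < 2))
    stop("each class needs at least two subjects", call. = FALSE)
  train_subjects <- with_seed(seed, {
    unlist(lapply(split(subj$subject, subj$label), function(s) {
      n_tr <- round(train_fraction * length(s))
      n_tr <- min(max(n_tr, 1L), length(s) - 1L)
      sample(s, n_tr)
    }))
  })
  list(train = records$id[records$subject %in% train_subjects],
       test  = records$id[!records$subject %in% train_subjects])
}

classifier_names <- function() c("svm", "rf", "ann", "knn", "nb", "dt")

# feature matrix for modelling: canonical feature columns when present,
# otherwise every numeric column except bookkeeping ones
clf_feature_names <- function(table) {
  feats <- intersect(names(table), feature_names())
  if (length(feats)) return(feats)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  setdiff(num, c("subject", "x", "y", "radius"))
}

#' Train one of the six benchmark classifiers
#'
#' Supported classifiers and defaults (all exposed via `hyper`): support
#' vector machine with RBF kernel (`cost = 1`, `gamma = 1/p`), random
#' forest (500 trees), single-hidden-layer neural network (16 units, decay
#' 0.01, 300 iterations), k-nearest neighbours (`k = 5`), Gaussian naive
#' Bayes, and a CART decision tree. Features are standardized with
#' training-set statistics for svm/ann/knn. Deterministic under a fixed
#' seed; every model exposes a continuous score for ROC analysis.
#'
#' @param name one of `"svm"`, `"rf"`, `"ann"`, `"knn"`, `"nb"`, `"dt"`.
#' @param train_table tibble with a `label` column plus feature columns.
#' @param seed RNG seed.
#' @param positive label value of the positive class (default: the last
#'   factor level).
#' @param hyper named list overriding hyperparameter defaults.
#' @return An object of class `mammo_clf`; `predict()` on it returns a
#'   tibble with `score` (probability-like, larger = more positive) and
#'   `class`.
#' @export
train_classifier <- function(name, train_table, seed = 1L, positive = NULL,
                             hyper = list()) {
  if (!name %in% classifier_names())
    stop("unknown classifier: ", name, call. = FALSE)
  feats <- clf_feature_names(train_table)
  y <- as.factor(train_table$label)
  if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(y)[2]
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  X <- as.matrix(as.data.frame(train_table)[, feats, drop = FALSE])
  scaled <- name %in% c("svm", "ann", "knn")
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- if (scaled) scale(X, ctr, scl) else X
  h <- utils::modifyList(list(cost = 1, gamma = 1 / ncol(X), ntree = 500,
                              size = 16, decay = 0.01, maxit = 300,
                              k = 5), hyper)
  fit <- with_seed(seed, switch(name,
    svm = e1071::svm(Xs, y, kernel = "radial", cost = h$cost,
                     gamma = h$gamma, probability = TRUE),
    rf  = randomForest::randomForest(Xs, y, ntree = h$ntree),
    ann = nnet::nnet(Xs, as.numeric(y == positive), size = h$size,
                     decay = h$decay, maxit = h$maxit, entropy = TRUE,
                     trace = FALSE),
    knn = list(X = Xs, y = y, k = h$k),
    nb  = e1071::naiveBayes(as.data.frame(Xs), y),
    dt  = rpart::rpart(label ~ ., method = "class",
                       data = data.frame(Xs, label = y))))
  structure(list(name = name, fit = fit, features = feats,
                 center = ctr, scale = scl, scaled = scaled,
                 levels = levels(y), positive = positive, seed = seed),
            class = "mammo_clf")
}

#' @rdname train_classifier
#' @param object a `mammo_clf`.
#' @param newdata tibble containing the model's feature columns.
#' @param ... unused.
#' @export
predict.mammo_clf <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  Xs <- if (object$scaled) scale(X, object$center, object$scale) else X
  pos <- object$positive
  neg <- setdiff(object$levels, pos)
  out <- switch(object$name,
    svm = {
      pr <- with_seed(object$seed, predict(object$fit, Xs, probability = TRUE))
      s <- attr(pr, "probabilities")[, pos]
      list(score = s, class = as.character(pr))
    },
    rf = {
      s <- predict(object$fit, Xs, type = "prob")[, pos]
      list(score = s, class = as.character(predict(object$fit, Xs)))
    },
    ann = {
      s <- as.numeric(predict(object$fit, Xs))
      list(score = s, class = ifelse(s >= 0.5, pos, neg))
    },
    knn = {
      pr <- class::knn(object$fit$X, Xs, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      s <- ifelse(pr == pos, p, 1 - p)
      list(score = s, class = as.character(pr))
    },
    nb = {
      s <- predict(object$fit, as.data.frame(Xs), type = "raw")[, pos]
      list(score = s,
           class = as.character(predict(object$fit, as.data.frame(Xs))))
    },
    dt = {
      s <- predict(object$fit, data.frame(Xs), type = "prob")[, pos]
      list(score = s,
           class = as.character(predict(object$fit, data.frame(Xs),
                                        type = "class")))
    })
  tibble::tibble(score = unname(out$score), class = out$class)
}

#' Leave-one-out cross-validated scores
#'
#' For each case, a model trained on the remaining `n - 1` cases produces
#' its out-of-fold score and class.
#'
#' @inheritParams train_classifier
#' @param table tibble with `label` plus feature columns (`n >= 3` rows).
#' @return Tibble with one row per case: `id` (when present), `label`,
#'   `score`, `class`. A fold whose training set loses a class is scored
#'   `NA` with a warning.
#' @export
loocv_scores <- function(name, table, seed = 1L, positive = NULL,
                         hyper = list()) {
  n <- nrow(table)
  if (n < 3) stop("need at least 3 cases for LOOCV", call. = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    fold <- table[-i, ]
    if (length(unique(fold$label)) < 2) {
      warning("LOOCV fold ", i, " has a single class; scored NA",
              call. = FALSE)
      return(tibble::tibble(score = NA_real_, class = NA_character_))
    }
    m <- train_classifier(name, fold, seed = seed, positive = positive,
                          hyper = hyper)
    predict(m, table[i, ])
  })
  out <- dplyr::bind_rows(rows)
  out$label <- as.character(table$label)
  if ("id" %in% names(table)) out$id <- table$id
  out
}

#' Confusion table from truth and predictions
#'
#' @param truth,predicted vectors of class labels.
#' @param positive the positive class value.
#' @return A list with counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_table <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fn <- sum(truth == positive & predicted != positive)
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Metrics from a confusion table
#'
#' Accuracy, sensitivity, specificity, PPV, NPV, balanced accuracy and F1
#' by their standard formulas; a ratio with zero denominator is reported as
#' `NA`, never as 0.
#'
#' @param conf a [confusion_table()].
#' @param auc optional AUC to carry into the row.
#' @return A one-row tibble.
#' @export
metrics_from_confusion <- function(conf, auc = NA_real_) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- conf$TP; fp <- conf$FP; tn <- conf$TN; fn <- conf$FN
  sens <- safe(tp, tp + fn); spec <- safe(tn, tn + fp)
  ppv <- safe(tp, tp + fp); npv <- safe(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  tibble::tibble(accuracy = safe(tp + tn, tp + fp + tn + fn),
                 sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, auc = auc, ba = ba, f1 = f1)
}

#' Evaluate a fitted classifier on held-out cases
#'
#' Class predictions fill the confusion table; AUC comes from the
#' continuous scores via the midrank Mann-Whitney statistic.
#'
#' @param model a `mammo_clf`.
#' @param test_table tibble with `label` plus the model's features; cases
#'   must be unseen in training.
#' @return `list(confusion, metrics)` with `metrics` a one-row tibble
#'   (accuracy, sensitivity, specificity, PPV, NPV, AUC, BA, F1).
#' @export
evaluate <- function(model, test_table) {
  pred <- predict(model, test_table)
  truth <- as.character(test_table$label)
  conf <- confusion_table(truth, pred$class, model$positive)
  auc <- rank_auc(pred$score, truth == model$positive)
  list(confusion = conf, metrics = metrics_from_confusion(conf, auc))
}
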