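#' Texture feature table for a whole cohort under one pre-processing combo
#'
#' Runs the per-case pipeline — label removal, pre-processing combination,
#' k-means segmentation, pectoral removal, ROI extraction, angle-averaged
#' texture features — and stacks the results. Cases whose ROI cannot be
#' extracted are dropped with a message.
#'
#' @param cohort a `mammo_cohort` from [generate_cohort()], or a list of
#'   `list(record = ...)` elements.
#' @param combo one of [preproc_combos()].
#' @param params a [filter_params()].
#' @param k number of segmentation clusters.
#' @param patch_size ROI patch side (pixels).
#' @param levels,d texture quantization levels and GLCM distance.
#' @param seed seed forwarded to segmentation.
#' @return Tibble with `id`, `subject`, `tissue_class`, `severity` and the
#'   33 feature columns.
#' @export
extract_cohort_features <- function(cohort, combo = "CLAHE_USM",
                                    params = filter_params(), k = 3L,
                                    patch_size = 32L, levels = 8L, d = 1L,
                                    seed = 1L) {
  md <- if (inherits(cohort, "mammo_cohort")) cohort_metadata(cohort)
  rows <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]$record
    out <- tryCatch({
      rl <- remove_label(rec$image, params)
      pre <- apply_combo(rl$image, combo, params)
      seg <- kmeans_segment(pre, rl$breast_mask, k = k,
                            seed = derive_seed(seed, i))
      pect <- remove_pectoral(seg, pre, rec$laterality)
      roi <- extract_roi(rec, pect$image, seg, patch_size = patch_size)
      if (is.null(roi)) return(NULL)
      roi_features(roi, d = d, levels = levels)
    }, error = function(e) {
      message("case ", rec$id, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(out) && !is.null(md)) out$subject <- md$subject[i]
    out
  })
  dplyr::bind_rows(rows)
}

#' Run the full classifier-by-combination experiment
#'
#' Full factorial loop over pre-processing combinations and classifiers
#' for one task: features are extracted per combination, split 70/30 at
#' the case (subject) level, selected on the training split only (in
#' `"corr"` mode), and each classifier is trained and evaluated. The
#' report row shape mirrors the classifier x pre-processing metric tables
#' of the benchmark design (accuracy, sensitivity, specificity, PPV, NPV,
#' AUC, BA, F1).
#'
#' @param cohort a `mammo_cohort`.
#' @param task `"normal_abnormal"` (positive class: abnormal) or
#'   `"benign_malign"` (abnormal cases only; positive class: malign).
#' @param combos pre-processing combinations to run.
#' @param classifiers classifier names to run.
#' @param seed top-level seed; stage seeds are derived from it.
#' @param selection `"corr"` (train-split correlation filter at
#'   `threshold`), `"table1"` (the nine-feature preset), or `"none"`.
#' @param threshold correlation threshold for `"corr"` selection.
#' @param eval_mode `"test"` (held-out 30% metrics, the default) or
#'   `"loocv"` (pure leave-one-out over all cases).
#' @param train_fraction training fraction of the split.
#' @inheritParams extract_cohort_features
#' @return An object of class `mammo_report`: `task`, `rows` (one per
#'   classifier x combo, with `failed` flag), `config`, `seed`. `tidy()`
#'   returns the rows; `glance()` summarises; `autoplot()` draws the AUC
#'   comparison.
#' @export
run_experiment <- function(cohort, task = c("normal_abnormal",
                                            "benign_malign"),
                           combos = preproc_combos(),
                           classifiers = classifier_names(),
                           seed = 1L, params = filter_params(), k = 3L,
                           patch_size = 32L, levels = 8L, d = 1L,
                           selection = c("corr", "table1", "none"),
                           threshold = 0.90,
                           eval_mode = c("test", "loocv"),
                           train_fraction = 0.70) {
  task <- match.arg(task)
  selection <- match.arg(selection)
  eval_mode <- match.arg(eval_mode)
  positive <- if (task == "normal_abnormal") "abnormal" else "malign"

  rows <- list()
  for (combo in combos) {
    feats <- tryCatch(
      extract_cohort_features(cohort, combo, params, k, patch_size,
                              levels, d, seed = derive_seed(seed, 11L)),
      error = function(e) NULL)
    if (is.null(feats) || nrow(feats) == 0) {
      for (cl in classifiers)
        rows[[length(rows) + 1]] <- failed_row(cl, combo)
      next
    }
    if (task == "benign_malign") {
      feats <- dplyr::filter(feats, .data$tissue_class == "abnormal")
      feats$label <- feats$severity
    } else {
      feats$label <- feats$tissue_class
    }
    sp <- split_cases(feats, train_fraction, seed = derive_seed(seed, 17L))
    train <- feats[feats$id %in% sp$train, ]
    test <- feats[feats$id %in% sp$test, ]
    keep <- switch(selection,
      corr = correlation_filter(
        train[, intersect(names(train), feature_names())],
        threshold)$retained,
      table1 = table1_features(),
      none = intersect(names(feats), feature_names()))
    cols <- c("id", "subject", "label", keep)
    for (cl in classifiers) {
      row <- tryCatch({
        if (eval_mode == "test") {
          model <- train_classifier(cl, train[, cols],
                                    seed = derive_seed(seed, 23L),
                                    positive = positive)
          ev <- evaluate(model, test[, cols])
        } else {
          sc <- loocv_scores(cl, feats[, cols],
                             seed = derive_seed(seed, 23L),
                             positive = positive)
          conf <- confusion_table(sc$label, sc$class, positive)
          ev <- list(metrics = metrics_from_confusion(
            conf, rank_auc(sc$score, sc$label == positive)))
        }
        dplyr::bind_cols(tibble::tibble(classifier = cl, combo = combo),
                         ev$metrics, tibble::tibble(failed = FALSE))
      }, error = function(e) {
        message(cl, " x ", combo, " failed: ", conditionMessage(e))
        failed_row(cl, combo)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  structure(list(task = task, rows = dplyr::bind_rows(rows),
                 config = list(combos = combos, classifiers = classifiers,
                               selection = selection, threshold = threshold,
                               eval_mode = eval_mode,
                               train_fraction = train_fraction,
                               params = params, k = k,
                               patch_size = patch_size, levels = levels,
                               d = d),
                 seed = seed),
            class = "mammo_report")
}

failed_row <- function(classifier, combo) {
  dplyr::bind_cols(tibble::tibble(classifier = classifier, combo = combo),
                   metrics_from_confusion(list(TP = 0, FP = 0, TN = 0,
                                               FN = 0)),
                   tibble::tibble(failed = TRUE))
}

#' @export
print.mammo_report <- function(x, ...) {
  cat("<mammo_report>", x$task, "-", nrow(x$rows), "rows (",
      sum(x$rows$failed), "failed )\n")
  print(x$rows, n = 10)
  invisible(x)
}

#' @rdname run_experiment
#' @param x a `mammo_report`.
#' @param ... unused.
#' @method tidy mammo_report
#' @export
tidy.mammo_report <- function(x, ...) x$rows

#' @rdname run_experiment
#' @method glance mammo_report
#' @export
glance.mammo_report <- function(x, ...) {
  tibble::tibble(task = x$task, n_rows = nrow(x$rows),
                 n_failed = sum(x$rows$failed),
                 mean_auc = mean(x$rows$auc, na.rm = TRUE),
                 best_auc = suppressWarnings(max(x$rows$auc, na.rm = TRUE)))
}

#' @rdname run_experiment
#' @param object a `mammo_report`.
#' @method autoplot mammo_report
#' @export
autoplot.mammo_report <- function(object, ...) {
  rows <- dplyr::filter(object$rows, !.data$failed)
  rows$combo <- factor(rows$combo, levels = preproc_combos())
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$combo, y = .data$auc,
                                     colour = .data$classifier,
                                     group = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "pre-processing combination", y = "AUC",
                  colour = "classifier",
                  title = paste("Classifier AUC by pre-processing,",
                                sub("_", "/", object$task))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
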