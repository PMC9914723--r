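# small separable toy set shared across classifier tests
toy_set <- function(n_per = 20, gap = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = paste0("c", seq_len(2 * n_per)),
    f1 = c(rnorm(n_per, 0), rnorm(n_per, gap)),
    f2 = c(rnorm(n_per, 0), rnorm(n_per, gap)),
    label = rep(c("neg", "pos"), each = n_per))
}

test_that("the split is stratified, reproducible and subject-safe", {
  recs <- tibble::tibble(id = paste0("c", 1:100),
                         label = rep(c("a", "b"), c(60, 40)))
  sp <- split_cases(recs, 0.70, seed = 5)
  expect_equal(length(sp$train), 70)
  tr_lab <- recs$label[recs$id %in% sp$train]
  expect_equal(sum(tr_lab == "a"), 42, tolerance = 1)
  expect_equal(sum(tr_lab == "b"), 28, tolerance = 1)
  expect_identical(split_cases(recs, 0.70, seed = 5), sp)
  expect_false(identical(split_cases(recs, 0.70, seed = 6), sp))
  # paired lateralities stay on one side of the split
  recs$subject <- rep(1:50, each = 2)
  sp2 <- split_cases(recs, 0.70, seed = 7)
  subj_sides <- tapply(recs$id %in% sp2$train, recs$subject,
                       function(x) length(unique(x)))
  expect_true(all(subj_sides == 1))
  expect_error(split_cases(tibble::tibble(id = "a", label = "x",
                                          subject = 1), 0.7, 1),
               "at least two")
})

test_that("every classifier separates a separable toy set perfectly", {
  toy <- toy_set()
  for (cl in c("svm", "rf", "ann", "knn", "nb", "dt")) {
    m <- train_classifier(cl, toy, seed = 2, positive = "pos")
    pr <- predict(m, toy)
    expect_equal(mean(pr$class == toy$label), 1.0, info = cl)
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  toy <- toy_set(gap = 2, seed = 3)
  for (cl in c("svm", "rf", "ann", "knn", "nb", "dt")) {
    m1 <- train_classifier(cl, toy, seed = 9, positive = "pos")
    m2 <- train_classifier(cl, toy, seed = 9, positive = "pos")
    expect_identical(predict(m1, toy), predict(m2, toy), info = cl)
  }
  expect_error(train_classifier("mlp", toy, 1), "unknown")
})

test_that("label-permuted training yields chance-level test AUC", {
  set.seed(11)
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    tbl <- tibble::tibble(id = paste0("c", 1:n),
                          f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                          label = sample(rep(c("neg", "pos"), n / 2)))
    tr <- tbl[1:40, ]; te <- tbl[41:n, ]
    m <- train_classifier("rf", tr, seed = s, positive = "pos")
    evaluate(m, te)$metrics$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("LOOCV does the bookkeeping and nails a separable set", {
  toy <- toy_set(n_per = 6, gap = 8, seed = 4)
  sc <- loocv_scores("knn", toy, seed = 1, positive = "pos",
                     hyper = list(k = 1))
  expect_equal(nrow(sc), 12)
  expect_equal(sc$id, toy$id)
  expect_equal(mean(sc$class == toy$label), 1.0)
  tiny <- toy_set(n_per = 2, gap = 8)   # n = 4: 4 fits, each excluding one
  sc2 <- loocv_scores("dt", tiny, seed = 1, positive = "pos")
  expect_equal(nrow(sc2), 4)
  expect_error(loocv_scores("dt", tiny[1:2, ], 1), "at least 3")
})

test_that("metrics are algebraically consistent with the confusion table", {
  set.seed(12)
  for (s in 1:25) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp + tn + fn == 0) next
    conf <- list(TP = tp, FP = fp, TN = tn, FN = fn)
    m <- metrics_from_confusion(conf)
    tot <- tp + fp + tn + fn
    expect_equal(m$accuracy, (tp + tn) / tot)
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn),
                                  tolerance = 1e-12)
    else expect_true(is.na(m$sensitivity))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp),
                                  tolerance = 1e-12)
    else expect_true(is.na(m$specificity))
    if (tp + fp == 0) expect_true(is.na(m$ppv))
    if (!is.na(m$ba)) expect_equal(m$ba, (m$sensitivity + m$specificity) / 2,
                                   tolerance = 1e-12)
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                   tolerance = 1e-12)
  }
})

test_that("evaluate reports perfect and degenerate predictors correctly", {
  toy <- toy_set(gap = 10, seed = 5)
  m <- train_classifier("svm", toy, seed = 1, positive = "pos")
  ev <- evaluate(m, toy_set(gap = 10, seed = 6))
  expect_equal(unlist(ev$metrics[c("accuracy", "sensitivity", "specificity",
                                   "auc", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
  # all-positive predictor on a balanced set
  conf <- confusion_table(rep(c("pos", "neg"), each = 10),
                          rep("pos", 20), "pos")
  m2 <- metrics_from_confusion(conf)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  expect_equal(m2$ba, 0.5)
  expect_true(is.na(m2$npv))
})

test_that("report AUC equals exhaustive pairwise comparison for small n", {
  set.seed(13)
  for (s in 1:20) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, TRUE)
    lab <- c(TRUE, FALSE, rbinom(n - 2, 1, 0.5) == 1)
    got <- mammotex:::rank_auc(sc, lab)
    expect_equal(got, oracle_auc(sc, lab), tolerance = 1e-12)
  }
})
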