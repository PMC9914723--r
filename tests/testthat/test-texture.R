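test_that("quantization bins the in-mask range uniformly", {
  m <- matrix(c(0L, 255L, 128L, 64L), 2, 2)
  q <- quantize_gray(m, levels = 8)
  expect_equal(q[1, 1], 0L)
  expect_equal(q[2, 1], 7L)      # 255 lands in the top bin
  expect_equal(q[1, 2], 4L)      # 128 / 32
  const <- quantize_gray(matrix(90L, 3, 3), levels = 8)
  expect_true(all(const == 0L))
  set.seed(1)
  r <- quantize_gray(matrix(sample(0:255, 100, TRUE), 10, 10), levels = 6)
  expect_lte(length(unique(as.vector(r))), 6)
  # masked pixels become NA
  mask <- matrix(1L, 2, 2); mask[2, 2] <- 0L
  qm <- quantize_gray(m, mask, 8)
  expect_true(is.na(qm[2, 2]))
})

test_that("quantization is invariant to adding a constant intensity", {
  set.seed(2)
  m <- matrix(sample(10:100, 64, TRUE), 8, 8)
  expect_identical(quantize_gray(m, levels = 8),
                   quantize_gray(m + 50L, levels = 8))
})

test_that("GLCM counts hand-checkable cases symmetrically", {
  q <- make_quantized(matrix(0L, 2, 2), 1)
  M <- glcm(q, d = 1, theta = 0)
  expect_equal(M$counts[1, 1], 4)   # 2 pairs, both directions
  expect_equal(M$p[1, 1], 1)
  q2 <- make_quantized(matrix(rep(c(0, 0, 1, 1), 4), 4, 4, byrow = TRUE), 2)
  M2 <- glcm(q2, d = 1, theta = 0)
  expect_equal(M2$counts, oracle_glcm_counts(q2, 1, 0))
  # transposing the grid swaps 0 and 90 degrees
  q3 <- random_quantized(3)
  expect_equal(glcm(q3, 1, 0)$counts,
               glcm(make_quantized(t(q3), attr(q3, "levels")), 1, 90)$counts)
  expect_error(glcm(make_quantized(matrix(0L, 1, 1), 1), 1, 0), "degenerate")
})

test_that("GLCM features on a constant patch hit their closed forms", {
  q <- make_quantized(matrix(0L, 4, 4), 1)
  f <- suppressWarnings(glcm_features(glcm(q, 1, 0)))
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_maximum_probability"]), 1)
  expect_warning(glcm_features(glcm(q, 1, 0)), "degenerate")
})

test_that("a two-level checkerboard has unit contrast", {
  cb <- make_quantized(outer(1:6, 1:6, function(r, c) (r + c) %% 2), 2)
  f <- glcm_features(glcm(cb, 1, 0))
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(f, oracle_glcm_features(oracle_glcm_counts(cb, 1, 0)),
               tolerance = 1e-12)
})

test_that("GLCM matrices and all 22 features match brute force on random grids", {
  worst <- 0
  for (s in 1:100) {
    q <- random_quantized(s)
    th <- texture_angles()[(s %% 4) + 1]
    d <- 1 + (s %% 2)
    M <- tryCatch(glcm(q, d, th), error = function(e) NULL)
    if (is.null(M)) next
    expect_equal(M$counts, oracle_glcm_counts(q, d, th))
    expect_equal(sum(M$p), 1, tolerance = 1e-12)
    expect_equal(M$counts, t(M$counts))
    got <- suppressWarnings(glcm_features(M))
    want <- oracle_glcm_features(oracle_glcm_counts(q, d, th))
    rel <- abs(got - want) / pmax(abs(want), 1)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-10)
})

test_that("GLRLM counts runs by hand on small cases", {
  q <- make_quantized(matrix(c(5L, 5L, 5L, 2L), 1, 4), 6)
  R <- glrlm(q, 0)
  expect_equal(R$r[6, 3], 1)   # level 5 (index 6), run length 3
  expect_equal(R$r[3, 1], 1)   # level 2 (index 3), run length 1
  expect_equal(R$Nr, 2)
  const <- make_quantized(matrix(1L, 4, 4), 2)
  Rc <- glrlm(const, 0)
  expect_equal(Rc$r[2, 4], 4)  # one full-width run per row
  expect_equal(sum(col(Rc$r) * Rc$r), Rc$Np)
})

test_that("run-length conservation holds at every angle", {
  for (s in 1:25) {
    q <- random_quantized(s + 200)
    for (th in texture_angles()) {
      R <- glrlm(q, th)
      expect_equal(sum(col(R$r) * R$r), sum(!is.na(q)))
    }
  }
})

test_that("GLRLM features hit closed forms and the brute-force oracle", {
  single <- make_quantized(matrix(3L, 1, 1), 4)
  f1 <- glrlm_features(glrlm(single, 0))
  expect_equal(unname(f1[c("glrlm_sre", "glrlm_lre", "glrlm_rp")]),
               c(1, 1, 1))
  const <- make_quantized(matrix(0L, 4, 4), 1)
  f2 <- glrlm_features(glrlm(const, 0))
  expect_equal(unname(f2["glrlm_sre"]), 1 / 16)
  expect_equal(unname(f2["glrlm_lre"]), 16)
  expect_equal(unname(f2["glrlm_rp"]), 4 / 16)
  worst <- 0
  for (s in 1:100) {
    q <- random_quantized(s + 500)
    th <- texture_angles()[(s %% 4) + 1]
    R <- glrlm(q, th)
    want_R <- oracle_glrlm(q, th)
    expect_equal(R$r[, seq_len(ncol(want_R))], want_R)
    got <- glrlm_features(R)
    want <- oracle_glrlm_features(want_R, sum(!is.na(q)))
    rel <- abs(got - want) / pmax(abs(want), 1)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-10)
})

test_that("an ROI yields 33 finite angle-averaged features", {
  ph <- generate_phantom(phantom_params(seed = 61, size = 160,
                                        lesion = "malign",
                                        lesion_center = c(60, 90),
                                        lesion_radius = 11))
  rl <- remove_label(ph$record$image)
  fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
  pc <- remove_pectoral(fit, rl$image, "right")
  roi <- extract_roi(ph$record, pc$image, fit, patch_size = 32)
  fv <- roi_features(roi)
  feats <- unlist(fv[feature_names()])
  expect_equal(length(feats), 33)
  expect_equal(sum(startsWith(names(feats), "glcm_")), 22)
  expect_equal(sum(startsWith(names(feats), "glrlm_")), 11)
  expect_true(all(is.finite(feats)))
  expect_gt(fv$glcm_energy, 0); expect_lte(fv$glcm_energy, 1)
  expect_gte(fv$glcm_entropy, 0)
  expect_gt(fv$glrlm_rp, 0); expect_lte(fv$glrlm_rp, 1)
})

test_that("angle averaging is invariant to 90-degree rotation", {
  set.seed(7)
  patch <- gray_image(matrix(sample(0:255, 24 * 24, TRUE), 24, 24))
  rot <- gray_image(t(unclass(patch))[, 24:1])   # 90-degree rotation
  a <- roi_features(patch)
  b <- roi_features(rot)
  expect_equal(unlist(a[feature_names()]), unlist(b[feature_names()]),
               tolerance = 1e-12)
})

test_that("isotropic constant ROI averages equal single-angle values", {
  q <- make_quantized(matrix(0L, 6, 6), 1)
  single <- suppressWarnings(
    c(glcm_features(glcm(q, 1, 0)), glrlm_features(glrlm(q, 0))))
  fv <- suppressWarnings(roi_features(gray_image(matrix(40L, 6, 6))))
  # GLCM features identical across angles for a constant grid
  expect_equal(unlist(fv[glcm_feature_names()]),
               single[glcm_feature_names()])
})
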