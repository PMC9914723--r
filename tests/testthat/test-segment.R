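test_that("two symmetric clusters give the closed-form centroids and J", {
  fit <- kmeans_segment(gray_image(matrix(c(0, 1, 10, 11), 2, 2)), k = 2)
  expect_equal(fit$centroids, c(0.5, 10.5))
  expect_equal(fit$J, 1.0)
  expect_true(fit$converged)
})

test_that("constant regions reduce k with a warning and reach J = 0", {
  expect_warning(fit <- kmeans_segment(gray_image(matrix(7L, 4, 4)), k = 3),
                 "reducing k")
  expect_equal(fit$J, 0)
  expect_equal(length(fit$centroids), 1)
})

test_that("the objective is monotonically non-increasing over iterations", {
  set.seed(13)
  for (i in 1:5) {
    img <- gray_image(matrix(sample(0:255, 900, TRUE), 30, 30))
    fit <- kmeans_segment(img, k = 4, seed = i)
    expect_true(all(diff(fit$J_trace) <= 1e-9))
  }
})

test_that("every pixel is assigned to its nearest centroid", {
  set.seed(14)
  img <- gray_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  fit <- kmeans_segment(img, k = 3)
  d <- abs(outer(as.numeric(unclass(img)), fit$centroids, "-"))
  nearest <- apply(d, 1, min)
  got <- d[cbind(seq_along(fit$assignment), as.vector(fit$assignment))]
  expect_equal(got, nearest)
})

test_that("k-means matches exhaustive partition enumeration on toys", {
  # draws from well-separated intensity modes, <= 16 pixels
  for (s in 1:20) {
    set.seed(s)
    k <- sample(2:3, 1)
    n <- sample(6:16, 1)
    centers <- sample(10:60, 1) + (seq_len(k) - 1) * sample(70:90, 1)
    group <- sort(rep_len(seq_len(k), n))
    v <- pmin(pmax(round(rnorm(n, centers[group], 5)), 0), 255)
    if (length(unique(v)) < k) next
    fit <- kmeans_segment(gray_image(matrix(v, 1)), k = k, seed = s)
    expect_equal(fit$J, oracle_kmeans_J(v, k), tolerance = 1e-10)
  }
})

test_that("noise-free phantom segmentation recovers the truth partition", {
  ph <- generate_phantom(phantom_params(seed = 51, size = 192,
                                        noise_gaussian_sd = 0,
                                        label_box = c(170, 4, 180, 10)))
  img <- unclass(ph$record$image)
  img[ph$masks$background == 1] <- 5L  # mask the label as remove_label would
  fit <- kmeans_segment(gray_image(img), k = 3, seed = 1)
  truth <- ph$masks$background * 1L + ph$masks$breast * 2L +
    ph$masks$pectoral * 3L
  expect_gt(mean(fit$assignment == truth), 0.99)
})

test_that("pectoral removal removes the wedge but spares breast and lesion", {
  ph <- generate_phantom(phantom_params(seed = 52, size = 192,
                                        lesion = "benign",
                                        lesion_center = c(70, 110),
                                        lesion_radius = 12,
                                        noise_gaussian_sd = 2))
  rl <- remove_label(ph$record$image)
  fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
  out <- remove_pectoral(fit, rl$image, "right")
  pect_truth <- ph$masks$pectoral == 1
  breast_truth <- ph$masks$breast == 1
  expect_gt(sum(out$pectoral_mask[pect_truth]) / sum(pect_truth), 0.90)
  expect_lt(sum(out$pectoral_mask[breast_truth]) / sum(breast_truth), 0.05)
  expect_equal(sum(out$pectoral_mask[ph$masks$lesion == 1]), 0)
})

test_that("no pectoral wedge means an empty pectoral mask", {
  ph <- generate_phantom(phantom_params(seed = 53, size = 128,
                                        pectoral_fraction = 0,
                                        noise_gaussian_sd = 0))
  rl <- remove_label(ph$record$image)
  fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
  expect_warning(out <- remove_pectoral(fit, rl$image, "right"), "corner")
  expect_equal(sum(out$pectoral_mask), 0)
})

test_that("left/right mirror phantoms give mirrored pectoral masks", {
  masks <- lapply(c("right", "left"), function(lat) {
    ph <- generate_phantom(phantom_params(seed = 54, size = 160,
                                          laterality = lat,
                                          noise_gaussian_sd = 0))
    rl <- remove_label(ph$record$image)
    fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
    remove_pectoral(fit, rl$image, lat)$pectoral_mask
  })
  mirrored <- masks[[2]][, rev(seq_len(ncol(masks[[2]])))]
  expect_identical(masks[[1]], mirrored)
})

test_that("ROIs are centred on the lesion and clipped at borders", {
  ph <- generate_phantom(phantom_params(seed = 55, size = 192,
                                        lesion = "malign",
                                        lesion_center = c(70, 110),
                                        lesion_radius = 12))
  rl <- remove_label(ph$record$image)
  fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
  pc <- remove_pectoral(fit, rl$image, "right")
  roi <- extract_roi(ph$record, pc$image, fit, patch_size = 32)
  expect_s3_class(roi, "mammo_roi")
  expect_equal(dim(roi$patch), c(32, 32))
  expect_equal(roi$provenance, "lesion-centered")
  # patch centred on the lesion: centre pixel of the patch is the lesion centre
  expect_equal(roi$center, c(70, 110))
  expect_gt(sum(roi$mask), 0)
  # lesion at the image corner still yields a valid, clipped patch
  rec2 <- ph$record
  rec2$lesion_center <- c(2, 110)
  roi2 <- extract_roi(rec2, pc$image, fit, patch_size = 32)
  expect_equal(dim(roi2$patch), c(32, 32))
  expect_gt(sum(roi2$mask), 0)
})

test_that("normal-case ROIs lie inside the breast", {
  ph <- generate_phantom(phantom_params(seed = 56, size = 192,
                                        noise_gaussian_sd = 2))
  rl <- remove_label(ph$record$image)
  fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
  pc <- remove_pectoral(fit, rl$image, "right")
  roi <- extract_roi(ph$record, pc$image, fit, patch_size = 32)
  expect_equal(roi$provenance, "cluster-derived")
  r0 <- roi$center[2] - 16 + 1; c0 <- roi$center[1] - 16 + 1
  inside <- ph$masks$breast[r0:(r0 + 31), c0:(c0 + 31)]
  expect_gt(mean(inside), 0.95)
})

test_that("abnormal records without geometry are skipped with a message", {
  ph <- generate_phantom(phantom_params(seed = 57, size = 128))
  rl <- remove_label(ph$record$image)
  fit <- kmeans_segment(rl$image, rl$breast_mask, k = 3, seed = 1)
  rec <- ph$record
  rec$tissue_class <- "abnormal"
  rec$lesion_center <- NULL
  expect_message(roi <- extract_roi(rec, rl$image, fit, 32), "skipped")
  expect_null(roi)
})
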