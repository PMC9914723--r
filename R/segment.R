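#' k-means intensity segmentation
#'
#' Lloyd's algorithm on pixel intensities, minimizing the within-cluster
#' sum of squared distances \eqn{J = \sum_j \sum_i \lVert x_i^{(j)} - c_j
#' \rVert^2}. Centroids are initialized at evenly spaced quantiles of the
#' intensity distribution, assignment uses Euclidean distance with ties
#' going to the lower-index cluster, and an empty cluster is re-seeded at
#' the point farthest from its current centroid. Mammograms separate into
#' three clusters — background, breast tissue, pectoral muscle — so
#' `k = 3` is the default. Pixels outside `breast_mask` are assigned to the
#' background (lowest-centroid) cluster by construction.
#'
#' @param img a [gray_image()].
#' @param breast_mask optional 0/1 matrix restricting the pixels that are
#'   clustered; `NULL` clusters the whole frame.
#' @param k number of clusters (>= 2); reduced with a warning when fewer
#'   distinct intensities exist.
#' @param seed RNG seed (the algorithm is deterministic; the seed only
#'   matters for degenerate re-seeding ties).
#' @param tol convergence threshold on centroid movement (intensity units).
#' @param max_iter iteration cap.
#' @return An object of class `mammo_kmeans`: `k`, `centroids` (ascending),
#'   `assignment` (integer matrix of cluster indices, 1 = background),
#'   `J` (final objective), `J_trace` (per-iteration objective),
#'   `iterations`, `converged`.
#' @examples
#' m <- gray_image(matrix(c(0, 1, 10, 11), 2, 2))
#' fit <- kmeans_segment(m, k = 2)
#' fit$centroids  # 0.5, 10.5
#' fit$J          # 1.0
#' @export
kmeans_segment <- function(img, breast_mask = NULL, k = 3L, seed = 1L,
                           tol = 1e-4, max_iter = 100L) {
  img <- gray_image(img)
  m <- as_pixel_matrix(img)
  idx <- if (is.null(breast_mask)) seq_along(m) else which(breast_mask > 0)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  v <- as.numeric(m[idx])
  ndist <- length(unique(v))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (ndist < k) {
    warning("only ", ndist, " distinct intensities; reducing k from ", k,
            " to ", ndist, call. = FALSE)
    k <- ndist
  }
  cen <- as.numeric(quantile(v, (seq_len(k) - 0.5) / k, names = FALSE))
  # quantile ties can duplicate centroids; nudge apart deterministically
  if (anyDuplicated(cen)) cen <- cen + (seq_len(k) - 1) * 1e-9

  assign_idx <- integer(length(v)); J_trace <- numeric(0)
  converged <- FALSE; it <- 0L
  with_seed(seed, {
    while (it < max_iter) {
      it <- it + 1L
      d2 <- outer(v, cen, function(a, b) (a - b)^2)
      assign_idx <- max.col(-d2, ties.method = "first")
      for (j in seq_len(k)) {          # re-seed empty clusters
        if (!any(assign_idx == j)) {
          far <- which.max(d2[cbind(seq_along(v), assign_idx)])
          cen[j] <- v[far]; assign_idx[far] <- j
        }
      }
      J_trace <- c(J_trace, sum((v - cen[assign_idx])^2))
      new_cen <- vapply(seq_len(k), function(j) mean(v[assign_idx == j]),
                        numeric(1))
      delta <- max(abs(new_cen - cen))
      cen <- new_cen
      if (delta < tol) { converged <- TRUE; break }
    }
  })
  # final assignment under converged centroids, clusters sorted by intensity
  d2 <- outer(v, cen, function(a, b) (a - b)^2)
  assign_idx <- max.col(-d2, ties.method = "first")
  J <- sum((v - cen[assign_idx])^2)
  J_trace <- c(J_trace, J)
  ord <- order(cen)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignment <- matrix(1L, nrow(m), ncol(m))
  assignment[idx] <- relabel[assign_idx]
  structure(list(k = k, centroids = cen[ord], assignment = assignment,
                 J = J, J_trace = J_trace, iterations = it,
                 converged = converged),
            class = "mammo_kmeans")
}

#' @export
print.mammo_kmeans <- function(x, ...) {
  cat("<mammo_kmeans> k =", x$k, " J =", signif(x$J, 6),
      " iterations =", x$iterations, "\n")
  cat("centroids:", paste(signif(x$centroids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname kmeans_segment
#' @param x a `mammo_kmeans` object.
#' @param ... unused.
#' @method tidy mammo_kmeans
#' @export
tidy.mammo_kmeans <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$k), centroid = x$centroids,
                 size = as.integer(tabulate(x$assignment, x$k)))
}

#' @rdname kmeans_segment
#' @method glance mammo_kmeans
#' @export
glance.mammo_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, J = x$J, iterations = x$iterations,
                 converged = x$converged)
}

#' Remove the pectoral muscle
#'
#' The connected component of the cluster touching the top corner on the
#' chest-wall side (top-left for a right breast, top-right for a left one)
#' is declared pectoral and zeroed. Only that connected component is
#' removed — not the whole cluster — so bright lesions sharing the cluster
#' are untouched.
#'
#' @param model a `mammo_kmeans` fit from [kmeans_segment()].
#' @param img the [gray_image()] that was segmented.
#' @param laterality `"right"` or `"left"`.
#' @return `list(image, pectoral_mask)`; when no non-background cluster
#'   touches the corner a warning is issued and nothing is removed.
#' @export
remove_pectoral <- function(model, img, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  img <- gray_image(img)
  m <- as_pixel_matrix(img)
  a <- model$assignment
  nr <- nrow(a); nc <- ncol(a)
  w <- min(5L, nr, nc)
  cols <- if (laterality == "right") seq_len(w) else nc - w + seq_len(w)
  win <- a[seq_len(w), cols, drop = FALSE]
  cand <- win[win > 1L]
  empty <- matrix(0L, nr, nc)
  if (length(cand) == 0) {
    warning("no cluster touches the chest-wall corner; nothing removed",
            call. = FALSE)
    return(list(image = img, pectoral_mask = empty))
  }
  c0 <- as.integer(names(which.max(table(cand))))
  labs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((a == c0) * 1)))
  win_labs <- labs[seq_len(w), cols, drop = FALSE]
  comp <- win_labs[win == c0][1]
  pect <- (labs == comp) * 1L
  m[pect == 1L] <- 0L
  list(image = gray_image(m), pectoral_mask = pect)
}

#' Extract a region of interest
#'
#' Abnormal cases get a square patch centred on the lesion (clipped to the
#' image bounds); normal cases get a patch centred on the centroid of the
#' brightest remaining cluster inside the breast, giving a comparable
#' dense-tissue sample. The ROI mask marks breast pixels (non-zero after
#' label and pectoral removal) within the patch.
#'
#' @param record a `mammo_record`.
#' @param cleaned the [gray_image()] after label and pectoral removal.
#' @param model the `mammo_kmeans` fit for `cleaned`'s segmentation.
#' @param patch_size square patch side (pixels).
#' @return An object of class `mammo_roi`: `source_id`, `patch`
#'   (gray_image), `mask` (0/1), `center` (`c(x, y)`, 0-based),
#'   `provenance` (`"lesion-centered"` or `"cluster-derived"`),
#'   `tissue_class`, `severity` — or `NULL` (with a message) for an
#'   abnormal record lacking lesion geometry.
#' @export
extract_roi <- function(record, cleaned, model, patch_size = 128L) {
  cleaned <- gray_image(cleaned)
  m <- as_pixel_matrix(cleaned)
  nr <- nrow(m); nc <- ncol(m)
  ps <- min(patch_size, nr, nc)
  if (record$tissue_class == "abnormal") {
    if (is.null(record$lesion_center)) {
      message("case ", record$id,
              ": abnormal without lesion geometry, skipped")
      return(NULL)
    }
    cr <- record$lesion_center[2] + 1L  # y -> row
    cc <- record$lesion_center[1] + 1L  # x -> col
    provenance <- "lesion-centered"
  } else {
    bright <- model$assignment == model$k & m > 0
    if (!any(bright)) bright <- m > 0
    w <- which(bright, arr.ind = TRUE)
    cr <- round(mean(w[, 1])); cc <- round(mean(w[, 2]))
    provenance <- "cluster-derived"
  }
  half <- floor(ps / 2)
  r0 <- min(max(cr - half, 1L), nr - ps + 1L)
  c0 <- min(max(cc - half, 1L), nc - ps + 1L)
  patch <- m[r0 + seq_len(ps) - 1L, c0 + seq_len(ps) - 1L, drop = FALSE]
  mask <- (patch > 0) * 1L
  if (sum(mask) == 0)
    stop("degenerate ROI: no breast pixels in patch for ", record$id,
         call. = FALSE)
  structure(list(source_id = record$id, patch = gray_image(patch),
                 mask = mask, center = c(cc - 1L, cr - 1L),
                 provenance = provenance,
                 tissue_class = record$tissue_class,
                 severity = record$severity),
            class = "mammo_roi")
}
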