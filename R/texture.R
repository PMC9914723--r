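#' Canonical texture feature names
#'
#' The 22 gray-level co-occurrence matrix (GLCM) features of the extended
#' Haralick family followed by the 11 gray-level run-length matrix (GLRLM)
#' features (Galloway/Chu normalizations), in the package's stable column
#' order.
#'
#' @return Character vector of 33 names.
#' @export
feature_names <- function() c(glcm_feature_names(), glrlm_feature_names())

#' @rdname feature_names
#' @export
glcm_feature_names <- function() paste0("glcm_", c(
  "autocorrelation", "contrast", "correlation_m", "correlation_p",
  "cluster_prominence", "cluster_shade", "dissimilarity", "energy",
  "entropy", "homogeneity_m", "homogeneity_p", "maximum_probability",
  "sum_of_squares", "sum_average", "sum_variance", "sum_entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2",
  "idn", "idmn"))

#' @rdname feature_names
#' @export
glrlm_feature_names <- function() paste0("glrlm_", c(
  "sre", "lre", "gln", "rln", "rp",
  "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge"))

#' Quantize a gray patch to a small number of levels
#'
#' Uniform binning of the in-mask intensity range \[min, max\] into
#' `levels` bins (bin width `(max - min + 1) / levels` on the integer
#' scale), so quantization is range-relative: adding a constant to every
#' pixel leaves the quantized grid unchanged. Out-of-mask pixels become
#' `NA` and are ignored by all texture counts.
#'
#' @param patch a [gray_image()] (or integer matrix).
#' @param mask optional 0/1 matrix; `NULL` uses every pixel.
#' @param levels number of gray levels (>= 2).
#' @return Integer matrix of levels `0 .. levels-1` with `NA` outside the
#'   mask.
#' @export
quantize_gray <- function(patch, mask = NULL, levels = 8L) {
  stopifnot(levels >= 2)
  m <- as_pixel_matrix(gray_image(patch))
  inm <- if (is.null(mask)) rep(TRUE, length(m)) else mask > 0
  if (!any(inm)) stop("empty mask", call. = FALSE)
  v <- m[inm]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(m), ncol(m))
  if (hi == lo) {
    q[inm] <- 0L
  } else {
    width <- (hi - lo + 1) / levels
    q[inm] <- pmin(as.integer(floor((m[inm] - lo) / width)), levels - 1L)
  }
  attr(q, "levels") <- as.integer(levels)
  q
}

# displacement (drow, dcol) for a texture angle, distance d
angle_offset <- function(theta, d = 1L) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135", call. = FALSE))
}

#' The four texture analysis angles
#'
#' Displacement directions (degrees) over which GLCM and GLRLM features
#' are computed and averaged.
#'
#' @return Numeric vector `c(0, 45, 90, 135)`.
#' @export
texture_angles <- function() c(0, 45, 90, 135)

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized levels for pixel pairs separated by
#' the `(d, theta)` displacement where both pixels are in-mask, accumulated
#' symmetrically (each pair counted in both directions).
#'
#' @param quantized output of [quantize_gray()].
#' @param d pixel distance (>= 1).
#' @param theta angle in degrees: 0, 45, 90 or 135.
#' @return An object of class `glcmatrix`: `counts` (Ng x Ng), `p`
#'   (normalized, sums to 1), `Ng`, `d`, `theta`.
#' @export
glcm <- function(quantized, d = 1L, theta = 0) {
  Ng <- attr(quantized, "levels")
  if (is.null(Ng)) Ng <- max(quantized, na.rm = TRUE) + 1L
  stopifnot(d >= 1)
  off <- angle_offset(theta, as.integer(d))
  nr <- nrow(quantized); nc <- ncol(quantized)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r2 <- rows + off[1]; c2 <- cols + off[2]
  rok <- rows[r2 >= 1 & r2 <= nr]; cok <- cols[c2 >= 1 & c2 <= nc]
  counts <- matrix(0, Ng, Ng)
  if (length(rok) && length(cok)) {
    a <- quantized[rok, cok, drop = FALSE]
    b <- quantized[rok + off[1], cok + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ia <- a[ok]; ib <- b[ok]
      tab <- tabulate(ia * Ng + ib + 1L, nbins = Ng * Ng)
      counts <- matrix(tab, Ng, Ng, byrow = TRUE)
      counts <- counts + t(counts)   # symmetric accumulation
    }
  }
  total <- sum(counts)
  if (total == 0) stop("degenerate ROI: no co-occurring pixel pair",
                       call. = FALSE)
  structure(list(counts = counts, p = counts / total, Ng = Ng,
                 d = as.integer(d), theta = theta), class = "glcmatrix")
}

# entropy in bits with the 0*log2(0) = 0 convention
entropy_bits <- function(x) {
  x <- x[x > 0]
  -sum(x * log2(x))
}

#' The 22 GLCM texture features
#'
#' Extended Haralick set over the normalized co-occurrence matrix `p` and
#' its marginals: autocorrelation, contrast, correlation (two estimators),
#' cluster prominence, cluster shade, dissimilarity, energy, entropy,
#' homogeneity (two estimators), maximum probability, sum of squares
#' (variance), sum average, sum variance, sum entropy, difference variance,
#' difference entropy, information measures of correlation 1 and 2, and the
#' normalized inverse differences IDN and IDMN. Logarithms are base 2 with
#' `0 * log 0 = 0`; gray levels are indexed from 1 in the weights. When a
#' marginal is degenerate (`sd = 0`) the correlation-type features are
#' defined as 0 with a warning.
#'
#' @param M a `glcmatrix` from [glcm()].
#' @return Named numeric vector of length 22 (names from
#'   [glcm_feature_names()]).
#' @export
glcm_features <- function(M) {
  p <- M$p; Ng <- M$Ng
  i <- matrix(seq_len(Ng), Ng, Ng)         # row level index, 1-based
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))

  ks <- 2:(2 * Ng)
  pxy_sum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(Ng - 1)
  pxy_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))

  HX <- entropy_bits(px); HY <- entropy_bits(py); HXY <- entropy_bits(p)
  pxpy <- outer(px, py)
  HXY1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  HXY2 <- entropy_bits(pxpy)

  degenerate <- sx == 0 || sy == 0
  if (degenerate)
    warning("degenerate GLCM marginal (sd = 0); correlation features set to 0",
            call. = FALSE)
  corr_m <- if (degenerate) 0 else sum((i - mux) * (j - muy) * p) / (sx * sy)
  corr_p <- if (degenerate) 0 else (sum(i * j * p) - mux * muy) / (sx * sy)

  savg <- sum(ks * pxy_sum)
  dmean <- sum(kd * pxy_diff)
  eps <- 1e-12
  imc1 <- (HXY - HXY1) / max(HX, HY, eps)
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))

  setNames(c(
    sum(i * j * p),                                  # autocorrelation
    sum((i - j)^2 * p),                              # contrast
    corr_m, corr_p,
    sum((i + j - mux - muy)^4 * p),                  # cluster prominence
    sum((i + j - mux - muy)^3 * p),                  # cluster shade
    sum(abs(i - j) * p),                             # dissimilarity
    sum(p^2),                                        # energy
    HXY,                                             # entropy
    sum(p / (1 + abs(i - j))),                       # homogeneity (m)
    sum(p / (1 + (i - j)^2)),                        # homogeneity (p)
    max(p),                                          # maximum probability
    sum((i - mux)^2 * p),                            # sum of squares
    savg,                                            # sum average
    sum((ks - savg)^2 * pxy_sum),                    # sum variance
    entropy_bits(pxy_sum),                           # sum entropy
    sum((kd - dmean)^2 * pxy_diff),                  # difference variance
    entropy_bits(pxy_diff),                          # difference entropy
    imc1, imc2,
    sum(p / (1 + abs(i - j) / Ng)),                  # IDN
    sum(p / (1 + (i - j)^2 / Ng^2))                  # IDMN
  ), glcm_feature_names())
}

# scan lines of a quantized grid in direction theta, as a list of vectors
direction_lines <- function(quantized, theta) {
  nr <- nrow(quantized); nc <- ncol(quantized)
  switch(as.character(theta),
    "0"   = lapply(seq_len(nr), function(r) quantized[r, ]),
    "90"  = lapply(seq_len(nc), function(c) quantized[, c]),
    "45"  = { rc <- row(quantized) + col(quantized)
              unname(split(quantized, rc)) },
    "135" = { rc <- row(quantized) - col(quantized)
              unname(split(quantized, rc)) },
    stop("theta must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of constant quantized level along the scan lines of
#' direction `theta`; out-of-mask (`NA`) pixels break runs. The invariant
#' \eqn{\sum_{i,j} j \, r(i,j) = N_p} (runs tile the in-mask pixels) holds
#' for every direction.
#'
#' @inheritParams glcm
#' @return An object of class `rlmatrix`: `r` (Ng x Nl run counts), `Ng`,
#'   `Nl` (maximum representable run length), `Nr` (total runs), `Np`
#'   (in-mask pixels), `theta`.
#' @export
glrlm <- function(quantized, theta = 0) {
  Ng <- attr(quantized, "levels")
  if (is.null(Ng)) Ng <- max(quantized, na.rm = TRUE) + 1L
  Np <- sum(!is.na(quantized))
  if (Np == 0) stop("empty mask", call. = FALSE)
  Nl <- max(nrow(quantized), ncol(quantized))
  r <- matrix(0, Ng, Nl)
  for (line in direction_lines(quantized, theta)) {
    v <- ifelse(is.na(line), -1L, line)   # sentinel breaks runs
    runs <- rle(as.vector(v))
    keep <- runs$values >= 0
    if (!any(keep)) next
    lv <- runs$values[keep]; ln <- runs$lengths[keep]
    for (u in seq_along(lv)) r[lv[u] + 1L, ln[u]] <- r[lv[u] + 1L, ln[u]] + 1
  }
  structure(list(r = r, Ng = Ng, Nl = Nl, Nr = sum(r), Np = Np,
                 theta = theta), class = "rlmatrix")
}

#' The 11 GLRLM texture features
#'
#' Short/long run emphases, gray-level and run-length non-uniformities, run
#' percentage, and the low/high gray-level emphases and their short/long
#' run combinations, with the standard normalization by the total run count
#' `Nr` (`RP = Nr / Np`). Gray levels are indexed from 1 so the low
#' gray-level weights `1/i^2` stay finite.
#'
#' @param R an `rlmatrix` from [glrlm()].
#' @return Named numeric vector of length 11 (names from
#'   [glrlm_feature_names()]).
#' @export
glrlm_features <- function(R) {
  r <- R$r; Nr <- R$Nr; Np <- R$Np
  if (Nr == 0) stop("no runs", call. = FALSE)
  i <- matrix(seq_len(R$Ng), R$Ng, R$Nl)       # gray level, 1-based
  j <- matrix(seq_len(R$Nl), R$Ng, R$Nl, byrow = TRUE)
  setNames(c(
    sum(r / j^2) / Nr,                          # SRE
    sum(r * j^2) / Nr,                          # LRE
    sum(rowSums(r)^2) / Nr,                     # GLN
    sum(colSums(r)^2) / Nr,                     # RLN
    Nr / Np,                                    # RP
    sum(r / i^2) / Nr,                          # LGRE
    sum(r * i^2) / Nr,                          # HGRE
    sum(r / (i^2 * j^2)) / Nr,                  # SRLGE
    sum(r * i^2 / j^2) / Nr,                    # SRHGE
    sum(r * j^2 / i^2) / Nr,                    # LRLGE
    sum(r * i^2 * j^2) / Nr                     # LRHGE
  ), glrlm_feature_names())
}

#' Angle-averaged texture features of one ROI
#'
#' Quantizes the ROI, computes the 22 GLCM and 11 GLRLM features at each of
#' the four angles 0, 45, 90 and 135 degrees, and returns the per-feature
#' arithmetic mean over angles.
#'
#' @param roi a `mammo_roi` from [extract_roi()], or a [gray_image()]
#'   (then `mask` applies).
#' @param d GLCM pixel distance.
#' @param levels number of quantization gray levels.
#' @param mask optional mask when `roi` is a plain image.
#' @return A one-row tibble with `id`, `tissue_class`, `severity` (when
#'   available) and the 33 feature columns in [feature_names()] order.
#' @export
roi_features <- function(roi, d = 1L, levels = 8L, mask = NULL) {
  if (inherits(roi, "mammo_roi")) {
    patch <- roi$patch; mask <- roi$mask
    meta <- tibble::tibble(id = roi$source_id,
                           tissue_class = roi$tissue_class,
                           severity = roi$severity)
  } else {
    patch <- roi
    meta <- tibble::tibble(id = NA_character_,
                           tissue_class = NA_character_,
                           severity = NA_character_)
  }
  q <- quantize_gray(patch, mask, levels)
  per_angle <- lapply(texture_angles(), function(th) {
    c(glcm_features(glcm(q, d = d, theta = th)),
      glrlm_features(glrlm(q, theta = th)))
  })
  avg <- Reduce(`+`, per_angle) / length(per_angle)
  dplyr::bind_cols(meta, tibble::as_tibble(as.list(avg)))
}
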