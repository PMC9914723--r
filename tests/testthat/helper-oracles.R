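# Independent brute-force oracles. These re-derive every texture quantity
# by naive enumeration (explicit loops over pixel pairs, runs, score pairs
# and cluster partitions), deliberately sharing no code with the package's
# vectorized implementations.

make_quantized <- function(m, levels = max(m, na.rm = TRUE) + 1L) {
  q <- matrix(as.integer(m), nrow(m), ncol(m))
  attr(q, "levels") <- as.integer(levels)
  q
}

oracle_offset <- function(theta, d) {
  list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
       "135" = c(-d, -d))[[as.character(theta)]]
}

# symmetric GLCM by looping over every pixel and checking its partner
oracle_glcm_counts <- function(q, d, theta) {
  Ng <- attr(q, "levels")
  off <- oracle_offset(theta, d)
  P <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
    a <- q[r, c]; b <- q[r2, c2]
    if (is.na(a) || is.na(b)) next
    P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
    P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
  }
  P
}

# direct loop evaluation of the 22 GLCM feature formulas
oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  p <- P / sum(P)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- sqrt(sum((1:Ng - mux)^2 * px)); sy <- sqrt(sum((1:Ng - muy)^2 * py))
  psum <- numeric(2 * Ng); pdiff <- numeric(Ng)
  autoc <- contr <- dissi <- energ <- entro <- hom1 <- hom2 <- 0
  cprom <- cshad <- sosvh <- idn <- idmn <- corr_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    v <- p[i, j]
    autoc <- autoc + i * j * v
    contr <- contr + (i - j)^2 * v
    dissi <- dissi + abs(i - j) * v
    energ <- energ + v^2
    entro <- entro - v * lg2(v)
    hom1 <- hom1 + v / (1 + abs(i - j))
    hom2 <- hom2 + v / (1 + (i - j)^2)
    cprom <- cprom + (i + j - mux - muy)^4 * v
    cshad <- cshad + (i + j - mux - muy)^3 * v
    sosvh <- sosvh + (i - mux)^2 * v
    idn <- idn + v / (1 + abs(i - j) / Ng)
    idmn <- idmn + v / (1 + (i - j)^2 / Ng^2)
    corr_num <- corr_num + (i - mux) * (j - muy) * v
    psum[i + j - 1] <- psum[i + j - 1] + v   # index k-1, k = 2..2Ng
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + v
  }
  savg <- 0; for (k in 2:(2 * Ng)) savg <- savg + k * psum[k - 1]
  svar <- 0; sent <- 0
  for (k in 2:(2 * Ng)) {
    svar <- svar + (k - savg)^2 * psum[k - 1]
    sent <- sent - psum[k - 1] * lg2(psum[k - 1])
  }
  dmean <- 0; for (k in 0:(Ng - 1)) dmean <- dmean + k * pdiff[k + 1]
  dvar <- 0; dent <- 0
  for (k in 0:(Ng - 1)) {
    dvar <- dvar + (k - dmean)^2 * pdiff[k + 1]
    dent <- dent - pdiff[k + 1] * lg2(pdiff[k + 1])
  }
  HX <- -sum(sapply(px, function(x) x * lg2(x)))
  HY <- -sum(sapply(py, function(x) x * lg2(x)))
  HXY <- entro
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    HXY1 <- HXY1 - p[i, j] * lg2(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg2(px[i] * py[j])
  }
  corr <- if (sx == 0 || sy == 0) 0 else corr_num / (sx * sy)
  corrp <- if (sx == 0 || sy == 0) 0 else (autoc - mux * muy) / (sx * sy)
  c(glcm_autocorrelation = autoc, glcm_contrast = contr,
    glcm_correlation_m = corr, glcm_correlation_p = corrp,
    glcm_cluster_prominence = cprom, glcm_cluster_shade = cshad,
    glcm_dissimilarity = dissi, glcm_energy = energ, glcm_entropy = entro,
    glcm_homogeneity_m = hom1, glcm_homogeneity_p = hom2,
    glcm_maximum_probability = max(p), glcm_sum_of_squares = sosvh,
    glcm_sum_average = savg, glcm_sum_variance = svar,
    glcm_sum_entropy = sent, glcm_difference_variance = dvar,
    glcm_difference_entropy = dent,
    glcm_imc1 = (HXY - HXY1) / max(HX, HY, 1e-12),
    glcm_imc2 = sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0)),
    glcm_idn = idn, glcm_idmn = idmn)
}

# run-length matrix by walking each direction line pixel by pixel
oracle_glrlm <- function(q, theta) {
  Ng <- attr(q, "levels")
  nr <- nrow(q); nc <- ncol(q)
  Nl <- max(nr, nc)
  step <- switch(as.character(theta), "0" = c(0, 1), "45" = c(-1, 1),
                 "90" = c(-1, 0), "135" = c(-1, -1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]   # line start: no predecessor
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, c)
  }
  R <- matrix(0, Ng, Nl)
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- q[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) R[cur + 1, len] <- R[cur + 1, len] + 1
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur)) R[cur + 1, len] <- R[cur + 1, len] + 1
  }
  R
}

oracle_glrlm_features <- function(R, Np) {
  Nr <- sum(R)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    v <- R[i, j]
    sre <- sre + v / j^2;       lre <- lre + v * j^2
    lgre <- lgre + v / i^2;     hgre <- hgre + v * i^2
    srlge <- srlge + v / (i^2 * j^2); srhge <- srhge + v * i^2 / j^2
    lrlge <- lrlge + v * j^2 / i^2;   lrhge <- lrhge + v * i^2 * j^2
  }
  c(glrlm_sre = sre / Nr, glrlm_lre = lre / Nr,
    glrlm_gln = sum(rowSums(R)^2) / Nr, glrlm_rln = sum(colSums(R)^2) / Nr,
    glrlm_rp = Nr / Np, glrlm_lgre = lgre / Nr, glrlm_hgre = hgre / Nr,
    glrlm_srlge = srlge / Nr, glrlm_srhge = srhge / Nr,
    glrlm_lrlge = lrlge / Nr, glrlm_lrhge = lrhge / Nr)
}

# AUC by exhaustive comparison of every positive/negative score pair
oracle_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# optimal 1-D k-means objective: contiguous partitions of the sorted data
oracle_kmeans_J <- function(v, k) {
  v <- sort(v); n <- length(v)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    J <- 0
    for (g in seq_len(k)) {
      seg <- v[(b[g] + 1):b[g + 1]]
      J <- J + sum((seg - mean(seg))^2)
    }
    best <- min(best, J)
  }
  best
}

# area of the convex hull of mask pixels (shoelace on chull vertices)
hull_area <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  h <- grDevices::chull(pts)
  x <- pts[h, 2]; y <- pts[h, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# small helper: random masked quantized grid for property loops
random_quantized <- function(seed, max_side = 12L, Ng = 4L,
                             mask_frac = 0.15) {
  set.seed(seed)
  nr <- sample(2:max_side, 1); nc <- sample(2:max_side, 1)
  q <- matrix(sample(0:(Ng - 1), nr * nc, TRUE), nr, nc)
  q[matrix(runif(nr * nc) < mask_frac, nr, nc)] <- NA
  if (all(is.na(q))) q[1, 1] <- 0L
  make_quantized(q, Ng)
}
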