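#' Parameters for the synthetic phantom mammogram
#'
#' The phantom emulates the geometry of a mediolateral-oblique (MLO)
#' mammogram: a near-black background, a half-elliptical breast region
#' attached to the chest-wall side with low-frequency tissue texture, a
#' brighter pectoral-muscle wedge in the upper chest-wall corner, a bright
#' label rectangle in a background corner, and an optional lesion. Benign
#' lesions are smooth high-intensity discs; malignant lesions are spiculated
#' star-shaped blobs with a jagged boundary and heterogeneous internal
#' speckle, so shape and texture — not only intensity — separate the classes.
#'
#' @param seed RNG seed; identical parameters give bit-identical output.
#' @param size image side length in pixels.
#' @param laterality `"right"` (chest wall at the left edge) or `"left"`.
#' @param lesion `"none"`, `"benign"` or `"malign"`.
#' @param lesion_center lesion centre `c(x, y)` in pixels (top-left origin);
#'   default is mid-breast.
#' @param lesion_radius lesion radius in pixels.
#' @param lesion_contrast peak intensity added at the lesion centre (0-255).
#' @param n_spicules number of spicule arms for malignant lesions.
#' @param pectoral_fraction fraction of the width the wedge covers at the
#'   top edge (0-0.5); 0 disables the wedge.
#' @param label_box label rectangle `c(x0, y0, x1, y1)` or `NULL` for the
#'   default top corner opposite the chest wall.
#' @param noise_gaussian_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param noise_salt_pepper_p per-pixel probability of impulse noise
#'   (replaced by 0 or 255 with probability p/2 each).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(seed = 1L, size = 1024L,
                           laterality = c("right", "left"),
                           lesion = c("none", "benign", "malign"),
                           lesion_center = NULL,
                           lesion_radius = round(0.05 * size),
                           lesion_contrast = 60,
                           n_spicules = 8L,
                           pectoral_fraction = 0.35,
                           label_box = NULL,
                           noise_gaussian_sd = 3,
                           noise_salt_pepper_p = 0) {
  laterality <- match.arg(laterality)
  lesion <- match.arg(lesion)
  stopifnot(size >= 32, lesion_radius > 0,
            lesion_contrast >= 0, lesion_contrast <= 255,
            pectoral_fraction >= 0, pectoral_fraction <= 0.5,
            noise_salt_pepper_p >= 0, noise_salt_pepper_p <= 1,
            noise_gaussian_sd >= 0)
  if (is.null(lesion_center))
    lesion_center <- c(round(0.30 * size), round(0.55 * size))
  structure(list(seed = seed, size = as.integer(size),
                 laterality = laterality, lesion = lesion,
                 lesion_center = lesion_center,
                 lesion_radius = lesion_radius,
                 lesion_contrast = lesion_contrast,
                 n_spicules = as.integer(n_spicules),
                 pectoral_fraction = pectoral_fraction,
                 label_box = label_box,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_salt_pepper_p = noise_salt_pepper_p),
            class = "phantom_params")
}

# Smooth random field: coarse iid normal grid, bilinearly upsampled.
smooth_field <- function(size, ncell, amp) {
  g <- matrix(rnorm((ncell + 1)^2, 0, amp), ncell + 1, ncell + 1)
  pos <- (seq_len(size) - 1) / (size - 1) * ncell  # in [0, ncell]
  i0 <- pmin(floor(pos), ncell - 1); f <- pos - i0
  a <- g[i0 + 1, i0 + 1]; b <- g[i0 + 2, i0 + 1]
  c_ <- g[i0 + 1, i0 + 2]; d <- g[i0 + 2, i0 + 2]
  fr <- matrix(f, size, size); fc <- matrix(f, size, size, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) +
    c_ * (1 - fr) * fc + d * fr * fc
}

#' Generate a synthetic phantom mammogram with ground-truth masks
#'
#' @param params a [phantom_params()] object.
#' @param id case identifier stored in the record.
#' @return A list with `record` (a `mammo_record`: `id`, `image`,
#'   `laterality`, `tissue_class`, `severity`, `lesion_center`,
#'   `lesion_radius`) and `masks` — binary matrices `background`,
#'   `pectoral`, `breast`, `lesion`. Background/pectoral/breast partition
#'   the frame; the lesion mask is nested inside the breast mask.
#' @examples
#' ph <- generate_phantom(phantom_params(seed = 1, size = 128,
#'                                       lesion = "benign",
#'                                       lesion_center = c(40, 70),
#'                                       lesion_radius = 9))
#' table(ph$masks$lesion)
#' @export
generate_phantom <- function(params, id = "phantom") {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  s <- p$size
  with_seed(p$seed, {
    # build in right-breast orientation (chest wall at x = 0), mirror at end
    x <- matrix(seq_len(s) - 1, s, s, byrow = TRUE)  # column index
    y <- matrix(seq_len(s) - 1, s, s)                # row index
    center <- p$lesion_center
    if (p$laterality == "left")  # mirror requested centre into build frame
      center[1] <- (s - 1) - center[1]

    ellipse <- (x / (0.60 * s))^2 + ((y - 0.48 * s) / (0.44 * s))^2 <= 1
    wedge <- matrix(FALSE, s, s)
    if (p$pectoral_fraction > 0) {
      h0 <- 0.5 * s
      wedge <- y < h0 & x < p$pectoral_fraction * s * (1 - y / h0)
    }
    pectoral <- wedge
    breast <- ellipse & !wedge
    background <- !ellipse & !wedge

    # one low-frequency tissue texture field, amplitude-scaled per region
    field <- smooth_field(s, 8, 1)
    img <- matrix(5, s, s)
    img[breast]   <- 110 + 12 * field[breast]
    img[pectoral] <- 180 + 6 * field[pectoral]

    lesion_mask <- matrix(FALSE, s, s)
    if (p$lesion != "none") {
      cx <- center[1]; cy <- center[2]; r <- p$lesion_radius
      # lesion fits in a (2r+5)^2 bounding box; work there only
      rws <- max(1, cy + 1 - r - 2):min(s, cy + 1 + r + 2)
      cls <- max(1, cx + 1 - r - 2):min(s, cx + 1 + r + 2)
      dx <- matrix(cls - 1 - cx, length(rws), length(cls), byrow = TRUE)
      dy <- matrix(rws - 1 - cy, length(rws), length(cls))
      d <- sqrt(dx^2 + dy^2)
      if (p$lesion == "benign") {
        box_mask <- d <= r
        bump <- p$lesion_contrast * cos(pmin(d / r, 1) * pi / 2)
      } else {
        theta <- atan2(dy, dx)
        phase <- runif(1, 0, 2 * pi)
        spike <- (0.5 + 0.5 * cos(p$n_spicules * theta + phase))^1.5
        rtheta <- r * (0.45 + 0.55 * spike)
        box_mask <- d <= rtheta
        bump <- p$lesion_contrast * pmax(1 - d / pmax(rtheta, 1), 0)^0.7
        speckle <- matrix(rnorm(length(d), 0, 0.25 * p$lesion_contrast),
                          nrow(d), ncol(d))
        bump[box_mask] <- bump[box_mask] + speckle[box_mask]
      }
      lesion_mask[rws, cls] <- box_mask
      if (any(lesion_mask & !breast))
        stop("lesion outside breast region", call. = FALSE)
      add <- matrix(0, s, s)
      add[rws, cls][box_mask] <- pmax(bump[box_mask], 0)
      img[lesion_mask] <- img[lesion_mask] + add[lesion_mask]
    }

    # bright label artifact in a background corner (opposite the chest wall)
    box <- p$label_box
    if (is.null(box))
      box <- c(round(0.86 * s), round(0.03 * s), round(0.96 * s),
               round(0.08 * s))
    lx <- seq(box[1], box[3]) + 1; ly <- seq(box[2], box[4]) + 1
    img[ly, lx] <- 250

    if (p$noise_gaussian_sd > 0)
      img <- img + matrix(rnorm(s * s, 0, p$noise_gaussian_sd), s, s)
    if (p$noise_salt_pepper_p > 0) {
      u <- matrix(runif(s * s), s, s)
      img[u < p$noise_salt_pepper_p / 2] <- 0
      img[u >= p$noise_salt_pepper_p / 2 & u < p$noise_salt_pepper_p] <- 255
    }
    img <- pmin(pmax(round(img), 0), 255)

    if (p$laterality == "left") {
      flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
      img <- flip(img); background <- flip(background)
      pectoral <- flip(pectoral); breast <- flip(breast)
      lesion_mask <- flip(lesion_mask)
    }

    record <- structure(list(
      id = id, image = gray_image(img), laterality = p$laterality,
      tissue_class = if (p$lesion == "none") "normal" else "abnormal",
      severity = switch(p$lesion, none = NA_character_, benign = "benign",
                        malign = "malign"),
      lesion_center = if (p$lesion == "none") NULL else p$lesion_center,
      lesion_radius = if (p$lesion == "none") NA_real_ else p$lesion_radius),
      class = "mammo_record")
    list(record = record,
         masks = list(background = background * 1L, pectoral = pectoral * 1L,
                      breast = breast * 1L, lesion = lesion_mask * 1L))
  })
}

#' @export
print.mammo_record <- function(x, ...) {
  cat("<mammo_record>", x$id, "-", x$laterality, x$tissue_class,
      if (!is.na(x$severity)) x$severity else "",
      sprintf("[%d x %d]\n", nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' Generate a reproducible phantom cohort
#'
#' Lesion geometry and contrast are randomized within fixed ranges: radius
#' 4-7% of the image side, peak contrast 50-80 intensity units, centre
#' uniform over the mid-breast (placement is rejected and redrawn if the
#' lesion would leave the breast). Consecutive cases are paired as the two
#' lateralities of one subject, mirroring the source database's film
#' pairing.
#'
#' @param n_normal,n_benign,n_malign case counts (each >= 0).
#' @param seed top-level seed; per-case seeds are derived from it.
#' @param size image side length in pixels.
#' @param contrast_range range of the peak lesion contrast.
#' @param noise_gaussian_sd,noise_salt_pepper_p noise settings per case.
#' @return A list of class `mammo_cohort`: one element per case, each a
#'   `list(record, masks)` as from [generate_phantom()]; the attribute
#'   `"metadata"` holds the cohort tibble (see [cohort_metadata()]).
#' @export
generate_cohort <- function(n_normal, n_benign, n_malign, seed = 1L,
                            size = 256L, contrast_range = c(50, 80),
                            noise_gaussian_sd = 3, noise_salt_pepper_p = 0) {
  stopifnot(n_normal >= 0, n_benign >= 0, n_malign >= 0)
  lesions <- c(rep("none", n_normal), rep("benign", n_benign),
               rep("malign", n_malign))
  n <- length(lesions)
  cases <- with_seed(derive_seed(seed, 1L), {
    lesions <- sample(lesions)  # interleave classes across subject pairs
    lapply(seq_len(n), function(i) {
      lat <- if (i %% 2L == 1L) "right" else "left"
      id <- sprintf("phm%03d", i)
      kind <- lesions[i]
      case_seed <- derive_seed(seed, 100L + i)
      if (kind == "none") {
        pp <- phantom_params(seed = case_seed, size = size, laterality = lat,
                             lesion = "none",
                             noise_gaussian_sd = noise_gaussian_sd,
                             noise_salt_pepper_p = noise_salt_pepper_p)
        return(generate_phantom(pp, id = id))
      }
      r <- round(runif(1, 0.04, 0.07) * size)
      contrast <- runif(1, contrast_range[1], contrast_range[2])
      repeat {  # rejection sampling keeps the lesion inside the breast
        cx <- round(runif(1, 0.12, 0.45) * size)
        cy <- round(runif(1, 0.35, 0.75) * size)
        margin <- (cx / (0.60 * size))^2 +
          ((cy - 0.48 * size) / (0.44 * size))^2
        pect_edge <- 0.35 * size * (1 - cy / (0.5 * size))
        if (margin < 0.70 && cx - r > pect_edge + 2) break
      }
      if (lat == "left") cx <- (size - 1) - cx
      pp <- phantom_params(seed = case_seed, size = size, laterality = lat,
                           lesion = kind, lesion_center = c(cx, cy),
                           lesion_radius = r, lesion_contrast = contrast,
                           noise_gaussian_sd = noise_gaussian_sd,
                           noise_salt_pepper_p = noise_salt_pepper_p)
      generate_phantom(pp, id = id)
    })
  })
  structure(cases, class = "mammo_cohort",
            metadata = cohort_metadata_impl(cases))
}

cohort_metadata_impl <- function(cases) {
  dplyr::bind_rows(lapply(seq_along(cases), function(i) {
    r <- cases[[i]]$record
    tibble::tibble(
      id = r$id, subject = ceiling(i / 2),
      laterality = r$laterality, tissue_class = r$tissue_class,
      severity = r$severity,
      x = if (is.null(r$lesion_center)) NA_real_ else r$lesion_center[1],
      y = if (is.null(r$lesion_center)) NA_real_ else r$lesion_center[2],
      radius = r$lesion_radius)
  }))
}

#' Cohort metadata table
#'
#' @param cohort a `mammo_cohort` from [generate_cohort()].
#' @return The cohort's metadata tibble (`id`, `subject`, `laterality`,
#'   `tissue_class`, `severity`, `x`, `y`, `radius`).
#' @export
cohort_metadata <- function(cohort) attr(cohort, "metadata")

#' Write a cohort to disk
#'
#' Emits one PGM per case, 0/255 truth-mask PGMs, and the metadata table in
#' the mini-MIAS dialect.
#'
#' @param cohort a `mammo_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cohort) {
    write_pgm(case$record$image, file.path(dir, paste0(case$record$id, ".pgm")))
    for (mk in names(case$masks))
      write_pgm(gray_image(case$masks[[mk]] * 255L),
                file.path(dir, sprintf("%s_mask_%s.pgm", case$record$id, mk)))
  }
  md <- cohort_metadata(cohort)
  write_mias_metadata(md, file.path(dir, "info.txt"),
                      height = nrow(cohort[[1]]$record$image))
  invisible(dir)
}
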