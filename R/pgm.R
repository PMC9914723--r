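#' Gray image container
#'
#' A gray image is an integer matrix with values in 0-255, row-major with a
#' top-left origin: rows index y (downwards), columns index x (rightwards).
#' `gray_image()` validates and coerces; `is_gray_image()` tests the
#' contract without coercing.
#'
#' @param pixels numeric or integer matrix with all values in \[0, 255\].
#' @return An integer matrix of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  m <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  class(m) <- c("gray_image", class(m))
  m
}

#' @rdname gray_image
#' @param x object to test.
#' @export
is_gray_image <- function(x) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x <= 255)
}

# strip class so arithmetic stays plain
as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

# ---- PGM parsing ---------------------------------------------------------

# Read header tokens one at a time from a raw connection, skipping
# '#' comments, which the format allows anywhere in the header.
read_pgm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0L) {
      if (length(tok)) break
      stop("PGM header truncated", call. = FALSE)
    }
    c_chr <- rawToChar(ch)
    if (c_chr == "#") {               # comment runs to end of line
      repeat {
        ch <- readBin(con, "raw", n = 1L)
        if (length(ch) == 0L || rawToChar(ch) %in% c("\n", "\r")) break
      }
    } else if (grepl("[[:space:]]", c_chr)) {
      if (length(tok)) break
    } else {
      tok <- c(tok, c_chr)
    }
  }
  paste(tok, collapse = "")
}

#' Read a PGM (portable gray map) image
#'
#' Supports the ASCII (`P2`) and binary (`P5`) dialects with `maxval` up to
#' 255; header comments are skipped. Higher bit depths are rejected: the
#' pipeline is defined on 8-bit imagery.
#'
#' @param path path to a `.pgm` file.
#' @return A [gray_image()] with the file's dimensions and pixel values.
#' @seealso [write_pgm()]
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pgm_token(con)
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic number '", magic, "', expected P2 or P5)",
         call. = FALSE)
  width  <- suppressWarnings(as.integer(read_pgm_token(con)))
  height <- suppressWarnings(as.integer(read_pgm_token(con)))
  maxval <- suppressWarnings(as.integer(read_pgm_token(con)))
  if (anyNA(c(width, height, maxval)) || width < 1 || height < 1)
    stop("malformed PGM dimensions", call. = FALSE)
  if (maxval > 255L || maxval < 1L)
    stop("unsupported PGM maxval ", maxval, " (only 8-bit, maxval <= 255)",
         call. = FALSE)
  n <- width * height
  if (magic == "P5") {
    bytes <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    if (length(bytes) < n)
      stop("truncated PGM pixel data: expected ", n, " bytes, got ",
           length(bytes), call. = FALSE)
    vals <- bytes
  } else {
    vals <- suppressWarnings(scan(con, what = integer(), n = n, quiet = TRUE,
                                  comment.char = "#"))
    if (length(vals) < n)
      stop("truncated PGM pixel data: expected ", n, " values, got ",
           length(vals), call. = FALSE)
  }
  if (any(vals > maxval))
    stop("pixel value exceeds declared maxval", call. = FALSE)
  # pixels are stored row by row (raster order)
  gray_image(matrix(vals, nrow = height, ncol = width, byrow = TRUE))
}

#' Write a PGM (portable gray map) image
#'
#' Emits a standard-conformant `P2` (ASCII) or `P5` (binary) file that
#' [read_pgm()] inverts exactly.
#'
#' @param img a [gray_image()] (or matrix coercible to one).
#' @param path output path.
#' @param mode `"binary"` (P5, default) or `"ascii"` (P2).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  img <- gray_image(img)
  h <- nrow(img); w <- ncol(img)
  vals <- as.integer(t(as_pixel_matrix(img)))  # raster order
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write: ", path, call. = FALSE))
  on.exit(close(con))
  if (mode == "binary") {
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(vals, con, size = 1L)
  } else {
    writeChar(sprintf("P2\n%d %d\n255\n", w, h), con, eos = NULL)
    lines <- vapply(split(vals, ceiling(seq_along(vals) / w)),
                    paste, character(1), collapse = " ")
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  }
  invisible(path)
}
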