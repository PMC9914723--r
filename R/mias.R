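#' Parse a mini-MIAS style metadata table
#'
#' Each whitespace-separated row is `id tissue_code class_code [severity x y
#' radius]`, e.g. `"mdb001 G CIRC B 535 425 197"`. Rows whose class code is
#' `NORM` describe normal tissue and carry no lesion fields. The source
#' table's lesion y-coordinate uses a bottom-left origin; it is flipped on
#' ingest to the package's top-left raster convention
#' (`y_internal = height - 1 - y_file`).
#'
#' Laterality and subject follow the database's film-pairing convention:
#' consecutive image numbers are the two views of one subject, odd numbers
#' the right breast and even numbers the left.
#'
#' @param path path to the metadata text file.
#' @param height image height in pixels used for the y flip (default 1024).
#' @return A tibble with one row per image: `id`, `subject`, `laterality`,
#'   `tissue_class` (`"normal"`/`"abnormal"`), `severity` (`"benign"`,
#'   `"malign"` or `NA`), `x`, `y`, `radius` (pixels, `NA` when absent).
#'   Abnormal rows with missing geometry are kept (with a warning) but are
#'   skipped later by lesion-centred ROI extraction.
#' @export
read_mias_metadata <- function(path, height = 1024L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- lapply(lines, parse_mias_row, height = height)
  out <- dplyr::bind_rows(recs)
  n_missing <- sum(out$tissue_class == "abnormal" & is.na(out$x))
  if (n_missing > 0)
    warning(n_missing, " abnormal record(s) lack lesion geometry; ",
            "they will be excluded from lesion-centred ROI extraction",
            call. = FALSE)
  out
}

parse_mias_row <- function(line, height) {
  f <- strsplit(line, "[[:space:]]+")[[1]]
  if (length(f) < 3) stop("malformed metadata row: '", line, "'", call. = FALSE)
  id <- f[1]
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", id)))
  laterality <- if (!is.na(num)) ifelse(num %% 2L == 1L, "right", "left")
                else NA_character_
  subject <- if (!is.na(num)) ceiling(num / 2) else NA_real_
  cls <- f[3]
  if (cls == "NORM") {
    return(tibble::tibble(id = id, subject = subject, laterality = laterality,
                          tissue_class = "normal", severity = NA_character_,
                          x = NA_real_, y = NA_real_, radius = NA_real_))
  }
  sev <- if (length(f) >= 4) f[4] else NA_character_
  if (is.na(sev) || !sev %in% c("B", "M"))
    stop("unknown severity code '", sev, "' in row: '", line, "'",
         call. = FALSE)
  severity <- if (sev == "B") "benign" else "malign"
  if (length(f) >= 7) {
    x <- as.numeric(f[5]); y_file <- as.numeric(f[6]); r <- as.numeric(f[7])
    y <- height - 1 - y_file
  } else {
    x <- NA_real_; y <- NA_real_; r <- NA_real_
  }
  tibble::tibble(id = id, subject = subject, laterality = laterality,
                 tissue_class = "abnormal", severity = severity,
                 x = x, y = y, radius = r)
}

#' Write records in the mini-MIAS metadata dialect
#'
#' Inverse of [read_mias_metadata()]: lesion y-coordinates are flipped back
#' to the source's bottom-left origin, normal rows are emitted as
#' `id <code> NORM`, abnormal rows with geometry as
#' `id <code> <class> B|M x y radius`.
#'
#' @param records tibble as returned by [read_mias_metadata()].
#' @param path output path.
#' @param height image height for the y flip.
#' @return `path`, invisibly.
#' @export
write_mias_metadata <- function(records, path, height = 1024L) {
  rows <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (r$tissue_class == "normal") return(paste(r$id, "G", "NORM"))
    sev <- if (r$severity == "benign") "B" else "M"
    if (is.na(r$x)) return(paste(r$id, "G", "CIRC", sev))
    paste(r$id, "G", "CIRC", sev,
          round(r$x), round(height - 1 - r$y), round(r$radius))
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Export records to CSV
#'
#' Stable export with header `id,laterality,tissue_class,severity,x,y,radius`
#' (top-left-origin coordinates).
#'
#' @inheritParams write_mias_metadata
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  out <- records[, c("id", "laterality", "tissue_class", "severity",
                     "x", "y", "radius")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
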