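#' Correlation-based feature elimination
#'
#' Greedy scan over the feature columns in their canonical order: a feature
#' is dropped when its absolute Pearson correlation with any
#' already-retained feature exceeds `threshold` (anticorrelated duplicates
#' are equally redundant, hence the absolute value). Constant columns have
#' undefined correlation; they are treated as `r = 0` and retained with a
#' warning.
#'
#' @param table data frame whose numeric columns are features (non-numeric
#'   columns such as `id` are ignored); at least two rows, no missing
#'   values.
#' @param threshold correlation threshold in (0, 1\]; default 0.90.
#' @return An object of class `mammo_selection`: `retained` (ordered
#'   names), `dropped` (tibble `dropped`, `kept_partner`, `correlation`),
#'   `threshold`, and `per_feature_auc` (`NULL` until
#'   [per_feature_auc()] results are attached).
#' @export
correlation_filter <- function(table, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  num <- vapply(table, is.numeric, logical(1))
  feats <- as.data.frame(table)[, num, drop = FALSE]
  if (nrow(feats) < 2) stop("need at least two rows", call. = FALSE)
  if (anyNA(feats)) stop("missing values in feature table", call. = FALSE)
  nm <- names(feats)
  const <- vapply(feats, function(x) sd(x) == 0, logical(1))
  if (any(const))
    warning("constant column(s) treated as r = 0 and retained: ",
            paste(nm[const], collapse = ", "), call. = FALSE)
  retained <- character(0)
  dropped <- tibble::tibble(dropped = character(0),
                            kept_partner = character(0),
                            correlation = numeric(0))
  for (f in nm) {
    if (length(retained) == 0 || const[f]) {
      retained <- c(retained, f); next
    }
    rs <- vapply(retained, function(g) {
      if (const[g]) return(0)
      suppressWarnings(cor(feats[[f]], feats[[g]]))
    }, numeric(1))
    rs[is.na(rs)] <- 0
    hit <- which(abs(rs) > threshold)
    if (length(hit)) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        dropped = f, kept_partner = retained[hit[1]],
        correlation = rs[hit[1]]))
    } else {
      retained <- c(retained, f)
    }
  }
  structure(list(retained = retained, dropped = dropped,
                 threshold = threshold, per_feature_auc = NULL),
            class = "mammo_selection")
}

#' @export
print.mammo_selection <- function(x, ...) {
  cat("<mammo_selection>", length(x$retained), "retained,",
      nrow(x$dropped), "dropped (|r| >", x$threshold, ")\n")
  invisible(x)
}

#' @rdname correlation_filter
#' @param x a `mammo_selection`.
#' @param ... unused.
#' @method tidy mammo_selection
#' @export
tidy.mammo_selection <- function(x, ...) {
  out <- tibble::tibble(
    feature = c(x$retained, x$dropped$dropped),
    retained = c(rep(TRUE, length(x$retained)),
                 rep(FALSE, nrow(x$dropped))),
    kept_partner = c(rep(NA_character_, length(x$retained)),
                     x$dropped$kept_partner),
    correlation = c(rep(NA_real_, length(x$retained)),
                    x$dropped$correlation))
  if (!is.null(x$per_feature_auc))
    out <- dplyr::left_join(out, x$per_feature_auc, by = "feature")
  out
}

#' @rdname correlation_filter
#' @method glance mammo_selection
#' @export
glance.mammo_selection <- function(x, ...) {
  tibble::tibble(n_retained = length(x$retained),
                 n_dropped = nrow(x$dropped), threshold = x$threshold)
}

# midrank Mann-Whitney AUC of score against a logical positive label
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-feature ROC AUC screening
#'
#' For each feature the AUC of the feature value as a classification score
#' for the binary label, via the midrank Mann-Whitney statistic. The
#' reported AUC is direction-free — `max(A, 1 - A)` with a direction flag —
#' so a feature that separates the classes in either direction screens
#' equally well.
#'
#' @param table data frame of numeric feature columns (non-numeric columns
#'   ignored).
#' @param labels binary label vector (logical, or coercible: the positive
#'   class is `TRUE`, the second factor level, or the lexicographically
#'   larger value); both classes must be present.
#' @return A tibble `feature`, `auc`, `direction` (`+1` when larger values
#'   indicate the positive class).
#' @export
per_feature_auc <- function(table, labels) {
  pos <- as_positive(labels)
  if (all(pos) || all(!pos))
    stop("both classes must be present", call. = FALSE)
  num <- vapply(table, is.numeric, logical(1))
  feats <- as.data.frame(table)[, num, drop = FALSE]
  purrr::map_dfr(names(feats), function(f) {
    a <- rank_auc(feats[[f]], pos)
    tibble::tibble(feature = f, auc = max(a, 1 - a),
                   direction = ifelse(a >= 0.5, 1, -1))
  })
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) > 2) stop("labels must be binary", call. = FALSE)
  f == levels(f)[nlevels(f)]
}

#' The nine-feature replication preset
#'
#' Reduces a 33-feature table to the nine features retained by the
#' correlation-coefficient selection: GLCM autocorrelation, contrast,
#' cluster prominence and entropy; GLRLM short run emphasis, long run
#' emphasis, gray-level non-uniformity, short run low gray-level emphasis
#' and long run low gray-level emphasis — in that order. Non-feature
#' columns (id, labels) are kept in front. Idempotent.
#'
#' @param table data frame containing at least the nine feature columns.
#' @return The reduced tibble.
#' @export
apply_table1_preset <- function(table) {
  keep <- table1_features()
  missing <- setdiff(keep, names(table))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- setdiff(names(table), feature_names())
  tibble::as_tibble(table)[, c(meta, keep)]
}

#' @rdname apply_table1_preset
#' @export
table1_features <- function() c(
  "glcm_autocorrelation", "glcm_contrast", "glcm_cluster_prominence",
  "glcm_entropy", "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_srlge",
  "glrlm_lrlge")
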