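#' Build a run configuration
#'
#' A flat, serializable list of every parameter the end-to-end run uses; a
#' saved configuration re-runs to bit-identical outputs because every
#' stochastic stage is re-seeded deterministically from the single
#' top-level seed.
#'
#' @param seed top-level seed.
#' @param n_normal,n_benign,n_malign phantom cohort counts.
#' @param size phantom side length in pixels.
#' @param combos pre-processing combinations to run.
#' @param classifiers classifiers to run.
#' @param tasks tasks to run.
#' @param filter a [filter_params()] list.
#' @param k,patch_size,levels,d segmentation / texture parameters.
#' @param selection,threshold feature-selection mode and correlation
#'   threshold.
#' @param eval_mode `"test"` or `"loocv"`.
#' @param train_fraction training fraction.
#' @param out output directory for [run_all()].
#' @return A list of class `mammo_config`.
#' @export
run_config <- function(seed = 1L, n_normal = 20L, n_benign = 10L,
                       n_malign = 10L, size = 256L,
                       combos = preproc_combos(),
                       classifiers = classifier_names(),
                       tasks = c("normal_abnormal", "benign_malign"),
                       filter = filter_params(), k = 3L, patch_size = 32L,
                       levels = 8L, d = 1L, selection = "corr",
                       threshold = 0.90, eval_mode = "test",
                       train_fraction = 0.70, out = "mammotex_run") {
  structure(list(seed = seed, n_normal = n_normal, n_benign = n_benign,
                 n_malign = n_malign, size = size, combos = combos,
                 classifiers = classifiers, tasks = tasks, filter = filter,
                 k = k, patch_size = patch_size, levels = levels, d = d,
                 selection = selection, threshold = threshold,
                 eval_mode = eval_mode, train_fraction = train_fraction,
                 out = out),
            class = "mammo_config")
}

#' Validate a run configuration
#'
#' Checks every invariant of the nested parameter types and returns the
#' violations; never throws and never mutates.
#'
#' @param config a [run_config()] list.
#' @return Character vector of violations; `character(0)` means the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v
  v <- add(!(config$threshold > 0 && config$threshold <= 1),
           "correlation threshold must be in (0,1]")
  v <- add(config$filter$median_kernel %% 2 != 1,
           "median kernel must be odd")
  v <- add(config$filter$clahe_clip <= 0, "CLAHE clip limit must be > 0")
  v <- add(config$filter$usm_amount < 0, "USM amount must be >= 0")
  v <- add(config$k < 2, "k must be >= 2")
  v <- add(config$levels < 2, "quantization levels must be >= 2")
  v <- add(config$d < 1, "GLCM distance must be >= 1")
  v <- add(!(config$train_fraction > 0 && config$train_fraction < 1),
           "train fraction must be in (0,1)")
  v <- add(any(c(config$n_normal, config$n_benign, config$n_malign) < 0),
           "cohort counts must be >= 0")
  v <- add(!all(config$combos %in% preproc_combos()),
           "unknown pre-processing combination")
  v <- add(!all(config$classifiers %in% classifier_names()),
           "unknown classifier")
  v <- add(!all(config$tasks %in% c("normal_abnormal", "benign_malign")),
           "unknown task")
  v
}

#' Run the whole pipeline end to end
#'
#' Generates the phantom cohort, writes images, truth masks and metadata,
#' extracts the per-combination feature tables, runs the selection report,
#' trains and evaluates every classifier x combination cell for each task,
#' and writes `features_<combo>.csv`, `selection.json`,
#' `report_<task>.csv`, `auc_<task>.csv` and a line-per-event `run.log`
#' under `config$out`.
#'
#' @param config a valid [run_config()].
#' @return Invisibly, a list with the cohort, per-task `mammo_report`
#'   objects, and the output directory.
#' @export
run_all <- function(config = run_config()) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logfile,
                                append = TRUE)
  cat("", file = logfile)
  cfg_plain <- unclass(config)
  cfg_plain$filter <- unclass(cfg_plain$filter)
  cfg_plain$filter$label_threshold <- NULL
  log_line("config: ", jsonlite::toJSON(cfg_plain, auto_unbox = TRUE))

  cohort <- generate_cohort(config$n_normal, config$n_benign,
                            config$n_malign,
                            seed = derive_seed(config$seed, 1L),
                            size = config$size)
  write_cohort(cohort, file.path(config$out, "images"))
  log_line("cohort: ", length(cohort), " cases written")

  for (combo in config$combos) {
    ft <- extract_cohort_features(cohort, combo, config$filter, config$k,
                                  config$patch_size, config$levels,
                                  config$d,
                                  seed = derive_seed(config$seed, 11L))
    write.csv(ft, file.path(config$out,
                            sprintf("features_%s.csv", tolower(combo))),
              row.names = FALSE)
    log_line("features: ", combo, " -> ", nrow(ft), " rows")
  }

  # selection report on the first combo's features, both screening routes
  first_ft <- read.csv(file.path(
    config$out, sprintf("features_%s.csv", tolower(config$combos[1]))))
  sel <- correlation_filter(first_ft[, intersect(names(first_ft),
                                                 feature_names())],
                            config$threshold)
  sel$per_feature_auc <- per_feature_auc(
    first_ft[, intersect(names(first_ft), feature_names())],
    first_ft$tissue_class == "abnormal")
  jsonlite::write_json(list(retained = sel$retained,
                            dropped = sel$dropped,
                            threshold = sel$threshold,
                            per_feature_auc = sel$per_feature_auc),
                       file.path(config$out, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("selection: ", length(sel$retained), " features retained")

  reports <- list()
  for (task in config$tasks) {
    rep <- run_experiment(cohort, task, config$combos, config$classifiers,
                          seed = config$seed, params = config$filter,
                          k = config$k, patch_size = config$patch_size,
                          levels = config$levels, d = config$d,
                          selection = config$selection,
                          threshold = config$threshold,
                          eval_mode = config$eval_mode,
                          train_fraction = config$train_fraction)
    write.csv(rep$rows, file.path(config$out,
                                  sprintf("report_%s.csv", task)),
              row.names = FALSE)
    write.csv(rep$rows[, c("classifier", "combo", "auc")],
              file.path(config$out, sprintf("auc_%s.csv", task)),
              row.names = FALSE)
    log_line("report: ", task, " -> ", nrow(rep$rows), " rows, ",
             sum(rep$rows$failed), " failed")
    reports[[task]] <- rep
  }
  invisible(list(cohort = cohort, reports = reports, out = config$out))
}
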