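# TSV dialect shared by all stages: count matrix has a `feature_id` first
# column and one column per sample; metadata tables are plain TSVs. Readers
# are gzip-transparent (read.delim handles .gz paths natively).

#' Write / read a feature-by-sample count matrix as TSV
#'
#' @param counts features x samples numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly (writer); the validated matrix (reader).
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  atomic_write(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be 'feature_id'")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated feature_id: ", ids[duplicated(ids)][1])
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated sample id: ", names(df)[-1][duplicated(names(df)[-1])][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop("non-numeric values in sample column '", names(df)[-1][bad], "'")
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative count at feature '", ids[neg[1, 1]], "', sample '",
         colnames(m)[neg[1, 2]], "'")
  }
  rownames(m) <- ids
  m
}

#' Write / read sample metadata (sample_id, group, cohort)
#' @param samples metadata data.frame.
#' @param path file path.
#' @export
write_sample_meta <- function(samples, path) {
  atomic_write(function(tmp) {
    utils::write.table(samples, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stop("sample metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  df
}

#' Write / read feature metadata (feature_id, rna_type)
#' @param features metadata data.frame.
#' @param path file path.
#' @export
write_feature_meta <- function(features, path) {
  atomic_write(function(tmp) {
    utils::write.table(features, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' @rdname write_feature_meta
#' @export
read_feature_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "rna_type") %in% names(df))) {
    stop("feature metadata needs columns feature_id, rna_type")
  }
  if (anyDuplicated(df$feature_id)) stop("duplicated feature_id")
  df
}

#' Cross-check a cohort's matrix and metadata
#'
#' @param counts features x samples matrix.
#' @param samples sample metadata.
#' @param features feature metadata (optional).
#' @return TRUE invisibly; errors name the offending identifiers.
#' @export
validate_cohort <- function(counts, samples, features = NULL) {
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss)) stop("samples missing from metadata: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra)) stop("metadata samples missing from matrix: ",
                          paste(extra, collapse = ", "))
  if (!is.null(features)) {
    fmiss <- setdiff(rownames(counts), features$feature_id)
    if (length(fmiss)) stop("features missing from metadata: ",
                            paste(utils::head(fmiss, 5), collapse = ", "))
  }
  if (any(counts < 0)) stop("negative counts in matrix")
  invisible(TRUE)
}

#' Run configuration for the end-to-end pipeline
#'
#' All stage parameters and the master seed in one validated record; the
#' seed has no default so a configuration without one is rejected before
#' execution. Unknown keys are rejected by the function signature.
#'
#' @param counts,samples,features in-memory objects or TSV paths.
#' @param out_dir directory for stage artifacts.
#' @param seed master seed (required).
#' @param panel_size consensus panel size (default 3).
#' @param norm_method CPM library-size method.
#' @param filter,gate,selector,classifier,scheme stage parameter lists.
#' @param evaluate run the nested-CV evaluation and calibration stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, samples, features, out_dir, seed,
                       panel_size = 3,
                       norm_method = c("total-count", "trimmed-mean"),
                       filter = list(min_nonzero_frac = 0.80, min_count = 5,
                                     min_count_frac = 0.10),
                       gate = list(alpha = 0.05, min_abs_log2fc = 1.2,
                                   min_base_mean = 50),
                       selector = selector_config(),
                       classifier = classifier_spec(),
                       scheme = cv_scheme(),
                       evaluate = TRUE) {
  if (missing(seed) || is.null(seed)) stop("run_config requires a seed")
  structure(list(counts = counts, samples = samples, features = features,
                 out_dir = out_dir, seed = as.integer(seed),
                 panel_size = panel_size,
                 norm_method = match.arg(norm_method),
                 filter = filter, gate = gate, selector = selector,
                 classifier = classifier, scheme = scheme,
                 evaluate = evaluate),
            class = "run_config")
}

load_stage_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Execute the full screening pipeline and write stage artifacts
#'
#' Runs preprocessing, differential expression, stability/consistency
#' screening, nested-CV evaluation and calibration in order via
#' [exoscreen()], persists each stage's output under `config$out_dir`
#' (atomic writes), and returns a manifest with the configuration snapshot
#' and per-artifact MD5 checksums. Re-running with an identical
#' configuration and seed reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @return list of class `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counts <- load_stage_input(config$counts, read_count_matrix)
  samples <- load_stage_input(config$samples, read_sample_meta)
  features <- load_stage_input(config$features, read_feature_meta)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  fit <- exoscreen(counts, samples, features,
                   panel_size = config$panel_size,
                   norm_method = config$norm_method,
                   filter = config$filter, gate = config$gate,
                   selector_cfg = config$selector, spec = config$classifier,
                   scheme = config$scheme, evaluate = config$evaluate,
                   seed = config$seed)

  paths <- c(filtered_counts = "filtered_counts.tsv",
             normalized = "normalized_matrix.tsv",
             de_table = "de_table.tsv",
             stability = "stability_report.tsv",
             panel = "panel.tsv")
  paths <- file.path(config$out_dir, paths)
  names(paths) <- c("filtered_counts", "normalized", "de_table",
                    "stability", "panel")
  write_count_matrix(fit$filtered_counts, paths["filtered_counts"])
  write_count_matrix(fit$normalized$values, paths["normalized"])
  de_out <- fit$de
  de_out$pass_gate <- as.integer(de_out$feature_id %in% fit$candidates)
  atomic_write(function(tmp) utils::write.table(
    de_out, tmp, sep = "\t", quote = FALSE, row.names = FALSE),
    paths["de_table"])
  atomic_write(function(tmp) utils::write.table(
    fit$stability_table, tmp, sep = "\t", quote = FALSE, row.names = FALSE),
    paths["stability"])
  atomic_write(function(tmp) utils::write.table(
    as.data.frame(fit$panel), tmp, sep = "\t", quote = FALSE,
    row.names = FALSE), paths["panel"])

  if (config$evaluate) {
    eval_path <- file.path(config$out_dir, "nested_cv.json")
    calib_path <- file.path(config$out_dir, "calibration.json")
    ev <- fit$evaluation
    eval_json <- list(
      mean_auc = ev$mean_auc, auc_ci = as.list(ev$auc_ci),
      folds = lapply(ev$folds, function(f) {
        list(auc = f$metrics$auc, sensitivity = f$metrics$sensitivity,
             specificity = f$metrics$specificity,
             accuracy = f$metrics$accuracy, C = f$C, gamma = f$gamma,
             features = f$features)
      }))
    atomic_write(function(tmp) jsonlite::write_json(
      eval_json, tmp, auto_unbox = TRUE, digits = NA), eval_path)
    cal <- fit$calibration
    atomic_write(function(tmp) jsonlite::write_json(
      list(hl_stat = cal$hl_stat, hl_df = cal$hl_df, hl_p = cal$hl_p,
           brier = cal$brier, slope = cal$slope, intercept = cal$intercept,
           curve = cal$curve_points),
      tmp, auto_unbox = TRUE, digits = NA), calib_path)
    paths <- c(paths, nested_cv = eval_path, calibration = calib_path)
  }

  manifest <- structure(
    list(package_version = as.character(utils::packageVersion("exoscreen")),
         seed = config$seed,
         parameters = list(panel_size = config$panel_size,
                           norm_method = config$norm_method,
                           filter = config$filter, gate = config$gate,
                           evaluate = config$evaluate),
         checksums = {
           cs <- tools::md5sum(paths)
           names(cs) <- names(paths)
           as.list(cs)
         },
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
  atomic_write(function(tmp) jsonlite::write_json(
    unclass(manifest), tmp, auto_unbox = TRUE, digits = NA),
    file.path(config$out_dir, "manifest.json"))
  manifest
}
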