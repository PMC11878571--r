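# End-to-end orchestration: load a cohort from disk, run the longitudinal
# analysis (and optional multi-scale sensitivity sweep), and write TSV
# results plus a machine-readable run manifest with input hashes.

#' Run configuration for a full pipeline run
#'
#' @param data_dir Directory with the cohort metadata TSV
#'   (`cohort.tsv`), per-scale parcellation TSVs
#'   (`parcellation_scale<k>.tsv`) and matrix files.
#' @param out_dir Output directory for result tables and the manifest.
#' @param scale Primary analysis scale (default 3).
#' @param sensitivity_scales Scales for the sensitivity sweep (`NULL`
#'   disables it).
#' @param exclude_age_below Optional age threshold for the young-patient
#'   sensitivity exclusion.
#' @inheritParams analysis_config
#' @param ... Further [analysis_config()] settings.
#' @return A `run_config` list.
#' @export
run_config <- function(data_dir, out_dir, scale = 3L,
                       sensitivity_scales = NULL, exclude_age_below = NULL,
                       z_threshold = 2, alpha = 0.01, gamma = 1, seed = 1L,
                       ...) {
  cfg <- analysis_config(scale = scale, z_threshold = z_threshold,
                         alpha = alpha, gamma = gamma, seed = seed, ...)
  cfg$data_dir <- data_dir
  cfg$out_dir <- out_dir
  cfg$sensitivity_scales <- sensitivity_scales
  cfg$exclude_age_below_sensitivity <- exclude_age_below
  structure(cfg, class = "run_config")
}

load_cohort_at_scale <- function(data_dir, scale, quiet = TRUE) {
  parc_path <- file.path(data_dir, sprintf("parcellation_scale%d.tsv", scale))
  parc <- read_parcellation(parc_path, scale = scale)
  read_cohort(file.path(data_dir, "cohort.tsv"), data_dir, scale, parc,
              quiet = quiet)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

#' Write the result tables of a longitudinal analysis as TSV
#'
#' @param result A `longitudinal_analysis`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    df
  }
  paths <- character()
  emit <- function(df, name) {
    if (is.null(df)) return()
    paths[[name]] <<- write_tsv(fmt(as.data.frame(df)),
                                file.path(dir, paste0(name, ".tsv")))
  }
  emit(result$global_results, "global_results")
  emit(result$subgroup_results, "subgroup_results")
  emit(result$burden_results, "burden_results")
  emit(result$thalamic_lobe_results, "thalamic_lobe_results")
  emit(result$thalamic_modal_result, "thalamic_modal_result")
  emit(result$z_of_z, "z_of_z")
  emit(result$tables$global_residuals, "global_residuals")
  emit(result$tables$burden, "burden_table")
  if (!is.null(result$z_of_z_test))
    jsonlite::write_json(result$z_of_z_test,
                         file.path(dir, "z_of_z_test.json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(unlist(paths))
}

#' Run the full pipeline from on-disk inputs
#'
#' Loads the cohort, runs [run_longitudinal_analysis()] at the primary
#' scale, optionally runs [sensitivity_across_scales()], and writes all
#' result tables plus a JSON run manifest (configuration, seed, package
#' version, input file MD5 hashes) under `out_dir`.
#'
#' @param config A [run_config()].
#' @return The `longitudinal_analysis` result, invisibly; side effect is
#'   the populated `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_cohort_at_scale(config$data_dir, config$scale, quiet = FALSE)
  message("stage: longitudinal analysis at scale ", config$scale)
  result <- run_longitudinal_analysis(cohort, config)
  write_results(result, config$out_dir)
  if (!is.null(config$sensitivity_scales)) {
    message("stage: sensitivity sweep over scales ",
            paste(config$sensitivity_scales, collapse = ", "))
    cohorts <- lapply(config$sensitivity_scales, function(s)
      load_cohort_at_scale(config$data_dir, s))
    names(cohorts) <- config$sensitivity_scales
    sweep <- sensitivity_across_scales(cohorts, config)
    write_tsv(sweep, file.path(config$out_dir, "sensitivity_sweep.tsv"))
    if (!is.null(config$exclude_age_below_sensitivity)) {
      sweep2 <- sensitivity_across_scales(
        cohorts, config,
        exclude_age_below = config$exclude_age_below_sensitivity)
      write_tsv(sweep2,
                file.path(config$out_dir, "sensitivity_sweep_age_excluded.tsv"))
    }
  }
  inputs <- list.files(config$data_dir, full.names = TRUE)
  manifest <- list(
    package = "longconn",
    version = as.character(packageVersion("longconn")),
    seed = config$seed,
    config = config[setdiff(names(config), c("data_dir", "out_dir"))],
    n_controls = sum(cohort$subjects$group == "control"),
    n_pairs = result$n_pairs,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       force = TRUE)
  invisible(result)
}
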