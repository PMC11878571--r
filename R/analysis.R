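# End-to-end longitudinal analysis on a cohort: metric computation for
# every scan, normative fits on controls, patient residuals/Z-scores,
# abnormal-node burden, thalamocortical and thalamic-controllability
# analyses, paired statistics and subgroup tests.

.global_metric_names <- c("mean_degree", "transitivity", "modularity_q",
                          "global_efficiency", "mean_average_controllability",
                          "mean_modal_controllability")
.nodal_metric_names <- c("strength", "participation", "eigenvector",
                         "local_efficiency", "average_controllability",
                         "modal_controllability")

#' Default analysis configuration
#'
#' Defaults reproduce the primary analysis choices: scale 3, abnormality
#' threshold |Z| > 2, significance threshold P < 0.01, Louvain resolution
#' 1, weighted metrics, difference-score Cohen's d, exact Wilcoxon where
#' available.
#'
#' @param scale Parcellation scale (1--5).
#' @param z_threshold Abnormal-node threshold on |Z|.
#' @param alpha Significance threshold for the fixed multiple-comparison
#'   policy.
#' @param gamma Louvain resolution.
#' @param seed Integer seed (Louvain sweeps and any simulation embedded in
#'   a run).
#' @param analyses Which analysis blocks to run: subset of
#'   `"global"`, `"nodal"`, `"thalamic"`.
#' @param d_denominator Cohen's d denominator variant
#'   (see [cohens_d_paired()]).
#' @param exact_wilcoxon `NULL` (auto), `TRUE` or `FALSE`.
#' @param age2 Add a quadratic age term to the normative design.
#' @param exclude_age_below Drop patients whose early-scan age is below
#'   this threshold (`NULL` keeps everyone).
#' @return Named list of validated settings.
#' @export
analysis_config <- function(scale = 3L, z_threshold = 2, alpha = 0.01,
                            gamma = 1, seed = 1L,
                            analyses = c("global", "nodal", "thalamic"),
                            d_denominator = "difference_sd",
                            exact_wilcoxon = NULL, age2 = FALSE,
                            exclude_age_below = NULL) {
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L || scale > 5L)
    stop("scale must be an integer in 1..5", call. = FALSE)
  if (z_threshold <= 0) stop("z_threshold must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  analyses <- match.arg(analyses, c("global", "nodal", "thalamic"),
                        several.ok = TRUE)
  list(scale = scale, z_threshold = z_threshold, alpha = alpha,
       gamma = gamma, seed = as.integer(seed), analyses = analyses,
       d_denominator = d_denominator, exact_wilcoxon = exact_wilcoxon,
       age2 = age2, exclude_age_below = exclude_age_below)
}

# Global and nodal metrics for one adjacency, sharing one Louvain
# partition and one eigendecomposition of the normalized system matrix.
scan_metrics <- function(w, gamma, seed, nodal = TRUE) {
  lv <- modularity_louvain(w, gamma = gamma, seed = seed)
  a <- normalize_adjacency(w)
  ac <- average_controllability(a)
  mc <- modal_controllability(a)
  s <- node_strength(w)
  global <- c(mean_degree = mean(s),
              transitivity = transitivity_w(w),
              modularity_q = lv$q,
              global_efficiency = global_efficiency(w),
              mean_average_controllability = mean(ac),
              mean_modal_controllability = mean(mc))
  nod <- NULL
  if (nodal) {
    nod <- cbind(strength = s,
                 participation = participation_coefficient(w, lv$membership),
                 eigenvector = eigenvector_centrality(w),
                 local_efficiency = local_efficiency(w),
                 average_controllability = ac,
                 modal_controllability = mc)
  }
  list(global = global, nodal = nod)
}

#' Compute metric tables for every scan in a cohort
#'
#' @param cohort A `cohort`.
#' @param gamma,seed Louvain settings (see [modularity_louvain()]).
#' @param nodal Also compute nodal metrics (needed for the nodal and
#'   thalamic-controllability analyses).
#' @param thalamic Also compute thalamocortical lobe sums.
#' @return List with `scans` (the cohort scan table), `global`
#'   (scans x 6 matrix), `nodal` (scans x (parcels*metrics) matrix with
#'   `"<parcel>::<metric>"` columns, or `NULL`), `thal` (scans x 10 lobe-sum
#'   matrix with `"<hemisphere>:<lobe>"` columns, or `NULL`).
#' @export
compute_metric_tables <- function(cohort, gamma = 1, seed = 1L,
                                  nodal = TRUE, thalamic = TRUE) {
  keys <- paste(cohort$scans$subject_id, cohort$scans$timepoint, sep = "|")
  p <- nrow(cohort$parcellation)
  global <- matrix(NA_real_, length(keys), length(.global_metric_names),
                   dimnames = list(keys, .global_metric_names))
  nodal_m <- if (nodal)
    matrix(NA_real_, length(keys), p * length(.nodal_metric_names),
           dimnames = list(keys, as.vector(outer(
             cohort$parcellation$parcel_id, .nodal_metric_names,
             function(a, b) paste0(a, "::", b)))))
  thal_m <- NULL
  if (thalamic) {
    prof0 <- thalamocortical_connectivity(
      cohort$connectomes[[keys[1L]]], cohort$parcellation)
    thal_m <- matrix(NA_real_, length(keys), 10L,
                     dimnames = list(keys, lobe_key(prof0$hemisphere,
                                                    prof0$lobe)))
  }
  for (i in seq_along(keys)) {
    cn <- cohort$connectomes[[keys[i]]]
    sm <- scan_metrics(cn$matrix, gamma = gamma, seed = seed, nodal = nodal)
    global[i, ] <- sm$global
    if (nodal) nodal_m[i, ] <- as.vector(sm$nodal)
    if (thalamic)
      thal_m[i, ] <- thalamocortical_connectivity(cn,
                                                  cohort$parcellation)$streamline_sum
  }
  list(scans = cohort$scans, global = global, nodal = nodal_m, thal = thal_m)
}

# Z-score (or residualize) patient rows of a feature matrix against models
# fitted on control rows. Returns matrices [scan x feature] for the rows
# requested in `rows`.
score_rows <- function(model, features, scans, rows, what = c("z", "residual")) {
  what <- match.arg(what)
  out <- matrix(NA_real_, length(rows), length(model$features),
                dimnames = list(rownames(features)[rows], model$features))
  for (j in seq_along(rows)) {
    i <- rows[j]
    out[j, ] <- if (what == "z")
      zscore_features(model, features[i, ], scans$age_at_scan[i],
                      scans$sex[i], warn_extrapolation = FALSE)
    else
      residuals_normative(model, features[i, ], scans$age_at_scan[i],
                          scans$sex[i], warn_extrapolation = FALSE)
  }
  out
}

#' Run the full longitudinal analysis on a cohort
#'
#' Computes graph, controllability and thalamocortical features for every
#' scan; fits age + sex normative models on the controls; expresses
#' patients as residuals (global metrics) and Z-scores (nodal metrics,
#' thalamocortical lobe sums, thalamic modal controllability); counts
#' abnormal nodes outside `±z_threshold`; and compares early vs late scans
#' with paired Wilcoxon signed-rank tests and Cohen's d. Subgroup
#' differences in global residual changes are tested with Kruskal-Wallis,
#' and the affected-lobe z-of-z with a one-sample t-test.
#'
#' @param cohort A `cohort` with controls and paired patients.
#' @param config Settings from [analysis_config()].
#' @return A `longitudinal_analysis` list with tidy result data frames:
#'   `global_results`, `burden_results`, `thalamic_lobe_results`,
#'   `thalamic_modal_result`, `z_of_z`, `z_of_z_test`, `subgroup_results`,
#'   plus the underlying `tables` (residuals, Z-scores, burdens) and the
#'   `config` echo.
#' @export
run_longitudinal_analysis <- function(cohort, config = analysis_config()) {
  scans <- cohort$scans
  patients <- cohort$subjects[cohort$subjects$group == "patient", ]
  if (!is.null(config$exclude_age_below)) {
    early_age <- scans$age_at_scan[match(paste(patients$subject_id, "early"),
                                         paste(scans$subject_id,
                                               scans$timepoint))]
    drop_ids <- patients$subject_id[early_age < config$exclude_age_below]
    if (length(drop_ids)) {
      keep <- !(scans$subject_id %in% drop_ids)
      cohort$scans <- scans <- scans[keep, , drop = FALSE]
      cohort$subjects <- cohort$subjects[
        !(cohort$subjects$subject_id %in% drop_ids), , drop = FALSE]
      cohort$connectomes <- cohort$connectomes[
        paste(scans$subject_id, scans$timepoint, sep = "|")]
      patients <- cohort$subjects[cohort$subjects$group == "patient", ]
    }
  }
  if (nrow(patients) < 5L)
    stop("fewer than 5 complete patient pairs", call. = FALSE)

  need_nodal <- any(c("nodal", "thalamic") %in% config$analyses)
  need_thal <- "thalamic" %in% config$analyses
  tabs <- compute_metric_tables(cohort, gamma = config$gamma,
                                seed = config$seed, nodal = need_nodal,
                                thalamic = need_thal)
  ctrl <- which(scans$group == "control")
  i_early <- match(paste(patients$subject_id, "early", sep = "|"),
                   rownames(tabs$global))
  i_late <- match(paste(patients$subject_id, "late", sep = "|"),
                  rownames(tabs$global))
  ctrl_ages <- scans$age_at_scan[ctrl]
  ctrl_sex <- scans$sex[ctrl]
  out <- list(config = config, n_pairs = nrow(patients),
              patients = patients, tables = list())

  if ("global" %in% config$analyses) {
    gm <- fit_normative_model(tabs$global[ctrl, , drop = FALSE],
                              ctrl_ages, ctrl_sex, age2 = config$age2)
    res_ctrl <- score_rows(gm, tabs$global, scans, ctrl, what = "residual")
    res_e <- score_rows(gm, tabs$global, scans, i_early, what = "residual")
    res_l <- score_rows(gm, tabs$global, scans, i_late, what = "residual")
    out$global_results <- do.call(rbind, lapply(.global_metric_names, function(m)
      paired_comparison_row(m, res_e[, m], res_l[, m], config$alpha,
                            config$d_denominator, config$exact_wilcoxon)))
    out$tables$global_residuals <- rbind(
      data.frame(subject_id = scans$subject_id[ctrl], timepoint = "control",
                 res_ctrl, check.names = FALSE),
      data.frame(subject_id = patients$subject_id, timepoint = "early",
                 res_e, check.names = FALSE),
      data.frame(subject_id = patients$subject_id, timepoint = "late",
                 res_l, check.names = FALSE))
    out$models <- list(global = gm)

    change <- res_l - res_e
    subgroup <- list()
    for (by in c("histopathology", "seizure_free")) {
      lab <- patients[[by]]
      for (m in .global_metric_names) {
        row <- tryCatch({
          kt <- suppressWarnings(subgroup_kruskal(change[, m], lab))
          data.frame(grouping = by, metric = m, p_value = kt$p_value,
                     statistic = kt$statistic,
                     n_groups = length(kt$groups_used),
                     stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(grouping = by, metric = m, p_value = NA_real_,
                     statistic = NA_real_, n_groups = NA_integer_,
                     stringsAsFactors = FALSE))
        subgroup[[paste(by, m)]] <- row
      }
    }
    out$subgroup_results <- do.call(rbind, c(subgroup,
                                             make.row.names = FALSE))
  }

  if ("nodal" %in% config$analyses) {
    nm <- fit_normative_model(tabs$nodal[ctrl, , drop = FALSE],
                              ctrl_ages, ctrl_sex, age2 = config$age2)
    z_e <- score_rows(nm, tabs$nodal, scans, i_early)
    z_l <- score_rows(nm, tabs$nodal, scans, i_late)
    metric_of <- sub("^.*::", "", colnames(tabs$nodal))
    burden_rows <- list(); burden_tab <- list()
    for (m in .nodal_metric_names) {
      cols <- metric_of == m
      be <- t(apply(z_e[, cols, drop = FALSE], 1L, function(z)
        unlist(abnormal_burden(z, config$z_threshold)[1:3])))
      bl <- t(apply(z_l[, cols, drop = FALSE], 1L, function(z)
        unlist(abnormal_burden(z, config$z_threshold)[1:3])))
      for (ct in c("n_abnormal_total", "n_above", "n_below")) {
        burden_rows[[paste(m, ct)]] <- cbind(
          paired_comparison_row(m, be[, ct], bl[, ct], config$alpha,
                                config$d_denominator, config$exact_wilcoxon),
          count = ct)
      }
      burden_tab[[m]] <- rbind(
        data.frame(subject_id = patients$subject_id, timepoint = "early",
                   metric = m, be, stringsAsFactors = FALSE),
        data.frame(subject_id = patients$subject_id, timepoint = "late",
                   metric = m, bl, stringsAsFactors = FALSE))
    }
    out$burden_results <- do.call(rbind, c(burden_rows,
                                           make.row.names = FALSE))
    out$tables$burden <- do.call(rbind, c(burden_tab,
                                          make.row.names = FALSE))
    out$tables$nodal_z_early <- z_e
    out$tables$nodal_z_late <- z_l
    out$models$nodal <- nm
  }

  if (need_thal) {
    # Thalamocortical lobe sums.
    tm <- fit_normative_model(tabs$thal[ctrl, , drop = FALSE],
                              ctrl_ages, ctrl_sex, age2 = config$age2)
    tz_e <- score_rows(tm, tabs$thal, scans, i_early)
    tz_l <- score_rows(tm, tabs$thal, scans, i_late)
    out$thalamic_lobe_results <- do.call(rbind, lapply(
      colnames(tabs$thal), function(k)
        paired_comparison_row(k, tz_e[, k], tz_l[, k], config$alpha,
                              config$d_denominator, config$exact_wilcoxon)))
    dz <- tz_l - tz_e
    zoz <- vapply(seq_len(nrow(patients)), function(j) {
      suppressWarnings(affected_lobe_z_of_z(
        setNames(dz[j, ], colnames(dz)),
        patients$affected_hemisphere[j], patients$affected_lobe[j]))
    }, numeric(1))
    out$z_of_z <- data.frame(subject_id = patients$subject_id,
                             z_of_z = zoz, stringsAsFactors = FALSE)
    out$z_of_z_test <- one_sample_t(zoz, mu = 0)
    out$tables$thal_z_early <- tz_e
    out$tables$thal_z_late <- tz_l
    out$models$thalamic <- tm

    # Thalamic modal controllability: Z-scores of the 14 thalamic parcels'
    # modal controllability; the paired test runs on each patient's mean
    # thalamic Z.
    thal_cols <- paste0(thalamic_parcel_ids(cohort$parcellation),
                        "::modal_controllability")
    mm <- fit_normative_model(tabs$nodal[ctrl, thal_cols, drop = FALSE],
                              ctrl_ages, ctrl_sex, age2 = config$age2)
    mz_e <- score_rows(mm, tabs$nodal[, thal_cols, drop = FALSE], scans,
                       i_early)
    mz_l <- score_rows(mm, tabs$nodal[, thal_cols, drop = FALSE], scans,
                       i_late)
    out$thalamic_modal_result <- paired_comparison_row(
      "thalamic_modal_controllability", rowMeans(mz_e), rowMeans(mz_l),
      config$alpha, config$d_denominator, config$exact_wilcoxon)
    out$tables$thalamic_modal_z_early <- mz_e
    out$tables$thalamic_modal_z_late <- mz_l
  }
  structure(out, class = "longitudinal_analysis")
}

#' Thalamic modal-controllability Z-score table
#'
#' Z-scores of thalamic-parcel modal controllability for each patient scan
#' against control-fitted normative models, in long format (14 rows per
#' patient timepoint: 7 per hemisphere).
#'
#' @param cohort A `cohort`.
#' @param gamma,seed Louvain settings (a Louvain partition is computed per
#'   connectome because metric tables are shared machinery; it does not
#'   affect modal controllability).
#' @param age2 Quadratic age term in the normative design.
#' @return Data frame `subject_id`, `timepoint`, `parcel_id`, `z`.
#' @export
thalamic_modal_z <- function(cohort, gamma = 1, seed = 1L, age2 = FALSE) {
  res <- run_longitudinal_analysis(
    cohort, analysis_config(scale = cohort$scale, gamma = gamma, seed = seed,
                            analyses = "thalamic", age2 = age2))
  long <- function(m, tp) {
    data.frame(subject_id = sub("\\|.*$", "", rownames(m))[rep(seq_len(nrow(m)),
                                                               each = ncol(m))],
               timepoint = tp,
               parcel_id = rep(sub("::.*$", "", colnames(m)), nrow(m)),
               z = as.vector(t(m)), stringsAsFactors = FALSE)
  }
  rbind(long(res$tables$thalamic_modal_z_early, "early"),
        long(res$tables$thalamic_modal_z_late, "late"))
}

#' @export
print.longitudinal_analysis <- function(x, ...) {
  cat(sprintf("<longitudinal_analysis> scale %d, %d patient pairs, alpha %.3g\n",
              x$config$scale, x$n_pairs, x$config$alpha))
  if (!is.null(x$global_results)) {
    cat("\nGlobal metrics (paired Wilcoxon on age/sex-adjusted residuals):\n")
    print(x$global_results, digits = 3)
  }
  if (!is.null(x$burden_results)) {
    sig <- x$burden_results[x$burden_results$significant %in% TRUE, ]
    cat(sprintf("\nNodal burden comparisons: %d of %d significant at P < %.3g\n",
                nrow(sig), nrow(x$burden_results), x$config$alpha))
  }
  if (!is.null(x$z_of_z_test))
    cat(sprintf("\nAffected-lobe z-of-z: mean %.3f, one-sample t P = %.3g\n",
                x$z_of_z_test$mean, x$z_of_z_test$p_value))
  invisible(x)
}

#' Sensitivity sweep across parcellation scales
#'
#' Repeats the longitudinal analysis at each supplied scale (optionally
#' excluding the youngest patients) and tabulates p-values as
#' `-log10(p)`.
#'
#' @param cohorts Named list of `cohort` objects keyed by scale
#'   (`"1"` ... `"5"`), or a single cohort.
#' @param config Base [analysis_config()]; its `scale` is overridden per
#'   sweep entry.
#' @param exclude_age_below Optional early-scan age threshold below which
#'   patients are excluded (overrides the config field).
#' @return Data frame `scale`, `analysis`, `metric`, `count`, `p_value`,
#'   `neg_log10_p`, `cohens_d`, `n_pairs`.
#' @export
sensitivity_across_scales <- function(cohorts, config = analysis_config(),
                                      exclude_age_below = NULL) {
  if (inherits(cohorts, "cohort")) cohorts <- setNames(list(cohorts),
                                                       cohorts$scale)
  if (!is.null(exclude_age_below)) config$exclude_age_below <- exclude_age_below
  rows <- lapply(names(cohorts), function(s) {
    cfg <- config
    cfg$scale <- as.integer(s)
    if (cohorts[[s]]$scale != cfg$scale)
      stop("cohort keyed ", s, " has scale ", cohorts[[s]]$scale,
           call. = FALSE)
    res <- run_longitudinal_analysis(cohorts[[s]], cfg)
    pieces <- list()
    if (!is.null(res$global_results))
      pieces$global <- data.frame(analysis = "global",
                                  res$global_results[, c("metric", "n_pairs",
                                                         "p_value",
                                                         "cohens_d")],
                                  count = NA_character_)
    if (!is.null(res$burden_results))
      pieces$nodal <- data.frame(analysis = "nodal_burden",
                                 res$burden_results[, c("metric", "n_pairs",
                                                        "p_value",
                                                        "cohens_d")],
                                 count = res$burden_results$count)
    if (!is.null(res$thalamic_lobe_results))
      pieces$thal <- data.frame(analysis = "thalamocortical",
                                res$thalamic_lobe_results[, c("metric",
                                                              "n_pairs",
                                                              "p_value",
                                                              "cohens_d")],
                                count = NA_character_)
    df <- do.call(rbind, c(pieces, make.row.names = FALSE))
    df$scale <- as.integer(s)
    df
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$neg_log10_p <- -log10(out$p_value)
  out[, c("scale", "analysis", "metric", "count", "n_pairs", "p_value",
          "neg_log10_p", "cohens_d")]
}
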