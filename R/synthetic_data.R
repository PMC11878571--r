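# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: a cross-sectional control cohort whose connectome edge
# weights carry multiplicative age and sex effects, and paired early/late
# patient scans sharing subject-level structure, with optional injected
# ground-truth effects on the late scan. The anatomical backbone (which
# edges exist, and their baseline weights) is a weighted block model over
# the parcellation: strong within-lobe blocks, weaker between-lobe and
# cross-hemisphere connections, and ipsilateral thalamocortical bundles.

#' Build a synthetic multi-resolution parcellation
#'
#' Mirrors the atlas conventions the pipeline validates: per hemisphere,
#' five cortical lobes (parcel count per lobe growing with scale), seven
#' thalamic parcels and three hippocampal parcels, plus four midline
#' brainstem parcels.
#'
#' @param scale Scale 1--5; cortical parcels per lobe per hemisphere are
#'   2, 3, 5, 8, 12.
#' @return A validated `parcellation`.
#' @export
make_parcellation <- function(scale) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1L, scale <= 5L)
  per_lobe <- c(2L, 3L, 5L, 8L, 12L)[scale]
  rows <- list()
  for (h in c("left", "right")) {
    hs <- substr(h, 1, 1)
    for (l in .lobe_taxonomy_default)
      for (i in seq_len(per_lobe))
        rows[[length(rows) + 1L]] <- data.frame(
          parcel_id = sprintf("ctx-%sh-%s-%d", hs, l, i),
          name = sprintf("%s %s %d", h, l, i),
          hemisphere = h, lobe = l, structure_class = "cortical",
          stringsAsFactors = FALSE)
    for (i in 1:7)
      rows[[length(rows) + 1L]] <- data.frame(
        parcel_id = sprintf("thal-%sh-%d", hs, i),
        name = sprintf("%s thalamus %d", h, i),
        hemisphere = h, lobe = NA_character_, structure_class = "thalamic",
        stringsAsFactors = FALSE)
    for (part in c("head", "body", "tail"))
      rows[[length(rows) + 1L]] <- data.frame(
        parcel_id = sprintf("hipp-%sh-%s", hs, part),
        name = sprintf("%s hippocampus %s", h, part),
        hemisphere = h, lobe = NA_character_,
        structure_class = "hippocampal", stringsAsFactors = FALSE)
  }
  for (i in 1:4)
    rows[[length(rows) + 1L]] <- data.frame(
      parcel_id = sprintf("bstem-%d", i), name = sprintf("brainstem %d", i),
      hemisphere = "midline", lobe = NA_character_,
      structure_class = "brainstem", stringsAsFactors = FALSE)
  as_parcellation(do.call(rbind, rows), scale = scale)
}

#' Simulation manifest: every knob of the synthetic cohort
#'
#' The manifest fully determines a generated cohort given a seed. Defaults
#' mirror the study conditions the pipeline is meant for: 57 controls and
#' 23 patient pairs, an inter-scan interval with median 1.15 years
#' (log-normal, sdlog 0.67, matching an interquartile range of roughly
#' 0.78--1.93 years), control ages 6--18 and patient early-scan ages
#' 3--16 years (so a subset of patients is younger than every control).
#' Edge weights are `backbone * exp(age, sex, subject and scan effects)`:
#' the multiplicative (log-normal) noise keeps weights nonnegative while
#' inducing approximately linear metric-age relations for the normative
#' GLM to recover.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param control_age_range,patient_age_range Uniform age ranges, years.
#' @param interval_meanlog,interval_sdlog Log-normal inter-scan interval
#'   parameters (years).
#' @param beta_age Log-weight increase per year of age.
#' @param beta_sex Log-weight offset for males.
#' @param sigma_subject SD of the subject-level global log-scaling.
#' @param sigma_subject_edge SD of subject-level per-edge log effects
#'   (shared between a patient's two scans).
#' @param sigma_scan SD of scan-level per-edge log noise.
#' @param sigma_session SD of the scan-level global log-scaling (session
#'   and tractography test-retest variability; the dominant within-pair
#'   noise source for aggregate weight features).
#' @param age_center Age (years) at which the age effect is zero.
#' @param weights Named list of backbone block weights.
#' @return Named list (class `simulation_manifest`).
#' @export
simulation_manifest <- function(n_controls = 57L, n_patients = 23L,
                                control_age_range = c(6, 18),
                                patient_age_range = c(3, 16),
                                interval_meanlog = log(1.15),
                                interval_sdlog = 0.67,
                                beta_age = 0.015, beta_sex = 0.05,
                                sigma_subject = 0.1,
                                sigma_subject_edge = 0.1,
                                sigma_scan = 0.1,
                                sigma_session = 0.05,
                                age_center = 10,
                                weights = list(
                                  ctx_within_lobe = 30, ctx_between_lobe = 6,
                                  ctx_homologous = 10, ctx_cross = 1.5,
                                  thal_ipsi_ctx = 12, thal_contra_ctx = 1,
                                  thal_within = 15, thal_cross = 2,
                                  hipp_within = 20, hipp_temporal = 15,
                                  hipp_ipsi_ctx = 4, hipp_cross = 0.8,
                                  bstem_thal = 8, bstem_within = 10,
                                  bstem_other = 2)) {
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 control_age_range = control_age_range,
                 patient_age_range = patient_age_range,
                 interval_meanlog = interval_meanlog,
                 interval_sdlog = interval_sdlog,
                 beta_age = beta_age, beta_sex = beta_sex,
                 sigma_subject = sigma_subject,
                 sigma_subject_edge = sigma_subject_edge,
                 sigma_scan = sigma_scan, sigma_session = sigma_session,
                 age_center = age_center,
                 weights = weights),
            class = "simulation_manifest")
}

# Deterministic backbone of expected weights for a parcellation. Purely a
# function of parcel attributes, so it is identical for every subject.
backbone_weights <- function(parcellation, manifest) {
  wg <- manifest$weights
  n <- nrow(parcellation)
  hemi <- parcellation$hemisphere
  lobe <- parcellation$lobe
  cls <- parcellation$structure_class
  b <- matrix(0, n, n)
  same_hemi <- outer(hemi, hemi, "==") & hemi != "midline"
  same_lobe <- outer(lobe, lobe, "==")
  same_lobe[is.na(same_lobe)] <- FALSE
  is_ctx <- cls == "cortical"; is_thal <- cls == "thalamic"
  is_hipp <- cls == "hippocampal"; is_bstem <- cls == "brainstem"
  pair <- function(a, b2) outer(a, b2) | outer(b2, a)
  cc <- outer(is_ctx, is_ctx)
  b[cc & same_hemi & same_lobe] <- wg$ctx_within_lobe
  b[cc & same_hemi & !same_lobe] <- wg$ctx_between_lobe
  b[cc & !same_hemi & same_lobe] <- wg$ctx_homologous
  b[cc & !same_hemi & !same_lobe] <- wg$ctx_cross
  tc <- pair(is_thal, is_ctx)
  b[tc & same_hemi] <- wg$thal_ipsi_ctx
  b[tc & !same_hemi] <- wg$thal_contra_ctx
  tt <- outer(is_thal, is_thal)
  b[tt & same_hemi] <- wg$thal_within
  b[tt & !same_hemi] <- wg$thal_cross
  hh <- outer(is_hipp, is_hipp)
  b[hh & same_hemi] <- wg$hipp_within
  hc <- pair(is_hipp, is_ctx)
  temporal <- !is.na(lobe) & lobe == "temporal"
  ht <- pair(is_hipp, temporal)
  b[hc & same_hemi & !ht] <- wg$hipp_ipsi_ctx
  b[ht & same_hemi] <- wg$hipp_temporal
  b[hc & !same_hemi] <- wg$hipp_cross
  b[pair(is_hipp, is_thal)] <- wg$hipp_cross
  b[pair(is_bstem, is_thal)] <- wg$bstem_thal
  b[outer(is_bstem, is_bstem)] <- wg$bstem_within
  b[pair(is_bstem, is_ctx | is_hipp)] <- wg$bstem_other
  diag(b) <- 0
  b
}

# One scan's weight matrix: backbone scaled by exp of age/sex terms, a
# subject scalar, subject-level edge effects (upper triangle, symmetrized)
# and scan-level edge noise.
simulate_scan_matrix <- function(backbone, manifest, age, sex,
                                 subject_scalar, subject_edge_log) {
  n <- nrow(backbone)
  ut <- upper.tri(backbone)
  scan_edge <- matrix(0, n, n)
  scan_edge[ut] <- rnorm(sum(ut), 0, manifest$sigma_scan)
  scan_edge <- scan_edge + t(scan_edge)
  lf <- manifest$beta_age * (age - manifest$age_center) +
    manifest$beta_sex * as.numeric(sex == "male") + subject_scalar +
    rnorm(1, 0, manifest$sigma_session)
  w <- backbone * exp(lf + subject_edge_log + scan_edge)
  diag(w) <- 0
  w
}

new_subject_edge_log <- function(n, manifest) {
  ut <- upper.tri(matrix(0, n, n))
  m <- matrix(0, n, n)
  m[ut] <- rnorm(sum(ut), 0, manifest$sigma_subject_edge)
  m + t(m)
}

#' Generate a cross-sectional control cohort
#'
#' @param n Number of controls (>= 10).
#' @param scale Parcellation scale.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param manifest A [simulation_manifest()].
#' @return A `cohort` of `n` single-scan controls.
#' @export
generate_control_cohort <- function(n = 57L, scale = 3L, seed = 1L,
                                    manifest = simulation_manifest()) {
  if (n < 10L) stop("need at least 10 controls", call. = FALSE)
  parc <- make_parcellation(scale)
  backbone <- backbone_weights(parc, manifest)
  set.seed(seed)
  ages <- runif(n, manifest$control_age_range[1], manifest$control_age_range[2])
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  scans <- data.frame(subject_id = sprintf("ctrl-%03d", seq_len(n)),
                      group = "control", timepoint = "control",
                      age_at_scan = ages, sex = sexes,
                      histopathology = NA_character_, seizure_free = NA,
                      affected_lobe = NA_character_,
                      affected_hemisphere = NA_character_,
                      stringsAsFactors = FALSE)
  connectomes <- list()
  for (i in seq_len(n)) {
    s_scalar <- rnorm(1, 0, manifest$sigma_subject)
    s_edge <- new_subject_edge_log(nrow(parc), manifest)
    w <- simulate_scan_matrix(backbone, manifest, ages[i], sexes[i],
                              s_scalar, s_edge)
    connectomes[[paste(scans$subject_id[i], "control", sep = "|")]] <-
      connectome(w, parcel_ids = parc$parcel_id, scale = scale,
                 subject_id = scans$subject_id[i], timepoint = "control")
  }
  new_cohort(scans, connectomes, parc, scale)
}

#' Specify an injectable ground-truth effect
#'
#' Effects act multiplicatively on edge weights of the targeted structure,
#' scaled so that `magnitude` is approximately in units of the
#' between-subject (control) SD of the targeted feature: the multiplier is
#' `exp(magnitude * sigma_subject)`, and `sigma_subject` is the dominant
#' source of between-subject variation for aggregate weight features.
#'
#' @param target One of `"global_strength"`, `"nodal_strength_subset"`,
#'   `"participation_structure"`, `"thalamocortical_lobe"`,
#'   `"thalamic_modal"`.
#' @param magnitude Effect size in approximate control-SD units.
#' @param selector Target selector: parcel ids for
#'   `nodal_strength_subset`/`participation_structure`, a
#'   `c(hemisphere, lobe)` pair for `thalamocortical_lobe`, a hemisphere
#'   (`"left"`/`"right"`/`"both"`) for `thalamic_modal`; ignored for
#'   `global_strength`.
#' @param apply_to `"late_only"` (default) or `"both"` scans.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(target = c("global_strength", "nodal_strength_subset",
                                   "participation_structure",
                                   "thalamocortical_lobe", "thalamic_modal"),
                        magnitude, selector = NULL,
                        apply_to = c("late_only", "both")) {
  target <- match.arg(target)
  apply_to <- match.arg(apply_to)
  if (!is.finite(magnitude)) stop("magnitude must be finite", call. = FALSE)
  structure(list(target = target, magnitude = magnitude,
                 selector = selector, apply_to = apply_to),
            class = "effect_spec")
}

apply_effect <- function(w, eff, parcellation, manifest) {
  f <- exp(eff$magnitude * manifest$sigma_subject)
  idx_of <- function(ids) {
    idx <- match(ids, parcellation$parcel_id)
    if (any(is.na(idx)))
      stop("effect selector names unknown parcels: ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  }
  switch(eff$target,
    global_strength = w * f,
    nodal_strength_subset = {
      idx <- idx_of(eff$selector)
      w[idx, ] <- w[idx, ] * f
      w[, idx] <- w[, idx] * f
      w[idx, idx] <- w[idx, idx] / f  # undo the double scaling inside the set
      w
    },
    participation_structure = {
      # Inflate the targeted parcels' out-of-lobe connections, raising
      # their participation coefficient without (much) changing others.
      idx <- idx_of(eff$selector)
      same_lobe <- outer(parcellation$lobe, parcellation$lobe, "==")
      same_lobe[is.na(same_lobe)] <- FALSE
      mask <- matrix(FALSE, nrow(w), ncol(w))
      mask[idx, ] <- TRUE; mask[, idx] <- TRUE
      mask <- mask & !same_lobe
      w[mask] <- w[mask] * f
      w
    },
    thalamocortical_lobe = {
      h <- eff$selector[[1]]; l <- eff$selector[[2]]
      thal <- which(parcellation$structure_class == "thalamic" &
                      parcellation$hemisphere == h)
      ctx <- which(parcellation$structure_class == "cortical" &
                     parcellation$hemisphere == h & parcellation$lobe == l)
      if (!length(thal) || !length(ctx))
        stop("effect selector resolves to no thalamocortical edges",
             call. = FALSE)
      w[thal, ctx] <- w[thal, ctx] * f
      w[ctx, thal] <- w[ctx, thal] * f
      w
    },
    thalamic_modal = {
      h <- if (is.null(eff$selector)) "both" else eff$selector
      thal <- which(parcellation$structure_class == "thalamic" &
                      (h == "both" | parcellation$hemisphere == h))
      if (!length(thal)) stop("no thalamic parcels selected", call. = FALSE)
      w[thal, ] <- w[thal, ] * f
      w[, thal] <- w[, thal] * f
      w[thal, thal] <- w[thal, thal] / f
      w
    })
}

#' Generate paired early/late patient scans
#'
#' Each patient gets an early scan drawn from the control-generating
#' process at an early-scan age, and a late scan after a log-normal
#' inter-scan interval. The two scans share the subject's global scaling
#' and per-edge effects; independent scan-level noise differentiates them.
#' Injected effects from `effects` are applied to the late scan (or both),
#' and each patient is assigned an affected lobe, histopathology label and
#' seizure-freedom outcome.
#'
#' @param n Number of patients (>= 5).
#' @param scale Parcellation scale.
#' @param seed Integer seed.
#' @param manifest A [simulation_manifest()].
#' @param effects List of [effect_spec()] objects.
#' @return A `cohort` of `n` patients (two scans each) with a
#'   `ground_truth` attribute recording the injected effects.
#' @export
generate_patient_pairs <- function(n = 23L, scale = 3L, seed = 1L,
                                   manifest = simulation_manifest(),
                                   effects = list()) {
  if (n < 5L) stop("need at least 5 patients", call. = FALSE)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  parc <- make_parcellation(scale)
  backbone <- backbone_weights(parc, manifest)
  set.seed(seed + 1L)
  age_e <- runif(n, manifest$patient_age_range[1], manifest$patient_age_range[2])
  interval <- rlnorm(n, manifest$interval_meanlog, manifest$interval_sdlog)
  age_l <- age_e + interval
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  lobes <- sample(.lobe_taxonomy_default, n, replace = TRUE)
  hemis <- sample(c("left", "right"), n, replace = TRUE)
  histo <- sample(c("FCD", "tumour", "other"), n, replace = TRUE,
                  prob = c(0.45, 0.35, 0.2))
  szfree <- rbinom(n, 1, 0.6) == 1
  ids <- sprintf("pat-%03d", seq_len(n))
  scans <- rbind(
    data.frame(subject_id = ids, group = "patient", timepoint = "early",
               age_at_scan = age_e, sex = sexes, histopathology = histo,
               seizure_free = szfree, affected_lobe = lobes,
               affected_hemisphere = hemis, stringsAsFactors = FALSE),
    data.frame(subject_id = ids, group = "patient", timepoint = "late",
               age_at_scan = age_l, sex = sexes, histopathology = histo,
               seizure_free = szfree, affected_lobe = lobes,
               affected_hemisphere = hemis, stringsAsFactors = FALSE))
  connectomes <- list()
  for (i in seq_len(n)) {
    s_scalar <- rnorm(1, 0, manifest$sigma_subject)
    s_edge <- new_subject_edge_log(nrow(parc), manifest)
    for (tp in c("early", "late")) {
      age <- if (tp == "early") age_e[i] else age_l[i]
      w <- simulate_scan_matrix(backbone, manifest, age, sexes[i],
                                s_scalar, s_edge)
      for (eff in effects)
        if (eff$apply_to == "both" || tp == "late")
          w <- apply_effect(w, eff, parc, manifest)
      connectomes[[paste(ids[i], tp, sep = "|")]] <-
        connectome(w, parcel_ids = parc$parcel_id, scale = scale,
                   subject_id = ids[i], timepoint = tp)
    }
  }
  cohort <- new_cohort(scans, connectomes, parc, scale)
  attr(cohort, "ground_truth") <- list(seed = seed, effects = effects,
                                       manifest = manifest)
  cohort
}

#' Merge control and patient cohorts at the same scale
#'
#' @param controls,patients `cohort` objects sharing a parcellation.
#' @return A combined `cohort`; the patients' `ground_truth` attribute is
#'   carried over.
#' @export
combine_cohorts <- function(controls, patients) {
  stopifnot(controls$scale == patients$scale,
            identical(controls$parcellation$parcel_id,
                      patients$parcellation$parcel_id))
  out <- new_cohort(rbind(controls$scans, patients$scans),
                    c(controls$connectomes, patients$connectomes),
                    controls$parcellation, controls$scale)
  attr(out, "ground_truth") <- attr(patients, "ground_truth")
  out
}

#' Generate a complete synthetic study cohort
#'
#' Convenience wrapper: controls plus patient pairs at one scale, under a
#' single seed.
#'
#' @inheritParams generate_patient_pairs
#' @param manifest A [simulation_manifest()] (its `n_controls`/`n_patients`
#'   set the cohort sizes).
#' @return A combined `cohort`.
#' @export
generate_study_cohort <- function(scale = 3L, seed = 1L,
                                  manifest = simulation_manifest(),
                                  effects = list()) {
  combine_cohorts(
    generate_control_cohort(manifest$n_controls, scale, seed, manifest),
    generate_patient_pairs(manifest$n_patients, scale, seed + 1000L,
                           manifest, effects))
}

#' Write a small complete fixture suite to disk
#'
#' Emits, per requested scale, the parcellation TSV and dense-text matrix
#' files plus a shared cohort metadata TSV, together with a ground-truth
#' JSON listing the injected effects — everything [read_cohort()] needs
#' for an end-to-end run.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_controls,n_patients Fixture sizes (kept deliberately small).
#' @param scales Scales to emit.
#' @param effects List of [effect_spec()] objects applied to patients.
#' @return Invisible list of written paths.
#' @export
write_fixture_suite <- function(out_dir, seed = 1L, n_controls = 12L,
                                n_patients = 6L, scales = c(1L, 3L),
                                effects = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- simulation_manifest(n_controls = n_controls,
                                  n_patients = n_patients)
  written <- character()
  for (sc in scales) {
    cohort <- generate_study_cohort(scale = sc, seed = seed,
                                    manifest = manifest, effects = effects)
    write_cohort(cohort, out_dir)
    written <- c(written, sprintf("parcellation_scale%d.tsv", sc))
  }
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = seed, n_controls = n_controls, n_patients = n_patients,
         scales = scales,
         effects = lapply(effects, function(e)
           list(target = e$target, magnitude = e$magnitude,
                selector = e$selector, apply_to = e$apply_to))),
    gt_path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(list(dir = out_dir, ground_truth = gt_path,
                 metadata = file.path(out_dir, "cohort.tsv")))
}
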