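test_that("generated cohorts are deterministic given the seed", {
  man <- simulation_manifest(n_controls = 10, n_patients = 5)
  a <- generate_study_cohort(scale = 1, seed = 5, manifest = man)
  b <- generate_study_cohort(scale = 1, seed = 5, manifest = man)
  expect_identical(a$scans, b$scans)
  for (k in names(a$connectomes))
    expect_identical(a$connectomes[[k]]$matrix, b$connectomes[[k]]$matrix)
  c2 <- generate_study_cohort(scale = 1, seed = 6, manifest = man)
  expect_false(identical(a$connectomes[[1]]$matrix,
                         c2$connectomes[[1]]$matrix))
})

test_that("every generated matrix satisfies the connectome invariants", {
  co <- generate_study_cohort(scale = 2, seed = 7,
                              manifest = simulation_manifest(n_controls = 10,
                                                             n_patients = 5))
  for (cn in co$connectomes) expect_silent(validate_connectome(cn))
  parc <- co$parcellation
  expect_equal(nrow(parc), nrow(co$connectomes[[1]]$matrix))
})

test_that("synthetic parcellations satisfy the atlas invariants at all scales", {
  for (s in 1:5) {
    parc <- make_parcellation(s)
    expect_s3_class(parc, "parcellation")
    expect_equal(sum(parc$structure_class == "thalamic"), 14)
    expect_equal(sum(parc$structure_class == "hippocampal"), 6)
  }
  expect_gt(nrow(make_parcellation(5)), nrow(make_parcellation(1)))
})

test_that("interval distribution has the configured median near 1.15 y", {
  man <- simulation_manifest(n_controls = 10, n_patients = 500)
  co <- generate_patient_pairs(500, 1, seed = 9, manifest = man)
  e <- co$scans[co$scans$timepoint == "early", "age_at_scan"]
  l <- co$scans[co$scans$timepoint == "late", "age_at_scan"]
  expect_equal(median(l - e), 1.15, tolerance = 0.1)
})

test_that("generative age effect is recovered by the normative fit", {
  man <- simulation_manifest(n_controls = 60, n_patients = 5,
                             beta_age = 0.03)
  co <- generate_control_cohort(60, 1, seed = 13, manifest = man)
  md <- sapply(names(co$connectomes),
               function(k) mean_degree(co$connectomes[[k]]))
  fit <- lm(log(md) ~ co$scans$age_at_scan)
  expect_lt(abs(unname(coef(fit)[2]) - 0.03), 0.015)
  # and a zero age coefficient stays near zero
  man0 <- simulation_manifest(n_controls = 60, n_patients = 5, beta_age = 0)
  co0 <- generate_control_cohort(60, 1, seed = 13, manifest = man0)
  md0 <- sapply(names(co0$connectomes),
                function(k) mean_degree(co0$connectomes[[k]]))
  fit0 <- summary(lm(log(md0) ~ co0$scans$age_at_scan))
  expect_lt(abs(fit0$coefficients[2, 1]), 3 * fit0$coefficients[2, 2])
})

test_that("injected effects land on their targets", {
  man <- simulation_manifest(n_controls = 10, n_patients = 5)
  parc <- make_parcellation(1)
  base <- generate_patient_pairs(5, 1, seed = 17, manifest = man)
  # global strength: late matrices scaled by exp(m * sigma_subject)
  up <- generate_patient_pairs(5, 1, seed = 17, manifest = man,
                               effects = list(effect_spec("global_strength", 1)))
  f <- exp(1 * man$sigma_subject)
  expect_equal(up$connectomes[["pat-001|late"]]$matrix,
               base$connectomes[["pat-001|late"]]$matrix * f)
  expect_equal(up$connectomes[["pat-001|early"]]$matrix,
               base$connectomes[["pat-001|early"]]$matrix)
  # thalamocortical effect confined to the targeted ipsilateral lobe
  tl <- generate_patient_pairs(5, 1, seed = 17, manifest = man,
                               effects = list(effect_spec(
                                 "thalamocortical_lobe", 2,
                                 selector = c("left", "temporal"))))
  p_base <- thalamocortical_connectivity(base$connectomes[["pat-002|late"]],
                                         parc)
  p_eff <- thalamocortical_connectivity(tl$connectomes[["pat-002|late"]],
                                        parc)
  hit <- p_eff$hemisphere == "left" & p_eff$lobe == "temporal"
  expect_equal(p_eff$streamline_sum[hit],
               p_base$streamline_sum[hit] * exp(2 * man$sigma_subject))
  expect_equal(p_eff$streamline_sum[!hit], p_base$streamline_sum[!hit])
  # nodal subset: targeted rows scale, internal edges scale once
  sel <- parc$parcel_id[1:3]
  ns <- generate_patient_pairs(5, 1, seed = 17, manifest = man,
                               effects = list(effect_spec(
                                 "nodal_strength_subset", 1, selector = sel)))
  wb <- base$connectomes[["pat-003|late"]]$matrix
  we <- ns$connectomes[["pat-003|late"]]$matrix
  expect_equal(we[1, 5], wb[1, 5] * f)
  expect_equal(we[1, 2], wb[1, 2] * f)
  expect_equal(we[5, 6], wb[5, 6])
  expect_error(generate_patient_pairs(5, 1, seed = 17, manifest = man,
                                      effects = list(effect_spec(
                                        "nodal_strength_subset", 1,
                                        selector = "nope"))),
               "unknown parcels")
})

test_that("thalamic_modal effect shifts targeted hemisphere Z only", {
  man <- simulation_manifest(n_controls = 30, n_patients = 8)
  ctrl <- generate_control_cohort(30, 1, seed = 19, manifest = man)
  pats <- generate_patient_pairs(8, 1, seed = 20, manifest = man,
                                 effects = list(effect_spec(
                                   "thalamic_modal", 3, selector = "left")))
  co <- combine_cohorts(ctrl, pats)
  tz <- thalamic_modal_z(co)
  late <- tz[tz$timepoint == "late", ]
  early <- tz[tz$timepoint == "early", ]
  d_left <- mean(late$z[grepl("-lh-", late$parcel_id)]) -
    mean(early$z[grepl("-lh-", early$parcel_id)])
  d_right <- mean(late$z[grepl("-rh-", late$parcel_id)]) -
    mean(early$z[grepl("-rh-", early$parcel_id)])
  expect_gt(abs(d_left), abs(d_right) + 0.5)
})

test_that("fixture suite round-trips and records its ground truth", {
  dir <- withr::local_tempdir()
  eff <- list(effect_spec("global_strength", 0.5))
  out <- write_fixture_suite(dir, seed = 3, n_controls = 10, n_patients = 5,
                             scales = 1, effects = eff)
  parc <- read_parcellation(file.path(dir, "parcellation_scale1.tsv"), 1)
  co <- read_cohort(out$metadata, dir, 1, parc, quiet = TRUE)
  expect_equal(length(co$connectomes), 10 + 10)
  gt <- jsonlite::read_json(out$ground_truth)
  expect_equal(gt$effects[[1]]$target, "global_strength")
  expect_equal(gt$effects[[1]]$magnitude, 0.5)
})
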