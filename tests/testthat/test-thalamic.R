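test_that("lobe sums on constructed block fixtures are exact", {
  parc <- make_parcellation(1)
  n <- nrow(parc)
  # all-zero matrix: all ten sums zero
  prof0 <- thalamocortical_connectivity(matrix(0, n, n), parc)
  expect_equal(nrow(prof0), 10)
  expect_equal(prof0$streamline_sum, rep(0, 10))
  # left thalamus -> left frontal total 42, everything else 0
  w <- matrix(0, n, n)
  thal_l <- which(parc$structure_class == "thalamic" &
                    parc$hemisphere == "left")
  front_l <- which(parc$structure_class == "cortical" &
                     parc$hemisphere == "left" & parc$lobe == "frontal")
  w[thal_l[1], front_l[1]] <- w[front_l[1], thal_l[1]] <- 30
  w[thal_l[2], front_l[2]] <- w[front_l[2], thal_l[2]] <- 12
  prof <- thalamocortical_connectivity(w, parc)
  expect_equal(prof$streamline_sum[prof$hemisphere == "left" &
                                     prof$lobe == "frontal"], 42)
  expect_equal(sum(prof$streamline_sum), 42)
})

test_that("contralateral edges never contribute to lobe sums", {
  parc <- make_parcellation(1)
  n <- nrow(parc)
  w <- matrix(0, n, n)
  thal_l <- which(parc$structure_class == "thalamic" &
                    parc$hemisphere == "left")
  ctx_r <- which(parc$structure_class == "cortical" &
                   parc$hemisphere == "right")
  w[thal_l, ctx_r] <- 5
  w[ctx_r, thal_l] <- 5
  prof <- thalamocortical_connectivity(w, parc)
  expect_equal(prof$streamline_sum, rep(0, 10))
})

test_that("lobe sums match an exhaustive pair loop and total correctly", {
  parc <- make_parcellation(1)
  set.seed(41)
  co <- generate_control_cohort(10, 1, seed = 41,
                                manifest = simulation_manifest())
  w <- co$connectomes[[1]]$matrix
  prof <- thalamocortical_connectivity(w, parc)
  total <- 0
  for (r in seq_len(nrow(prof))) {
    h <- prof$hemisphere[r]; l <- prof$lobe[r]
    s <- 0
    for (i in which(parc$structure_class == "thalamic" &
                      parc$hemisphere == h))
      for (j in which(parc$structure_class == "cortical" &
                        parc$hemisphere == h & parc$lobe == l))
        s <- s + w[i, j]
    expect_equal(prof$streamline_sum[r], s)
    total <- total + s
  }
  expect_equal(sum(prof$streamline_sum), total)
})

test_that("z-of-z standardizes within patient and is affine invariant", {
  keys <- as.vector(outer(c("frontal", "temporal", "parietal", "occipital",
                            "insular-cingulate"), c("left", "right"),
                          function(l, h) paste(h, l, sep = ":")))
  dz <- setNames(c(3, rep(0, 9)), keys)
  # direct arithmetic: (3 - 0.3) / sd(dz)
  expect_equal(affected_lobe_z_of_z(dz, "left", "frontal"),
               (3 - 0.3) / sd(dz))
  # affected lobe equal to the mean -> 0
  dz2 <- setNames(c(0.5, rnorm(9)), keys)
  dz2[1] <- mean(dz2[2:10])  # then dz2[1] equals the mean of all ten
  expect_equal(affected_lobe_z_of_z(dz2, "left", "frontal"), 0,
               tolerance = 1e-12)
  # affine invariance
  set.seed(43)
  dz3 <- setNames(rnorm(10), keys)
  expect_equal(affected_lobe_z_of_z(dz3, "right", "parietal"),
               affected_lobe_z_of_z(5 + 2.5 * dz3, "right", "parietal"))
  # degenerate spread
  expect_warning(out <- affected_lobe_z_of_z(setNames(rep(1, 10), keys),
                                             "left", "frontal"),
                 "zero spread")
  expect_true(is.na(out))
  expect_error(affected_lobe_z_of_z(dz3[1:9], "left", "frontal"), "10")
})

test_that("lobe_z_changes composes Z-scoring of the two scans", {
  set.seed(47)
  n <- 40
  ages <- runif(n, 6, 18)
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  keys <- as.vector(outer(c("frontal", "temporal", "parietal", "occipital",
                            "insular-cingulate"), c("left", "right"),
                          function(l, h) paste(h, l, sep = ":")))
  y <- sapply(keys, function(k) 100 + 3 * ages + rnorm(n, 0, 5))
  m <- fit_normative_model(y, ages, sexes)
  prof <- function(vals) data.frame(
    hemisphere = sub(":.*", "", keys), lobe = sub(".*:", "", keys),
    streamline_sum = vals, stringsAsFactors = FALSE)
  v_early <- 100 + 3 * 10 + rnorm(10, 0, 5)
  v_late <- v_early
  v_late[3] <- v_late[3] + 2 * m$residual_sd[3]  # +2 SD on one lobe
  ch <- lobe_z_changes(prof(v_early), prof(v_late), m,
                       age_early = 10, age_late = 10, sex = "female")
  expect_equal(ch$dz[3], 2, tolerance = 1e-10)
  expect_equal(ch$dz[-3], rep(0, 9), tolerance = 1e-10)
  # identical profiles give all-zero change at equal ages
  ch0 <- lobe_z_changes(prof(v_early), prof(v_early), m, 10, 10, "female")
  expect_equal(ch0$dz, rep(0, 10))
})

test_that("thalamic modal Z table has 14 rows per patient timepoint", {
  man <- simulation_manifest(n_controls = 15, n_patients = 5)
  co <- generate_study_cohort(scale = 1, seed = 53, manifest = man)
  tz <- thalamic_modal_z(co)
  expect_equal(nrow(tz), 5 * 2 * 14)
  one <- tz[tz$subject_id == "pat-001" & tz$timepoint == "early", ]
  expect_equal(nrow(one), 14)
  expect_equal(sum(grepl("^thal-lh", one$parcel_id)), 7)
  expect_equal(sum(grepl("^thal-rh", one$parcel_id)), 7)
})
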