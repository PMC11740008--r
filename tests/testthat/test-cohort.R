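# Generator tests use a coarse 4 mm grid (same mm geometry) for speed.
gen_cfg <- function(seed = 91, n = 12, ...) {
  cohort_config(n_patients = n, shape = c(60L, 48L, 50L), spacing = c(4, 4, 4),
                seed = seed, ...)
}

test_that("patient generation is deterministic and anatomically valid", {
  cfg <- gen_cfg()
  a <- generate_patient(cfg, 2001)
  b <- generate_patient(cfg, 2001)
  expect_identical(a$planning$structures, b$planning$structures)
  expect_identical(a$truth$displacement, b$truth$displacement)
  for (f in seq_along(a$fractions)) {
    expect_identical(a$fractions[[f]]$structures, b$fractions[[f]]$structures)
  }
  # required structures, shared grid, CTV never in the rectum
  required <- c("CTV", "BladderNeck", "Bladder", "Rectum",
                "FemHeadL", "FemHeadR", "Body")
  for (ss in c(list(a$planning), a$fractions)) {
    expect_true(all(required %in% names(ss$structures)))
    expect_false(any(ss$structures$CTV & ss$structures$Rectum))
    expect_false(any(ss$structures$CTV & ss$structures$Bladder))
    expect_false(any(ss$structures$BladderNeck & ss$structures$Bladder))
    for (m in ss$structures) expect_identical(dim(m), ss$grid$shape)
  }
  # femoral geometry is shared between planning and fractions
  expect_identical(a$planning$structures$FemHeadL, a$fractions[[3]]$structures$FemHeadL)
})

test_that("zero motion scale freezes the fraction anatomies", {
  cfg <- gen_cfg(motion_scale = 0)
  pat <- generate_patient(cfg, 2002)
  com0 <- center_of_mass(get_structure(pat$planning, "CTV"))
  for (fr in pat$fractions) {
    expect_equal(center_of_mass(get_structure(fr, "CTV")), com0)
  }
  expect_true(all(pat$truth$displacement == 0))
})

test_that("COM shifts respect the calibration band", {
  cfg <- gen_cfg(seed = 93, n = 20)
  shifts <- c()
  maxpairs <- c()
  for (i in 1:20) {
    pat <- generate_patient(cfg, protontwin:::patient_seed_for(cfg, i))
    com0 <- center_of_mass(get_structure(pat$planning, "CTV"))
    d <- vapply(pat$fractions, function(fr)
      com_distance(com0, center_of_mass(get_structure(fr, "CTV"))), 0)
    shifts <- c(shifts, d)
    pd <- as.matrix(dist(pat$truth$displacement))
    maxpairs <- c(maxpairs, max(pd))
  }
  expect_gte(length(shifts), 100)
  # planning-to-fraction COM shifts span (a subset of) the configured band;
  # realized shifts are voxel-quantized, so allow half a voxel diagonal of
  # slack around the continuous-draw band
  slack <- sqrt(sum(cfg$spacing^2)) / 2
  expect_true(all(shifts >= cfg$com_band[1] - slack))
  expect_true(all(shifts <= cfg$com_band[2] + slack))
  expect_true(all(maxpairs >= cfg$com_band[1] - 2 * slack &
                    maxpairs <= cfg$com_band[2] + 2 * slack))
})

test_that("cohort assembly splits patients and seeds them independently", {
  cfg <- gen_cfg(seed = 94, n = 13)
  cohort <- generate_cohort(cfg)
  expect_length(cohort$ids, 13)
  expect_length(intersect(cohort$train_ids, cohort$test_ids), 0)
  expect_setequal(c(cohort$train_ids, cohort$test_ids), cohort$ids)
  expect_error(generate_cohort(gen_cfg(n = 11)), "n >= 12")

  # per-patient seeding: patient i's anatomy does not depend on cohort size
  cfg2 <- gen_cfg(seed = 94, n = 12)
  p_small <- generate_patient(cfg2, protontwin:::patient_seed_for(cfg2, 3))
  p_large <- generate_patient(cfg, protontwin:::patient_seed_for(cfg, 3))
  expect_identical(p_small$planning$structures$CTV,
                   p_large$planning$structures$CTV)

  # materialization reproduces the cohort rows
  id <- cohort$train_ids[1]
  pat <- materialize_patient(cohort, id)
  f_direct <- extract_features(pat$planning)
  row <- cohort$pairs[cohort$pairs$patient == id &
                        cohort$pairs$src_idx == 0, ][1, ]
  expect_equal(as.numeric(row[paste0("f", 1:7)]), unname(f_direct))
})

test_that("training tables slice the requested pair structure", {
  cohort <- generate_cohort(gen_cfg(seed = 95, n = 12))
  k <- cohort$config$n_fractions
  seqt <- training_table(cohort, "train", mode = "sequential")
  expect_true(all(seqt$rows$tgt_idx == seqt$rows$src_idx + 1))
  expect_equal(nrow(seqt$X), length(cohort$train_ids) * k)
  plant <- training_table(cohort, "test", mode = "planning")
  expect_true(all(plant$rows$planning_image == "pCT"))
  expect_equal(nrow(plant$X), length(cohort$test_ids) * k)
  allt <- training_table(cohort, "all", mode = "all")
  expect_equal(nrow(allt$X), length(cohort$ids) * choose(k + 1, 2))
})

test_that("the generated displacement signal is recoverable by the margin model", {
  # coarse-grid miniature of the recovery study: train on 15 patients,
  # require the fit to beat the predict-the-mean baseline on held-out patients
  cohort <- generate_cohort(gen_cfg(seed = 96, n = 25))
  tr <- training_table(cohort, "train", mode = "planning")
  te <- training_table(cohort, "test", mode = "planning")
  model <- fit_gpr(tr$X, tr$Y, seed = 2)
  pr <- predict_with_uncertainty(model, te$X)
  err <- pr$mu - te$Y
  base <- sweep(te$Y, 2, colMeans(tr$Y))
  expect_true(all(sqrt(colMeans(err^2)) < sqrt(colMeans(base^2))))
})
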