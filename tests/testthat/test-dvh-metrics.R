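test_that("DVH V and D follow the sorted-voxel convention", {
  g <- voxel_grid(c(10L, 1L, 1L), c(10, 10, 10))  # 1 cc voxels
  mask <- array(TRUE, g$shape)
  s <- structure_mask("s", mask, g)
  dose <- array(as.numeric(1:10), g$shape)
  expect_equal(dvh_metric(dose, s, list(type = "D", volume = 50, unit = "%")), 6)
  expect_equal(dvh_metric(dose, s, list(type = "V", threshold = 7, unit = "%")), 40)
  expect_equal(dvh_metric(dose, s, list(type = "Dmean")), 5.5)
  # uniform field
  u <- array(26, g$shape)
  expect_equal(dvh_metric(u, s, list(type = "V", threshold = 26, unit = "%")), 100)
  expect_equal(dvh_metric(u, s, list(type = "D", volume = 98, unit = "%")), 26)
  # threshold above the maximum
  expect_equal(dvh_metric(dose, s, list(type = "V", threshold = 11, unit = "cc")), 0)
  expect_error(dvh_metric(dose, s, list(type = "D", volume = 20, unit = "cc")),
               "exceeds")
  empty <- structure_mask("e", array(FALSE, g$shape), g)
  expect_error(dvh_metric(dose, empty, list(type = "Dmean")), "empty")
})

test_that("DVH monotonicity and oracle equivalence on random dose grids", {
  set.seed(31)
  for (rep in 1:4) {
    g <- voxel_grid(c(12L, 12L, 12L), c(2, 2, 2))
    mask <- array(runif(prod(g$shape)) < 0.4, g$shape)
    mask[1, 1, 1] <- TRUE
    s <- structure_mask("s", mask, g)
    dose <- array(runif(prod(g$shape), 0, 30), g$shape)
    vv <- voxel_volume_cc(g)
    doses <- dose[mask]
    # V monotone decreasing in the threshold, D decreasing in the volume
    thr <- sort(runif(5, 0, 30))
    Vs <- vapply(thr, function(t)
      dvh_metric(dose, s, list(type = "V", threshold = t, unit = "cc")), 0)
    expect_true(all(diff(Vs) <= 1e-12))
    vols <- sort(runif(5, 1, 99))
    Ds <- vapply(vols, function(v)
      dvh_metric(dose, s, list(type = "D", volume = v, unit = "%")), 0)
    expect_true(all(diff(Ds) <= 1e-12))
    # oracle equivalence
    for (t in thr) {
      expect_equal(dvh_metric(dose, s, list(type = "V", threshold = t, unit = "cc")),
                   oracle_dvh_V(doses, vv, t))
    }
    for (v in vols) {
      expect_equal(dvh_metric(dose, s, list(type = "D", volume = v, unit = "%")),
                   oracle_dvh_D(doses, vv, v / 100 * sum(mask) * vv))
    }
    expect_gte(dvh_metric(dose, s, list(type = "Dmean")), min(doses))
    expect_lte(dvh_metric(dose, s, list(type = "Dmean")), max(doses))
  }
})

test_that("near-maximum D0.03cc accumulates the hottest volume", {
  # voxel volume 0.01 cc
  g <- voxel_grid(c(4L, 1L, 1L), c(10, 10, 0.1))
  s <- structure_mask("s", array(TRUE, g$shape), g)
  dose <- array(c(30, 29, 28, 27), g$shape)
  expect_equal(d003cc(dose, s), 28)  # third voxel completes 0.03 cc
  expect_equal(d003cc(array(5, g$shape), s), 5)
  # hottest voxel alone holds 0.03 cc
  g2 <- voxel_grid(c(4L, 1L, 1L), c(10, 10, 10))
  s2 <- structure_mask("s", array(TRUE, g2$shape), g2)
  expect_equal(d003cc(array(c(30, 29, 28, 27), g2$shape), s2), 30)
  # structure smaller than 0.03 cc
  g3 <- voxel_grid(c(2L, 1L, 1L), c(1, 1, 1))
  s3 <- structure_mask("s", array(TRUE, g3$shape), g3)
  expect_error(d003cc(array(1, g3$shape), s3), "0.03")
})

test_that("D2cm finds the hottest body voxel beyond 20 mm from V", {
  ss <- mini_patient_ss()
  v <- evaluation_volume(ss)
  body <- get_structure(ss, "Body")
  # zero dose outside V
  d0 <- array(0, ss$grid$shape); d0[v$mask] <- 26
  expect_equal(d2cm(d0, v, body, 26), 0)
  # uniform prescription everywhere
  expect_equal(d2cm(array(26, ss$grid$shape), v, body, 26), 100)
  # radial profile oracle: dose = f(distance from V)
  dist <- distance_map_mm(v)
  prof <- 26 * exp(-dist / 10)
  sel <- body$mask & dist >= 20 - 1e-9
  expect_equal(d2cm(prof, v, body, 26), 100 * max(prof[sel]) / 26)
  # grid too small: body restricted to within 20 mm
  near_body <- structure_mask("Body", dist < 10, ss$grid)
  expect_error(d2cm(prof, v, near_body, 26), "grid too small")
})

test_that("Paddick conformity index closed forms", {
  g <- tiny_grid(c(16L, 16L, 16L), c(2, 2, 2))
  tv <- box_mask(g, c(-6, -6, -6), c(6, 6, 6))
  target <- structure_mask("CTV", tv, g)
  # prescription isodose exactly the target
  dose <- array(0, g$shape); dose[tv] <- 26
  expect_equal(pci(target, dose, 26), 1)
  # isodose twice the target volume, fully covering it
  n_tv <- sum(tv)
  big <- tv
  extra <- which(!tv)[seq_len(n_tv)]
  big[extra] <- TRUE
  dose2 <- array(0, g$shape); dose2[big] <- 26
  expect_equal(pci(target, dose2, 26), 0.5)
  # disjoint isodose
  dose3 <- array(0, g$shape); dose3[extra] <- 26
  expect_equal(pci(target, dose3, 26), 0)
  # nothing reaches prescription
  expect_equal(pci(target, array(1, g$shape), 26), 0)
  expect_error(pci(structure_mask("e", array(FALSE, g$shape), g), dose, 26),
               "empty")
})

test_that("metric bundle composes from individual metric calls", {
  ss <- mini_patient_ss()
  plan <- optimize_plan_surrogate(ss, margin_set(3), rx = 26)
  mb <- metric_bundle(plan, ss, "2STAR")
  dose <- plan$dose
  expect_equal(mb$ctv_v100,
               dvh_metric(dose, get_structure(ss, "CTV"),
                          list(type = "V", threshold = 26, unit = "%")))
  expect_equal(mb$bladder_v14_6,
               dvh_metric(dose, get_structure(ss, "Bladder"),
                          list(type = "V", threshold = 14.6, unit = "cc")))
  expect_equal(mb$bladderneck_dmean,
               dvh_metric(dose, get_structure(ss, "BladderNeck"),
                          list(type = "Dmean")))
  expect_equal(mb$pci, pci(get_structure(ss, "CTV"), dose, 26))
  expect_equal(mb$body_d003cc_gy, d003cc(dose, get_structure(ss, "Body")))
  # the high-dose rectum metric switches name with the trial
  expect_true("rectum_v20_8" %in% names(mb))
  expect_false("rectum_v22" %in% names(mb))
  # 2SMART needs a urethra structure
  expect_error(metric_bundle(plan, ss, "2SMART"), "Urethra")
})
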