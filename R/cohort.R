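# Synthetic pelvic cohort: analytic structures (ellipsoids, spheres, capped
# tubes) rasterized on a regular grid, with a per-patient linear-Gaussian
# interfractional motion model whose systematic component is a function of
# anatomy latents recoverable from the geometric features — so the
# margin-model stage has learnable signal and a known ground truth.

#' Cohort generator configuration
#'
#' Defaults define the study conditions: 2 mm isotropic grid over a
#' 240 x 192 x 200 mm pelvic field of view, CTV 30-50 cc, femoral head radius
#' 20-28 mm, bladder 150-260 cc with an inferior bladder-neck cap abutting the
#' CTV, a posterior rectal tube separated from the CTV by a 3-8 mm hydrogel
#' spacer gap, five fraction anatomies per patient, and per-patient
#' interfractional CTV displacement whose magnitude is calibrated to the
#' 2.1-13.2 mm planning-to-fraction COM-shift range.
#'
#' @param n_patients cohort size (>= 12 for [generate_cohort()]; default 40,
#'   giving 30 training patients / 150 planning-to-fraction training pairs
#'   and 10 demonstration patients).
#' @param shape,spacing grid definition (voxels; mm).
#' @param n_fractions fraction anatomies per patient (default 5).
#' @param motion_scale multiplier on the drawn displacements; 0 freezes all
#'   fraction anatomies at the planning anatomy (the COM band is then ignored).
#' @param com_band accepted planning-to-fraction COM-shift norm range in mm
#'   (rejection-sampled; `NULL` disables).
#' @param drift_gain per-axis gain turning the deviation of the planning-day
#'   relative CTV position from `drift_ref` into a systematic interfraction
#'   drift: patients whose prostate sits unusually relative to the bony
#'   anatomy drift more, which is exactly the signal the geometric features
#'   carry.
#' @param drift_ref reference relative CTV position (mm) at which the
#'   systematic drift is zero.
#' @param offset_sd per-axis sd (mm) of the patient's systematic CTV offset
#'   (anatomy variation, part of what `drift_gain` acts on).
#' @param noise_sd per-axis sd (mm) of the per-fraction random motion at
#'   motion amplitude 1.
#' @param amp_range per-patient random motion amplitude range (uniform).
#' @param seed mandatory integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 40L,
                          shape = c(120L, 96L, 100L),
                          spacing = c(2, 2, 2),
                          n_fractions = 5L,
                          motion_scale = 1,
                          com_band = c(2.1, 13.2),
                          drift_gain = c(0.4, 0.6, 0.5),
                          drift_ref = c(-100, -14, 16),
                          offset_sd = c(3, 4, 4),
                          noise_sd = c(1.0, 1.5, 1.5),
                          amp_range = c(0.7, 1.6),
                          seed = 20260101L) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(n_patients >= 1L, n_fractions >= 1L, motion_scale >= 0,
            all(spacing > 0), all(shape >= 1))
  structure(list(n_patients = as.integer(n_patients),
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_fractions = as.integer(n_fractions),
                 motion_scale = motion_scale, com_band = com_band,
                 drift_gain = drift_gain, drift_ref = drift_ref,
                 offset_sd = offset_sd,
                 noise_sd = noise_sd, amp_range = amp_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

raster_ellipsoid <- function(grid, center, semi) {
  u <- ((grid_axis(grid, 1) - center[1]) / semi[1])^2
  v <- ((grid_axis(grid, 2) - center[2]) / semi[2])^2
  w <- ((grid_axis(grid, 3) - center[3]) / semi[3])^2
  m <- outer(outer(u, v, "+"), w, "+") <= 1
  m
}

raster_sphere <- function(grid, center, radius) {
  raster_ellipsoid(grid, center, rep(radius, 3))
}

# Tube along z: circular cross-section of radius r, z in [z1, z2].
raster_ztube <- function(grid, cx, cy, r, z1, z2) {
  circ <- outer(((grid_axis(grid, 1) - cx) / r)^2,
                ((grid_axis(grid, 2) - cy) / r)^2, "+") <= 1
  zsel <- grid_axis(grid, 3) >= z1 & grid_axis(grid, 3) <= z2
  outer(circ, zsel, "&")
}

# Elliptic cylinder along z (the body outline).
raster_body <- function(grid, cx, cy, ax, ay) {
  circ <- outer(((grid_axis(grid, 1) - cx) / ax)^2,
                ((grid_axis(grid, 2) - cy) / ay)^2, "+") <= 1
  outer(circ, rep(TRUE, grid$shape[3]), "&")
}

draw_anatomy <- function(cfg) {
  # femoral geometry; head radius co-varies with pelvic width (allometric
  # scaling of skeletal dimensions), with residual individual variation
  fem_sep <- runif(1, 150, 170)
  fem_r <- min(max(24 + 0.35 * (fem_sep - 160) + rnorm(1, 0, 0.5), 20), 28)
  fem_y <- runif(1, -4, 4)
  fem_z <- runif(1, -6, 6)
  # CTV ellipsoid, 30-50 cc by rejection
  repeat {
    semi <- c(runif(1, 21, 25), runif(1, 17, 21), runif(1, 19, 24))
    vol <- 4 / 3 * pi * prod(semi) / 1000
    if (vol >= 30 && vol <= 50) break
  }
  a_p <- pmax(pmin(rnorm(3, 0, cfg$offset_sd), 2 * cfg$offset_sd), -2 * cfg$offset_sd)
  ctv_c <- c(0, 12, -4) + a_p
  # bladder, 150-260 cc by rejection
  repeat {
    bsemi <- c(runif(1, 32, 44), runif(1, 28, 38), runif(1, 26, 34))
    bvol <- 4 / 3 * pi * prod(bsemi) / 1000
    if (bvol >= 150 && bvol <= 260) break
  }
  list(fem_sep = fem_sep, fem_r = fem_r, fem_y = fem_y, fem_z = fem_z,
       ctv_semi = semi, ctv_center = ctv_c, a_p = a_p,
       bladder_semi = bsemi,
       bn_r = runif(1, 7, 10),
       rect_r = runif(1, 10, 14),
       gap = runif(1, 3, 8),
       gtv_r = runif(1, 6, 9),
       gtv_off = c(runif(1, -5, 5), runif(1, -4, 4), runif(1, -5, 5)),
       amp = runif(1, cfg$amp_range[1], cfg$amp_range[2]))
}

rasterize_patient <- function(an, grid) {
  cc <- an$ctv_center
  ctv_ell <- raster_ellipsoid(grid, cc, an$ctv_semi)
  # urethra: thin tube through the gland exiting inferiorly; carved out of the
  # CTV (urethra-sparing convention)
  bn_center <- c(cc[1], cc[2] - 2, cc[3] + an$ctv_semi[3] + 2)
  urethra <- raster_ztube(grid, cc[1], cc[2], 3,
                          cc[3] - an$ctv_semi[3] - 12, bn_center[3])
  bn_sphere <- raster_sphere(grid, bn_center, an$bn_r)
  bl_center <- c(cc[1], cc[2] - 6, cc[3] + an$ctv_semi[3] + an$bladder_semi[3] - 4)
  bladder_ell <- raster_ellipsoid(grid, bl_center, an$bladder_semi)
  rect_cy <- cc[2] + an$ctv_semi[2] + an$gap + an$rect_r
  rectum <- raster_ztube(grid, cc[1], rect_cy, an$rect_r, cc[3] - 45, cc[3] + 45)
  list(
    ctv_ell = ctv_ell, urethra = urethra, bn_sphere = bn_sphere,
    bladder_ell = bladder_ell, rectum = rectum,
    femL = raster_sphere(grid, c(an$fem_sep / 2, an$fem_y, an$fem_z), an$fem_r),
    femR = raster_sphere(grid, c(-an$fem_sep / 2, an$fem_y, an$fem_z), an$fem_r),
    body = raster_body(grid, 0, 4, 114, 88),
    gtv = raster_sphere(grid, cc + an$gtv_off, an$gtv_r))
}

# Assemble disjoint structures for one anatomical state. The prostatic CTV and
# the bladder-neck cap may abut but never overlap; everything else is carved
# to be pairwise disjoint.
assemble_structures <- function(parts) {
  ctv <- parts$ctv_ell & !parts$urethra
  bn <- parts$bn_sphere & !parts$ctv_ell & !parts$urethra
  bladder <- parts$bladder_ell & !parts$bn_sphere & !parts$ctv_ell &
    !parts$urethra & !parts$rectum
  gtv <- parts$gtv & ctv
  list(CTV = ctv, GTV = gtv, Urethra = parts$urethra, BladderNeck = bn,
       Bladder = bladder, Rectum = parts$rectum,
       FemHeadL = parts$femL, FemHeadR = parts$femR, Body = parts$body)
}

#' Generate one synthetic pelvic patient
#'
#' Deterministic given `(cfg, patient_seed)`. The planning anatomy (pCT) and
#' `cfg$n_fractions` fraction anatomies share the femoral geometry; on each
#' fraction the prostatic block (CTV, GTV, urethra, bladder-neck cap) is
#' rigidly displaced by a draw from the patient's motion model, with bladder
#' carved around it so structures stay disjoint. Draws whose quantized COM
#' shift falls outside `cfg$com_band`, or that push the CTV into the rectum,
#' are rejected and redrawn (error after 100 attempts).
#'
#' @param cfg a [cohort_config()].
#' @param patient_seed integer seed for this patient.
#' @return A `synthetic_patient`: `patient_id`, `planning` (pCT
#'   [structure_set()]), `fractions` (list of CBCT structure sets), and
#'   `truth` (ground-truth displacements and latent variables).
#' @export
generate_patient <- function(cfg, patient_seed) {
  grid <- voxel_grid(cfg$shape, cfg$spacing)
  with_preserved_seed(patient_seed, {
    an <- parts <- structs <- NULL
    ok <- FALSE
    for (attempt in 1:100) {
      an <- draw_anatomy(cfg)
      parts <- rasterize_patient(an, grid)
      structs <- assemble_structures(parts)
      if (!any(structs$CTV & structs$Rectum) && any(structs$BladderNeck) &&
          any(structs$GTV)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible geometry after 100 rejection attempts")
    planning <- structure_set(grid, structs, image_label = "pCT")

    rel0 <- relative_ctv_position(planning)
    rel0 <- relative_ctv_position(planning)
    drift <- cfg$drift_gain * (as.numeric(rel0) - cfg$drift_ref)
    band <- if (cfg$motion_scale > 0) cfg$com_band else NULL
    # The band is enforced on the continuous draws so behaviour is
    # grid-resolution independent; the realized (voxel-quantized) shifts can
    # deviate by up to half a voxel diagonal.
    draw_fraction_set <- function() {
      displacement <- matrix(0, cfg$n_fractions, 3,
                             dimnames = list(NULL, c("dx", "dy", "dz")))
      drawn <- matrix(0, cfg$n_fractions, 3)
      fractions <- vector("list", cfg$n_fractions)
      for (f in seq_len(cfg$n_fractions)) {
        ok <- FALSE
        for (attempt in 1:100) {
          delta <- drift + rnorm(3, 0, an$amp * cfg$noise_sd)
          # the hydrogel spacer blocks posterior drift beyond the gap
          delta[2] <- min(delta[2], an$gap - 1.5)
          delta <- delta * cfg$motion_scale
          if (!is.null(band)) {
            nrm <- sqrt(sum(delta^2))
            if (nrm < band[1] || nrm > band[2]) next
          }
          dq <- round(delta / cfg$spacing) * cfg$spacing
          # quantization must not round the posterior shift into the spacer gap
          dq[2] <- min(dq[2], floor((an$gap - 1) / cfg$spacing[2]) * cfg$spacing[2])
          sh <- as.integer(round(dq / cfg$spacing))
          moved <- parts
          for (nm in c("ctv_ell", "urethra", "bn_sphere", "gtv")) {
            moved[[nm]] <- shift_array(parts[[nm]], sh, FALSE)
          }
          st <- assemble_structures(moved)
          if (any(st$CTV & st$Rectum) || !any(st$BladderNeck)) next
          displacement[f, ] <- dq
          drawn[f, ] <- delta
          fractions[[f]] <- structure_set(grid, st, image_label = sprintf("CB%d", f))
          ok <- TRUE
          break
        }
        if (!ok) stop("infeasible geometry after 100 rejection attempts")
      }
      list(displacement = displacement, drawn = drawn, fractions = fractions)
    }
    # the per-patient pairwise COM spread must also sit inside the band
    fs <- NULL
    for (attempt in 1:100) {
      fs <- draw_fraction_set()
      if (is.null(band) || cfg$n_fractions < 2L) break
      maxpair <- max(stats::dist(fs$drawn))
      if (maxpair >= band[1] && maxpair <= band[2]) break
      fs <- NULL
    }
    if (is.null(fs)) stop("infeasible geometry after 100 rejection attempts")
    displacement <- fs$displacement
    fractions <- fs$fractions
    structure(list(patient_id = sprintf("seed%d", patient_seed),
                   planning = planning, fractions = fractions,
                   truth = list(displacement = displacement, a_p = an$a_p,
                                planning_rel_pos = rel0,
                                drift = drift, amp = an$amp, anatomy = an)),
              class = "synthetic_patient")
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("synthetic_patient %s: pCT + %d fractions, COM shifts %s mm\n",
              x$patient_id, length(x$fractions),
              paste(sprintf("%.1f", sqrt(rowSums(x$truth$displacement^2))),
                    collapse = ", ")))
  invisible(x)
}

patient_seed_for <- function(cfg, i) {
  as.integer((as.numeric(cfg$seed) + 104729 * i) %% 2147483647)
}

#' Generate a synthetic cohort with a train/test split
#'
#' Patients are seeded independently (per-patient seeds derived from the
#' cohort seed), so the anatomy of patient i does not depend on how many
#' others are generated. For each patient every (planning image, later
#' fraction) pair contributes one feature/target row: features extracted from
#' the earlier image, target the relative CTV position on the later fraction.
#' The masks themselves are not retained — use [materialize_patient()] to
#' regenerate any patient bit-identically.
#'
#' @param cfg a [cohort_config()] with `n_patients >= 12`.
#' @return A `synthetic_cohort`: `config`, `ids`, `seeds`, `train_ids`,
#'   `test_ids`, `pairs` (feature/target data frame with a `split` column)
#'   and `truth` per patient.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  n <- cfg$n_patients
  if (n < 12L) stop("cohort too small: need n >= 12")
  ids <- sprintf("P%03d", seq_len(n))
  seeds <- setNames(vapply(seq_len(n), function(i) patient_seed_for(cfg, i), 0L), ids)
  n_test <- min(10L, n - 10L)
  test_ids <- with_preserved_seed(cfg$seed, sort(sample(ids, n_test)))
  train_ids <- setdiff(ids, test_ids)

  rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    pat <- generate_patient(cfg, seeds[[i]])
    truth[[ids[i]]] <- pat$truth
    images <- c(list(pat$planning), pat$fractions)
    feats <- lapply(images, extract_features)
    rels <- lapply(images, relative_ctv_position)
    k <- length(images)
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = ids[i],
          planning_image = images[[a]]$image_label,
          target_image = images[[b]]$image_label,
          src_idx = a - 1L, tgt_idx = b - 1L,
          as.list(feats[[a]]),
          dx = rels[[b]][["dx"]], dy = rels[[b]][["dy"]], dz = rels[[b]][["dz"]],
          planning_dx = rels[[a]][["dx"]], planning_dy = rels[[a]][["dy"]],
          planning_dz = rels[[a]][["dz"]])
      }
    }
    rm(pat, images)
  }
  pairs <- do.call(rbind, rows)
  pairs$split <- ifelse(pairs$patient %in% test_ids, "test", "train")
  structure(list(config = cfg, ids = ids, seeds = seeds,
                 train_ids = train_ids, test_ids = test_ids,
                 pairs = pairs, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients (%d train / %d test), %d feature/target rows\n",
              length(x$ids), length(x$train_ids), length(x$test_ids), nrow(x$pairs)))
  invisible(x)
}

#' Re-generate one cohort patient bit-identically
#' @param cohort a [generate_cohort()] result.
#' @param id patient id from `cohort$ids`.
#' @return A `synthetic_patient`.
#' @export
materialize_patient <- function(cohort, id) {
  seed <- cohort$seeds[[id]]
  if (is.null(seed)) stop(sprintf("unknown patient id '%s'", id))
  pat <- generate_patient(cohort$config, seed)
  pat$patient_id <- id
  pat
}

#' Feature matrix and target matrix for the margin model
#'
#' @param cohort a [generate_cohort()] result.
#' @param split `"train"`, `"test"` or `"all"`.
#' @param mode which (source image, target fraction) pairs to keep:
#'   `"sequential"` (default) uses each image to predict the immediately
#'   following fraction (pCT to CB1, CB1 to CB2, ...), one row per treated
#'   fraction — the online-workflow structure; `"planning"` keeps only
#'   planning-CT to fraction rows (used for held-out evaluation of
#'   treatment-day predictions); `"all"` keeps every forward pair.
#' @return list with `X` (n x 7), `Y` (n x 3) and the underlying `rows`.
#' @export
training_table <- function(cohort, split = "train",
                           mode = c("sequential", "planning", "all")) {
  mode <- match.arg(mode)
  rows <- cohort$pairs
  if (split != "all") rows <- rows[rows$split == split, , drop = FALSE]
  if (mode == "sequential") {
    rows <- rows[rows$tgt_idx == rows$src_idx + 1L, , drop = FALSE]
  } else if (mode == "planning") {
    rows <- rows[rows$src_idx == 0L, , drop = FALSE]
  }
  list(X = as.matrix(rows[, paste0("f", 1:7)]),
       Y = as.matrix(rows[, c("dx", "dy", "dz")]),
       rows = rows)
}
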