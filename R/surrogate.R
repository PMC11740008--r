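# Surrogate robust-plan engine. It replaces the treatment planning system's
# Monte-Carlo dose calculation and minimax optimizer with a geometric
# target-coverage-plus-falloff model so the margin/scoring/selection workflow
# is exercisable end to end; it is isolated behind this interface so a real
# TPS dose export can be substituted.

#' Enumerate the 21 robustness scenarios
#'
#' Setup/range uncertainty space of robust proton optimization: the nominal
#' position plus six cardinal setup shifts (each using the margin magnitude of
#' its own direction, e.g. the +y shift uses the posterior margin), crossed
#' with three range scales `{1, 1 - p, 1 + p}` for range uncertainty `p`
#' (default 3.5%). Always exactly 7 x 3 = 21 entries, nominal first.
#'
#' @param margins a [margin_set()].
#' @param range_pct fractional range uncertainty (default 0.035).
#' @return data frame with columns `dx, dy, dz` (mm) and `range_scale`,
#'   class `scenario_set`.
#' @export
enumerate_scenarios <- function(margins, range_pct = 0.035) {
  m <- as_margin_set(margins)
  shifts <- rbind(
    nominal   = c(0, 0, 0),
    left      = c(m[["left"]], 0, 0),
    right     = c(-m[["right"]], 0, 0),
    anterior  = c(0, -m[["anterior"]], 0),
    posterior = c(0, m[["posterior"]], 0),
    superior  = c(0, 0, m[["superior"]]),
    inferior  = c(0, 0, -m[["inferior"]]))
  scales <- c(1, 1 - range_pct, 1 + range_pct)
  out <- data.frame(
    shift = rep(rownames(shifts), each = length(scales)),
    dx = rep(shifts[, 1], each = length(scales)),
    dy = rep(shifts[, 2], each = length(scales)),
    dz = rep(shifts[, 3], each = length(scales)),
    range_scale = rep(scales, times = nrow(shifts)),
    row.names = NULL)
  class(out) <- c("scenario_set", "data.frame")
  out
}

#' Surrogate dose configuration
#'
#' @param penumbra_mm 80-20 lateral falloff width outside the expanded target
#'   (default 5 mm).
#' @param shoulder_mm full-dose shoulder beyond the expanded target before the
#'   falloff begins (default 2 mm, one voxel at the default grid): a robust
#'   optimizer holds prescription coverage at the scenario-shifted target
#'   edge, not strictly inside it.
#' @param range_pct fractional range uncertainty (default 0.035).
#' @param min_robust_d98 worst-case scenario D98 requirement as a fraction of
#'   prescription (default 0.95); a plan below it is kept but flagged with a
#'   warning.
#' @return list of surrogate-engine settings.
#' @export
plan_config <- function(penumbra_mm = 5, shoulder_mm = 2, range_pct = 0.035,
                        min_robust_d98 = 0.95) {
  list(penumbra_mm = penumbra_mm, shoulder_mm = shoulder_mm,
       range_pct = range_pct, min_robust_d98 = min_robust_d98)
}

# Normalized sigmoidal falloff: 1 out to the shoulder, ~50% at
# shoulder + penumbra, 80->20 over `penumbra_mm` mm.
falloff_profile <- function(d, penumbra_mm, shoulder_mm = 0) {
  w <- penumbra_mm / (2 * log(4))
  d50 <- penumbra_mm
  f <- function(x) 1 / (1 + exp((x - d50) / w))
  f(pmax(d - shoulder_mm, 0)) / f(0)
}

# Trilinear interpolation of a 3D array at mm points (rows of `pts`);
# points outside the grid are clamped to its faces.
interp_trilinear <- function(arr, grid, pts) {
  fi <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/") + 1
  n <- grid$shape
  for (k in 1:3) fi[, k] <- pmin(pmax(fi[, k], 1), n[k])
  i0 <- pmin(floor(fi), matrix(rep(n - 1L, each = nrow(fi)), ncol = 3))
  fr <- fi - i0
  lin <- function(a, b, c) {
    (a - 1) + (b - 1) * n[1] + (c - 1) * n[1] * n[2] + 1
  }
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    v <- v + w * arr[lin(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v
}

default_beams <- function() {
  data.frame(beam = c("LAO", "RAO", "LatL", "LatR"),
             gantry_deg = c(50, 300, 90, 270),
             weight = c(0.15, 0.15, 0.35, 0.35))
}

#' Create a surrogate robustly-optimized proton plan
#'
#' The margin-expanded CTV receives the full prescription; outside it the dose
#' falls off sigmoidally with the configured penumbra. For boosted (SIB)
#' plans a GTV-expanded region is raised to the boost prescription. The 21
#' robustness scenarios are then checked: the worst-case shifted-CTV D98
#' (with the range scale acting as a falloff-distance multiplier) must reach
#' `cfg$min_robust_d98` of prescription, otherwise a warning is issued and the
#' plan is flagged.
#'
#' @param ss planning [structure_set()] (CTV required; GTV required only when
#'   `boost_rx` is given).
#' @param margins a [margin_set()].
#' @param rx CTV prescription in Gy over the full course (e.g. 26).
#' @param cfg a [plan_config()].
#' @param label plan label, e.g. `"Clinic(Fx1)"`.
#' @param boost_rx optional SIB boost prescription in Gy (e.g. 32).
#' @param fractions number of fractions the prescription is split over
#'   (default 2).
#' @return A `proton_plan`: label, margins, planning image, prescription,
#'   beams, total RBE-weighted dose grid in Gy, femoral alignment reference,
#'   and the worst-case robustness check result.
#' @export
optimize_plan_surrogate <- function(ss, margins, rx, cfg = plan_config(),
                                    label = "plan", boost_rx = NULL,
                                    fractions = 2L) {
  margins <- as_margin_set(margins)
  ctv <- get_structure(ss, "CTV")
  if (!any(ctv$mask)) stop("empty structure")
  target <- expand_mask(ctv, margins)
  dist <- distance_map_mm(target)
  dose <- rx * falloff_profile(dist, cfg$penumbra_mm, cfg$shoulder_mm)
  if (!is.null(boost_rx)) {
    gtv <- get_structure(ss, "GTV")
    if (!any(gtv$mask)) stop("empty structure")
    btarget <- expand_mask(gtv, margins)
    bdose <- boost_rx * falloff_profile(distance_map_mm(btarget),
                                        cfg$penumbra_mm, cfg$shoulder_mm)
    dose <- pmax(dose, bdose)
    dim(dose) <- ss$grid$shape
  }

  scen <- enumerate_scenarios(margins, cfg$range_pct)
  ctv_idx <- which(ctv$mask, arr.ind = TRUE)
  ctv_mm <- sweep(sweep(ctv_idx - 1, 2, ss$grid$spacing, "*"), 2, ss$grid$origin, "+")
  worst <- Inf
  vv <- voxel_volume_cc(ss$grid)
  for (s in seq_len(nrow(scen))) {
    pts <- sweep(ctv_mm, 2, c(scen$dx[s], scen$dy[s], scen$dz[s]), "+")
    dsub <- interp_trilinear(dist, ss$grid, pts)
    dvals <- rx * falloff_profile(dsub / scen$range_scale[s],
                                  cfg$penumbra_mm, cfg$shoulder_mm)
    d98 <- dvh_from_values(dvals, vv, list(type = "D", volume = 98, unit = "%"))
    if (d98 < worst) worst <- d98
  }
  robust_ok <- worst >= cfg$min_robust_d98 * rx
  if (!robust_ok) {
    warning(sprintf("plan '%s': worst-case CTV D98 %.1f Gy below %.0f%% of prescription",
                    label, worst, 100 * cfg$min_robust_d98))
  }

  structure(list(label = label, margins = margins,
                 planning_image_label = ss$image_label,
                 rx = rx, boost_rx = boost_rx, fractions = as.integer(fractions),
                 dose = dose, grid = ss$grid,
                 fem_center = fem_box_center(ss),
                 beams = default_beams(),
                 penumbra_mm = cfg$penumbra_mm, range_pct = cfg$range_pct,
                 robust = list(ok = robust_ok, worst_d98_gy = worst)),
            class = "proton_plan")
}

#' @export
print.proton_plan <- function(x, ...) {
  cat(sprintf("proton_plan '%s' on %s: rx %g Gy / %d fx%s\n",
              x$label, x$planning_image_label, x$rx, x$fractions,
              if (!is.null(x$boost_rx)) sprintf(" (SIB %g Gy)", x$boost_rx) else ""))
  print(x$margins)
  invisible(x)
}

#' Evaluate a plan's dose against a treatment-day anatomy
#'
#' Emulates bony image guidance: the fraction anatomy is rigidly aligned to
#' the plan's planning image by translating it so the femoral bounding-box
#' centers coincide (translation only, rounded to whole voxels). The plan's
#' stored dose grid is then paired with the aligned fraction structures;
#' residual CTV displacement relative to the femora is what the margins must
#' absorb.
#'
#' @param plan a `proton_plan`.
#' @param fraction_ss the treatment-day [structure_set()] (femoral structures
#'   required).
#' @return list with `dose` (the plan's grid, Gy), `ss` (the aligned
#'   structure set) and `shift_mm` (applied translation).
#' @export
recompute_dose_on_fraction <- function(plan, fraction_ss) {
  if (!same_grid(plan$grid, fraction_ss$grid)) {
    stop("plan and fraction anatomy must share one voxel grid")
  }
  t_mm <- as.numeric(plan$fem_center) - as.numeric(fem_box_center(fraction_ss))
  t_vox <- as.integer(round(t_mm / fraction_ss$grid$spacing))
  aligned <- if (all(t_vox == 0L)) fraction_ss else shift_structure_set(fraction_ss, t_vox)
  list(dose = plan$dose, ss = aligned, shift_mm = t_vox * fraction_ss$grid$spacing)
}
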