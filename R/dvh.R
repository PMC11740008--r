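# Dose-volume metrics: Vx, Dx, Dmean, D0.03cc, D2cm and the Paddick
# conformity index. Dx uses the step (sorted-voxel) convention without
# inter-voxel interpolation, so results are reproducible across libraries to
# within half a voxel volume.

# Shared kernel on a bag of voxel doses with uniform voxel volume (cc).
dvh_from_values <- function(doses, voxel_cc, spec) {
  n <- length(doses)
  if (n == 0L) stop("empty structure")
  total_cc <- n * voxel_cc
  type <- spec$type
  if (type == "Dmean") return(mean(doses))
  unit <- spec$unit %||% "%"
  if (type == "V") {
    vol_cc <- sum(doses >= spec$threshold - 1e-12) * voxel_cc
    return(if (unit == "%") 100 * vol_cc / total_cc else vol_cc)
  }
  if (type == "D") {
    v_cc <- if (unit == "%") spec$volume / 100 * total_cc else spec$volume
    if (v_cc > total_cc + 1e-9) stop("requested volume exceeds structure volume")
    sorted <- sort(doses, decreasing = TRUE)
    k <- max(1L, ceiling(v_cc / voxel_cc - 1e-9))
    return(sorted[min(k, n)])
  }
  stop(sprintf("unknown DVH spec type '%s'", type))
}

#' Dose-volume metric of one structure
#'
#' * `V`: volume receiving at least `threshold` Gy, as `%` of the structure
#'   or absolute `cc`.
#' * `D`: largest dose such that at least `volume` (`%` of the structure or
#'   `cc`) receives it, from the sorted voxel doses (step DVH, no
#'   interpolation).
#' * `Dmean`: volume-weighted mean dose.
#'
#' @param dose Gy array on the structure's grid.
#' @param structure a [structure_mask()] (non-empty).
#' @param spec list, one of `list(type = "V", threshold = , unit = "%"|"cc")`,
#'   `list(type = "D", volume = , unit = "%"|"cc")`, `list(type = "Dmean")`.
#' @return metric value (Gy for `D`/`Dmean`; `%` or cc for `V`).
#' @export
dvh_metric <- function(dose, structure, spec) {
  if (!identical(dim(dose), structure$grid$shape)) stop("dose and mask grids differ")
  dvh_from_values(dose[structure$mask], voxel_volume_cc(structure$grid), spec)
}

#' Near-maximum dose D0.03cc
#'
#' Minimum dose within the hottest 0.03 cc of the structure: voxel doses are
#' sorted descending and volumes accumulated until 0.03 cc is reached.
#'
#' @param dose Gy array.
#' @param structure a [structure_mask()] with volume >= 0.03 cc.
#' @return Gy.
#' @export
d003cc <- function(dose, structure) {
  vv <- voxel_volume_cc(structure$grid)
  n <- sum(structure$mask)
  if (n * vv < 0.03 - 1e-12) stop("structure smaller than 0.03 cc")
  dvh_from_values(dose[structure$mask], vv, list(type = "D", volume = 0.03, unit = "cc"))
}

#' Evaluation volume V for conformity metrics
#'
#' The CTV expanded 5 mm in every direction except 3 mm posteriorly; used only
#' for the dose-falloff metric [d2cm()].
#'
#' @param ss a [structure_set()] with CTV.
#' @return A [structure_mask()] named `"V"`.
#' @export
evaluation_volume <- function(ss) {
  v <- expand_mask(get_structure(ss, "CTV"),
                   margin_set(left = 5, right = 5, anterior = 5, posterior = 3,
                              superior = 5, inferior = 5))
  v$name <- "V"
  v
}

#' Dose falloff metric D2cm
#'
#' Maximum dose among body voxels at Euclidean distance >= 20 mm from the
#' evaluation volume V, as a percentage of prescription. The search is
#' restricted to the body mask so air is never scored.
#'
#' @param dose Gy array.
#' @param v_structure the evaluation volume ([evaluation_volume()]).
#' @param body the body [structure_mask()].
#' @param rx prescription in Gy.
#' @return percent of prescription.
#' @export
d2cm <- function(dose, v_structure, body, rx) {
  dist <- distance_map_mm(v_structure)
  sel <- body$mask & dist >= 20 - 1e-9
  if (!any(sel)) stop("grid too small: no body voxel at >= 20 mm from V")
  100 * max(dose[sel]) / rx
}

#' Paddick conformity index
#'
#' `PCI = TV_PIV^2 / (TV * PIV)` where PIV is the prescription isodose volume
#' anywhere on the grid and TV_PIV its intersection with the target. 1 means
#' the prescription isodose coincides with the target; defined as 0 when the
#' prescription dose is reached nowhere.
#'
#' @param target target [structure_mask()] (non-empty).
#' @param dose Gy array.
#' @param rx prescription in Gy.
#' @return value in `[0, 1]`.
#' @export
pci <- function(target, dose, rx) {
  if (!any(target$mask)) stop("empty target")
  piv <- dose >= rx - 1e-12
  n_piv <- sum(piv)
  if (n_piv == 0L) return(0)
  n_tv <- sum(target$mask)
  n_both <- sum(target$mask & piv)
  n_both^2 / (n_tv * n_piv)
}

trial_rectum_high <- function(trial) if (trial == "2SMART") 22 else 20.8
trial_rectum_high_name <- function(trial) if (trial == "2SMART") "rectum_v22" else "rectum_v20_8"

metric_bundle_dose <- function(dose, ss, trial = c("2STAR", "2SMART"),
                               rx = 26, boost_rx = if (trial == "2SMART") 32 else NULL) {
  trial <- match.arg(trial)
  need <- REQUIRED_PLANNING_STRUCTURES
  if (trial == "2SMART") need <- c(need, "Urethra")
  for (nm in need) {
    if (is.null(ss$structures[[nm]]) || !any(ss$structures[[nm]])) {
      stop(sprintf("missing structure '%s' required for %s evaluation", nm, trial))
    }
  }
  ctv <- get_structure(ss, "CTV")
  body <- get_structure(ss, "Body")
  bn <- get_structure(ss, "BladderNeck")
  bl <- get_structure(ss, "Bladder")
  re <- get_structure(ss, "Rectum")
  v <- evaluation_volume(ss)

  m <- list(
    ctv_v100 = dvh_metric(dose, ctv, list(type = "V", threshold = rx, unit = "%")),
    ctv_d98 = 100 * dvh_metric(dose, ctv, list(type = "D", volume = 98, unit = "%")) / rx,
    body_d003cc = 100 * d003cc(dose, body) / rx,
    body_d003cc_gy = d003cc(dose, body),
    d2cm = d2cm(dose, v, body, rx),
    pci = pci(ctv, dose, rx),
    bladderneck_v100 = dvh_metric(dose, bn, list(type = "V", threshold = rx, unit = "%")),
    bladderneck_dmean = dvh_metric(dose, bn, list(type = "Dmean")),
    bladder_v14_6 = dvh_metric(dose, bl, list(type = "V", threshold = 14.6, unit = "cc")),
    bladder_v20_8 = dvh_metric(dose, bl, list(type = "V", threshold = 20.8, unit = "cc")),
    rectum_v13 = dvh_metric(dose, re, list(type = "V", threshold = 13, unit = "cc")),
    rectum_v17_6 = dvh_metric(dose, re, list(type = "V", threshold = 17.6, unit = "cc")))
  m[[trial_rectum_high_name(trial)]] <-
    dvh_metric(dose, re, list(type = "V", threshold = trial_rectum_high(trial), unit = "cc"))
  if (trial == "2SMART") {
    ur <- get_structure(ss, "Urethra")
    m$urethra_d003cc <- d003cc(dose, ur)
    m$urethra_d10pct <- dvh_metric(dose, ur, list(type = "D", volume = 10, unit = "%"))
  }
  structure(m, class = "dvh_metrics", trial = trial, rx = rx, boost_rx = boost_rx)
}

#' All scored and constraint dose-volume metrics for one (plan, anatomy) pair
#'
#' Computes the 12 scored metrics (CTV V100, D98, hot spot D0.03cc, D2cm,
#' Paddick conformity, bladder-neck V100 and mean dose, bladder V14.6/V20.8,
#' rectum V13/V17.6 and the trial-specific high-dose rectum volume) plus
#' auxiliary constraint metrics (urethra D0.03cc and D10% for 2SMART).
#' Percent-of-prescription metrics are taken against the CTV prescription.
#'
#' @param plan a `proton_plan`.
#' @param ss the evaluation [structure_set()] on the same grid (already
#'   aligned; see [recompute_dose_on_fraction()]).
#' @param trial `"2STAR"` or `"2SMART"` (the latter requires a Urethra
#'   structure and switches the high-dose rectum metric to V22).
#' @return A `dvh_metrics` named list.
#' @export
metric_bundle <- function(plan, ss, trial = c("2STAR", "2SMART")) {
  trial <- match.arg(trial)
  if (!same_grid(plan$grid, ss$grid)) stop("plan and anatomy must share one grid")
  metric_bundle_dose(plan$dose, ss, trial, rx = plan$rx, boost_rx = plan$boost_rx)
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("dvh_metrics (%s): CTV V100 %.2f%%, D98 %.1f%%, PCI %.3f, BN V100 %.1f%%\n",
              attr(x, "trial"), x$ctv_v100, x$ctv_d98, x$pci, x$bladderneck_v100))
  invisible(x)
}
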