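# Digital-twin workflow driver: build per-fraction candidate pools, evaluate
# them on treatment-day anatomy, select the highest-scoring plan, carry plans
# across fractions, and evaluate the cumulative treatment.

#' Workflow configuration
#'
#' @param trial `"2STAR"` (26 Gy CTV prescription) or `"2SMART"` (26 Gy CTV
#'   with a 32 Gy simultaneous integrated boost to the GTV).
#' @param rx CTV prescription Gy over the two-fraction course.
#' @param boost_rx SIB boost Gy (used only for 2SMART).
#' @param clinical_margins the constant clinical margin set (default 5 mm, 3 mm
#'   posterior).
#' @param margin_bounds clamp bounds `c(lower, upper)` in mm for predicted
#'   margins.
#' @param dt_offsets uncertainty offsets defining the four digital-twin margin
#'   sets.
#' @param plan surrogate-engine settings, see [plan_config()].
#' @param scoring scoring configuration (default
#'   [default_scoring_functions()] for the trial).
#' @return A `run_config` list.
#' @export
run_config <- function(trial = c("2STAR", "2SMART"), rx = 26,
                       boost_rx = 32,
                       clinical_margins = clinical_margin_set(),
                       margin_bounds = c(1.5, 5.0),
                       dt_offsets = c(-0.5, 0, 0.5, 1),
                       plan = plan_config(),
                       scoring = NULL) {
  trial <- match.arg(trial)
  if (is.null(scoring)) scoring <- default_scoring_functions(trial, rx = rx, boost_rx = boost_rx)
  structure(list(trial = trial, rx = rx,
                 boost_rx = if (trial == "2SMART") boost_rx else NULL,
                 clinical_margins = as_margin_set(clinical_margins),
                 margin_bounds = margin_bounds, dt_offsets = dt_offsets,
                 plan = plan, scoring = scoring),
            class = "run_config")
}

#' Build the candidate plan pool for one fraction
#'
#' One clinical plan with the constant institutional margins plus four
#' digital-twin plans whose margins come from the fitted model's prediction on
#' the planning image ([build_margin_sets()]). Plans carried over from earlier
#' fractions are prepended, so the first-fraction pool has 5 plans and the
#' second-fraction pool 10.
#'
#' @param fraction fraction index (1-based).
#' @param planning_ss planning-image [structure_set()] (pCT for fraction 1,
#'   the previous fraction's CBCT afterwards).
#' @param model a fitted [fit_gpr()] model.
#' @param carried list of `proton_plan`s carried from earlier fractions.
#' @param cfg a [run_config()].
#' @return A `plan_pool`: list with `fraction` and `plans`.
#' @export
build_pool <- function(fraction, planning_ss, model, carried = list(),
                       cfg = run_config()) {
  fx <- sprintf("Fx%d", fraction)
  pr <- predict_with_uncertainty(model, extract_features(planning_ss))
  rel <- relative_ctv_position(planning_ss)
  msets <- build_margin_sets(pr$mu, pr$sigma, rel,
                             list(offsets = cfg$dt_offsets,
                                  lower = cfg$margin_bounds[1],
                                  upper = cfg$margin_bounds[2]))
  mk <- function(margins, label) {
    optimize_plan_surrogate(planning_ss, margins, cfg$rx, cfg$plan,
                            label = label, boost_rx = cfg$boost_rx)
  }
  plans <- c(list(mk(cfg$clinical_margins, sprintf("Clinic(%s)", fx))),
             lapply(seq_along(msets), function(i) {
               suffix <- sub("^DT", "", names(msets)[i])
               mk(msets[[i]], sprintf("DT(%s)%s", fx, suffix))
             }))
  structure(list(fraction = fraction, plans = c(carried, plans)),
            class = "plan_pool")
}

#' @export
print.plan_pool <- function(x, ...) {
  cat(sprintf("plan_pool (fraction %d): %d plans\n", x$fraction, length(x$plans)))
  for (p in x$plans) cat("  -", p$label, "\n")
  invisible(x)
}

#' Evaluate every pool member on a treatment-day anatomy
#'
#' Each plan's dose is paired with the femur-aligned fraction anatomy
#' ([recompute_dose_on_fraction()]), the metric bundle computed, and the
#' adapted ProKnow score card derived.
#'
#' @param pool a [build_pool()] result.
#' @param fraction_ss the treatment-day [structure_set()].
#' @param cfg a [run_config()].
#' @return list of evaluations, each with `label`, `metrics`, `scorecard`.
#' @export
evaluate_pool <- function(pool, fraction_ss, cfg = run_config()) {
  lapply(pool$plans, function(plan) {
    rec <- recompute_dose_on_fraction(plan, fraction_ss)
    metrics <- metric_bundle_dose(rec$dose, rec$ss, cfg$trial,
                                  rx = plan$rx, boost_rx = plan$boost_rx)
    list(label = plan$label, metrics = metrics,
         scorecard = total_score(metrics, cfg$scoring))
  })
}

#' Select the optimal plan from scored candidates
#'
#' Argmax of the total score. Ties are broken by (1) the smaller mean margin
#' (less healthy tissue exposed), then (2) preferring the clinical plan, then
#' (3) the lowest pool index. Invariant under pool reordering.
#'
#' @param scorecards list of evaluations from [evaluate_pool()] (or of
#'   `score_card`s).
#' @param pool the matching `plan_pool`.
#' @return list with `label` and `index` of the selected plan.
#' @export
select_plan <- function(scorecards, pool) {
  if (length(pool$plans) == 0L) stop("empty pool")
  totals <- vapply(scorecards, function(s) {
    if (!is.null(s$scorecard)) s$scorecard$total else s$total
  }, numeric(1))
  best <- max(totals)
  cand <- which(totals >= best - 1e-9)
  if (length(cand) > 1L) {
    mm <- vapply(pool$plans[cand], function(p) mean_margin(p$margins), numeric(1))
    cand <- cand[mm <= min(mm) + 1e-9]
  }
  if (length(cand) > 1L) {
    is_clin <- grepl("^Clinic", vapply(pool$plans[cand], `[[`, "", "label"))
    if (any(is_clin)) cand <- cand[is_clin]
  }
  idx <- min(cand)
  list(label = pool$plans[[idx]]$label, index = idx)
}

align_dose_to <- function(plan, target_ss) {
  t_mm <- as.numeric(fem_box_center(target_ss)) - as.numeric(plan$fem_center)
  t_vox <- as.integer(round(t_mm / target_ss$grid$spacing))
  shift_array(plan$dose, t_vox, fill = 0)
}

#' Cumulative two-fraction evaluation
#'
#' Each selected plan contributes half of its total plan dose (one fraction).
#' The two delivered half-doses are summed on the planning-image frame after
#' femoral (bony) alignment, and the metric bundle plus score card are
#' computed against the planning structure set.
#'
#' @param selected_plans list of the two selected `proton_plan`s (Fx1, Fx2).
#' @param planning_ss the planning (pCT) [structure_set()].
#' @param cfg a [run_config()].
#' @return list with `metrics` and `scorecard` for the summed course dose.
#' @export
cumulative_evaluation <- function(selected_plans, planning_ss, cfg = run_config()) {
  if (length(selected_plans) != 2L || any(vapply(selected_plans, is.null, TRUE))) {
    stop("missing fraction: cumulative evaluation needs both selected plans")
  }
  cum <- 0.5 * align_dose_to(selected_plans[[1]], planning_ss) +
    0.5 * align_dose_to(selected_plans[[2]], planning_ss)
  metrics <- metric_bundle_dose(cum, planning_ss, cfg$trial, rx = cfg$rx,
                                boost_rx = cfg$boost_rx)
  list(metrics = metrics, scorecard = total_score(metrics, cfg$scoring))
}

#' Run the two-fraction digital-twin workflow for one patient
#'
#' Fraction 1: a pool of five plans (clinical + four digital-twin margin
#' variants) is built on the planning CT, evaluated on the first treatment
#' CBCT, and the highest-scoring plan selected. Fraction 2: five new plans are
#' built on that CBCT, pooled with the five carried plans (ten candidates),
#' evaluated on the second treatment CBCT, and selected. Finally the two
#' delivered half-doses are accumulated on the planning frame and scored; the
#' same is done for the non-adaptive reference course (the clinical plan
#' delivered at both fractions).
#'
#' @param patient a `synthetic_patient` (or any list with `$planning` and
#'   `$fractions`; with more than two fraction anatomies the maximally
#'   separated pair is used, see [select_max_separation_pair()]).
#' @param model a fitted [fit_gpr()] model.
#' @param cfg a [run_config()].
#' @return A `treatment_record`.
#' @export
run_two_fraction_workflow <- function(patient, model, cfg = run_config()) {
  pct <- patient$planning
  fr <- patient$fractions
  if (length(fr) < 2L) stop("patient needs at least two fraction anatomies")
  pair <- if (length(fr) > 2L) select_max_separation_pair(fr) else c(i = 1L, j = 2L)
  cb1 <- fr[[pair[["i"]]]]
  cb2 <- fr[[pair[["j"]]]]

  pool1 <- build_pool(1L, pct, model, list(), cfg)
  ev1 <- evaluate_pool(pool1, cb1, cfg)
  sel1 <- select_plan(ev1, pool1)

  pool2 <- build_pool(2L, cb1, model, carried = pool1$plans, cfg)
  ev2 <- evaluate_pool(pool2, cb2, cfg)
  sel2 <- select_plan(ev2, pool2)

  cum_dt <- cumulative_evaluation(list(pool1$plans[[sel1$index]],
                                       pool2$plans[[sel2$index]]), pct, cfg)
  clin_idx1 <- which(vapply(pool1$plans, `[[`, "", "label") == "Clinic(Fx1)")
  cum_clin <- cumulative_evaluation(list(pool1$plans[[clin_idx1]],
                                         pool1$plans[[clin_idx1]]), pct, cfg)

  summarize_fx <- function(pool, ev, sel, clin_label) {
    labels <- vapply(pool$plans, `[[`, "", "label")
    clin_i <- which(labels == clin_label)
    list(labels = labels,
         totals = setNames(vapply(ev, function(e) e$scorecard$total, 0), labels),
         selected = sel$label,
         selected_metrics = ev[[sel$index]]$metrics,
         selected_scorecard = ev[[sel$index]]$scorecard,
         clinical_metrics = ev[[clin_i]]$metrics,
         clinical_scorecard = ev[[clin_i]]$scorecard,
         margins = lapply(pool$plans, `[[`, "margins"))
  }
  structure(list(
    patient_id = patient$patient_id %||% "patient",
    pair = pair,
    fx1 = summarize_fx(pool1, ev1, sel1, "Clinic(Fx1)"),
    fx2 = summarize_fx(pool2, ev2, sel2, "Clinic(Fx1)"),
    cumulative = list(dt = cum_dt, clinical = cum_clin),
    trial = cfg$trial),
    class = "treatment_record")
}

#' @export
print.treatment_record <- function(x, ...) {
  cat(sprintf("treatment_record %s (%s): Fx1 -> %s, Fx2 -> %s\n",
              x$patient_id, x$trial, x$fx1$selected, x$fx2$selected))
  cat(sprintf("  cumulative score: DT %.2f vs clinical %.2f\n",
              x$cumulative$dt$scorecard$total, x$cumulative$clinical$scorecard$total))
  invisible(x)
}

#' Paired cohort comparison of plan-quality totals
#'
#' Two-sided paired Wilcoxon signed-rank test on per-patient totals, exact for
#' n <= 25 untied non-zero differences. Identical paired samples return
#' p = 1 by convention (no evidence of a difference); zero differences are
#' dropped, as is standard for the signed-rank statistic.
#'
#' @param clinical_totals,dt_totals equal-length numeric vectors (n >= 5).
#' @param paired must remain `TRUE` (the design is paired per patient).
#' @return two-sided p-value.
#' @export
compare_cohort <- function(clinical_totals, dt_totals, paired = TRUE) {
  if (length(clinical_totals) != length(dt_totals)) stop("length mismatch")
  if (length(dt_totals) < 5L) stop("need at least 5 paired observations")
  if (!paired) stop("only the paired design is supported")
  d <- dt_totals - clinical_totals
  nz <- d[d != 0]
  if (length(nz) == 0L) return(1)
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  res <- suppressWarnings(wilcox.test(nz, mu = 0, exact = exact, correct = TRUE))
  min(1, res$p.value)
}

#' Run the digital-twin trial over a cohort of synthetic patients
#'
#' Materializes each requested patient, runs the two-fraction workflow, and
#' tabulates per-patient cumulative scores, per-fraction bladder-neck V100 for
#' the selected (digital-twin) and clinical courses, and the selected plan
#' labels. Also reports the paired Wilcoxon p-value on the cumulative scores.
#'
#' @param cohort a [generate_cohort()] result.
#' @param model a fitted [fit_gpr()] model.
#' @param cfg a [run_config()].
#' @param patient_ids patients to treat (default: the cohort's test split).
#' @return list with `summary` (data frame), `records` and `p_value`.
#' @export
run_cohort_trial <- function(cohort, model, cfg = run_config(),
                             patient_ids = cohort$test_ids) {
  rows <- list()
  records <- list()
  for (id in patient_ids) {
    pat <- materialize_patient(cohort, id)
    rec <- run_two_fraction_workflow(pat, model, cfg)
    rows[[id]] <- data.frame(
      patient = id,
      selected_fx1 = rec$fx1$selected,
      selected_fx2 = rec$fx2$selected,
      dt_total = rec$cumulative$dt$scorecard$total,
      clinical_total = rec$cumulative$clinical$scorecard$total,
      dt_bladderneck_v100 = mean(c(rec$fx1$selected_metrics$bladderneck_v100,
                                   rec$fx2$selected_metrics$bladderneck_v100)),
      clinical_bladderneck_v100 = mean(c(rec$fx1$clinical_metrics$bladderneck_v100,
                                         rec$fx2$clinical_metrics$bladderneck_v100)),
      dt_ctv_v100 = mean(c(rec$fx1$selected_metrics$ctv_v100,
                           rec$fx2$selected_metrics$ctv_v100)),
      clinical_ctv_v100 = mean(c(rec$fx1$clinical_metrics$ctv_v100,
                                 rec$fx2$clinical_metrics$ctv_v100)))
    records[[id]] <- rec
    rm(pat)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  p <- if (nrow(summary) >= 5L) {
    compare_cohort(summary$clinical_total, summary$dt_total)
  } else {
    NA_real_
  }
  list(summary = summary, records = records, p_value = p)
}
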