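# Adapted 12-function ProKnow plan-quality scoring: piecewise-linear
# per-metric points with a hard zero beyond the failure threshold, summed to
# a total score. The CTV V100 function is fully determined by its published
# anchor behaviour (0 below 90%, 2.0 points per percentage point up to a
# 35-point cap at 100%); the remaining 11 defaults are package defaults
# anchored at the trial constraint limits and are meant to be replaced by an
# institution-specific configuration file.

#' Define one piecewise-linear scoring function
#'
#' @param metric name of the scored metric (a field of `dvh_metrics`).
#' @param orientation `"higher"` if larger metric values are better (targets),
#'   `"lower"` for organ-at-risk metrics.
#' @param breakpoints data frame with columns `value` and `points`; points are
#'   linearly interpolated between breakpoints and clamped beyond the
#'   best-value end. Beyond the failure end (below the lowest breakpoint for
#'   higher-better, above the highest for lower-better) the score is a hard 0.
#' @param max_points maximum attainable points (default: the largest
#'   breakpoint value).
#' @return A `scoring_function`.
#' @export
scoring_function <- function(metric, orientation = c("higher", "lower"),
                             breakpoints, max_points = max(breakpoints$points)) {
  orientation <- match.arg(orientation)
  breakpoints <- breakpoints[order(breakpoints$value), , drop = FALSE]
  if (any(breakpoints$points < 0)) stop("points must be non-negative")
  mono <- diff(breakpoints$points)
  ok <- if (orientation == "higher") all(mono >= 0) else all(mono <= 0)
  if (!ok) stop("breakpoints must be monotone in the stated orientation")
  structure(list(metric = metric, orientation = orientation,
                 breakpoints = breakpoints, max_points = max_points),
            class = "scoring_function")
}

#' Score one metric value
#'
#' Linear interpolation between the function's breakpoints, clamped to the
#' best-value plateau, with a hard zero beyond the failure threshold (below
#' the lowest breakpoint for higher-better metrics, above the highest for
#' lower-better ones).
#'
#' @param value finite metric value.
#' @param fn a [scoring_function()].
#' @return points in `[0, max_points]`.
#' @export
score_metric <- function(value, fn) {
  if (!is.finite(value)) stop("non-finite metric value")
  bp <- fn$breakpoints
  if (fn$orientation == "higher" && value < min(bp$value) - 1e-12) return(0)
  if (fn$orientation == "lower" && value > max(bp$value) + 1e-12) return(0)
  pts <- if (nrow(bp) == 1L) bp$points else approx(bp$value, bp$points, xout = value, rule = 2)$y
  min(max(pts, 0), fn$max_points)
}

#' Default adapted ProKnow scoring configuration
#'
#' Twelve scoring functions, one per scored metric. The CTV V100 function
#' awards 0 below 90% coverage, then 2.0 points per percentage point from 15
#' points at 90% to a 35-point cap at 100% (so 98.07% scores 31.14 and 98.59%
#' scores 32.18). The other eleven defaults are linear ramps anchored at the
#' trial's constraint limits (0 points at the limit, 10 at the ideal); they
#' are package defaults, not a published rubric, and should be overridden via
#' [read_scoring_config()] where an institutional rubric exists.
#'
#' @param trial `"2STAR"` or `"2SMART"`.
#' @param rx CTV prescription Gy (default 26).
#' @param boost_rx SIB boost Gy used to anchor the 2SMART hot-spot function
#'   (default 32).
#' @return named list of 12 [scoring_function()]s.
#' @export
default_scoring_functions <- function(trial = c("2STAR", "2SMART"),
                                      rx = 26, boost_rx = 32) {
  trial <- match.arg(trial)
  bp <- function(...) {
    v <- list(...)
    data.frame(value = vapply(v, `[[`, 0, 1), points = vapply(v, `[[`, 0, 2))
  }
  lim <- if (trial == "2SMART") {
    list(bl_lo = 25, bl_hi = 10, re_hi = 1, hot = 110 * boost_rx / rx)
  } else {
    list(bl_lo = 15, bl_hi = 5, re_hi = 1, hot = 110)
  }
  fns <- list(
    ctv_v100 = scoring_function("ctv_v100", "higher", bp(c(90, 15), c(100, 35))),
    ctv_d98 = scoring_function("ctv_d98", "higher", bp(c(90, 0), c(100, 10))),
    body_d003cc = scoring_function("body_d003cc", "lower",
                                   bp(c(lim$hot - 5, 10), c(lim$hot, 0))),
    d2cm = scoring_function("d2cm", "lower", bp(c(30, 10), c(60, 0))),
    pci = scoring_function("pci", "higher", bp(c(0.6, 0), c(1, 10))),
    bladderneck_v100 = scoring_function("bladderneck_v100", "lower",
                                        bp(c(0, 10), c(60, 0))),
    bladderneck_dmean = scoring_function("bladderneck_dmean", "lower",
                                         bp(c(5, 10), c(rx, 0))),
    bladder_v14_6 = scoring_function("bladder_v14_6", "lower",
                                     bp(c(0, 10), c(lim$bl_lo, 0))),
    bladder_v20_8 = scoring_function("bladder_v20_8", "lower",
                                     bp(c(0, 10), c(lim$bl_hi, 0))),
    rectum_v13 = scoring_function("rectum_v13", "lower", bp(c(0, 10), c(7, 0))),
    rectum_v17_6 = scoring_function("rectum_v17_6", "lower", bp(c(0, 10), c(4, 0))))
  high_name <- trial_rectum_high_name(trial)
  fns[[high_name]] <- scoring_function(high_name, "lower", bp(c(0, 10), c(lim$re_hi, 0)))
  fns
}

#' Total adapted ProKnow score
#'
#' Scores every configured metric and sums the points. Deterministic and
#' additive: changing one metric changes only that metric's contribution.
#'
#' @param metrics a `dvh_metrics` bundle ([metric_bundle()]).
#' @param config list of [scoring_function()]s (default:
#'   [default_scoring_functions()] for the bundle's trial).
#' @return A `score_card`: named per-metric points, `total`, `max_total`.
#' @export
total_score <- function(metrics, config = NULL) {
  if (is.null(config)) {
    config <- default_scoring_functions(attr(metrics, "trial") %||% "2STAR",
                                        rx = attr(metrics, "rx") %||% 26)
  }
  pts <- vapply(config, function(fn) {
    v <- metrics[[fn$metric]]
    if (is.null(v)) stop(sprintf("missing metric '%s'", fn$metric))
    score_metric(v, fn)
  }, numeric(1))
  names(pts) <- vapply(config, `[[`, "", "metric")
  structure(list(points = pts, total = sum(pts),
                 max_total = sum(vapply(config, `[[`, 0, "max_points"))),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("score_card: total %.2f / %.0f\n", x$total, x$max_total))
  invisible(x)
}

#' Evaluate the trial's planning constraints
#'
#' Strict-inequality check of every constraint row of the trial protocol
#' (dose limits for bladder, rectum and, for 2SMART, urethra; CTV coverage
#' D98 >= 100% and the hot-spot limit D0.03cc < 110% of the prescription —
#' the boost prescription for 2SMART).
#'
#' @param metrics a `dvh_metrics` bundle.
#' @param trial `"2STAR"` or `"2SMART"` (default: the bundle's trial).
#' @return data frame with columns `constraint`, `value`, `limit`,
#'   `direction`, `pass`.
#' @export
check_constraints <- function(metrics, trial = NULL) {
  trial <- trial %||% attr(metrics, "trial") %||% "2STAR"
  rx <- attr(metrics, "rx") %||% 26
  boost <- attr(metrics, "boost_rx") %||% 32
  hot_limit_gy <- 1.1 * if (trial == "2SMART") boost else rx
  need <- function(nm) {
    v <- metrics[[nm]]
    if (is.null(v)) stop(sprintf("missing metric '%s'", nm))
    v
  }
  rows <- list(
    list("CTV D98 >= 100%", need("ctv_d98"), 100, ">="),
    list("D0.03cc < 110% rx", need("body_d003cc_gy"), hot_limit_gy, "<"),
    list(sprintf("Bladder V14.6Gy < %g cc", if (trial == "2SMART") 25 else 15),
         need("bladder_v14_6"), if (trial == "2SMART") 25 else 15, "<"),
    list(sprintf("Bladder V20.8Gy < %g cc", if (trial == "2SMART") 10 else 5),
         need("bladder_v20_8"), if (trial == "2SMART") 10 else 5, "<"),
    list("Rectum V13Gy < 7 cc", need("rectum_v13"), 7, "<"),
    list("Rectum V17.6Gy < 4 cc", need("rectum_v17_6"), 4, "<"),
    list(sprintf("Rectum V%gGy < 1 cc", trial_rectum_high(trial)),
         need(trial_rectum_high_name(trial)), 1, "<"))
  if (trial == "2SMART") {
    rows <- c(rows, list(
      list("Urethra D0.03cc < 33.8 Gy", need("urethra_d003cc"), 33.8, "<"),
      list("Urethra D10% < 30.4 Gy", need("urethra_d10pct"), 30.4, "<")))
  }
  out <- data.frame(
    constraint = vapply(rows, `[[`, "", 1),
    value = vapply(rows, `[[`, 0, 2),
    limit = vapply(rows, `[[`, 0, 3),
    direction = vapply(rows, `[[`, "", 4))
  out$pass <- ifelse(out$direction == "<", out$value < out$limit,
                     out$value >= out$limit)
  out
}

#' Write a scoring configuration to JSON
#' @param config named list of [scoring_function()]s.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_scoring_config <- function(config, path) {
  obj <- lapply(config, function(fn) {
    list(metric = fn$metric, orientation = fn$orientation,
         breakpoints = fn$breakpoints, max_points = fn$max_points)
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a scoring configuration from JSON
#' @param path JSON file written by [write_scoring_config()] (or hand-edited).
#' @return named list of [scoring_function()]s.
#' @export
read_scoring_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(fn) {
    scoring_function(fn$metric, fn$orientation,
                     as.data.frame(fn$breakpoints), fn$max_points)
  })
}
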