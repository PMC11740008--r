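# Workflow tests run on a coarse 4 mm grid so each surrogate plan is cheap;
# the geometry (mm sizes) is unchanged.
coarse_cfg <- function(seed = 55, n = 12) {
  cohort_config(n_patients = n, shape = c(60L, 48L, 50L), spacing = c(4, 4, 4),
                seed = seed)
}

# a small but valid margin model trained on arbitrary smooth data
toy_model <- local({
  set.seed(77)
  X <- matrix(runif(12 * 7, -1, 1), 12, 7)
  Y <- cbind(X[, 1], X[, 2], X[, 3]) * 2
  NULL
})

fit_toy_model <- function() {
  set.seed(77)
  X <- matrix(runif(12 * 7, -1, 1), 12, 7)
  Y <- cbind(X[, 1], X[, 2], X[, 3]) * 2
  fit_gpr(X, Y, n_restarts = 2, seed = 1)
}

test_that("pool cardinalities are 5 at Fx1 and 10 at Fx2", {
  pat <- generate_patient(coarse_cfg(), 1001)
  model <- fit_toy_model()
  cfg <- run_config("2STAR")
  pool1 <- suppressWarnings(build_pool(1, pat$planning, model, list(), cfg))
  expect_length(pool1$plans, 5)
  labels1 <- vapply(pool1$plans, `[[`, "", "label")
  expect_equal(labels1[1], "Clinic(Fx1)")
  expect_equal(sum(grepl("^DT\\(Fx1\\)", labels1)), 4)

  pool2 <- suppressWarnings(build_pool(2, pat$fractions[[1]], model,
                                       carried = pool1$plans, cfg))
  expect_length(pool2$plans, 10)
  labels2 <- vapply(pool2$plans, `[[`, "", "label")
  expect_true(all(labels1 %in% labels2))  # carried plans keep their labels
  expect_equal(sum(grepl("Fx2", labels2)), 5)
})

test_that("plan selection takes the argmax with margin/clinical tie-breaks", {
  fake_plan <- function(label, m) {
    structure(list(label = label, margins = margin_set(m)),
              class = "proton_plan")
  }
  pool <- list(fraction = 1,
               plans = list(fake_plan("Clinic(Fx1)", 5),
                            fake_plan("DT(Fx1)", 3),
                            fake_plan("DT(Fx1)+0.5sigma", 4)))
  class(pool) <- "plan_pool"
  card <- function(total) list(scorecard = list(total = total))
  sel <- select_plan(list(card(10), card(30), card(20)), pool)
  expect_equal(sel$label, "DT(Fx1)")
  # tie: the 3 mm mean margin wins over 5 mm
  sel2 <- select_plan(list(card(30), card(30), card(10)), pool)
  expect_equal(sel2$label, "DT(Fx1)")
  # three-way tie on score and margins: the clinical plan is preferred
  pool3 <- pool
  pool3$plans[[2]]$margins <- margin_set(5)
  pool3$plans[[3]]$margins <- margin_set(5)
  sel3 <- select_plan(list(card(30), card(30), card(30)), pool3)
  expect_equal(sel3$label, "Clinic(Fx1)")
  # invariance under pool reordering
  perm <- c(3, 1, 2)
  pool_p <- pool
  pool_p$plans <- pool$plans[perm]
  sel_p <- select_plan(list(card(20), card(10), card(30)), pool_p)
  expect_equal(sel_p$label, "DT(Fx1)")
  expect_error(select_plan(list(), structure(list(plans = list()),
                                             class = "plan_pool")), "empty")
})

test_that("evaluating the pool on the planning anatomy reproduces planning scores", {
  pat <- generate_patient(coarse_cfg(), 1002)
  model <- fit_toy_model()
  cfg <- run_config("2STAR")
  pool <- suppressWarnings(build_pool(1, pat$planning, model, list(), cfg))
  ev <- evaluate_pool(pool, pat$planning, cfg)
  expect_length(ev, length(pool$plans))
  for (i in seq_along(ev)) {
    direct <- total_score(metric_bundle(pool$plans[[i]], pat$planning, "2STAR"),
                          cfg$scoring)
    expect_equal(ev[[i]]$scorecard$total, direct$total)
  }
})

test_that("the two-fraction workflow is deterministic and self-consistent", {
  ccfg <- coarse_cfg()
  pat <- generate_patient(ccfg, 1003)
  model <- fit_toy_model()
  cfg <- run_config("2STAR")
  rec1 <- suppressWarnings(run_two_fraction_workflow(pat, model, cfg))
  rec2 <- suppressWarnings(run_two_fraction_workflow(pat, model, cfg))
  expect_equal(rec1$fx1$totals, rec2$fx1$totals)
  expect_equal(rec1$fx2$totals, rec2$fx2$totals)
  expect_equal(rec1$fx1$selected, rec2$fx1$selected)
  expect_equal(rec1$cumulative$dt$scorecard$total,
               rec2$cumulative$dt$scorecard$total)
  # pool invariants and argmax property
  expect_length(rec1$fx1$totals, 5)
  expect_length(rec1$fx2$totals, 10)
  expect_true(all(vapply(rec1$fx1$labels, function(l) l %in% rec1$fx2$labels,
                         TRUE)))
  expect_equal(unname(rec1$fx1$totals[rec1$fx1$selected]),
               max(rec1$fx1$totals))
  expect_equal(unname(rec1$fx2$totals[rec1$fx2$selected]),
               max(rec1$fx2$totals))
})

test_that("cumulative evaluation is additive over the two half-doses", {
  pat <- generate_patient(coarse_cfg(), 1004)
  cfg <- run_config("2STAR")
  plan <- optimize_plan_surrogate(pat$planning, margin_set(3), cfg$rx,
                                  label = "Clinic(Fx1)")
  # same plan delivered twice on the planning anatomy: cumulative metrics
  # equal the single-plan metrics
  cum <- cumulative_evaluation(list(plan, plan), pat$planning, cfg)
  single <- metric_bundle(plan, pat$planning, "2STAR")
  expect_equal(unclass(cum$metrics), unclass(single))
  # linearity of the mean dose over the two deliveries
  plan2 <- optimize_plan_surrogate(pat$planning, margin_set(5), cfg$rx,
                                   label = "Clinic(Fx1)b")
  cum2 <- cumulative_evaluation(list(plan, plan2), pat$planning, cfg)
  m1 <- metric_bundle(plan, pat$planning, "2STAR")
  m2 <- metric_bundle(plan2, pat$planning, "2STAR")
  expect_equal(cum2$metrics$bladderneck_dmean,
               mean(c(m1$bladderneck_dmean, m2$bladderneck_dmean)))
  expect_error(cumulative_evaluation(list(plan), pat$planning, cfg),
               "missing fraction")
})

test_that("the paired cohort comparison matches the exact signed-rank law", {
  x <- c(10, 12, 9, 14, 11, 13, 8, 15, 10, 12)
  expect_equal(compare_cohort(x, x), 1)
  # all differences positive, n = 10: exact two-sided p = 2 / 2^10
  y <- x + runif(10, 0.5, 1.5)
  set.seed(40)
  y <- x + seq(0.5, 5, length.out = 10)
  expect_equal(compare_cohort(x, y), 2 / 1024, tolerance = 1e-12)
  # symmetry under swapping the groups
  set.seed(41)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(compare_cohort(a, b), compare_cohort(b, a))
  expect_error(compare_cohort(1:5, 1:6), "length mismatch")
  expect_error(compare_cohort(1:4, 2:5), "at least 5")
})
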