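w14 <- eval_window(1, 3)  # the window [1, 4)

test_that("scenario classification follows the printed branch conditions", {
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 1.5, 3.5)), w14), "3a")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 0.5, 0.8)), w14), "EXCLUDED")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 0, 4.5, 6)), w14), "4c")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 0.5, 2)), w14), "1a")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 2, 0.5, 3)), w14), "1b")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 0, 0.5, 3)), w14), "1c")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 2, 6)), w14), "2a")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 2, 2, 6)), w14), "2b")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 0, 2, 6)), w14), "2c")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 2, 2, 3)), w14), "3b")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 0, 2, 3)), w14), "3c")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 5, 7)), w14), "4a")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 2, 4.5, 5)), w14), "4b")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 0.5, 6)), w14), "5a")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 2, 0.5, 6)), w14), "5b")
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 0, 0.5, 6)), w14), "5c")
  # detection exactly at the window start: progression was (a.s.) before t
  expect_equal(classify_scenario(outcomes_table(outcome_row("a", 1, 0.5, 1)), w14), "EXCLUDED")
})

test_that("model-based weights reproduce the printed branches", {
  rf <- exponential_risk(0.2, 0)
  # absolute case / absolute control
  expect_equal(model_case_weight(outcomes_table(outcome_row("a", 1, 1.5, 3.5)), w14, rf), 1)
  expect_equal(model_control_weight(outcomes_table(outcome_row("a", 1, 1.5, 3.5)), w14, rf), 0)
  oc4 <- outcomes_table(outcome_row("a", 2, 4.5, 5))
  expect_equal(model_case_weight(oc4, w14, rf), 0)
  expect_equal(model_control_weight(oc4, w14, rf), 1)
  # treated after the window, interval starts inside it (2b): Pi(4|2)
  oc2b <- outcomes_table(outcome_row("a", 2, 2, 5))
  expect_equal(model_case_weight(oc2b, w14, rf), 1 - exp(-0.4), tolerance = 1e-12)
  # detected after the window (2a): ratio weights, complementary
  oc2a <- outcomes_table(outcome_row("a", 1, 2, 6))
  wc <- model_case_weight(oc2a, w14, rf)
  wk <- model_control_weight(oc2a, w14, rf)
  expect_equal(wc, (1 - exp(-0.4)) / (1 - exp(-0.8)), tolerance = 1e-12)
  expect_equal(wc + wk, 1, tolerance = 1e-15)
  # detected inside window, interval straddling the start (1a): no control mass
  oc1a <- outcomes_table(outcome_row("a", 1, 0.5, 2))
  expect_equal(model_control_weight(oc1a, w14, rf), 0)
  expect_gt(model_case_weight(oc1a, w14, rf), 0)
  # censored inside window (1c/3c): control weight is conditional survival
  oc3c <- outcomes_table(outcome_row("a", 0, 2, 3))
  expect_equal(model_control_weight(oc3c, w14, rf), exp(-0.2 * 2), tolerance = 1e-12)
  expect_error(model_case_weight(outcomes_table(outcome_row("a", 1, 0.5, 0.8)), w14, rf),
               "excluded")
  # a predictor assigning zero risk to an observed progression is degenerate
  expect_error(model_case_weight(oc2a, w14, exponential_risk(0, 0.1)),
               "degenerate risk interval")
})

test_that("model-based weights stay in [0,1] and scenario 2a weights sum to one", {
  for (seed in c(2, 3, 4)) {
    rc <- random_cohort(40, seed = seed)
    cohort <- weighted_cohort(rc$outcomes, w14, rc$risks, "model_based")
    expect_true(all(cohort$w_case >= 0 & cohort$w_case <= 1))
    expect_true(all(cohort$w_control >= 0 & cohort$w_control <= 1))
    in2a <- cohort$scenario == "2a"
    if (any(in2a))
      expect_equal(cohort$w_case[in2a] + cohort$w_control[in2a],
                   rep(1, sum(in2a)), tolerance = 1e-12)
    excl <- cohort$scenario == "EXCLUDED"
    expect_true(all(cohort$w_case[excl] == 0 & cohort$w_control[excl] == 0))
  }
})

test_that("reverse Kaplan-Meier matches hand calculations", {
  oc <- outcomes_table(
    outcome_row("a", 1, 0.5, 1), outcome_row("b", 0, 1.5, 2),
    outcome_row("c", 1, 2.5, 3), outcome_row("d", 0, 3.5, 4))
  G <- reverse_km(oc)
  expect_equal(G$G(3), 2 / 3, tolerance = 1e-12)
  expect_equal(G$conditional(3, 3), 1)
  expect_equal(G$G(1.9), 1)
  # no censoring events at all
  none <- reverse_km(outcomes_table(outcome_row("a", 1, 0.5, 1),
                                    outcome_row("b", 2, 1, 2)))
  expect_equal(none$G(c(0.5, 5, 50)), c(1, 1, 1))
  # everyone censored at the same time tau
  tau <- outcomes_table(outcome_row("a", 0, 1, 5), outcome_row("b", 0, 2, 5),
                        outcome_row("c", 0, 3, 5))
  Gt <- reverse_km(tau)
  expect_equal(Gt$G(4.999), 1)
  expect_equal(Gt$G(5), 0)
  expect_error(Gt$conditional(6, 5), "no censoring support")
})

test_that("IPCW weights are reciprocals of the censoring-free probability", {
  # one censoring event at time 2 with five subjects at risk: G(s>=2) = 0.8
  oc <- outcomes_table(
    outcome_row("cen", 0, 1.5, 2),
    outcome_row("c1", 1, 1.2, 3), outcome_row("c2", 1, 2, 3.9),
    outcome_row("c3", 1, 4.5, 5), outcome_row("c4", 1, 4.2, 6))
  cohort <- weighted_cohort(oc, w14, exponential_risk(0.2, 0.02), "ipcw")
  expect_equal(cohort$w_case[cohort$subject_id == "c1"], 1.25, tolerance = 1e-12)
  expect_equal(cohort$w_case[cohort$subject_id == "c2"], 1.25, tolerance = 1e-12)
  # absolute controls share the uniform weight 1/G(4|1)
  ctrl <- cohort$w_control[cohort$subject_id %in% c("c3", "c4")]
  expect_equal(ctrl, rep(1.25, 2), tolerance = 1e-12)
  # without censoring all nonzero weights are one
  rc <- degenerate_cohort(30, seed = 5)
  c2 <- weighted_cohort(rc$outcomes, w14, rc$risks, "ipcw")
  expect_true(all(c2$w_case[c2$w_case > 0] == 1))
  expect_true(all(c2$w_control[c2$w_control > 0] == 1))
  # a cohort of only partially-known subjects has no IPCW mass
  only2a <- outcomes_table(outcome_row("x", 1, 2, 6), outcome_row("y", 1, 2.5, 7))
  c3 <- weighted_cohort(only2a, w14, exponential_risk(0.2, 0), "ipcw")
  expect_true(all(c3$w_case == 0) && all(c3$w_control == 0))
  expect_error(td_auc(c3), "no cases")
})

test_that("weight audit export writes the expected columns", {
  rc <- random_cohort(12, seed = 9)
  cohort <- weighted_cohort(rc$outcomes, w14, rc$risks, "model_based")
  path <- withr::local_tempfile(fileext = ".csv")
  write_weight_audit(cohort, path)
  audit <- read.csv(path)
  expect_equal(names(audit),
               c("subject_id", "scenario", "w_case", "w_control", "approach"))
  expect_equal(unique(audit$approach), "model_based")
  expect_equal(nrow(audit), 12)
})
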