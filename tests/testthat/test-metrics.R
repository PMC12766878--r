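w14 <- eval_window(1, 3)

fake_cohort <- function(w_case, w_control, risk) {
  structure(data.frame(subject_id = paste0("f", seq_along(risk)),
                       scenario = "3a", w_case = w_case,
                       w_control = w_control, risk = risk,
                       stringsAsFactors = FALSE),
            class = c("weighted_cohort", "data.frame"),
            window = w14, approach = "model_based",
            n_at_risk = length(risk))
}

test_that("weighted sensitivity and specificity match hand ratios", {
  co <- fake_cohort(w_case = c(1, 0.5), w_control = c(0, 0), risk = c(0.8, 0.2))
  expect_equal(weighted_sensitivity(co, 0.5), 2 / 3, tolerance = 1e-12)
  expect_equal(weighted_sensitivity(co, 0), 1)
  expect_equal(weighted_sensitivity(co, 0.9), 0)
  co2 <- fake_cohort(w_case = c(0, 0), w_control = c(1, 1), risk = c(0.1, 0.9))
  expect_equal(weighted_specificity(co2, 0.5), 0.5)
  expect_equal(weighted_specificity(co2, 1 + 1e-9), 1)
  expect_error(weighted_sensitivity(co2, 0.5), "no cases")
  expect_error(weighted_specificity(co, 0.5), "no controls")
})

test_that("IPCW specificity equals the simplified unweighted proportion", {
  rc <- random_cohort(60, seed = 21)
  cohort <- weighted_cohort(rc$outcomes, w14, rc$risks, "ipcw")
  ctrl <- cohort$w_control > 0
  expect_gt(sum(ctrl), 0)
  for (c in c(0, sort(unique(cohort$risk[ctrl])), 1)) {
    expect_equal(weighted_specificity(cohort, c),
                 mean(cohort$risk[ctrl] < c), tolerance = 1e-12)
  }
})

test_that("AUC equals brute-force pairwise concordance and handles ties", {
  perfect <- fake_cohort(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0.9, 0.9, 0.1, 0.1))
  expect_equal(td_auc(perfect), 1)
  tied <- fake_cohort(c(1, 1, 0), c(0, 0, 1), c(0.4, 0.4, 0.4))
  expect_equal(td_auc(tied), 0.5)
  for (seed in c(31, 32, 33)) {
    rc <- random_cohort(20, seed = seed)
    for (ap in c("model_based", "ipcw")) {
      cohort <- weighted_cohort(rc$outcomes, w14, rc$risks, ap)
      if (sum(cohort$w_case) == 0 || sum(cohort$w_control) == 0) next
      expect_equal(td_auc(cohort), pairwise_auc(cohort), tolerance = 1e-10)
    }
  }
})

test_that("model-based Brier score matches hand arithmetic", {
  oc <- outcomes_table(outcome_row("case", 1, 1.5, 3.5),
                       outcome_row("ctrl", 2, 4.5, 5))
  risks <- list(case = exponential_risk(0.48, 0), ctrl = exponential_risk(0.035, 0))
  # Pi(4|1): case 1 - e^{-1.44} ~ 0.763..., use values actually queried
  b <- brier_model(oc, w14, risks)
  pc <- risks$case$cif(4, 1); pk <- risks$ctrl$cif(4, 1)
  expect_equal(b, ((1 - pc)^2 + pk^2) / 2, tolerance = 1e-12)
  # explicit numbers: one absolute case with Pi = 0.8, one control with 0.1
  co <- fake_cohort(c(1, 0), c(0, 1), c(0.8, 0.1))
  expect_equal(icmetrics:::brier_from_cohort(co), (0.04 + 0.01) / 2,
               tolerance = 1e-12)
  # zero-weight subjects contribute nothing
  co0 <- fake_cohort(c(1, 0, 0), c(0, 1, 0), c(0.8, 0.1, 0.5))
  expect_equal(icmetrics:::brier_from_cohort(co0), (0.04 + 0.01) / 3,
               tolerance = 1e-12)
})

test_that("IPCW Brier score applies inverse censoring weights as printed", {
  # single absolute case, Pi = 0.6, G(T+|t) = 0.5, n_t = 1 -> 0.32
  oc <- outcomes_table(outcome_row("c1", 1, 1.2, 3),
                       outcome_row("g1", 0, 1.5, 2),
                       outcome_row("pre", 0, 0.2, 0.5))
  G <- reverse_km(oc)
  expect_equal(G$conditional(3, 1), 0.5)
  rf <- list(c1 = exponential_risk(-log(1 - 0.6) / 3, 0),
             g1 = exponential_risk(0.1, 0), pre = exponential_risk(0.1, 0))
  expect_equal(rf$c1$cif(4, 1), 0.6, tolerance = 1e-12)
  b <- brier_ipcw(oc, w14, rf)
  # n_t = 2 (c1 and g1 at risk at t = 1)
  expect_equal(b, (1 - 0.6)^2 * 2 / 2, tolerance = 1e-12)
  # no absolute cases or controls: zero by construction, with a warning
  only2a <- outcomes_table(outcome_row("x", 1, 2, 6))
  expect_warning(b0 <- brier_ipcw(only2a, w14, exponential_risk(0.2, 0)),
                 "no absolute")
  expect_equal(b0, 0)
})

test_that("model and IPCW Brier coincide on a degenerate no-censoring cohort", {
  rc <- degenerate_cohort(40, seed = 8)
  expect_equal(brier_model(rc$outcomes, w14, rc$risks),
               brier_ipcw(rc$outcomes, w14, rc$risks), tolerance = 1e-9)
})

test_that("EPCE closed forms and quadrature agree", {
  # control past the window under all-cause hazard 0.1: -log F2 = 0.3
  oc <- outcomes_table(outcome_row("ctrl", 0, 4.5, 6))
  rf <- exponential_risk(0, 0.1)
  expect_equal(epce_model(oc, w14, rf), 0.3, tolerance = 1e-10)
  # F1 via Simpson vs an independent adaptive quadrature
  oc1 <- outcomes_table(outcome_row("case", 1, 0.5, 3))
  rfe <- exponential_risk(0.25, 0.05)
  got <- epce_model(oc1, w14, rfe)
  F1 <- integrate(function(s) rfe$cif(s, 1) - rfe$cif(1, 1), 1, 3,
                  rel.tol = 1e-10)$value
  expect_equal(got, -log(F1), tolerance = 1e-6)
  # mean invariance: duplicated subject leaves the estimate unchanged
  oc2 <- outcomes_table(outcome_row("a", 1, 0.5, 3), outcome_row("b", 1, 0.5, 3))
  expect_equal(epce_model(oc2, w14, rfe), got, tolerance = 1e-12)
  # the literal double-log variant is untenable whenever p < 1: its inner
  # log is negative, which is exactly why the single-log form is the default
  expect_error(epce_model(oc, w14, rf, double_log = TRUE),
               "non-positive predictive probability")
  # a predictor with no progression mass cannot explain a detection
  expect_error(epce_model(oc1, w14, exponential_risk(0, 0.1)),
               "non-positive predictive probability")
})

test_that("reference metrics use latent truth with indicator weights", {
  oc <- outcomes_table(
    outcome_row("case", 1, 1.5, 3.5, true_t_prg = 2.5, true_t_trt = Inf),
    outcome_row("ctrl", 0, 3.5, 6, true_t_prg = Inf, true_t_trt = Inf),
    outcome_row("mixed", 2, 1.5, 2.5, true_t_prg = 3, true_t_trt = 2.5))
  risks <- list(case = exponential_risk(0.5, 0),
                ctrl = exponential_risk(0.01, 0),
                mixed = exponential_risk(0.2, 0.2))
  rep <- reference_metrics(oc, w14, risks)
  # treated before progression, both in window: neither case nor control
  expect_equal(rep$n_at_risk, 3)
  expect_equal(rep$n_absolute_cases, 1)
  expect_equal(rep$n_absolute_controls, 1)
  expect_equal(rep$auc, 1)
  pc <- risks$case$cif(4, 1); pk <- risks$ctrl$cif(4, 1)
  expect_equal(rep$brier, ((1 - pc)^2 + pk^2) / 3, tolerance = 1e-12)
  expect_error(reference_metrics(outcomes_table(outcome_row("x", 1, 1, 3)),
                                 w14, exponential_risk(0.2, 0)),
               "require true_t_prg")
})

test_that("naive metrics equal the reference when intervals are degenerate", {
  rc <- degenerate_cohort(50, seed = 12)
  nv <- naive_metrics(rc$outcomes, w14, rc$risks)
  ref <- reference_metrics(rc$outcomes, w14, rc$risks, epce = FALSE)
  expect_equal(nv$auc, ref$auc, tolerance = 1e-9)
  expect_equal(nv$brier, ref$brier, tolerance = 1e-9)
  # without any detection inside the window the naive case set is empty
  late <- outcomes_table(outcome_row("a", 1, 4.5, 6), outcome_row("b", 0, 5, 7))
  expect_error(naive_metrics(late, w14, exponential_risk(0.1, 0)), "no cases")
})

test_that("all four approaches coincide in the no-censoring limit", {
  rc <- degenerate_cohort(60, seed = 14)
  rep <- evaluate_accuracy(rc$outcomes, w14, rc$risks,
                           approaches = c("model_based", "ipcw", "naive",
                                          "reference"), epce = FALSE)
  expect_lt(max(rep$auc) - min(rep$auc), 1e-6)
  expect_lt(max(rep$brier) - min(rep$brier), 1e-6)
})

test_that("adding noise to predicted risks does not improve reference AUC", {
  rc <- degenerate_cohort(80, seed = 17)
  base <- reference_metrics(rc$outcomes, w14, rc$risks, epce = FALSE)$auc
  set.seed(99)
  noisy_aucs <- replicate(200, {
    risks_n <- lapply(rc$risks, function(rf) {
      eps <- runif(1, -0.5, 0.5)
      risk_function(
        cif = function(s, t0) pmin(pmax(rf$cif(s, t0) * (1 + eps), 0), 1),
        surv = function(s, t0) pmin(rf$surv(s, t0), 1 - pmin(pmax(rf$cif(s, t0) * (1 + eps), 0), 1)))
    })
    names(risks_n) <- names(rc$risks)
    reference_metrics(rc$outcomes, w14, risks_n, epce = FALSE)$auc
  })
  expect_lte(mean(noisy_aucs), base + 1e-12)
})

test_that("the true risk model attains the lowest EPCE on average", {
  rates <- seq(0.05, 0.3, length.out = 6)
  set.seed(42)
  diffs <- replicate(25, {
    rows <- lapply(seq_along(rates), function(i) {
      lam <- rates[i]
      t_prg <- rexp(1, lam)
      if (t_prg < 10) outcome_row(paste0("s", i), 1, max(t_prg - runif(1, 0, 1), 0),
                                  t_prg + runif(1, 0, 1))
      else outcome_row(paste0("s", i), 0, 9, 10)
    })
    oc <- subject_outcomes(do.call(rbind, rows))
    truth <- lapply(rates, function(l) exponential_risk(l, 0))
    wrong <- lapply(rates, function(l) exponential_risk(l * 3 + 0.2, 0))
    names(truth) <- names(wrong) <- oc$subject_id
    suppressWarnings(epce_model(oc, w14, wrong) - epce_model(oc, w14, truth))
  })
  expect_gt(mean(diffs), 0)
})

test_that("metric reports serialise to CSV and JSON", {
  rc <- random_cohort(40, seed = 51)
  rep <- suppressWarnings(
    evaluate_accuracy(rc$outcomes, w14, rc$risks,
                      approaches = c("model_based", "naive")))
  expect_equal(rep$approach, c("model_based", "naive"))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, csv)
  back <- read.csv(csv)
  expect_equal(back$auc, rep$auc, tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, js)
  expect_equal(jsonlite::read_json(js)[[1]]$auc, rep$auc[1], tolerance = 1e-9)
})
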