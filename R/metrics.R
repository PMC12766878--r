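#' Weighted time-dependent sensitivity
#'
#' The weighted fraction of case mass whose predicted window-end risk
#' \eqn{\Pi(t+dt \mid t)} is at or above the threshold `c`:
#' \eqn{\sum_i I\{\Pi_i \ge c\} w_i / \sum_i w_i} with `w` the case weights
#' of the cohort (model-based probabilities of being a case, or unnormalised
#' IPCW weights over the absolute cases).
#'
#' @param cohort a [weighted_cohort()].
#' @param c threshold in `[0, 1]`.
#' @return Estimated sensitivity.
#' @export
weighted_sensitivity <- function(cohort, c) {
  w <- cohort$w_case
  if (sum(w) <= 0) stop("no cases in window: all case weights are zero")
  sum((cohort$risk >= c) * w, na.rm = TRUE) / sum(w)
}

#' Weighted time-dependent specificity
#'
#' The weighted fraction of control mass with predicted risk below `c`.
#' For the IPCW approach the control weights are constant across absolute
#' controls, so the weighted form reduces to the plain proportion.
#'
#' @inheritParams weighted_sensitivity
#' @return Estimated specificity.
#' @export
weighted_specificity <- function(cohort, c) {
  w <- cohort$w_control
  if (sum(w) <= 0) stop("no controls: all control weights are zero")
  sum((cohort$risk < c) * w, na.rm = TRUE) / sum(w)
}

#' ROC curve over the window
#'
#' Sensitivity and one-minus-specificity traced over the threshold grid of
#' sorted unique predicted risks (sensitivity and specificity are step
#' functions that only change at observed risk values), augmented with
#' sentinels so the curve reaches (0,0) and (1,1).
#'
#' @inheritParams weighted_sensitivity
#' @return Data frame with decreasing `threshold`, `sens`, `one_minus_spec`.
#' @export
roc_curve <- function(cohort) {
  keep <- !is.na(cohort$risk) & (cohort$w_case > 0 | cohort$w_control > 0)
  r <- cohort$risk[keep]
  wc <- cohort$w_case[keep]; wk <- cohort$w_control[keep]
  if (sum(wc) <= 0) stop("no cases in window: all case weights are zero")
  if (sum(wk) <= 0) stop("no controls: all control weights are zero")
  thr <- c(Inf, sort(unique(r), decreasing = TRUE))
  sens <- vapply(thr, function(cc) sum(wc[r >= cc]) / sum(wc), 0)
  oms <- vapply(thr, function(cc) sum(wk[r >= cc]) / sum(wk), 0)
  data.frame(threshold = thr, sens = sens, one_minus_spec = oms)
}

#' Time-dependent AUC
#'
#' Integrates the ROC curve \eqn{\int_0^1 sen \, d(1 - spe)} by the
#' trapezoidal rule over the threshold grid of [roc_curve()].  With step
#' functions changing only at observed risk values this equals the weighted
#' pairwise concordance
#' \eqn{\sum_{i,j} w^{case}_i w^{ctrl}_j \{I(\Pi_i > \Pi_j) +
#' \tfrac12 I(\Pi_i = \Pi_j)\} / (\sum_i w^{case}_i)(\sum_j w^{ctrl}_j)},
#' ties counting one half.
#'
#' @inheritParams weighted_sensitivity
#' @return AUC in `[0, 1]`.
#' @export
td_auc <- function(cohort) {
  roc <- roc_curve(cohort)
  x <- roc$one_minus_spec; y <- roc$sens
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# shared skeleton for indicator-weight cohorts (reference / naive)
make_cohort <- function(outcomes, window, risk, w_case, w_control, scen,
                        approach, n_at_risk) {
  t2 <- window$t + window$dt
  pr <- vapply(seq_len(nrow(outcomes)), function(i) {
    if (w_case[i] > 0 || w_control[i] > 0 || scen[i] != "EXCLUDED")
      risk_for(risk, outcomes$subject_id[i])$cif(t2, window$t)
    else NA_real_
  }, 0)
  structure(
    data.frame(subject_id = outcomes$subject_id, scenario = scen,
               w_case = w_case, w_control = w_control, risk = pr,
               stringsAsFactors = FALSE),
    class = c("weighted_cohort", "data.frame"),
    window = window, approach = approach, n_at_risk = n_at_risk)
}

#' Model-based Brier score
#'
#' \deqn{\widehat{BS}(t+dt, t) = \frac{1}{n_t} \sum_{i \in risk set}
#'   (1 - \Pi_i)^2 W_i + (0 - \Pi_i)^2 W'_i,}
#' with \eqn{\Pi_i = \Pi_i(t+dt|t)}, model-based case/control weights
#' \eqn{W_i, W'_i}, and \eqn{n_t} the number of subjects at risk at `t`.
#' The per-subject weights need not sum to one (e.g. censored subjects), and
#' the estimator divides by `n_t` regardless; `normalized = TRUE` divides by
#' the total weight instead (sensitivity analysis only).
#'
#' @param outcomes a [subject_outcomes()] table.
#' @param window an [eval_window()].
#' @param risk a [risk_function()] or named list of per-subject ones.
#' @param normalized divide by total weight instead of `n_t`.
#' @return Brier score estimate.
#' @export
brier_model <- function(outcomes, window, risk, normalized = FALSE) {
  cohort <- weighted_cohort(outcomes, window, risk, "model_based")
  brier_from_cohort(cohort, normalized)
}

brier_from_cohort <- function(cohort, normalized = FALSE) {
  n_t <- attr(cohort, "n_at_risk")
  if (n_t == 0) stop("empty risk set at window start")
  terms <- cohort$w_case * (1 - cohort$risk)^2 + cohort$w_control * cohort$risk^2
  denom <- if (normalized) sum(cohort$w_case + cohort$w_control) else n_t
  sum(terms, na.rm = TRUE) / denom
}

#' IPCW Brier score
#'
#' \deqn{\widehat{BS}(t+dt, t) = \frac{1}{n_t}\Big[
#'   \sum_{i: abs. case} (1-\Pi_i)^2 / G(T_i^{+}|t) +
#'   \sum_{i: abs. control} \Pi_i^2 / G(t+dt|t)\Big],}
#' using only the absolute cases and absolute controls, inversely weighted by
#' the reverse Kaplan-Meier censoring-free probability [reverse_km()].
#'
#' @inheritParams brier_model
#' @param G optional [reverse_km()] estimate.
#' @return Brier score estimate; 0 (with a warning) when there are neither
#'   absolute cases nor absolute controls.
#' @export
brier_ipcw <- function(outcomes, window, risk, G = NULL) {
  cohort <- weighted_cohort(outcomes, window, risk, "ipcw", G = G)
  if (all(cohort$w_case == 0) && all(cohort$w_control == 0))
    warning("no absolute cases or controls in the window; IPCW Brier is 0 by construction")
  brier_from_cohort(cohort)
}

#' Model-based expected predictive cross-entropy (EPCE)
#'
#' The mean, over subjects at risk at `t`, of the negative log predictive
#' probability of the observed window outcome:
#' \deqn{\widehat{EPCE}(t+dt, t) = \frac{1}{n_t} \sum_i
#'   -\log\{\tilde\delta^{(1)}_i F_{1i} + \tilde\delta^{(2)}_i F_{2i}\},}
#' where, with \eqn{\tilde T^{(1)} = \max(T^{-}, t)} and \eqn{\tilde T^{(2)}}
#' the window-truncated terminal time (detection, treatment, or `t+dt` when
#' censored),
#' \eqn{F_1 = \int_{\tilde T^{(1)}}^{\tilde T^{(2)}}
#'   \{\Pi(s|t) - \Pi(\tilde T^{(1)}|t)\}\, ds}
#' integrates the conditional probability of progression inside the risk
#' interval, and \eqn{F_2 = S(t+dt|t)} is the conditional overall survival.
#' The indicators are \eqn{\tilde\delta^{(1)} = I(T^{-} < t+dt)} (on the
#' risk set) and \eqn{\tilde\delta^{(2)} = I(T^{-} \ge t+dt, \delta = 0)}.
#' The first is strict so that a risk interval starting exactly at the window
#' end does not contribute an empty \eqn{F_1} integral.  Subjects with a
#' progression or treatment exit whose last negative examination falls at or
#' after `t+dt` then have both indicators zero; the window contains no
#' information on them, so they are skipped with a warning and excluded from
#' the numerator but still counted in \eqn{n_t}.
#'
#' `double_log = TRUE` retains, for audit, the literal double-log variant
#' \eqn{-\log\log(\cdot)} sometimes displayed for this estimator; the default
#' single-log form is the proper scoring rule.
#'
#' @inheritParams brier_model
#' @param double_log audit switch, see Details.
#' @param quad_points number of (odd) Simpson quadrature points for
#'   \eqn{F_1}.
#' @return EPCE estimate (lower is better; can be negative because
#'   \eqn{F_1} integrates over time and may exceed one).
#' @export
epce_model <- function(outcomes, window, risk, double_log = FALSE,
                       quad_points = 101) {
  t <- window$t; t2 <- window$t + window$dt
  term <- terminal_time(outcomes)
  atrisk <- ifelse(outcomes$delta == 1, term > t, term >= t)
  n_t <- sum(atrisk)
  if (n_t == 0) stop("empty risk set at window start")
  total <- 0; skipped <- 0
  for (i in which(atrisk)) {
    tn <- outcomes$t_neg[i]; d <- outcomes$delta[i]
    d1 <- as.numeric(tn < t2)
    d2 <- as.numeric(tn >= t2 && d == 0)
    if (d1 == 0 && d2 == 0) { skipped <- skipped + 1; next }
    rf <- risk_for(risk, outcomes$subject_id[i])
    T1 <- max(tn, t)
    T2 <- if (d == 1) min(outcomes$t_pos[i], t2)
          else if (d == 2) min(outcomes$t_trt[i], t2)
          else t2
    F1 <- if (d1 > 0 && T2 > T1) {
      s <- seq(T1, T2, length.out = quad_points)
      f <- rf$cif(s, t) - rf$cif(T1, t)
      simpson(s, f)
    } else 0
    F2 <- if (d2 > 0) rf$surv(t2, t) else 0
    p <- d1 * F1 + d2 * F2
    if (double_log) p <- log(p)
    if (p <= 0)
      stop("non-positive predictive probability for subject '",
           outcomes$subject_id[i], "' (log argument ", p, ")")
    total <- total - log(p)
  }
  if (skipped > 0)
    warning(skipped, " subject(s) with a progression/treatment exit and no ",
            "examination inside the window carry no predictive probability; skipped")
  total / n_t
}

# composite Simpson on a uniform grid (odd number of points)
simpson <- function(x, y) {
  n <- length(x)
  if (n < 3) return(sum(diff(x) * (y[-n] + y[-1]) / 2))
  if (n %% 2 == 0) { # fall back to trapezoid on last panel
    return(simpson(x[1:(n - 1)], y[1:(n - 1)]) +
             (x[n] - x[n - 1]) * (y[n] + y[n - 1]) / 2)
  }
  h <- (x[n] - x[1]) / (n - 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
             2 * sum(y[seq(3, n - 2, 2)]))
}

#' Reference metrics from latent true event times
#'
#' The no-censoring ideal: with the latent progression and treatment times
#' known, a subject at risk at `t` is a case iff the progression time falls
#' in `[t, t+dt)` and precedes treatment, and a control iff neither event
#' occurs before `t+dt`.  AUC and Brier score use these 0/1 indicator weights
#' with the same predicted risks as the other approaches.  The reference EPCE
#' uses the continuous-observation contributions: cases score the conditional
#' cause-specific density \eqn{-\log f(T^{*}|t)} (numerical derivative of the
#' CIF), controls \eqn{-\log S(t+dt|t)}; subjects treated inside the window
#' are known to be neither and are skipped from the numerator (counted in
#' \eqn{n_t}), mirroring [epce_model()].
#'
#' @inheritParams brier_model
#' @param epce compute the reference EPCE as well.
#' @return A `metric_report` data frame row; see [evaluate_accuracy()].
#' @export
reference_metrics <- function(outcomes, window, risk, epce = TRUE) {
  if (any(is.na(outcomes$true_t_prg)) || any(is.na(outcomes$true_t_trt)))
    stop("reference metrics require true_t_prg and true_t_trt for every subject ",
         "(use Inf for events beyond the horizon)")
  t <- window$t; t2 <- window$t + window$dt
  tp <- outcomes$true_t_prg; tt <- outcomes$true_t_trt
  atrisk <- pmin(tp, tt) >= t
  case <- atrisk & tp >= t & tp < t2 & tp < tt
  ctrl <- atrisk & pmin(tp, tt) >= t2
  n_t <- sum(atrisk)
  if (n_t == 0) stop("empty risk set at window start")
  scen <- ifelse(atrisk, ifelse(case, "3a", ifelse(ctrl, "4a", "3b")), "EXCLUDED")
  cohort <- make_cohort(outcomes, window, risk, as.numeric(case),
                        as.numeric(ctrl), scen, "reference", n_t)
  auc <- td_auc(cohort)
  brier <- brier_from_cohort(cohort)
  ep <- NA_real_
  if (epce) {
    h <- 1e-4; total <- 0
    for (i in which(atrisk)) {
      rf <- risk_for(risk, outcomes$subject_id[i])
      if (case[i]) {
        s <- tp[i]
        f <- (rf$cif(min(s + h, t2 + 10), t) - rf$cif(max(s - h, t), t)) /
          (min(s + h, t2 + 10) - max(s - h, t))
        if (f <= 0) stop("zero predicted density at the true event time of ",
                         "subject '", outcomes$subject_id[i], "'")
        total <- total - log(f)
      } else if (ctrl[i]) {
        total <- total - log(rf$surv(t2, t))
      } # treated inside window: skipped
    }
    ep <- total / n_t
  }
  metric_report("reference", window, auc, brier, ep, n_t,
                sum(case), sum(ctrl))
}

#' Naive metrics ignoring interval censoring
#'
#' Treats the detection time \eqn{T^{+}} as the exact progression time: cases
#' are subjects detected inside the window (`t <= t_pos < t+dt`), and treated
#' or censored subjects are handled as right-censored at their observed
#' terminal times through the usual IPCW machinery (reverse Kaplan-Meier with
#' both censoring and treatment exits as "censoring events").  Controls are
#' subjects whose observed terminal time reaches `t+dt`.
#'
#' @inheritParams brier_model
#' @param G optional [reverse_km()] with `event_codes = c(0, 2)`.
#' @return A `metric_report` data frame row.
#' @export
naive_metrics <- function(outcomes, window, risk, G = NULL) {
  t <- window$t; t2 <- window$t + window$dt
  term <- terminal_time(outcomes)
  atrisk <- term >= t
  n_t <- sum(atrisk)
  if (n_t == 0) stop("empty risk set at window start")
  if (is.null(G)) G <- reverse_km(outcomes, event_codes = c(0, 2))
  case <- atrisk & outcomes$delta == 1 & outcomes$t_pos >= t & outcomes$t_pos < t2
  ctrl <- atrisk & term >= t2
  if (!any(case)) stop("no cases in window: no detections inside [t, t+dt)")
  w_case <- numeric(nrow(outcomes)); w_ctrl <- numeric(nrow(outcomes))
  for (i in which(case)) w_case[i] <- 1 / G$conditional(outcomes$t_pos[i], t)
  if (any(ctrl)) w_ctrl[ctrl] <- 1 / G$conditional(t2, t)
  scen <- ifelse(atrisk, ifelse(case, "3a", ifelse(ctrl, "4a", "3c")), "EXCLUDED")
  cohort <- make_cohort(outcomes, window, risk, w_case, w_ctrl, scen,
                        "naive", n_t)
  metric_report("naive", window, td_auc(cohort), brier_from_cohort(cohort),
                NA_real_, n_t, sum(case), sum(ctrl))
}

metric_report <- function(approach, window, auc, brier, epce, n_at_risk,
                          n_abs_cases = NA_integer_, n_abs_controls = NA_integer_) {
  structure(data.frame(approach = approach, t = window$t, dt = window$dt,
                       auc = auc, brier = brier, epce = epce,
                       n_at_risk = n_at_risk,
                       n_absolute_cases = n_abs_cases,
                       n_absolute_controls = n_abs_controls,
                       stringsAsFactors = FALSE),
            class = c("metric_report", "data.frame"))
}

#' Evaluate predictive accuracy over a window
#'
#' One-stop evaluation: computes AUC, Brier score and (model-based and
#' reference only) EPCE for the requested approaches and returns them as one
#' tidy report table.
#'
#' @inheritParams brier_model
#' @param approaches subset of `"model_based"`, `"ipcw"`, `"naive"`,
#'   `"reference"` (the latter requires latent truth columns).
#' @param epce compute EPCE where the approach supports it.
#' @return A `metric_report` data frame, one row per approach, with columns
#'   `approach`, `t`, `dt`, `auc`, `brier`, `epce`, `n_at_risk`,
#'   `n_absolute_cases`, `n_absolute_controls`.
#' @export
evaluate_accuracy <- function(outcomes, window, risk,
                              approaches = c("model_based", "ipcw"),
                              epce = TRUE) {
  approaches <- match.arg(approaches,
                          c("model_based", "ipcw", "naive", "reference"),
                          several.ok = TRUE)
  t2 <- window$t + window$dt
  rows <- lapply(approaches, function(ap) {
    if (ap == "model_based") {
      cohort <- weighted_cohort(outcomes, window, risk, "model_based")
      abs_case <- sum(cohort$scenario == "3a")
      abs_ctrl <- sum(cohort$scenario %in% c("4a", "4b", "4c"))
      ep <- if (epce) epce_model(outcomes, window, risk) else NA_real_
      metric_report("model_based", window, td_auc(cohort),
                    brier_from_cohort(cohort), ep,
                    attr(cohort, "n_at_risk"), abs_case, abs_ctrl)
    } else if (ap == "ipcw") {
      cohort <- weighted_cohort(outcomes, window, risk, "ipcw")
      metric_report("ipcw", window, td_auc(cohort), brier_from_cohort(cohort),
                    NA_real_, attr(cohort, "n_at_risk"),
                    sum(cohort$w_case > 0), sum(cohort$w_control > 0))
    } else if (ap == "naive") {
      naive_metrics(outcomes, window, risk)
    } else {
      reference_metrics(outcomes, window, risk, epce = epce)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Write a metric report
#'
#' @param report a `metric_report` from [evaluate_accuracy()].
#' @param path output path; `.json` writes JSON (requires jsonlite),
#'   anything else CSV.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  }
  invisible(path)
}
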