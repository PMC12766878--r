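#' Classify a subject's risk interval relative to the window
#'
#' Each subject still under observation at the window start is assigned one of
#' fifteen scenario codes describing how the progression risk interval
#' `(t_neg, terminal]` sits relative to the window `[t, t+dt)`.  The digit
#' encodes the interval position (1: straddles the window start; 2: starts
#' inside the window, ends after it; 3: lies inside the window; 4: lies
#' entirely after the window; 5: straddles the whole window) and the letter
#' the terminal observation (a: primary event detected, b: early treatment,
#' c: right-censored).  Subjects whose follow-up ends before `t` are coded
#' `"EXCLUDED"` and drop out of every metric; so is a subject whose positive
#' examination falls exactly at `t`, since their risk interval `(t_neg, t]`
#' places the latent progression time (almost surely) before the window.
#'
#' Boundary convention: the window is half-open, `[t, t+dt)`; ties of the
#' risk-interval bounds with `t` or `t+dt` are resolved so that `t_neg <= t`
#' goes to groups 1/5 and a terminal time exactly at `t+dt` goes to the
#' "after the window" branch (groups 2/5), consistent with the half-open
#' window.
#'
#' @param outcomes a [subject_outcomes()] table (one or more rows).
#' @param window an [eval_window()].
#' @return Character vector of scenario codes, one per subject.
#' @export
classify_scenario <- function(outcomes, window) {
  t <- window$t; t2 <- window$t + window$dt
  term <- terminal_time(outcomes)
  letter <- c("c", "a", "b")[outcomes$delta + 1]
  code <- character(nrow(outcomes))
  for (i in seq_len(nrow(outcomes))) {
    tn <- outcomes$t_neg[i]
    code[i] <-
      if (term[i] < t || (outcomes$delta[i] == 1 && term[i] <= t)) "EXCLUDED"
      else if (tn > t2) paste0("4", letter[i])
      else if (tn > t) {                      # risk interval starts inside window
        if (term[i] < t2) paste0("3", letter[i]) else paste0("2", letter[i])
      } else {                                # risk interval starts at/before t
        if (term[i] < t2) paste0("1", letter[i]) else paste0("5", letter[i])
      }
  }
  code
}

# Pi(b | t_neg) and friends for one subject, via the risk-function contract.
# All model-based weights condition on the last negative examination time.
model_weights_one <- function(tn, term, scen, window, rf) {
  t <- window$t; t2 <- window$t + window$dt
  cif <- function(s) rf$cif(s, tn)
  denom_pos <- function() {
    d <- cif(term)
    if (d <= 0)
      stop("degenerate risk interval: predictor assigns zero progression risk ",
           "to an observed progression in (", tn, ", ", term, "]")
    d
  }
  w_case <- switch(scen,
    "1a" = (denom_pos() - cif(t)) / denom_pos(),
    "1b" = cif(term) - cif(t),
    "1c" = cif(t2) - cif(t),
    "2a" = cif(t2) / denom_pos(),
    "2b" = cif(t2),
    "2c" = cif(t2),
    "3a" = 1,
    "3b" = cif(term),
    "3c" = cif(t2),
    "5a" = (cif(t2) - cif(t)) / denom_pos(),
    "5b" = cif(t2) - cif(t),
    "5c" = cif(t2) - cif(t),
    0)                                        # 4a/4b/4c
  w_ctrl <- switch(scen,
    "1c" = rf$surv(t2, tn),
    "2a" = (denom_pos() - cif(t2)) / denom_pos(),
    "2b" = 1 - cif(t2),
    "2c" = 1 - cif(t2),
    "3c" = rf$surv(t2, tn),
    "4a" = 1, "4b" = 1, "4c" = 1,
    "5a" = (denom_pos() - cif(t2)) / denom_pos(),
    "5b" = 1 - cif(t2),
    "5c" = 1 - cif(t2),
    0)                                        # 1a/1b/3a/3b
  # clip numerical noise only
  clip <- function(w) min(max(w, 0), 1)
  c(case = clip(w_case), control = clip(w_ctrl))
}

#' Model-based case weight
#'
#' The probability, under the prediction model itself, that the subject is a
#' case for the window, i.e. that the latent progression time falls in
#' `[t, t+dt)` (and before the competing event), given what was observed.
#' The weight is a piecewise expression in the model's conditional cumulative
#' incidence \eqn{\Pi(\cdot \mid t_{neg})}, with the branch selected by
#' [classify_scenario()]: e.g. an interval straddling the window start with
#' detection inside the window (1a) gets
#' \eqn{\{\Pi(T^{+}|T^{-}) - \Pi(t|T^{-})\}/\Pi(T^{+}|T^{-})}, an absolute
#' case (3a) gets 1, and an interval entirely after the window (4a/b/c)
#' gets 0.
#'
#' @param outcome single-row [subject_outcomes()] table.
#' @param window an [eval_window()].
#' @param risk a [risk_function()] (or named list keyed by subject id).
#' @return Weight in `[0, 1]`.
#' @export
model_case_weight <- function(outcome, window, risk) {
  scen <- classify_scenario(outcome, window)
  if (scen == "EXCLUDED") stop("subject is excluded (follow-up ends before t)")
  rf <- risk_for(risk, outcome$subject_id[1])
  unname(model_weights_one(outcome$t_neg[1], terminal_time(outcome)[1],
                           scen, window, rf)["case"])
}

#' Model-based control weight
#'
#' The probability that the subject survives the window event-free, under the
#' prediction model.  Complements [model_case_weight()]; for scenario 2a the
#' two weights add up to one exactly, because such a subject is either a case
#' or a control.  Censored-in-window subjects (1c/3c) get the conditional
#' overall survival \eqn{S(t+dt \mid T^{-})}; absolute controls (4a/b/c)
#' get 1.
#'
#' @inheritParams model_case_weight
#' @return Weight in `[0, 1]`.
#' @export
model_control_weight <- function(outcome, window, risk) {
  scen <- classify_scenario(outcome, window)
  if (scen == "EXCLUDED") stop("subject is excluded (follow-up ends before t)")
  rf <- risk_for(risk, outcome$subject_id[1])
  unname(model_weights_one(outcome$t_neg[1], terminal_time(outcome)[1],
                           scen, window, rf)["control"])
}

#' Reverse Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates \eqn{G(s)}, the probability of being censoring-free at `s`, by
#' the Kaplan-Meier estimator with the roles of event and censoring swapped:
#' right-censoring times (`delta = 0`) are the "events" and observed
#' progression/treatment terminal times are censored observations.  At tied
#' times, subjects with an observed event at `s` remain in the risk set for
#' the censoring "event" at `s` (they were still at risk of being censored
#' then).  The conditional form is `G(s | t) = G(s) / G(t)`.
#'
#' @param outcomes a [subject_outcomes()] table.
#' @param event_codes event codes treated as censoring "events" (default
#'   `0`; the naive right-censoring view uses `c(0, 2)`).
#' @return An object of class `censoring_survival`: callable step function
#'   `G(s)` (right-continuous, `G(0) = 1`), with `$conditional(s, t)` giving
#'   `G(s|t)` and erroring when `G(t) = 0` ("no censoring support").
#' @export
reverse_km <- function(outcomes, event_codes = 0) {
  if (nrow(outcomes) == 0) stop("at least one subject required")
  time <- terminal_time(outcomes)
  status <- as.integer(outcomes$delta %in% event_codes)
  if (sum(status) == 0) {
    G <- function(s) rep(1, length(s))
  } else {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1)
    steps <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
    G <- function(s) steps(s)
  }
  structure(list(
    G = G,
    conditional = function(s, t) {
      gt <- G(t)
      if (any(gt <= 0))
        stop("no censoring support: G(t) = 0 at conditioning time ", t)
      G(s) / gt
    }
  ), class = "censoring_survival")
}

#' @export
print.censoring_survival <- function(x, ...) {
  cat("<censoring_survival> reverse Kaplan-Meier G(s)\n")
  invisible(x)
}

#' Build a weighted cohort for one window
#'
#' Assembles, for every subject, the scenario code, the case and control
#' weights under the requested approach, and the predicted risk at the window
#' end \eqn{\Pi(t+dt \mid t)} used as the classification score.  Model-based
#' weights come from the subject's own predicted curves
#' ([model_case_weight()], [model_control_weight()]); IPCW weights are the
#' inverse censoring-free probabilities \eqn{1/G(T^{+}|t)} for absolute cases
#' (`t_neg >= t`, detection before `t+dt`) and \eqn{1/G(t+dt|t)} for absolute
#' controls (`t_neg > t+dt`), all other subjects receiving zero weight.
#' IPCW weights are stored unnormalised (>= 1); each metric's ratio does the
#' normalisation.
#'
#' @param outcomes a [subject_outcomes()] table.
#' @param window an [eval_window()].
#' @param risk a [risk_function()] shared by all subjects, or a named list of
#'   per-subject risk functions keyed by `subject_id`.
#' @param approach `"model_based"` or `"ipcw"`.
#' @param G optional [reverse_km()] estimate; computed from `outcomes` when
#'   needed and not supplied.
#' @return A data frame of class `weighted_cohort` with columns
#'   `subject_id`, `scenario`, `w_case`, `w_control`, `risk`; attributes
#'   `window`, `approach`, `n_at_risk`.
#' @export
weighted_cohort <- function(outcomes, window, risk,
                            approach = c("model_based", "ipcw"), G = NULL) {
  approach <- match.arg(approach)
  t <- window$t; t2 <- window$t + window$dt
  scen <- classify_scenario(outcomes, window)
  atrisk <- scen != "EXCLUDED"
  n <- nrow(outcomes)
  w_case <- numeric(n); w_ctrl <- numeric(n); pr <- rep(NA_real_, n)
  term <- terminal_time(outcomes)
  for (i in which(atrisk)) {
    rf <- risk_for(risk, outcomes$subject_id[i])
    pr[i] <- rf$cif(t2, t)
  }
  if (approach == "model_based") {
    for (i in which(atrisk)) {
      rf <- risk_for(risk, outcomes$subject_id[i])
      w <- model_weights_one(outcomes$t_neg[i], term[i], scen[i], window, rf)
      w_case[i] <- w["case"]; w_ctrl[i] <- w["control"]
    }
  } else {
    if (is.null(G)) G <- reverse_km(outcomes)
    abs_case <- atrisk & outcomes$delta == 1 & outcomes$t_neg >= t &
      outcomes$t_pos < t2
    abs_ctrl <- atrisk & outcomes$t_neg > t2
    for (i in which(abs_case)) w_case[i] <- 1 / G$conditional(outcomes$t_pos[i], t)
    if (any(abs_ctrl)) w_ctrl[abs_ctrl] <- 1 / G$conditional(t2, t)
  }
  out <- data.frame(subject_id = outcomes$subject_id, scenario = scen,
                    w_case = w_case, w_control = w_ctrl, risk = pr,
                    stringsAsFactors = FALSE)
  structure(out, class = c("weighted_cohort", "data.frame"),
            window = window, approach = approach, n_at_risk = sum(atrisk))
}

#' Export a weight audit table
#'
#' Writes `subject_id`, `scenario`, `w_case`, `w_control`, `approach` to CSV
#' for visual audit of the per-subject weights.
#'
#' @param cohort a [weighted_cohort()].
#' @param path CSV file path.
#' @export
write_weight_audit <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$approach <- attr(cohort, "approach")
  utils::write.csv(df[, c("subject_id", "scenario", "w_case", "w_control",
                          "approach")], path, row.names = FALSE)
  invisible(path)
}
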