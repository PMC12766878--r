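# One outcome row; unused terminal columns stay NA.
outcome_row <- function(id, delta, t_neg, term, true_t_prg = NA, true_t_trt = NA) {
  data.frame(subject_id = id, t_neg = t_neg,
             t_pos = if (delta == 1) term else NA_real_,
             t_trt = if (delta == 2) term else NA_real_,
             t_cen = if (delta == 0) term else NA_real_,
             delta = delta, true_t_prg = true_t_prg, true_t_trt = true_t_trt,
             stringsAsFactors = FALSE)
}

outcomes_table <- function(...) subject_outcomes(do.call(rbind, list(...)))

# Brute-force weighted pairwise concordance: the independent AUC oracle.
pairwise_auc <- function(cohort) {
  ok <- !is.na(cohort$risk)
  r <- cohort$risk[ok]; wc <- cohort$w_case[ok]; wk <- cohort$w_control[ok]
  num <- 0
  for (i in seq_along(r)) {
    if (wc[i] == 0) next
    for (j in seq_along(r)) {
      if (wk[j] == 0) next
      num <- num + wc[i] * wk[j] *
        (as.numeric(r[i] > r[j]) + 0.5 * as.numeric(r[i] == r[j]))
    }
  }
  num / (sum(wc) * sum(wk))
}

# Random interval-censored cohort with subject-specific exponential risks:
# latent progression/treatment times drawn from each subject's own rates,
# examinations on a jittered grid, exponential right censoring.
random_cohort <- function(n, seed, window = eval_window(1, 3),
                          cens_rate = 0.08) {
  set.seed(seed)
  rows <- vector("list", n); risks <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("R%03d", i)
    lp <- runif(1, 0.02, 0.25); lt <- runif(1, 0, 0.1)
    risks[[i]] <- exponential_risk(lp, lt)
    tot <- lp + lt
    t_event <- if (tot > 0) rexp(1, tot) else Inf
    is_prg <- is.finite(t_event) && runif(1) < lp / tot
    t_prg <- if (is_prg) t_event else Inf
    t_trt <- if (!is_prg) t_event else Inf
    t_cen <- min(rexp(1, cens_rate), 14)
    exams <- cumsum(runif(12, 0.5, 2.5))
    exit <- min(t_prg, t_trt, t_cen)
    neg <- exams[exams < exit]
    t_neg <- if (length(neg)) max(neg) else 0
    det <- exams[exams >= t_prg]
    det <- if (length(det)) det[1] else Inf
    if (is_prg && det <= min(t_trt, t_cen)) {
      rows[[i]] <- outcome_row(id, 1, t_neg, det, t_prg, t_trt)
    } else if (t_trt < t_cen) {
      rows[[i]] <- outcome_row(id, 2, t_neg, t_trt, t_prg, t_trt)
    } else {
      rows[[i]] <- outcome_row(id, 0, t_neg, t_cen, t_prg, t_trt)
    }
  }
  out <- subject_outcomes(do.call(rbind, rows))
  names(risks) <- out$subject_id
  list(outcomes = out, risks = risks)
}

# No-censoring limit: progression-only latent times observed by examinations
# that collapse onto the event times (risk-interval width 1e-9), no right
# censoring before `horizon`.
degenerate_cohort <- function(n, seed, horizon = 14) {
  set.seed(seed)
  rows <- vector("list", n); risks <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("D%03d", i)
    lp <- runif(1, 0.05, 0.3)
    risks[[i]] <- exponential_risk(lp, 0)
    t_prg <- rexp(1, lp)
    if (t_prg < horizon) {
      rows[[i]] <- outcome_row(id, 1, max(t_prg - 1e-9, 0), t_prg, t_prg, Inf)
    } else {
      rows[[i]] <- outcome_row(id, 0, horizon - 1e-9, horizon, Inf, Inf)
    }
  }
  out <- subject_outcomes(do.call(rbind, rows))
  names(risks) <- out$subject_id
  list(outcomes = out, risks = risks)
}
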