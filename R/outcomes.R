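#' Evaluation window
#'
#' The clinically relevant interval \eqn{[t, t+\Delta t)} over which predicted
#' risks are evaluated: metrics condition on subjects still at risk at `t` and
#' ask whether the primary event falls before `t + dt`.
#'
#' @param t window start in years (>= 0).
#' @param dt window length in years (> 0).
#' @return An object of class `eval_window`.
#' @export
eval_window <- function(t, dt) {
  stopifnot(is.numeric(t), is.numeric(dt), length(t) == 1, length(dt) == 1)
  if (t < 0) stop("window start must be >= 0")
  if (dt <= 0) stop("window length must be > 0")
  structure(list(t = t, dt = dt), class = "eval_window")
}

#' @export
print.eval_window <- function(x, ...) {
  cat(sprintf("<eval_window> [%g, %g)\n", x$t, x$t + x$dt))
  invisible(x)
}

OUTCOME_COLS <- c("subject_id", "t_neg", "t_pos", "t_trt", "t_cen", "delta",
                  "true_t_prg", "true_t_trt")

#' Subject outcome table
#'
#' Builds and validates the per-subject observed event data used by all
#' metrics.  Each subject carries the time of the last negative examination
#' (`t_neg`), and exactly one terminal observation matching the event code
#' `delta`: a positive examination time `t_pos` (`delta = 1`, primary event
#' detected, interval-censored in `(t_neg, t_pos]`), an early-treatment time
#' `t_trt` (`delta = 2`, competing event), or a right-censoring time `t_cen`
#' (`delta = 0`).  Optional latent truth columns `true_t_prg` / `true_t_trt`
#' (simulation only) enable the no-censoring reference metrics; `NA` there
#' means "beyond the simulated horizon".
#'
#' @param df data frame with columns `subject_id`, `t_neg`, `t_pos`, `t_trt`,
#'   `t_cen`, `delta` and optionally `true_t_prg`, `true_t_trt`.  `NA` encodes
#'   absent values.
#' @return A validated `subject_outcomes` data frame (row order preserved).
#' @export
subject_outcomes <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject_id", "t_neg", "delta")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(OUTCOME_COLS, names(df))) df[[col]] <- NA_real_
  df <- df[OUTCOME_COLS]
  for (col in setdiff(OUTCOME_COLS, "subject_id"))
    df[[col]] <- as.numeric(df[[col]])
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    bad <- function(msg) stop("row ", i, " (subject ", r$subject_id, "): ", msg)
    if (is.na(r$delta) || !r$delta %in% c(0, 1, 2)) bad("delta must be 0, 1 or 2")
    if (is.na(r$t_neg) || r$t_neg < 0) bad("t_neg must be present and >= 0")
    present <- c(t_pos = !is.na(r$t_pos), t_trt = !is.na(r$t_trt),
                 t_cen = !is.na(r$t_cen))
    expect <- c(t_pos = r$delta == 1, t_trt = r$delta == 2, t_cen = r$delta == 0)
    if (!identical(unname(present), unname(expect)))
      bad("delta/time mismatch: exactly one of t_pos/t_trt/t_cen must match delta")
    if (r$delta == 1 && r$t_pos <= r$t_neg) bad("t_pos must be > t_neg")
    if (r$delta == 2 && r$t_trt < r$t_neg) bad("t_trt must be >= t_neg")
    if (r$delta == 0 && r$t_cen < r$t_neg) bad("t_cen must be >= t_neg")
    if (r$delta == 1 && !is.na(r$true_t_prg) &&
        (r$true_t_prg <= r$t_neg || r$true_t_prg > r$t_pos))
      bad("true_t_prg must lie in (t_neg, t_pos] when delta = 1")
  }
  class(df) <- c("subject_outcomes", "data.frame")
  df
}

# observed terminal time T^(2): whichever of t_pos / t_trt / t_cen was seen
terminal_time <- function(outcomes) {
  ifelse(outcomes$delta == 1, outcomes$t_pos,
         ifelse(outcomes$delta == 2, outcomes$t_trt, outcomes$t_cen))
}

#' Read / write subject outcome tables
#'
#' CSV with a header row and columns `subject_id`, `t_neg`, `t_pos`, `t_trt`,
#' `t_cen`, `delta` and optional `true_t_prg`, `true_t_trt`; empty cells mean
#' absent.  All times are decimal years.
#'
#' @param path file path.
#' @return `read_outcomes()` returns a validated [subject_outcomes()] table.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  subject_outcomes(df)
}

#' @rdname read_outcomes
#' @param outcomes a [subject_outcomes()] table.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(as.data.frame(outcomes), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write longitudinal biomarker records
#'
#' CSV with columns `subject_id`, `time` (years, >= 0), `value` (biomarker
#' level on the modelling scale).
#'
#' @param path file path.
#' @export
read_longitudinal <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$time < 0, na.rm = TRUE)) stop("measurement times must be >= 0")
  df
}

#' @rdname read_longitudinal
#' @param records data frame of longitudinal records.
#' @export
write_longitudinal <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
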