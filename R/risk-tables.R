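#' Read tabulated risk predictions
#'
#' Reads per-subject predicted risk curves produced by any external prediction
#' model, tabulated on a time grid: CSV columns `subject_id`, `t0`
#' (conditioning time), `s` (grid time, `s >= t0`, strictly increasing within
#' subject), `cif` (primary-event cumulative incidence \eqn{\Pi(s|t_0)}) and
#' `surv` (overall survival \eqn{S(s|t_0)}).
#'
#' Each subject's curve must satisfy `cif(t0) = 0`, `surv(t0) = 1`, `cif`
#' non-decreasing, `surv` non-increasing, both in `[0, 1]`, and
#' `cif(s) <= 1 - surv(s)` up to tolerance; violations are load errors.
#' Between grid points the curves are interpolated linearly (which preserves
#' monotonicity); queries beyond the last grid point raise an error at query
#' time.  Conditioning on a later time `t0 > t0_table` is handled by the
#' standard cumulative-incidence conditioning identity
#' \eqn{\Pi(s|t_0) = \{\Pi(s|t_0^{tab}) - \Pi(t_0|t_0^{tab})\}/S(t_0|t_0^{tab})}.
#'
#' @param path CSV file path.
#' @param tol tolerance for the monotonicity / consistency checks.
#' @return Named list of [risk_function()] objects keyed by `subject_id`.
#' @export
read_risk_tables <- function(path, tol = 1e-8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t0", "s", "cif", "surv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
                function(d) tabulated_risk(d$s, d$cif, d$surv, t0 = d$t0[1],
                                           tol = tol,
                                           label = as.character(d$subject_id[1])))
  out
}

#' Risk function from a tabulated curve
#'
#' @param s strictly increasing grid times (first point must equal `t0`).
#' @param cif,surv curve values on the grid.
#' @param t0 conditioning time of the tabulated curve.
#' @inheritParams read_risk_tables
#' @param label optional label.
#' @return A [risk_function()].
#' @export
tabulated_risk <- function(s, cif, surv, t0 = s[1], tol = 1e-8, label = NULL) {
  if (length(s) < 2 || any(diff(s) <= 0)) stop("grid must be strictly increasing")
  if (abs(s[1] - t0) > tol) stop("grid must start at the conditioning time t0")
  if (abs(cif[1]) > tol) stop("cif(t0) must be 0")
  if (abs(surv[1] - 1) > tol) stop("surv(t0) must be 1")
  if (any(diff(cif) < -tol)) stop("cif must be non-decreasing")
  if (any(diff(surv) > tol)) stop("surv must be non-increasing")
  if (any(cif < -tol | cif > 1 + tol)) stop("cif must lie in [0, 1]")
  if (any(surv < -tol | surv > 1 + tol)) stop("surv must lie in [0, 1]")
  if (any(cif > 1 - surv + 1e-6)) stop("cif must not exceed 1 - surv")
  s_max <- s[length(s)]
  q <- function(vals) function(x) {
    if (any(x > s_max + 1e-9))
      stop("query time ", max(x), " beyond tabulated grid end ", s_max)
    if (any(x < t0 - 1e-9))
      stop("query time before tabulated conditioning time ", t0)
    stats::approx(s, vals, xout = pmin(pmax(x, t0), s_max))$y
  }
  cif_at <- q(cif); surv_at <- q(surv)
  risk_function(
    cif = function(ss, tt0) {
      stopifnot(all(ss >= tt0 - 1e-9))
      if (tt0 < t0 - 1e-9)
        stop("cannot condition earlier than the tabulated t0 = ", t0)
      s0 <- surv_at(tt0)
      if (s0 <= 0) stop("zero survival at conditioning time ", tt0)
      pmin(pmax((cif_at(ss) - cif_at(tt0)) / s0, 0), 1)
    },
    surv = function(ss, tt0) {
      stopifnot(all(ss >= tt0 - 1e-9))
      s0 <- surv_at(tt0)
      if (s0 <= 0) stop("zero survival at conditioning time ", tt0)
      pmin(surv_at(ss) / s0, 1)
    },
    label = label
  )
}

#' Write tabulated risk predictions
#'
#' Inverse of [read_risk_tables()]: evaluates each risk function on `grid`
#' and writes the long CSV schema.
#'
#' @param risks named list of [risk_function()] keyed by subject id.
#' @param path CSV file path.
#' @param t0 conditioning time for the tabulated curves.
#' @param grid evaluation grid (must start at `t0`).
#' @export
write_risk_tables <- function(risks, path, t0, grid) {
  stopifnot(abs(grid[1] - t0) < 1e-12)
  rows <- lapply(names(risks), function(id) {
    rf <- risks[[id]]
    data.frame(subject_id = id, t0 = t0, s = grid,
               cif = rf$cif(grid, t0), surv = rf$surv(grid, t0))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
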