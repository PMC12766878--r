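#' Risk-function contract
#'
#' A `risk_function` bundles a subject's (or a whole model's) predicted
#' cause-specific cumulative incidence of the primary event,
#' \eqn{\Pi(s \mid t_0)}, and the overall (all-cause) survival probability
#' \eqn{S(s \mid t_0)}, both conditional on being event-free at the
#' conditioning time \eqn{t_0}.  Every metric in the package consumes
#' predictions only through this contract, so tabulated output from any
#' external prediction model can be evaluated alongside closed-form or
#' simulated oracles.
#'
#' `cif` and `surv` must be functions of `(s, t0)`, vectorised in `s`, with
#' `cif(t0, t0) == 0`, `surv(t0, t0) == 1`, `cif` non-decreasing and `surv`
#' non-increasing in `s`, and `cif(s, t0) <= 1 - surv(s, t0)` up to numerical
#' tolerance.
#'
#' @param cif function `(s, t0)` returning the primary-event cumulative
#'   incidence.
#' @param surv function `(s, t0)` returning overall survival.
#' @param cif_competing optional function `(s, t0)` with the competing-event
#'   cumulative incidence (used by probability-conservation checks).
#' @param label optional character label carried along for reporting.
#' @return An object of class `risk_function`.
#' @export
risk_function <- function(cif, surv, cif_competing = NULL, label = NULL) {
  stopifnot(is.function(cif), is.function(surv))
  structure(list(cif = cif, surv = surv, cif_competing = cif_competing,
                 label = label),
            class = "risk_function")
}

#' @export
print.risk_function <- function(x, ...) {
  cat("<risk_function>",
      if (!is.null(x$label)) paste0(" ", x$label), "\n", sep = "")
  invisible(x)
}

#' Closed-form exponential competing-risks predictor
#'
#' Constant cause-specific hazards `lambda_prg` (primary event) and
#' `lambda_trt` (competing event) give the closed forms
#' \deqn{\Pi(s \mid t_0) = \frac{\lambda_1}{\lambda_1+\lambda_2}
#'   \left\{1 - e^{-(\lambda_1+\lambda_2)(s-t_0)}\right\}, \qquad
#'   S(s \mid t_0) = e^{-(\lambda_1+\lambda_2)(s-t_0)}.}
#' Used throughout the test suite as an analytic oracle.
#'
#' @param lambda_prg,lambda_trt non-negative rates per year.
#' @return A [risk_function()].
#' @export
exponential_risk <- function(lambda_prg, lambda_trt = 0) {
  if (lambda_prg < 0 || lambda_trt < 0) stop("hazard rates must be >= 0")
  tot <- lambda_prg + lambda_trt
  frac <- if (tot > 0) lambda_prg / tot else 0
  risk_function(
    cif = function(s, t0) {
      stopifnot(all(s >= t0))
      frac * (1 - exp(-tot * (s - t0)))
    },
    surv = function(s, t0) {
      stopifnot(all(s >= t0))
      exp(-tot * (s - t0))
    },
    cif_competing = function(s, t0) {
      (1 - frac) * (1 - exp(-tot * (s - t0)))
    },
    label = sprintf("exponential(%.3g, %.3g)", lambda_prg, lambda_trt)
  )
}

# cumulative trapezoid with value 0 at x[1]
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

#' Numerically integrated risk from cause-specific hazards
#'
#' Builds a [risk_function()] from two cause-specific hazard functions by
#' the standard competing-risks decomposition
#' \deqn{\Pi(s \mid t_0) = \int_{t_0}^{s} h_1(u)\,
#'   \exp\!\left[-\int_{t_0}^{u} \{h_1(v)+h_2(v)\}\,dv\right] du,}
#' with \eqn{S(s \mid t_0)} the exponentiated negative all-cause cumulative
#' hazard.  No proportional-hazards structure is assumed; the hazards are
#' arbitrary non-negative functions of time.
#'
#' Integration uses cumulative trapezoids on a uniform grid over
#' `[0, t_max]`, starting at `init_per_year` points per year and doubling the
#' resolution until the sup-norm change of both the CIF and the survival
#' curve falls below `tol` (smooth integrands make this converge quickly).
#' Queries interpolate linearly between grid points; conditioning on any
#' `t0 > 0` uses the exact identities
#' \eqn{\Pi(s|t_0) = \{I(s)-I(t_0)\}/S(t_0)} and \eqn{S(s|t_0)=S(s)/S(t_0)}
#' where \eqn{I} and \eqn{S} are the unconditional curves.
#'
#' @param h_prg,h_trt vectorised non-negative hazard functions of time.
#' @param t_max upper end of the supported time range (years).
#' @param tol convergence tolerance for grid refinement.
#' @param init_per_year starting grid resolution (points per year).
#' @param max_per_year resolution cap.
#' @param label optional label.
#' @return A [risk_function()]; queries beyond `t_max` raise an error.
#' @export
risk_from_hazards <- function(h_prg, h_trt = function(t) rep(0, length(t)),
                              t_max = 20, tol = 1e-7,
                              init_per_year = 64, max_per_year = 2048,
                              label = NULL) {
  stopifnot(is.function(h_prg), is.function(h_trt), t_max > 0)
  per <- init_per_year
  prev <- NULL
  repeat {
    grid <- seq(0, t_max, length.out = max(round(per * t_max), 32) + 1)
    hp <- h_prg(grid); ht <- h_trt(grid)
    if (any(!is.finite(hp)) || any(!is.finite(ht)))
      stop("non-finite hazard values on [0, t_max]")
    if (any(hp < -1e-12) || any(ht < -1e-12)) stop("negative hazard values")
    Lam <- cumtrapz(grid, hp + ht)
    S <- exp(-Lam)
    I1 <- cumtrapz(grid, hp * S)
    I2 <- cumtrapz(grid, ht * S)
    if (!is.null(prev)) {
      keep <- seq(1, length(grid), by = 2)   # previous grid nests in current
      err <- max(abs(S[keep] - prev$S), abs(I1[keep] - prev$I1))
      if (err < tol) break
    }
    if (per * 2 > max_per_year) break
    prev <- list(S = S, I1 = I1)
    per <- per * 2
  }
  risk_from_grids(grid, S, I1, I2, label = label %||% "risk_from_hazards")
}

# risk_function backed by precomputed uniform-grid curves: S (overall
# survival), I1/I2 (unconditional cause-specific CIFs); O(1) interpolation
risk_from_grids <- function(grid, S, I1, I2 = NULL, label = NULL) {
  x0 <- grid[1]; h <- grid[2] - grid[1]; n <- length(grid)
  t_max <- grid[n]
  at <- function(vals, s) {
    if (any(s > t_max + 1e-9) || any(s < x0 - 1e-9))
      stop("query time outside the supported range [", x0, ", ", t_max, "]")
    idx <- (pmin(pmax(s, x0), t_max) - x0) / h
    i <- pmin(pmax(floor(idx), 0), n - 2)
    w <- idx - i
    vals[i + 1] * (1 - w) + vals[i + 2] * w
  }
  risk_function(
    cif = function(s, t0) {
      stopifnot(all(s >= t0 - 1e-9))
      s0 <- at(S, t0)
      if (s0 <= 0) stop("zero survival at conditioning time t0 = ", t0)
      pmin(pmax((at(I1, s) - at(I1, t0)) / s0, 0), 1)
    },
    surv = function(s, t0) {
      stopifnot(all(s >= t0 - 1e-9))
      s0 <- at(S, t0)
      if (s0 <= 0) stop("zero survival at conditioning time t0 = ", t0)
      pmin(at(S, s) / s0, 1)
    },
    cif_competing = if (!is.null(I2)) function(s, t0) {
      s0 <- at(S, t0)
      pmin(pmax((at(I2, s) - at(I2, t0)) / s0, 0), 1)
    },
    label = label
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a per-subject risk: `risk` is either one risk_function shared by
# all subjects or a named list keyed by subject_id.
risk_for <- function(risk, subject_id) {
  if (inherits(risk, "risk_function")) return(risk)
  if (is.list(risk)) {
    rf <- risk[[as.character(subject_id)]]
    if (is.null(rf))
      stop("no risk function supplied for subject '", subject_id, "'")
    return(rf)
  }
  stop("`risk` must be a risk_function or a named list of them")
}
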