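#' Boltzmann conductance-voltage relation
#'
#' The two-state activation curve used throughout:
#' \deqn{G_K(V) = G_{MAX} / (1 + \exp[(V_{1/2} - V)/s]),}
#' with maximal conductance \eqn{G_{MAX}}, midpoint \eqn{V_{1/2}} and slope
#' \eqn{s > 0}.
#'
#' @param v Membrane voltage(s), mV.
#' @param gmax Maximal conductance, uS.
#' @param v_half Activation midpoint, mV.
#' @param s Slope factor, mV (> 0).
#' @return Conductance (uS), same length as `v`.
#' @export
boltzmann_conductance <- function(v, gmax, v_half, s) {
  stopifnot(s > 0)
  gmax / (1 + exp((v_half - v) / s))
}

#' Steady-state current of each sweep in a current family
#'
#' Averages the current over the steady-state window at the end of every
#' test sweep (the protocol's `window_ms`), one value per test voltage.
#'
#' @param family A `"current_family"` object ([gen_current_family()] or
#'   [read_current_family()]).
#' @return A data frame with columns `voltage_mV` and `current_uA`.
#' @export
steady_state_current <- function(family) {
  stopifnot(inherits(family, "current_family"))
  p <- family$protocol
  t0 <- p$sweep_ms - p$window_ms
  idx <- which(family$time_ms >= t0 & family$time_ms <= p$sweep_ms)
  if (length(idx) == 0)
    stop("steady-state window [", t0, ", ", p$sweep_ms,
         "] ms contains no samples of the recorded time grid")
  data.frame(voltage_mV = p$test_voltages,
             current_uA = rowMeans(family$currents[, idx, drop = FALSE]))
}

#' Convert steady-state currents to conductance
#'
#' Applies the ohmic driving-force correction `G = I / (V - V_K)`. Points
#' recorded at the reversal potential carry no conductance information
#' (zero driving force) and are dropped with a warning.
#'
#' @param points Data frame with columns `voltage_mV` and `current_uA`
#'   (as returned by [steady_state_current()]).
#' @param v_rev_mV K+ reversal potential (mV).
#' @param condition Optional condition label carried along.
#' @return A `"gv_curve"`: data frame with columns `voltage_mV`,
#'   `conductance_uS` and attribute `condition`.
#' @export
compute_conductance <- function(points, v_rev_mV = -80, condition = NULL) {
  stopifnot(is.data.frame(points),
            all(c("voltage_mV", "current_uA") %in% names(points)))
  at_rev <- points$voltage_mV == v_rev_mV
  if (any(at_rev)) {
    warning("dropping ", sum(at_rev),
            " point(s) at the reversal potential (undefined G = I/0)")
    points <- points[!at_rev, , drop = FALSE]
  }
  out <- data.frame(voltage_mV = points$voltage_mV,
                    conductance_uS = points$current_uA /
                      (points$voltage_mV - v_rev_mV))
  attr(out, "condition") <- condition
  class(out) <- c("gv_curve", "data.frame")
  out
}

# Data-driven starting values: gmax from the observed plateau, v_half from
# the voltage nearest half-max, slope from the 25-75% rise width
# (V75 - V25 = 2 s ln 3, so s ~ width / 2.2).
boltzmann_start <- function(v, g) {
  gmax0 <- max(g)
  vh0 <- v[which.min(abs(g - gmax0 / 2))]
  v25 <- v[which.min(abs(g - 0.25 * gmax0))]
  v75 <- v[which.min(abs(g - 0.75 * gmax0))]
  s0 <- (v75 - v25) / 2.2
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(v)) / 6
  list(gmax = gmax0, v_half = vh0, s = s0)
}

#' Fit a Boltzmann activation curve to conductance data
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' [boltzmann_conductance()] to a G(V) curve. Starting values are derived
#' from the data; fits are unweighted by default, with optional per-point
#' weights.
#'
#' @param curve A `"gv_curve"` or any data frame with `voltage_mV` and
#'   `conductance_uS` columns; at least 4 distinct voltages.
#' @param weights Optional vector of per-point weights for weighted least
#'   squares.
#' @return An object of class `"boltzmann_fit"`: list with `gmax` (uS),
#'   `v_half` (mV), `slope` (mV), `rss` (uS^2), `converged`, `se` (named
#'   standard errors), `condition` and the underlying `model`.
#' @examples
#' v <- seq(-80, 40, by = 10)
#' g <- boltzmann_conductance(v, gmax = 1, v_half = -30, s = 10)
#' fit_boltzmann(data.frame(voltage_mV = v, conductance_uS = g))
#' @export
fit_boltzmann <- function(curve, weights = NULL) {
  stopifnot(all(c("voltage_mV", "conductance_uS") %in% names(curve)))
  v <- curve$voltage_mV
  g <- curve$conductance_uS
  if (length(unique(v)) < 4)
    stop("need at least 4 distinct voltages to fit a Boltzmann curve")
  if (sd(g) < .Machine$double.eps^0.5 * max(1, abs(mean(g))))
    stop("degenerate flat conductance curve: Boltzmann parameters undefined")
  st <- boltzmann_start(v, g)
  dat <- data.frame(v = v, g = g)
  args <- list(g ~ gmax / (1 + exp((v_half - v) / s)),
               data = dat, start = st,
               lower = c(gmax = 0, v_half = -Inf, s = 1e-6),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(gmax = st$gmax, v_half = st$v_half, slope = st$s,
                rss = NA_real_, converged = FALSE,
                se = c(gmax = NA_real_, v_half = NA_real_, s = NA_real_),
                condition = attr(curve, "condition"), model = NULL,
                message = conditionMessage(fit))
    class(out) <- "boltzmann_fit"
    return(out)
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(gmax = NA_real_, v_half = NA_real_, s = NA_real_))
  out <- list(gmax = unname(cf["gmax"]), v_half = unname(cf["v_half"]),
              slope = unname(cf["s"]),
              rss = sum(stats::residuals(fit)^2),
              converged = fit$convInfo$isConv,
              se = se, condition = attr(curve, "condition"), model = fit)
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit%s: GMAX = %.4g uS, V1/2 = %.2f mV, s = %.2f mV (rss %.3g%s)\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$gmax, x$v_half, x$slope, x$rss,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Compound-induced G(V) shift
#'
#' `V1/2(compound) - V1/2(control)`; negative values mean the activation
#' curve moved leftward (opening promoted).
#'
#' @param control,compound Converged [fit_boltzmann()] objects.
#' @return Shift in mV.
#' @export
gv_shift <- function(control, compound) {
  stopifnot(inherits(control, "boltzmann_fit"),
            inherits(compound, "boltzmann_fit"))
  if (!isTRUE(control$converged) || !isTRUE(compound$converged))
    stop("gv_shift requires converged Boltzmann fits")
  compound$v_half - control$v_half
}

#' Relative change in maximal conductance
#'
#' `GMAX(compound) / GMAX(control)`; 1 means no change, 0.17 corresponds to
#' an 83% reduction.
#'
#' @inheritParams gv_shift
#' @return Dimensionless ratio.
#' @export
gmax_ratio <- function(control, compound) {
  stopifnot(inherits(control, "boltzmann_fit"),
            inherits(compound, "boltzmann_fit"))
  if (!is.finite(control$gmax) || control$gmax <= 0)
    stop("control GMAX must be positive")
  compound$gmax / control$gmax
}

#' Compare two groups of G(V) shifts
#'
#' Two-tailed unpaired t test between per-cell shift measurements. The
#' Welch (unequal-variance) form is the default because group sizes in
#' these experiments are small and unequal; set `var_equal = TRUE` for the
#' pooled-variance test.
#'
#' @param group_a,group_b Numeric vectors of shifts (mV), each of length
#'   >= 2.
#' @param var_equal Assume equal variances? Default `FALSE` (Welch).
#' @return List with `t`, `p_value`, `df` and the underlying `htest`.
#' @export
compare_shifts <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 measurements")
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), test = ht)
}
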