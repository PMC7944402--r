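#' Hyperbolic concentration dependence of the G(V) shift
#'
#' Single-site binding curve \deqn{\Delta V(c) = \Delta V_{MAX} / (1 +
#' EC_{50}/c),} with the Hill coefficient fixed at 1. At `c = EC50` the
#' predicted shift is half of `delta_v_max`; the shift approaches
#' `delta_v_max` at saturating concentration.
#'
#' @param conc Concentration(s), uM (> 0).
#' @param ec50 Concentration of half-maximal shift, uM (> 0).
#' @param delta_v_max Shift at saturating concentration, mV.
#' @return Predicted shift(s), mV.
#' @export
hyperbolic_shift <- function(conc, ec50, delta_v_max) {
  if (any(conc <= 0)) stop("concentrations must be > 0")
  stopifnot(ec50 > 0)
  delta_v_max / (1 + ec50 / conc)
}

#' Fit the concentration-response curve of G(V) shifts
#'
#' Least-squares fit of [hyperbolic_shift()] to (concentration, shift)
#' pairs, estimating apparent affinity (`ec50`) and efficacy
#' (`delta_v_max`). The fit runs in linear concentration space; `ec50` is
#' initialised at the measured concentration whose shift is nearest half
#' of the extreme shift. Unweighted by default; pass `weights` (for
#' example `1/sem^2`) for weighted least squares. Standard errors come
#' from the Jacobian-based covariance at the optimum.
#'
#' @param points Data frame with columns `concentration_uM` and `shift_mV`;
#'   at least 3 distinct concentrations.
#' @param weights Optional per-point weights.
#' @return Object of class `"dose_response_fit"`: list with `ec50` (uM),
#'   `delta_v_max` (mV), `se` (named standard errors), `rss` (mV^2),
#'   `converged` and the underlying `model`.
#' @examples
#' conc <- c(3, 10, 30, 100, 300)
#' pts <- data.frame(concentration_uM = conc,
#'                   shift_mV = hyperbolic_shift(conc, 30, -56.5))
#' fit_dose_response(pts)
#' @export
fit_dose_response <- function(points, weights = NULL) {
  stopifnot(is.data.frame(points),
            all(c("concentration_uM", "shift_mV") %in% names(points)))
  conc <- points$concentration_uM
  shift <- points$shift_mV
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct concentrations to identify EC50 and dVmax")
  if (diff(range(shift)) < .Machine$double.eps^0.5 * max(1, abs(mean(shift))))
    stop("all shifts equal: EC50 is unidentifiable from these data")
  extreme <- shift[which.max(abs(shift))]
  ec50_0 <- conc[which.min(abs(shift - extreme / 2))]
  st <- list(dvmax = extreme, ec50 = max(ec50_0, min(conc) / 10))
  dat <- data.frame(conc = conc, shift = shift)
  args <- list(shift ~ dvmax / (1 + ec50 / conc),
               data = dat, start = st,
               lower = c(dvmax = -Inf, ec50 = 1e-9),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(ec50 = st$ec50, delta_v_max = st$dvmax,
                se = c(ec50 = NA_real_, dvmax = NA_real_), rss = NA_real_,
                converged = FALSE, model = NULL,
                message = conditionMessage(fit))
    class(out) <- "dose_response_fit"
    return(out)
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[c("ec50", "dvmax")],
                 error = function(e) c(ec50 = NA_real_, dvmax = NA_real_))
  out <- list(ec50 = unname(cf["ec50"]), delta_v_max = unname(cf["dvmax"]),
              se = se, rss = sum(stats::residuals(fit)^2),
              converged = fit$convInfo$isConv, model = fit)
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "Concentration-response fit: EC50 = %.3g uM, dVmax = %.3g mV (rss %.3g%s)\n",
    x$ec50, x$delta_v_max, x$rss,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Predict the G(V) shift at a given concentration
#'
#' @param fit A `"dose_response_fit"` object (or any list carrying `ec50`
#'   and `delta_v_max`).
#' @param conc Concentration(s), uM (> 0).
#' @return Predicted shift(s), mV.
#' @export
predict_shift <- function(fit, conc) {
  hyperbolic_shift(conc, fit$ec50, fit$delta_v_max)
}

#' Percent increase in maximal shift between two channels
#'
#' Quantifies how much a channel variant (for example one carrying the 2R
#' motif, M356R/A359R) boosts a compound's efficacy: the percent increase
#' of |delta_v_max| relative to the reference channel. Both efficacies
#' must have the same sign (both opening-promoting or both
#' closing-promoting).
#'
#' @param reference,variant `"dose_response_fit"` objects, or bare numeric
#'   `delta_v_max` values (mV).
#' @return Percent increase (57 means the variant's maximal shift is 1.57x
#'   the reference's).
#' @examples
#' efficacy_increase(-36.1, -56.5) # ~ 57
#' @export
efficacy_increase <- function(reference, variant) {
  ref <- if (is.list(reference)) reference$delta_v_max else reference
  var <- if (is.list(variant)) variant$delta_v_max else variant
  stopifnot(is.numeric(ref), is.numeric(var), ref != 0)
  if (sign(ref) != sign(var))
    stop("reference and variant efficacies have opposite signs; ",
         "a percent increase is not meaningful")
  (abs(var) / abs(ref) - 1) * 100
}
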