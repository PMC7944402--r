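#' Voltage-step protocol for a two-electrode voltage-clamp family
#'
#' Describes the stimulus used to record a family of K+ currents: a series
#' of depolarising test steps from a fixed holding potential, with the
#' steady-state current read out in a window at the end of each sweep.
#'
#' @param test_voltages Ordered vector of test-step voltages (mV), strictly
#'   increasing.
#' @param holding_mV Holding potential (mV). Default -80 mV.
#' @param v_rev_mV Reversal potential for K+ under the recording solutions
#'   (mV), used to convert current to conductance. Default -80 mV.
#' @param sweep_ms Duration of each test sweep (ms).
#' @param window_ms Length of the steady-state window at the end of the
#'   sweep over which current is averaged (ms). Must not exceed `sweep_ms`.
#' @param dt_ms Sampling interval (ms).
#'
#' @return An object of class `"voltage_protocol"`.
#' @examples
#' voltage_protocol(seq(-80, 50, by = 10))
#' @export
voltage_protocol <- function(test_voltages = seq(-80, 50, by = 10),
                             holding_mV = -80, v_rev_mV = -80,
                             sweep_ms = 100, window_ms = 10, dt_ms = 1) {
  stopifnot(is.numeric(test_voltages), length(test_voltages) >= 1,
            is.finite(test_voltages))
  if (is.unsorted(test_voltages, strictly = TRUE))
    stop("'test_voltages' must be strictly increasing")
  if (window_ms > sweep_ms)
    stop("steady-state window (", window_ms,
         " ms) exceeds sweep duration (", sweep_ms, " ms)")
  if (dt_ms <= 0 || sweep_ms <= 0 || window_ms <= 0)
    stop("'sweep_ms', 'window_ms' and 'dt_ms' must be positive")
  structure(list(test_voltages = as.numeric(test_voltages),
                 holding_mV = holding_mV, v_rev_mV = v_rev_mV,
                 sweep_ms = sweep_ms, window_ms = window_ms, dt_ms = dt_ms),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat("Voltage protocol:", length(x$test_voltages), "steps",
      sprintf("[%g, %g] mV,", min(x$test_voltages), max(x$test_voltages)),
      sprintf("holding %g mV, V_K %g mV, sweep %g ms (window %g ms, dt %g ms)\n",
              x$holding_mV, x$v_rev_mV, x$sweep_ms, x$window_ms, x$dt_ms))
  invisible(x)
}

#' Ground-truth parameter set for the synthetic generators
#'
#' Bundles the generating parameters that downstream fits are expected to
#' recover: control Boltzmann parameters, the compound-induced midpoint
#' shift and GMAX scaling, the hyperbolic concentration-response parameters,
#' and the noise level. Defaults describe a Shaker-like channel exposed to
#' 100 uM of a strongly shifting compound (Wu50 on the 2R-motif channel:
#' saturating shift -56.5 mV, EC50 30 uM).
#'
#' @param control_v_half Control activation midpoint V1/2 (mV).
#' @param control_slope Control Boltzmann slope s (mV), > 0.
#' @param control_gmax Control maximal conductance (uS), > 0.
#' @param shift Compound-induced G(V) shift, V1/2(compound) - V1/2(control)
#'   (mV); negative = opening-promoting.
#' @param gmax_ratio GMAX(compound)/GMAX(control), > 0.
#' @param ec50 Concentration of half-maximal shift (uM), > 0.
#' @param delta_v_max G(V) shift at saturating concentration (mV).
#' @param noise_sd Standard deviation of additive Gaussian noise, in the
#'   units of whichever signal a generator perturbs (uA for currents, mV
#'   for shifts). >= 0. For current families this may be a vector with
#'   one value per test voltage, e.g. to scale recording noise with the
#'   driving force.
#' @param seed Optional integer seed recorded in generator output metadata.
#'
#' @return An object of class `"ground_truth"` (a named list).
#' @examples
#' ground_truth(shift = -40.7, noise_sd = 0.1)
#' @export
ground_truth <- function(control_v_half = -30, control_slope = 10,
                         control_gmax = 1, shift = -40.7, gmax_ratio = 1,
                         ec50 = 30, delta_v_max = -56.5,
                         noise_sd = 0, seed = NULL) {
  if (control_slope <= 0) stop("'control_slope' must be > 0")
  if (control_gmax <= 0) stop("'control_gmax' must be > 0")
  if (ec50 <= 0) stop("'ec50' must be > 0")
  if (gmax_ratio <= 0) stop("'gmax_ratio' must be > 0")
  if (any(noise_sd < 0)) stop("'noise_sd' must be >= 0")
  structure(list(control_v_half = control_v_half,
                 control_slope = control_slope,
                 control_gmax = control_gmax,
                 shift = shift, gmax_ratio = gmax_ratio,
                 ec50 = ec50, delta_v_max = delta_v_max,
                 noise_sd = noise_sd, seed = seed),
            class = "ground_truth")
}

#' Compound metadata
#'
#' Charge and pH bookkeeping for a resin-acid derivative. The shifts these
#' compounds produce depend on the molecule carrying its negative charge,
#' so assays are run at a pH where the compound is fully deprotonated.
#'
#' @param name Compound name.
#' @param net_charge Net charge at assay pH; one of -1, 0, +1.
#' @param pKa_membrane Apparent pKa in the lipid membrane, or `NA` for
#'   permanently charged compounds.
#' @param assay_pH pH of the recording solution, in \[0, 14\].
#'
#' @return An object of class `"compound_spec"`.
#' @seealso [wu_compounds()] for the three characterised derivatives.
#' @export
compound_spec <- function(name, net_charge = -1L, pKa_membrane = NA_real_,
                          assay_pH = 7.4) {
  if (!net_charge %in% c(-1L, 0L, 1L)) stop("'net_charge' must be -1, 0 or +1")
  if (assay_pH < 0 || assay_pH > 14) stop("'assay_pH' must be in [0, 14]")
  structure(list(name = as.character(name), net_charge = as.integer(net_charge),
                 pKa_membrane = pKa_membrane, assay_pH = assay_pH),
            class = "compound_spec")
}

#' The three characterised resin-acid derivatives
#'
#' Wu50 has an apparent membrane pKa near 6.5 and is therefore assayed at
#' pH 9.0 to keep it fully charged; Wu161 and Wu181 are permanently
#' negatively charged and assayed at pH 7.4.
#'
#' @return A named list of [compound_spec()] objects.
#' @export
wu_compounds <- function() {
  list(Wu50  = compound_spec("Wu50",  -1L, pKa_membrane = 6.5, assay_pH = 9.0),
       Wu161 = compound_spec("Wu161", -1L, assay_pH = 7.4),
       Wu181 = compound_spec("Wu181", -1L, assay_pH = 7.4))
}
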