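#' Published G(V) shift measurements for Shaker Kv mutants
#'
#' The packaged table of published mean G(V) shifts (with SEM and group
#' size n) induced by 100 uM of Wu50 (pH 9.0) or Wu161 (pH 7.4) across the
#' Shaker Kv mutant panel: the 2R motif (M356R/A359R), the gating-charge
#' neutralisations R362Q and R365Q, the aromatic pocket mutations W454A
#' and F416A, and their combinations. Only values printed numerically in
#' the published text enter the table; the single exception (Wu50 on
#' 2R/W454A) is reconstructed from the published range of 2R-induced shift
#' increases and is flagged `derived = TRUE`. Rows whose shift could not
#' be measured (e.g. because the compound collapsed GMAX) are retained
#' with a `status` flag and `NA` shift rather than dropped.
#'
#' The `model_panel` column marks the mutant sets entering the published
#' additive-site decomposition: eight mutants for Wu50 (the four S4/pore
#' configuration classes, each with and without the 2R motif) and five for
#' Wu161.
#'
#' @param compound `"Wu50"`, `"Wu161"`, or `NULL` for the full table.
#' @return A shift dataset (data frame) with the flag columns consumed by
#'   [fit_site_model()], plus `pH`, `status`, `derived`, `model_panel`
#'   and `source` annotation columns.
#' @examples
#' ds <- load_published_shifts("Wu50")
#' ds[ds$model_panel, c("mutant_label", "shift_mV", "sem_mV", "n")]
#' @export
load_published_shifts <- function(compound = NULL) {
  path <- system.file("extdata", "shaker_wu_shifts.csv", package = "kvshift",
                      mustWork = TRUE)
  ds <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(compound)) {
    if (!compound %in% unique(ds$compound))
      stop("unknown compound '", compound, "'; available: ",
           paste(unique(ds$compound), collapse = ", "))
    ds <- ds[ds$compound == compound, , drop = FALSE]
    rownames(ds) <- NULL
  }
  ds
}

#' Published concentration-response parameters
#'
#' Hyperbolic dose-response parameters (EC50, saturating shift dVmax, with
#' SEMs) for Wu50, Wu161 and Wu181 on the WT Shaker Kv channel and on the
#' channel carrying the 2R motif (plus 2R/W454A for Wu50). These are the
#' fitted curve parameters from which efficacy comparisons between
#' channels are computed.
#'
#' @return Data frame with columns `compound`, `channel`, `ec50_uM`,
#'   `ec50_sem_uM`, `dvmax_mV`, `dvmax_sem_mV`, `pH`.
#' @seealso [efficacy_increase()]
#' @export
published_dose_response <- function() {
  path <- system.file("extdata", "shaker_wu_dose_response.csv",
                      package = "kvshift", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a current family as delimited text
#'
#' Long-format CSV exchange for voltage-clamp current families, one row
#' per sample with columns `sweep_voltage_mV`, `time_ms`, `current_uA`.
#' Reading requires the protocol (holding potential, reversal potential,
#' window) since the CSV carries only the recorded samples.
#'
#' @param family A `"current_family"`.
#' @param file Path to a CSV file.
#' @return `write_current_family()` returns `file` invisibly;
#'   `read_current_family()` returns a `"current_family"`.
#' @export
write_current_family <- function(family, file) {
  stopifnot(inherits(family, "current_family"))
  p <- family$protocol
  long <- data.frame(
    sweep_voltage_mV = rep(p$test_voltages, each = length(family$time_ms)),
    time_ms = rep(family$time_ms, times = length(p$test_voltages)),
    current_uA = as.vector(t(family$currents)))
  write.csv(long, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_current_family
#' @param protocol A [voltage_protocol()] whose test voltages must match
#'   the sweep voltages found in the file (it is rebuilt from the file's
#'   time grid when omitted).
#' @param condition Condition label to attach.
#' @export
read_current_family <- function(file, protocol = NULL, condition = NULL) {
  long <- read.csv(file)
  need <- c("sweep_voltage_mV", "time_ms", "current_uA")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("current-family file lacks required column(s): ",
         paste(miss, collapse = ", "))
  volts <- sort(unique(long$sweep_voltage_mV))
  times <- sort(unique(long$time_ms))
  if (is.null(protocol))
    protocol <- voltage_protocol(test_voltages = volts,
                                 sweep_ms = max(times),
                                 dt_ms = if (length(times) > 1)
                                   min(diff(times)) else 1)
  if (!isTRUE(all.equal(protocol$test_voltages, volts)))
    stop("sweep voltages in the file do not match the supplied protocol")
  currents <- matrix(NA_real_, nrow = length(volts), ncol = length(times))
  idx_v <- match(long$sweep_voltage_mV, volts)
  idx_t <- match(long$time_ms, times)
  currents[cbind(idx_v, idx_t)] <- long$current_uA
  if (anyNA(currents)) stop("incomplete sweep/time grid in ", file)
  structure(list(protocol = protocol, time_ms = times, currents = currents,
                 condition_label = condition, meta = list(file = file)),
            class = "current_family")
}

#' Run the simulate / G(V)-fit / dose-fit pipeline end to end
#'
#' Generates synthetic control and compound current families for each
#' requested concentration from one ground truth, runs the full analysis
#' chain (steady-state extraction, conductance, Boltzmann fits, shifts,
#' dose-response fit) and writes every artifact — current-family CSVs, a
#' shift table, fit JSON records and a run-metadata JSON recording the
#' seed and parameters — into an output directory.
#'
#' @param truth A [ground_truth()].
#' @param concentrations Concentrations (uM) at which to simulate
#'   compound exposure; the compound-induced shift at concentration c
#'   follows the hyperbolic curve of `truth`.
#' @param out_dir Output directory (created if needed).
#' @param protocol A [voltage_protocol()].
#' @param seed Integer seed governing all randomness of the run.
#' @param force Overwrite an existing non-empty `out_dir`? Default `FALSE`.
#' @return Invisibly, a list with the per-concentration fitted shifts
#'   (`shift_table`), the [fit_dose_response()] result (`dose_fit`) and
#'   the paths written.
#' @export
run_pipeline <- function(truth, concentrations = c(3, 10, 30, 100, 300),
                         out_dir, protocol = voltage_protocol(), seed = 1,
                         force = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ctrl_fam <- gen_current_family(protocol, truth, "control")
  write_current_family(ctrl_fam, file.path(out_dir, "control_traces.csv"))
  ctrl_fit <- fit_boltzmann(
    compute_conductance(steady_state_current(ctrl_fam),
                        v_rev_mV = protocol$v_rev_mV, condition = "control"))
  rows <- lapply(concentrations, function(conc) {
    t_c <- truth
    t_c$shift <- hyperbolic_shift(conc, truth$ec50, truth$delta_v_max)
    fam <- gen_current_family(protocol, t_c, "compound")
    write_current_family(
      fam, file.path(out_dir, sprintf("compound_%guM_traces.csv", conc)))
    fit <- fit_boltzmann(
      compute_conductance(steady_state_current(fam),
                          v_rev_mV = protocol$v_rev_mV,
                          condition = sprintf("compound %g uM", conc)))
    data.frame(concentration_uM = conc,
               shift_mV = gv_shift(ctrl_fit, fit),
               gmax_ratio = gmax_ratio(ctrl_fit, fit))
  })
  shift_table <- do.call(rbind, rows)
  write.csv(shift_table, file.path(out_dir, "shift_table.csv"),
            row.names = FALSE)
  dose_fit <- fit_dose_response(shift_table)
  jsonlite::write_json(
    list(control_boltzmann = ctrl_fit[c("gmax", "v_half", "slope", "rss",
                                        "converged")],
         dose_response = dose_fit[c("ec50", "delta_v_max", "rss",
                                    "converged")]),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "kvshift",
         version = as.character(utils::packageVersion("kvshift")),
         seed = seed, concentrations = concentrations,
         truth = unclass(truth)[
           c("control_v_half", "control_slope", "control_gmax", "shift",
             "gmax_ratio", "ec50", "delta_v_max", "noise_sd")],
         protocol = unclass(protocol)),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(shift_table = shift_table, dose_fit = dose_fit,
                 control_fit = ctrl_fit, out_dir = out_dir,
                 files = list.files(out_dir, full.names = TRUE)))
}
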