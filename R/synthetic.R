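#' Generate a synthetic voltage-clamp current family
#'
#' Simulates the K+ current evoked by each test step of a protocol for a
#' channel with Boltzmann-distributed open probability. The signal model
#' is the steady-state conductance times the ohmic driving force, reached
#' through single-exponential activation with a voltage-independent time
#' constant (the downstream analysis only uses the steady-state window, so
#' no attempt is made at realistic activation kinetics), plus optional
#' constant leak and additive i.i.d. Gaussian noise on every sample:
#' \deqn{I(V, t) = [G_K(V)(V - V_K) + I_{leak}] (1 - e^{-t/\tau}) + \epsilon.}
#'
#' @param protocol A [voltage_protocol()]. Its test voltages should
#'   bracket the channel's V1/2 (warned otherwise) and its sweep must
#'   contain the steady-state window.
#' @param truth A [ground_truth()]; `noise_sd` is in uA per sample.
#' @param condition `"control"` uses the control Boltzmann parameters;
#'   `"compound"` applies `truth$shift` to V1/2 and `truth$gmax_ratio` to
#'   GMAX.
#' @param tau_ms Activation time constant (ms).
#' @param leak_uA Constant leak current added to every sample (uA).
#' @param seed Optional integer seed; recorded in the output metadata.
#' @return A `"current_family"`: list with `protocol`, `time_ms`,
#'   `currents` (sweep x time matrix, uA), `condition_label` and `meta`
#'   (generating parameters and seed).
#' @examples
#' fam <- gen_current_family(voltage_protocol(), ground_truth())
#' steady_state_current(fam)
#' @export
gen_current_family <- function(protocol, truth,
                               condition = c("control", "compound"),
                               tau_ms = 10, leak_uA = 0, seed = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(truth, "ground_truth"))
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  v_half <- truth$control_v_half +
    if (condition == "compound") truth$shift else 0
  gmax <- truth$control_gmax *
    if (condition == "compound") truth$gmax_ratio else 1
  v <- protocol$test_voltages
  if (min(v) > v_half || max(v) < v_half)
    warning("test voltages do not bracket V1/2 (", round(v_half, 1),
            " mV); the Boltzmann midpoint will be poorly constrained")
  if (tau_ms * 3 > protocol$sweep_ms - protocol$window_ms)
    warning("activation (tau = ", tau_ms, " ms) may not have settled ",
            "before the steady-state window")
  time_ms <- seq(0, protocol$sweep_ms, by = protocol$dt_ms)
  g <- boltzmann_conductance(v, gmax, v_half, truth$control_slope)
  i_ss <- g * (v - protocol$v_rev_mV) + leak_uA
  act <- 1 - exp(-time_ms / tau_ms)
  currents <- outer(i_ss, act)
  noise_sd <- truth$noise_sd
  if (!length(noise_sd) %in% c(1, length(v)))
    stop("'noise_sd' must be a scalar or one value per test voltage")
  if (any(noise_sd > 0))
    currents <- currents +
      rnorm(length(currents), sd = rep(noise_sd, length.out = length(v)))
  structure(list(protocol = protocol, time_ms = time_ms, currents = currents,
                 condition_label = condition,
                 meta = list(gmax = gmax, v_half = v_half,
                             slope = truth$control_slope, tau_ms = tau_ms,
                             leak_uA = leak_uA, noise_sd = truth$noise_sd,
                             seed = seed)),
            class = "current_family")
}

#' Generate a synthetic concentration-response table
#'
#' Draws `n_per_conc` replicate shift measurements at each concentration
#' from the hyperbolic dose-response curve of `truth` with additive
#' Gaussian noise (`truth$noise_sd`, mV per replicate), then tabulates
#' mean, SEM and n per concentration — the format in which such data are
#' reported and fitted.
#'
#' @param truth A [ground_truth()] supplying `ec50`, `delta_v_max` and
#'   `noise_sd`.
#' @param concentrations Concentrations (uM, > 0).
#' @param n_per_conc Replicates per concentration.
#' @param seed Optional integer seed.
#' @return Data frame with columns `concentration_uM`, `shift_mV`
#'   (replicate mean), `sem_mV`, `n`; per-replicate draws are attached as
#'   attribute `"replicates"` (concentration x replicate matrix).
#' @export
gen_dose_response <- function(truth, concentrations, n_per_conc = 5,
                              seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- hyperbolic_shift(concentrations, truth$ec50, truth$delta_v_max)
  reps <- matrix(rnorm(length(mu) * n_per_conc, mean = rep(mu, n_per_conc),
                       sd = truth$noise_sd),
                 nrow = length(mu))
  out <- data.frame(concentration_uM = concentrations,
                    shift_mV = rowMeans(reps),
                    sem_mV = apply(reps, 1, sd) / sqrt(n_per_conc),
                    n = n_per_conc)
  attr(out, "replicates") <- reps
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic mutant shift panel from known site contributions
#'
#' Builds a shift dataset whose noiseless per-mutant means obey the
#' additive site model exactly: S3/S4 term when the 2R motif is present,
#' the pore-class term of each mutant's configuration, plus a common
#' residual. Per-measurement Gaussian noise (`noise_sd`, mV) emulates
#' cell-to-cell scatter; the tabulated `shift_mV` is the mean of
#' `n_per_mutant` draws, with the corresponding SEM.
#'
#' @param configs List of [mutant_config()] objects.
#' @param s3s4_mV S3/S4-site contribution (mV), applied when `has_2R`.
#' @param pore_mV Named numeric vector of S4/pore contributions, one per
#'   pore class occurring in `configs` (names as produced by
#'   [encode_mutant()]).
#' @param residual_mV Residual contribution common to all mutants (mV).
#' @param noise_sd Per-measurement noise SD (mV).
#' @param n_per_mutant Measurements per mutant.
#' @param compound,concentration_uM Labels carried into the table.
#' @param seed Optional integer seed.
#' @return A shift dataset (data frame) as consumed by
#'   [fit_site_model()], with attribute `"truth"` holding the generating
#'   parameters.
#' @export
gen_shift_table <- function(configs, s3s4_mV, pore_mV, residual_mV,
                            noise_sd = 0, n_per_mutant = 1,
                            compound = "synthetic", concentration_uM = 100,
                            seed = NULL) {
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "mutant_config")))
  if (!is.null(seed)) set.seed(seed)
  enc <- lapply(configs, encode_mutant)
  classes <- vapply(enc, `[[`, character(1), "pore_class")
  missing_cls <- setdiff(unique(classes), names(pore_mV))
  if (length(missing_cls))
    stop("no pore contribution supplied for class(es): ",
         paste(missing_cls, collapse = ", "))
  mu <- vapply(seq_along(configs), function(i)
    (if (enc[[i]]$s3s4_active) s3s4_mV else 0) +
      pore_mV[[classes[i]]] + residual_mV, numeric(1))
  reps <- matrix(rnorm(length(mu) * n_per_mutant,
                       mean = rep(mu, n_per_mutant), sd = noise_sd),
                 nrow = length(mu))
  out <- data.frame(
    mutant_label = vapply(configs, `[[`, character(1), "label"),
    has_2R = vapply(configs, `[[`, logical(1), "has_2R"),
    R362Q = vapply(configs, `[[`, logical(1), "R362Q"),
    R365Q = vapply(configs, `[[`, logical(1), "R365Q"),
    W454A = vapply(configs, `[[`, logical(1), "W454A"),
    F416A = vapply(configs, `[[`, logical(1), "F416A"),
    compound = compound, concentration_uM = concentration_uM,
    shift_mV = rowMeans(reps),
    sem_mV = if (n_per_mutant > 1) apply(reps, 1, sd) / sqrt(n_per_mutant)
             else NA_real_,
    n = n_per_mutant)
  attr(out, "truth") <- list(s3s4_mV = s3s4_mV, pore_mV = pore_mV,
                             residual_mV = residual_mV, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate a toy ligand/channel trajectory with prescribed contacts
#'
#' Constructs a minimal trajectory in which each protein residue is a
#' pseudo-atom pair (one heavy carbon, one hydrogen) and the ligand is a
#' small rigid body of three heavy atoms plus one hydrogen. Residue sites
#' are spaced far apart; in each frame the ligand is either translated to
#' sit `contact_nm` above one scheduled residue (a contact, since
#' `contact_nm` is below the cutoff) or parked far from everything. The
#' number of contact frames per (residue, subunit) is
#' `round(fraction * n_frames)`, so [contact_frequency()] recovers the
#' schedule exactly at 1/n_frames granularity. Because one ligand can only
#' visit one site per frame, the scheduled fractions must sum to at most 1.
#'
#' The ligand hydrogen is deliberately placed closer to the residue than
#' any ligand heavy atom during contacts, so analyses that incorrectly
#' include hydrogens are detectable.
#'
#' @param contact_schedule Either a named numeric vector (names = residue
#'   numbers, values = contact fractions in \[0, 1\], applied to subunit
#'   "A") or a data frame with columns `resno`, `chain`, `fraction`.
#' @param n_frames Number of frames.
#' @param cutoff_nm Contact cutoff the schedule is built against (nm, > 0).
#' @param n_subunits Number of protein chains (1-4, labelled A-D). All
#'   scheduled residues exist in every subunit; unscheduled
#'   (residue, subunit) pairs get zero contacts.
#' @param contact_nm Ligand-residue heavy-atom distance during a contact
#'   frame (must be < `cutoff_nm`).
#' @param seed Optional seed; contact frames are spread over the
#'   trajectory in a seed-reproducible order (frequencies are unaffected).
#' @return A `"trajectory_slice"`: list with `xyz` (frame x atom x 3
#'   array, nm), `atoms` (data frame: `eleno`, `elety`, `resid`, `resno`,
#'   `chain`, `elesy`, `is_heavy`, `is_ligand`), `n_frames`, `box`
#'   (`NULL`: toy systems are non-periodic) and `meta` (the schedule and
#'   seed).
#' @examples
#' traj <- gen_trajectory(c(`10` = 0.4), n_frames = 10)
#' contact_frequency(traj, cutoff_nm = 0.45)$frequencies
#' @export
gen_trajectory <- function(contact_schedule, n_frames, cutoff_nm = 0.45,
                           n_subunits = 1, contact_nm = 0.30, seed = NULL) {
  if (cutoff_nm <= 0) stop("'cutoff_nm' must be > 0")
  if (contact_nm >= cutoff_nm)
    stop("'contact_nm' must be below the cutoff so scheduled frames count ",
         "as contacts")
  stopifnot(n_frames >= 1, n_subunits >= 1, n_subunits <= 4)
  n_frames <- as.integer(n_frames)
  if (!is.data.frame(contact_schedule)) {
    stopifnot(!is.null(names(contact_schedule)))
    contact_schedule <- data.frame(
      resno = as.integer(names(contact_schedule)), chain = "A",
      fraction = as.numeric(contact_schedule))
  }
  stopifnot(all(c("resno", "chain", "fraction") %in% names(contact_schedule)))
  if (any(contact_schedule$fraction < 0 | contact_schedule$fraction > 1))
    stop("contact fractions must lie in [0, 1]")
  if (!all(contact_schedule$chain %in% LETTERS[seq_len(n_subunits)]))
    stop("scheduled chains must be among ",
         paste(LETTERS[seq_len(n_subunits)], collapse = ", "))
  k <- round(contact_schedule$fraction * n_frames)
  if (sum(k) > n_frames)
    stop("scheduled contact fractions sum to more than 1: a single ligand ",
         "cannot satisfy them in ", n_frames, " frames")
  if (!is.null(seed)) set.seed(seed)

  chains <- LETTERS[seq_len(n_subunits)]
  resnos <- sort(unique(contact_schedule$resno))
  spacing <- 10 * cutoff_nm
  # protein: CA (heavy) + HA (hydrogen) per residue, laid out on a grid
  prot <- expand.grid(resno = resnos, chain = chains,
                      stringsAsFactors = FALSE)
  prot_xyz <- cbind(
    x = spacing * (match(prot$resno, resnos) - 1),
    y = spacing * (match(prot$chain, chains) - 1),
    z = 0)
  atoms <- data.frame(
    eleno = integer(0), elety = character(0), resid = character(0),
    resno = integer(0), chain = character(0), elesy = character(0))
  coords0 <- NULL
  for (i in seq_len(nrow(prot))) {
    atoms <- rbind(atoms,
      data.frame(eleno = NA, elety = c("CA", "HA"), resid = "GLY",
                 resno = prot$resno[i], chain = prot$chain[i],
                 elesy = c("C", "H")))
    coords0 <- rbind(coords0, prot_xyz[i, ],
                     prot_xyz[i, ] + c(0.05, 0, 0))
  }
  # rigid ligand: C1/C2/O1 heavy + H1; H1 nearest the residue in contacts
  lig_offsets <- rbind(C1 = c(0, 0, 0), C2 = c(0.12, 0, 0),
                       O1 = c(0, 0.12, 0), H1 = c(0, 0, -0.08))
  atoms <- rbind(atoms,
    data.frame(eleno = NA, elety = rownames(lig_offsets), resid = "LIG",
               resno = 999L, chain = "X",
               elesy = c("C", "C", "O", "H")))
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$is_heavy <- atoms$elesy != "H"
  atoms$is_ligand <- atoms$resid == "LIG"
  n_prot_atoms <- 2 * nrow(prot)

  # frame assignment: concatenate the per-site contact blocks, pad with
  # parked frames, then permute (seed-reproducible)
  site_of_frame <- rep(0L, n_frames)
  pos <- 1
  for (j in seq_len(nrow(contact_schedule))) {
    if (k[j] > 0) site_of_frame[pos:(pos + k[j] - 1)] <- j
    pos <- pos + k[j]
  }
  site_of_frame <- site_of_frame[sample.int(n_frames)]

  parked <- c(0, 0, 100)
  xyz <- array(NA_real_, dim = c(n_frames, nrow(atoms), 3))
  for (f in seq_len(n_frames)) {
    s <- site_of_frame[f]
    anchor <- if (s == 0L) parked else {
      i <- which(prot$resno == contact_schedule$resno[s] &
                 prot$chain == contact_schedule$chain[s])
      prot_xyz[i, ] + c(0, 0, contact_nm)
    }
    lig <- sweep(lig_offsets, 2, anchor, `+`)
    xyz[f, , ] <- rbind(coords0, lig)
  }
  structure(list(xyz = xyz, atoms = atoms, n_frames = n_frames, box = NULL,
                 meta = list(schedule = contact_schedule,
                             contact_counts = k, cutoff_nm = cutoff_nm,
                             contact_nm = contact_nm, seed = seed)),
            class = "trajectory_slice")
}

#' @export
print.trajectory_slice <- function(x, ...) {
  cat("Trajectory slice:", x$n_frames, "frames,", nrow(x$atoms), "atoms (",
      sum(x$atoms$is_ligand), "ligand ),",
      length(unique(x$atoms$chain[!x$atoms$is_ligand])), "protein chain(s)\n")
  invisible(x)
}
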