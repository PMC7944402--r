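# Independent brute-force oracles used to cross-check the fitters.
# These deliberately share no code with the package internals.

# Exhaustive lattice search for the Boltzmann parameters: returns the
# lattice point with minimal sse.
grid_search_boltzmann <- function(v, g, gmax_grid, vhalf_grid, s_grid) {
  best <- list(sse = Inf)
  for (gm in gmax_grid) for (vh in vhalf_grid) for (s in s_grid) {
    pred <- gm / (1 + exp((vh - v) / s))
    sse <- sum((g - pred)^2)
    if (sse < best$sse) best <- list(gmax = gm, v_half = vh, s = s, sse = sse)
  }
  best
}

# Exhaustive lattice search for the hyperbolic dose-response parameters.
grid_search_dose <- function(conc, shift, ec50_grid, dvmax_grid) {
  best <- list(sse = Inf)
  for (e in ec50_grid) for (d in dvmax_grid) {
    pred <- d / (1 + e / conc)
    sse <- sum((shift - pred)^2)
    if (sse < best$sse) best <- list(ec50 = e, dvmax = d, sse = sse)
  }
  best
}

# All-pairs double-loop minimum distance between two coordinate sets.
brute_min_dist <- function(A, B) {
  m <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    m <- min(m, sqrt(sum((A[i, ] - B[j, ])^2)))
  m
}

# Exhaustive two-sample permutation test on the pooled-variance t
# statistic; returns the two-sided p value.
perm_test_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  t_of <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  t_obs <- t_of(a, b)
  t_all <- apply(idx, 2, function(k) t_of(pooled[k], pooled[-k]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Assemble a current_family with hand-crafted sweep currents, bypassing
# the generator's signal model.
manual_family <- function(currents, protocol) {
  structure(list(protocol = protocol,
                 time_ms = seq(0, protocol$sweep_ms, by = protocol$dt_ms),
                 currents = currents, condition_label = "manual",
                 meta = list()),
            class = "current_family")
}

# Assemble a minimal one-residue trajectory_slice (ligand carbon + one
# residue carbon) whose per-frame ligand-residue distance is prescribed
# exactly: the ligand moves along z above the residue.
manual_slice <- function(distances_nm, resno = 1L, chain = "A") {
  n_frames <- length(distances_nm)
  atoms <- data.frame(
    eleno = 1:2, elety = c("CA", "C1"), resid = c("GLY", "LIG"),
    resno = c(as.integer(resno), 999L), chain = c(chain, "X"),
    elesy = "C", is_heavy = TRUE, is_ligand = c(FALSE, TRUE))
  xyz <- array(0, dim = c(n_frames, 2, 3))
  xyz[, 2, 3] <- distances_nm
  structure(list(xyz = xyz, atoms = atoms, n_frames = n_frames, box = NULL,
                 meta = list()),
            class = "trajectory_slice")
}
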