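# Shared fixtures: independent steady-state oracle and small model builders.

# Algebraic steady state of the two-cycle serial cascade, solved stage by
# stage with uniroot on the flux-balance equations. Independent of the ODE
# integrator and Newton polish used by the package.
serial_ss_oracle <- function(R = 1, T1 = 1, T2 = 1,
                             Vm1 = 1, Km1 = 0.5, Vd1 = 0.5, Kd1 = 0.5,
                             Vm2 = 1, Km2 = 0.5, Vd2 = 0.5, Kd2 = 0.5) {
  f1 <- function(x1) Vm1 * R * (T1 - x1) / (Km1 + (T1 - x1)) -
    Vd1 * x1 / (Kd1 + x1)
  x1 <- stats::uniroot(f1, c(1e-12, T1 - 1e-12), tol = 1e-14)$root
  f2 <- function(x2) Vm2 * x1 * (T2 - x2) / (Km2 + (T2 - x2)) -
    Vd2 * x2 / (Kd2 + x2)
  x2 <- stats::uniroot(f2, c(1e-12, T2 - 1e-12), tol = 1e-14)$root
  list(B_P = x1, C_P = x2)
}

# single irreversible conversion cycle: all substrate ends up activated
one_way_cycle <- function(total = 2, vmax = 1, km = 0.5, input = 1.5) {
  network_model(
    species = dplyr::bind_rows(
      species_spec("S", total, pool_partner = "S_P", pool_total = total),
      species_spec("S_P", 0)),
    reactions = mm_activation("act", "S", "S_P", modifier = "E",
                              vmax = vmax, km = km),
    output = "S_P", inputs = c(E = input))
}

# positive-feedback variant of the serial motif: the output accelerates the
# upstream activation instead of the deactivation
positive_feedback_motif <- function(params = motif_params()) {
  m <- serial_motif(params)
  m$reactions <- dplyr::bind_rows(
    m$reactions,
    mm_activation("feedback_B", "B", "B_P", modifier = "C_P",
                  vmax = params$fb_vmax[1], km = params$fb_km[1]))
  m
}

max_pool_deviation <- function(traj, model) {
  sp <- model$species
  dev <- 0
  for (i in seq_len(nrow(sp))) {
    if (is.na(sp$pool_partner[i])) next
    s <- traj$concentrations[, sp$name[i]] +
      traj$concentrations[, sp$pool_partner[i]]
    dev <- max(dev, max(abs(s - sp$pool_total[i])))
  }
  dev
}
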