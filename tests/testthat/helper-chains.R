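# Shared fixtures: small topologies and settings shortcuts.

tiny_topology <- function(n = 3, ...) chain_topology(n, ...)

# settings with minimal step counts, for constructors and plumbing tests
quick_settings <- function(mode = "sgcmc", pH = 9, theta = NULL,
                           ionic_strength = 0.1, ...) {
  simulation_settings(mode = mode, pH = if (mode == "sgcmc") pH else NULL,
                      theta = theta, ionic_strength = ionic_strength,
                      n_steps = 1000, n_equilibration = 100,
                      n_replicates = 2, sample_every = 10, ...)
}

# uniformly random conformation (optionally perturbing the elastic terms)
random_conformation <- function(topology, elastic = FALSE) {
  n_rot <- length(topology$rotatable_bonds)
  states <- sample(c("t", "g+", "g-"), n_rot, replace = TRUE)
  if (!elastic) return(conformation(topology, states))
  conformation(
    topology, states,
    rep(topology$l0, topology$n_bonds) +
      stats::rnorm(topology$n_bonds, 0, 0.05 * topology$l0),
    pmin(179, pmax(1, rep(topology$alpha0, topology$n_bonds - 1L) +
                     stats::rnorm(topology$n_bonds - 1L, 0, 5)))
  )
}

dihedral_codes <- function(conf) match(conf$dihedral_states, c("t", "g+", "g-")) - 1L

# total energy through the compiled code path for an explicit state
cpp_total_energy <- function(topology, conf, charges, settings) {
  sbris:::kernel_total_energy_cpp(
    sbris:::kernel_topology(topology), sbris:::kernel_ctrl(settings),
    as.numeric(charges), dihedral_codes(conf),
    conf$bond_lengths, conf$bond_angles * pi / 180)
}

expect_within_3se <- function(mc_value, mc_se, exact, label = "value") {
  tol <- 3 * mc_se + 1e-9
  expect_lt(abs(mc_value - exact), tol,
            label = sprintf("%s: |%.5g - %.5g| vs 3 SE = %.3g",
                            label, mc_value, exact, tol))
}
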