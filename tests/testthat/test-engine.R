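test_that("Metropolis rule accepts downhill always and uphill with exp(-dE)", {
  expect_true(all(metropolis_accept(rep(-2, 50))))
  expect_true(all(metropolis_accept(rep(0, 50))))
  expect_false(any(metropolis_accept(rep(Inf, 50))))
  set.seed(8)
  n <- 40000
  rate <- mean(metropolis_accept(rep(log(10), n)))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("protonation flips carry the expected energy changes", {
  topo <- chain_topology(3, eps_int = c(t = 0, gp = 0, gm = 0))
  st <- quick_settings(pH = 10, bjerrum_length = 0)
  state <- system_state(topo, st)
  # isolated site: dE = ln10 (pH - pK)
  prop <- propose_protonation_flip(state, topo, st, site = 2)
  expect_equal(prop$delta_energy, log(10) * (10 - 9), tolerance = 1e-12)
  # flip back is the exact reverse
  back <- propose_protonation_flip(prop$state, topo, st, site = 2)
  expect_equal(back$delta_energy, -prop$delta_energy, tolerance = 1e-12)
  # neighbour activation through the trans middle bond
  topo2 <- chain_topology(3)    # eps_int t = 1
  st2 <- quick_settings(pH = 9, bjerrum_length = 0)
  s0 <- system_state(topo2, st2, protonation = c(1, 0, 0))
  p2 <- propose_protonation_flip(s0, topo2, st2, site = 2)
  expect_equal(p2$delta_energy, log(10) * 1, tolerance = 1e-12)   # eps_int(t) = 1
  expect_error(propose_protonation_flip(state, topo,
                                        quick_settings("ccmc", theta = 0.5)),
               "sgcmc")
})

test_that("rotations are isoenergetic for an uncharged free chain and bookkeep otherwise", {
  topo <- chain_topology(4)
  st <- quick_settings(pH = 14, bjerrum_length = 0)
  state <- system_state(topo, st, protonation = rep(0L, 4))
  set.seed(9)
  for (i in 1:6) {
    prop <- propose_rotation(state, topo, st)
    expect_equal(prop$delta_energy, 0, tolerance = 1e-12)
  }
  # charged neighbours: t -> g costs ln10 (eps_g - eps_t) plus the DH change
  st2 <- quick_settings(pH = 2, ionic_strength = 0.1)
  s2 <- system_state(topo, st2, protonation = rep(1L, 4))
  prop <- propose_rotation(s2, topo, st2, bond = 2, new_state = "g+")
  xyz_old <- build_coordinates(topo, s2$conformation)
  xyz_new <- build_coordinates(topo, prop$state$conformation)
  env <- electrostatic_environment(0.1)
  dlr <- long_range_energy(rep(1, 4), xyz_new, env, topo) -
         long_range_energy(rep(1, 4), xyz_old, env, topo)
  expect_equal(prop$delta_energy, log(10) * (3 - 1) + dlr, tolerance = 1e-10)
})

test_that("elastic proposals need elastic sampling and clashes give infinite energy", {
  topo <- chain_topology(3)
  st <- quick_settings(pH = 9)
  state <- system_state(topo, st, protonation = rep(0L, 3))
  expect_error(propose_elastic_perturbation(state, topo, st), "elastic_sampling")
  st2 <- quick_settings(pH = 9, elastic_sampling = TRUE)
  set.seed(10)
  prop <- propose_elastic_perturbation(state, topo, st2, which = "length", index = 1)
  expect_true(is.finite(prop$delta_energy))
  expect_gt(prop$delta_energy, 0)  # any displacement off the minimum costs energy
})

test_that("identical master seeds give bit-identical runs, different seeds differ", {
  topo <- chain_topology(4)
  mk <- function(seed) simulation_settings("sgcmc", pH = 8, ionic_strength = 0.1,
                                           seed = seed, n_steps = 3e4,
                                           n_equilibration = 2e3, n_replicates = 2,
                                           sample_every = 10)
  r1 <- run_simulation(mk(123), topo)
  r2 <- run_simulation(mk(123), topo)
  r3 <- run_simulation(mk(124), topo)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$theta, r2$theta)
  expect_false(identical(r1$replicates, r3$replicates))
})

test_that("incremental energies track full recomputation through long move sequences", {
  topo <- chain_topology(5)
  st <- simulation_settings("sgcmc", pH = 7.5, ionic_strength = 0.05, force = 1,
                            elastic_sampling = TRUE, sev_enabled = TRUE,
                            seed = 77, n_steps = 4e4, n_equilibration = 1e3,
                            n_replicates = 2, sample_every = 100,
                            check_every = 500)
  res <- run_simulation(st, topo)
  expect_lt(res$max_energy_drift, 1e-9)
})

test_that("sampled elastic marginals match the harmonic closed forms", {
  topo <- chain_topology(3)
  st <- simulation_settings("ccmc", theta = 0, ionic_strength = 0.1,
                            elastic_sampling = TRUE, seed = 5,
                            move_mix = c(flip = 0, rotation = 0.2, elastic = 0.8),
                            n_steps = 4e5, n_equilibration = 2e4,
                            n_replicates = 1, sample_every = 20)
  out <- sbris:::run_chain_cpp(sbris:::kernel_topology(topo),
                               sbris:::kernel_ctrl(st, 1L))
  var_l <- var(out$bond_length_mid)
  var_a <- var(out$bond_angle_mid)
  expect_equal(var_l, 1 / topo$k_length_int, tolerance = 0.1)
  expect_equal(var_a, 1 / topo$k_angle_int, tolerance = 0.1)
  expect_equal(mean(out$bond_length_mid), topo$l0, tolerance = 0.01)
  expect_equal(mean(out$bond_angle_mid), topo$alpha0 * pi / 180, tolerance = 0.01)
})

test_that("gauche+ and gauche- are populated symmetrically", {
  topo <- chain_topology(6)
  st <- simulation_settings("sgcmc", pH = 8.5, ionic_strength = 0.1, seed = 3,
                            n_steps = 2e5, n_equilibration = 2e4,
                            n_replicates = 4, sample_every = 25)
  res <- run_simulation(st, topo)
  diff <- res$replicates$p_gauche_plus - res$replicates$p_gauche_minus
  se <- sd(diff) / sqrt(length(diff))
  expect_lt(abs(mean(diff)), 3 * se + 0.005)
})

test_that("titration is monotonically non-increasing in pH", {
  topo <- chain_topology(6)
  thetas <- vapply(c(5, 7, 8.5, 9.5, 11), function(p) {
    st <- simulation_settings("sgcmc", pH = p, ionic_strength = 0.1, seed = 11,
                              n_steps = 1e5, n_equilibration = 1e4,
                              n_replicates = 2, sample_every = 25)
    run_simulation(st, topo)$theta
  }, numeric(1))
  expect_true(all(diff(thetas) < 0.02))   # allow 3-SE-scale wiggle
})

test_that("ccmc at full charge matches sgcmc at pH far below pK", {
  topo <- chain_topology(4)
  common <- list(ionic_strength = 0.1, seed = 21, n_steps = 2e5,
                 n_equilibration = 2e4, n_replicates = 4, sample_every = 25)
  r_sg <- run_simulation(do.call(simulation_settings,
                                 c(list(mode = "sgcmc", pH = 0), common)), topo)
  r_cc <- run_simulation(do.call(simulation_settings,
                                 c(list(mode = "ccmc", theta = 1), common)), topo)
  expect_equal(r_sg$theta, 1, tolerance = 1e-4)
  se <- sqrt(r_sg$persistence_length_se^2 + r_cc$persistence_length_se^2)
  expect_lt(abs(r_sg$persistence_length - r_cc$persistence_length), 3 * se + 1e-4)
})
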