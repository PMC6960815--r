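test_that("rotational energy counts per-state torsional costs", {
  topo <- chain_topology(4)
  conf <- conformation(topo, c("g+", "t", "g-"))
  expect_equal(rotational_energy(conf), 0)                       # default all zero
  expect_equal(rotational_energy(conf, c(t = 0, gp = 1, gm = 1)), 2)
  empty <- structure(list(dihedral_states = character(0)), class = "chain_conformation")
  expect_equal(rotational_energy(empty), 0)
  expect_error(rotational_energy(conf, c(t = 0, gp = 1, gm = 2)), "symmetric")
})

test_that("proton-binding term is ln10 (pH - pK) per protonated site", {
  expect_equal(protonation_energy(c(0, 0, 0), pH = 12, pK = 9), 0)
  expect_equal(protonation_energy(c(1, 0, 1, 1), pH = 9, pK = 9), 0)
  expect_equal(protonation_energy(c(1, 1), pH = 10, pK = 9), 2 * log(10))
})

test_that("Debye-Hueckel term reproduces hand-evaluated pair energies", {
  topo <- chain_topology(3)
  coords <- matrix(0, topo$n_nodes, 3)
  coords[, 1] <- seq_len(topo$n_nodes) * 10   # spread out, only sites 1,3 matter
  coords[topo$site_nodes[1], ] <- c(0, 0, 0)
  coords[topo$site_nodes[3], ] <- c(0, 0, 0.7)
  q <- c(1, 0, 1)
  # unscreened Coulomb at one Bjerrum length
  expect_equal(long_range_energy(q, coords, electrostatic_environment(0), topo), 1.0)
  # kappa d = 1 at I = 1 M and d = 0.304 nm
  coords[topo$site_nodes[3], ] <- c(0, 0, 0.304)
  e <- long_range_energy(q, coords, electrostatic_environment(1), topo)
  expect_equal(e, 0.7 / 0.304 * exp(-1), tolerance = 1e-12)
  expect_equal(e, 0.8471, tolerance = 1e-4)
  # zero charges; coincident charges
  expect_equal(long_range_energy(c(0, 0, 0), coords, electrostatic_environment(1), topo), 0)
  coords[topo$site_nodes[3], ] <- coords[topo$site_nodes[1], ]
  expect_error(long_range_energy(q, coords, electrostatic_environment(1), topo),
               "singularity")
})

test_that("nearest-neighbour pairs are excluded from the long-range sum", {
  topo <- chain_topology(3)
  coords <- build_coordinates(topo, conformation(topo))
  # only the (1,3) pair contributes: charging sites 1,2 gives zero
  expect_equal(long_range_energy(c(1, 1, 0), coords, electrostatic_environment(0.1), topo), 0)
  expect_gt(long_range_energy(c(1, 0, 1), coords, electrostatic_environment(0.1), topo), 0)
})

test_that("short-range term couples consecutive charged sites through the middle bond", {
  topo <- chain_topology(2)
  both <- c(1, 1)
  expect_equal(short_range_energy(both, conformation(topo, "t")), log(10))
  expect_equal(short_range_energy(both, conformation(topo, "g+")), 3 * log(10))
  expect_equal(short_range_energy(both, conformation(topo, "g-")), 3 * log(10))
  expect_equal(short_range_energy(c(1, 0), conformation(topo, "g+")), 0)
  # smeared charges scale as theta^2
  expect_equal(short_range_energy(c(0.5, 0.5), conformation(topo, "t")),
               0.25 * log(10))
})

test_that("elastic energy matches the reference force constants", {
  topo <- chain_topology(3)
  expect_equal(elastic_energy(conformation(topo), topo), 0)
  dl <- conformation(topo)
  dl$bond_lengths[2] <- topo$l0 + 0.01           # +0.1 Angstrom
  expect_equal(elastic_energy(dl, topo), 1.5 * 1.6878, tolerance = 1e-12)
  da <- conformation(topo)
  da$bond_angles[3] <- topo$alpha0 + 10
  expect_equal(elastic_energy(da, topo), 0.5 * 1.6878, tolerance = 1e-12)
})

test_that("mechanical work is -F rz in kBT units", {
  coords <- rbind(c(0, 0, 0), c(1, 1, 4.1164))
  expect_equal(mechanical_work(coords, 0), 0)
  expect_equal(mechanical_work(coords, 1), -1)
  flat <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_equal(mechanical_work(flat, 25), 0)
})

test_that("excluded volume flags only genuine hard-sphere overlaps", {
  topo <- chain_topology(50)
  xyz <- build_coordinates(topo, conformation(topo))
  expect_false(sev_overlap(xyz, topo))                 # extended chain is clash-free
  expect_false(sev_overlap(xyz, chain_topology(50, radius_ionizable = 0,
                                               radius_inert = 0)))
  small <- chain_topology(3)
  xyz2 <- build_coordinates(small, conformation(small))
  xyz2[7, ] <- xyz2[1, ] + c(0.2, 0, 0)                # 5 bonds apart, d = 0.2 nm
  expect_true(sev_overlap(xyz2, small))                # 0.2 < 0.155 + 0.17
  expect_false(sev_overlap(xyz2, small, enabled = FALSE))
})

test_that("total free energy is the sum of its terms and vanishes for the trivial state", {
  topo <- chain_topology(4)
  st <- quick_settings(pH = 9, ionic_strength = 1)
  e0 <- total_free_energy(topo, conformation(topo), rep(0, 4), st)
  expect_equal(as.numeric(e0), 0)
  set.seed(4)
  conf <- random_conformation(topo, elastic = TRUE)
  s <- c(1, 0, 1, 1)
  e <- total_free_energy(topo, conf, s, st)
  expect_equal(as.numeric(e), sum(attr(e, "terms")))
  # each single term reproduced by direct evaluation
  terms <- attr(e, "terms")
  env <- electrostatic_environment(1)
  xyz <- build_coordinates(topo, conf)
  expect_equal(unname(terms["protonation"]), protonation_energy(s, 9, topo$pK))
  expect_equal(unname(terms["long_range"]), long_range_energy(s, xyz, env, topo))
  expect_equal(unname(terms["elastic"]), elastic_energy(conf, topo))
})

test_that("compiled and plain-R total energies agree on random states", {
  set.seed(5)
  topo <- chain_topology(5)
  for (i in 1:8) {
    st <- simulation_settings("sgcmc", pH = runif(1, 4, 11),
                              ionic_strength = sample(c(1, 0.1, 0.001), 1),
                              force = sample(c(0, 1.5), 1),
                              sev_enabled = sample(c(TRUE, FALSE), 1),
                              elastic_sampling = TRUE,
                              n_steps = 10, n_equilibration = 0)
    conf <- random_conformation(topo, elastic = TRUE)
    s <- sample(0:1, 5, replace = TRUE)
    eR <- as.numeric(total_free_energy(topo, conf, s, st))
    eC <- cpp_total_energy(topo, conf, s, st)
    if (is.infinite(eR)) expect_equal(eC, eR) else expect_equal(eC, eR, tolerance = 1e-9)
  }
})

test_that("smeared charges at theta 0 or 1 match the frozen fluctuating limits", {
  topo <- chain_topology(4)
  set.seed(6)
  conf <- random_conformation(topo)
  env <- electrostatic_environment(0.1)
  xyz <- build_coordinates(topo, conf)
  for (th in c(0, 1)) {
    q_sm <- rep(th, 4)
    s_eq <- rep(th, 4)
    expect_equal(long_range_energy(q_sm, xyz, env, topo),
                 long_range_energy(s_eq, xyz, env, topo))
    expect_equal(short_range_energy(q_sm, conf), short_range_energy(s_eq, conf))
  }
})

test_that("screening makes the long-range energy non-increasing in ionic strength", {
  topo <- chain_topology(5)
  set.seed(7)
  conf <- random_conformation(topo)
  xyz <- build_coordinates(topo, conf)
  q <- rep(1, 5)
  e <- vapply(c(0.0001, 0.001, 0.01, 0.1, 1, 10),
              function(I) long_range_energy(q, xyz, electrostatic_environment(I), topo),
              numeric(1))
  expect_true(all(diff(e) <= 1e-12))
})
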