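test_that("non-interacting two-site chain titrates ideally and populates states uniformly", {
  topo <- chain_topology(2, eps_int = c(t = 0, gp = 0, gm = 0))
  st <- quick_settings(pH = 9, bjerrum_length = 0)
  ex <- enumerate_states(topo, st)
  expect_equal(ex$theta, 0.5, tolerance = 1e-12)
  expect_equal(ex$p_gauche, 2 / 3, tolerance = 1e-12)
  expect_equal(ex$capacitance, 2 * 0.5 * 0.5, tolerance = 1e-12)  # binomial
})

test_that("short-range repulsion suppresses protonation and gauche states (12-state sum)", {
  # hand enumeration: at pH = pK and lB = 0 every state has weight 1 except
  # the doubly protonated ones, which carry 10^-eps(phi)
  w11 <- c(t = 10^-1, g = 10^-3)
  Z <- 9 + w11[["t"]] + 2 * w11[["g"]]
  theta_hand <- (6 + 2 * (w11[["t"]] + 2 * w11[["g"]])) / (2 * Z)
  pg_hand <- (2 * (3 + w11[["g"]])) / Z
  m2 <- (6 + 4 * (w11[["t"]] + 2 * w11[["g"]])) / Z
  cap_hand <- m2 - (2 * theta_hand)^2

  topo <- chain_topology(2)   # reference eps_int: t = 1, g = 3
  st <- quick_settings(pH = 9, bjerrum_length = 0)
  ex <- enumerate_states(topo, st)
  expect_equal(ex$theta, theta_hand, tolerance = 1e-12)
  expect_equal(ex$p_gauche, pg_hand, tolerance = 1e-12)
  expect_equal(ex$capacitance, cap_hand, tolerance = 1e-12)
  expect_lt(ex$theta, 0.5)
  expect_lt(ex$p_gauche, 2 / 3)
})

test_that("ideal titration limits are exact", {
  expect_equal(ideal_titration(9, 9), 0.5)
  expect_equal(ideal_titration(7, 9), 1 / 1.01, tolerance = 1e-12)
  expect_equal(ideal_titration(100, 9), 0)
  expect_equal(ideal_titration(-100, 9), 1)
})

test_that("enumeration converges to the ideal curve as couplings vanish", {
  topo <- chain_topology(3, eps_int = c(t = 0, gp = 0, gm = 0))
  for (p in c(7, 9, 10.5)) {
    st <- quick_settings(pH = p, bjerrum_length = 0)
    expect_equal(enumerate_states(topo, st)$theta, ideal_titration(p, 9),
                 tolerance = 1e-12)
  }
})

test_that("enumerated capacitance equals N dtheta/dmu by finite differences", {
  topo <- chain_topology(3)
  for (p in c(6.5, 8, 9.5)) {
    d <- 1e-4
    th <- vapply(c(p - d / 2, p + d / 2), function(pp)
      enumerate_states(topo, quick_settings(pH = pp, ionic_strength = 1))$theta,
      numeric(1))
    cfd <- capacitance_from_titration(th[1], th[2], d, 3)
    ex <- enumerate_states(topo, quick_settings(pH = p, ionic_strength = 1))
    expect_equal(ex$capacitance, cfd, tolerance = 1e-6)
  }
})

test_that("enumeration respects mode and size constraints", {
  topo <- chain_topology(3)
  expect_error(enumerate_states(chain_topology(20), quick_settings()),
               "state space too large")
  expect_error(enumerate_states(topo, quick_settings(elastic_sampling = TRUE)),
               "rigid")
  cc <- enumerate_states(topo, quick_settings("ccmc", theta = 0.4))
  expect_equal(cc$theta, 0.4)
  expect_true(is.na(cc$capacitance))
})

test_that("oracle extension under force follows the orientational average", {
  # a rigid rod of fixed length r must satisfy <rz> = r L(beta F r)
  topo <- chain_topology(2, eps_int = c(t = 0, gp = 0, gm = 0),
                         eps_rot = c(t = 0, gp = 1e6, gm = 1e6))  # frozen trans
  st <- simulation_settings("sgcmc", pH = 20, ionic_strength = 1,
                            bjerrum_length = 0, force = 2,
                            n_steps = 10, n_equilibration = 0)
  ex <- enumerate_states(topo, st)
  conf <- conformation(topo)
  r <- sqrt(sum(end_to_end_vector(build_coordinates(topo, conf))^2))
  x <- 2 * r / sbris_constants$kBT_pN_nm
  expect_equal(ex$extension_z, r * (1 / tanh(x) - 1 / x), tolerance = 1e-9)
  expect_equal(ex$mean_sq_end_to_end, r^2, tolerance = 1e-9)
})
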