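test_that("capacitance is the variance of the bound-proton count", {
  expect_equal(binding_capacitance(c(5, 5, 5, 5)), 0)
  x <- c(0, 1, 0, 1)
  expect_equal(binding_capacitance(x), 0.25)
  expect_error(binding_capacitance(x, mode = "ccmc"), "undefined")
})

test_that("gauche probability uses the rotatable-bond denominator by default", {
  topo <- chain_topology(4)   # 3 rotatable of 9 bonds
  expect_equal(gauche_probability(c(0, 0, 0), topo), 0)
  expect_equal(gauche_probability(c(2, 1, 3), topo), 2 / 3)
  expect_equal(gauche_probability(c(2, 1, 3), topo, denominator = "all"), 2 / 9)
})

test_that("persistence length from <r2> reproduces the closed-form limits", {
  topo <- chain_topology(4)
  M <- topo$n_bonds; l0 <- topo$l0
  expect_equal(persistence_length_from_r2(M * l0^2, topo), l0)          # ideal chain
  expect_equal(persistence_length_from_r2((M * l0)^2, topo), M * l0 / 2 + l0 / 2)
  expect_equal(persistence_length_from_r2(0, topo), l0 / 2)             # lower bound
  expect_error(persistence_length_from_r2(-1, topo))
})

test_that("projection estimator: perfectly correlated and uncorrelated bonds", {
  topo <- chain_topology(6)
  xyz <- build_coordinates(topo, conformation(topo))
  M <- topo$n_bonds; c0 <- M %/% 2L
  # zig-zag: cos(0) for even offsets, cos(60 deg) for odd offsets
  n_all <- M - c0 + 1L
  n_odd <- sum((seq(c0, M) - c0) %% 2L == 1L)
  expected <- topo$l0 * ((n_all - n_odd) + 0.5 * n_odd)
  expect_equal(persistence_length_projection(xyz), expected, tolerance = 1e-9)

  # freely jointed reference: only the self term survives
  set.seed(31)
  fj <- replicate(4000, {
    u <- matrix(rnorm(30 * 3), 30)
    u <- u / sqrt(rowSums(u^2)) * 0.15
    apply(rbind(0, u), 2, cumsum)
  }, simplify = FALSE)
  lp <- persistence_length_projection(fj)
  expect_lt(abs(lp - 0.15), 0.02)
})

test_that("both persistence-length estimators agree for an uncharged long chain", {
  topo <- chain_topology(40)
  st <- simulation_settings("ccmc", theta = 0, ionic_strength = 0.1, seed = 13,
                            n_steps = 6e5, n_equilibration = 6e4,
                            n_replicates = 2, sample_every = 50)
  res <- run_simulation(st, topo)
  expect_lt(abs(res$persistence_length_projection - res$persistence_length) /
              res$persistence_length, 0.10)
})

test_that("Kirkwood-Shumaker energy has the exact limiting forms", {
  env <- electrostatic_environment(0.1)
  expect_equal(kirkwood_shumaker_energy(2, 0, 1.4, env), 0.7 * 4 / 1.4)
  expect_lt(kirkwood_shumaker_energy(0, 3, 2, env), 0)     # pure fluctuation attraction
  expect_equal(kirkwood_shumaker_energy(1, 1, 0.7, env), -0.5)
  expect_error(kirkwood_shumaker_energy(1, 1, 0, env), "positive")
})

test_that("replicate and block standard errors behave as advertised", {
  expect_equal(replicate_standard_error(c(2, 2, 2)), 0)
  expect_equal(replicate_standard_error(c(0, 1)), 0.5)
  expect_warning(se1 <- replicate_standard_error(3), "fewer than 2")
  expect_true(is.na(se1))

  # AR(1) series with known variance of the mean
  set.seed(17)
  phi <- 0.8; n <- 60000
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  analytic <- sqrt(1 / (1 - phi^2) * (1 + phi) / (1 - phi) / n)
  blocked <- block_standard_error(x, n_blocks = 40)
  naive <- sd(x) / sqrt(n)
  expect_lt(abs(blocked - analytic) / analytic, 0.3)
  expect_gt(blocked, 1.8 * naive)   # blocking must see the autocorrelation
})
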