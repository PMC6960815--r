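test_that("all-trans rigid chain is the planar zig-zag with the expected extension", {
  topo <- chain_topology(50)
  xyz <- build_coordinates(topo, conformation(topo))
  r <- end_to_end_vector(xyz)
  expect_equal(sqrt(sum(r^2)), 147 * 0.15 * cos(pi / 6), tolerance = 1e-3)
  # bond lengths and angles reproduced exactly
  d <- xyz[-1, ] - xyz[-nrow(xyz), ]
  expect_equal(sqrt(rowSums(d^2)), rep(0.15, 147), tolerance = 1e-12)
  expect_true(all(abs(xyz[, "y"]) < 1e-12))   # planar construction
})

test_that("first bond lies on the reference axis", {
  topo <- chain_topology(2)
  xyz <- build_coordinates(topo, conformation(topo))
  expect_equal(unname(xyz[2, ] - xyz[1, ]), c(0, 0, topo$l0))
  expect_equal(unname(xyz[1, ]), c(0, 0, 0))
})

test_that("end-to-end vector handles single bonds and closed loops", {
  expect_equal(end_to_end_vector(rbind(c(0, 0, 0), c(0, 0, 0.15))), c(0, 0, 0.15))
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(end_to_end_vector(loop), c(0, 0, 0))
})

test_that("swapping every gauche+ with gauche- leaves all pair distances unchanged", {
  topo <- chain_topology(5)
  set.seed(42)
  for (i in 1:5) {
    conf <- random_conformation(topo)
    states_m <- chartr("+-", "-+", conf$dihedral_states)
    conf_m <- conformation(topo, states_m)
    d1 <- dist(build_coordinates(topo, conf))
    d2 <- dist(build_coordinates(topo, conf_m))
    expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-9)
  }
})

test_that("internal-coordinate round trip is idempotent", {
  topo <- chain_topology(4)
  set.seed(1)
  for (i in 1:5) {
    conf <- random_conformation(topo, elastic = TRUE)
    xyz <- build_coordinates(topo, conf)
    back <- sbris:::coords_to_internal(topo, xyz)
    expect_equal(back$dihedral_states, conf$dihedral_states)
    expect_equal(back$bond_lengths, conf$bond_lengths, tolerance = 1e-9)
    expect_equal(back$bond_angles, conf$bond_angles, tolerance = 1e-9)
    xyz2 <- build_coordinates(topo, back)
    expect_equal(xyz2, xyz, tolerance = 1e-9)
  }
})

test_that("pair distances are invariant under rigid motion of the frame", {
  topo <- chain_topology(4)
  set.seed(2)
  conf <- random_conformation(topo)
  xyz <- build_coordinates(topo, conf)
  th <- 0.7; ax <- c(1, 2, -1) / sqrt(6)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- sweep(xyz %*% t(R), 2, c(3, -1, 2), `+`)
  expect_equal(as.vector(dist(moved)), as.vector(dist(xyz)), tolerance = 1e-9)
})

test_that("compiled and plain-R geometry agree", {
  topo <- chain_topology(5)
  set.seed(3)
  for (i in 1:5) {
    conf <- random_conformation(topo, elastic = TRUE)
    xyzR <- build_coordinates(topo, conf)
    xyzC <- sbris:::kernel_build_coords_cpp(
      sbris:::kernel_topology(topo), dihedral_codes(conf),
      conf$bond_lengths, conf$bond_angles * pi / 180)
    expect_lt(max(abs(xyzR - unname(xyzC))), 1e-12)
  }
})

test_that("XYZ export writes a readable snapshot", {
  topo <- chain_topology(3)
  xyz <- build_coordinates(topo, conformation(topo))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(xyz, topo, f)
  lines <- readLines(f)
  expect_equal(as.integer(lines[1]), topo$n_nodes)
  expect_length(lines, topo$n_nodes + 2L)
  expect_match(lines[3], "^N ")   # first node ionizable
  expect_match(lines[4], "^C ")
})
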