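test_that("model_params derives constants from their defining expressions", {
  p <- model_params()
  expect_identical(p$s_fene, -(98 / 5) * 1^2 * (3 / 7)^2 / 2)
  expect_equal(p$s_fene, -1.8)
  expect_equal(p$sigma, 2^(-1 / 6))
  expect_equal(p$rc, 2.5 * 2^(-1 / 6))
  expect_equal(p$vc, 4 * ((p$sigma / p$rc)^12 - (p$sigma / p$rc)^6))
  # derived constants are recomputed, never stored stale
  p2 <- model_params(r0 = 2, R = 0.5)
  expect_equal(p2$sigma, 2^(-1 / 6) * 2)
  expect_equal(p2$s_fene, -(98 / 5) * 4 * 0.25 / 2)
  expect_error(model_params(s_tau = -1))
  expect_error(model_params(R = 2)) # R must stay below r0
})

test_that("FENE potential matches its formula and respects its domain", {
  p <- model_params()
  expect_identical(v_fene(1, p), 0)
  expect_equal(v_fene(1.2, p), log(1 - (0.2 * 7 / 3)^2), tolerance = 1e-12)
  expect_equal(v_fene(1.2, p), -0.2456, tolerance = 1e-3)
  expect_equal(v_fene(0.8, p), v_fene(1.2, p)) # symmetric in |r - r0|
  expect_error(v_fene(1 + 3 / 7, p), "FENE domain")
  expect_error(v_fene(0.5, p), "FENE domain")
})

test_that("LJ potential is truncated, shifted, and continuous at the cutoff", {
  p <- model_params()
  expect_identical(v_lj(p$rc, p), 0)
  expect_identical(v_lj(10, p), 0)
  eps <- 1e-9
  expect_lt(abs(v_lj(p$rc - eps, p) - 0), 1e-7) # left limit agrees
  # minimum at r0 with depth 1 before the shift
  expect_equal(v_lj(p$r0, p), -1 - p$vc, tolerance = 1e-12)
  expect_gt(v_lj(0.8, p), v_lj(1, p))
  expect_error(v_lj(-1, p), "positive")
})

test_that("bending and torsion potentials vanish only at the reference", {
  p <- model_params()
  expect_identical(v_bend(p$theta0, p), 0)
  expect_identical(v_torsion(p$tau0, p), 0)
  th <- seq(0, pi, by = 0.1)
  expect_true(all(v_bend(th, p) >= 0 & v_bend(th, p) <= 2))
  # chirality: the torsion penalty is asymmetric under tau -> -tau
  expect_gt(v_torsion(-p$tau0, p), 1)
})

test_that("angle computations match elementary geometry", {
  p <- model_params()
  # straight chain: zero bond-vector angle
  expect_equal(bending_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), p), 0)
  # right angle
  expect_equal(bending_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), p), pi / 2)
  # interior convention flips to pi minus the bond-vector angle
  pint <- model_params(angle_convention = "interior")
  expect_equal(bending_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), pint), pi)
  # planar cis arrangement -> dihedral 0, trans -> pi
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, -1, 0))), pi)
  # mirror-imaging negates the signed dihedral
  a <- c(0.2, 1, 0.3); b <- c(0, 0, 0); cc <- c(1, 0.1, 0); d <- c(1.2, 1, 0.8)
  t1 <- dihedral_angle(a, b, cc, d)
  mir <- function(v) c(v[1], v[2], -v[3])
  expect_equal(dihedral_angle(mir(a), mir(b), mir(cc), mir(d)), -t1)
  # four points of an ideal helix reproduce tau0
  h <- ideal_helix(8, p)
  expect_equal(dihedral_angle(h[1, ], h[2, ], h[3, ], h[4, ]), p$tau0,
               tolerance = 1e-10)
})

test_that("total energy equals an independent brute-force oracle", {
  p <- model_params(s_tau = 8)
  set.seed(101)
  for (n in c(4, 7, 12)) {
    x <- random_valid_chain(n, p)
    expect_equal(total_energy(x, p), oracle_energy(x, p), tolerance = 1e-10)
    expect_equal(order_q(x, p), oracle_q(x, p), tolerance = 1e-10)
  }
  # dimer: no LJ/bend/torsion terms at all
  dimer <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_identical(total_energy(dimer, p), 0)
})

test_that("the bonded-pair switch changes the LJ sum as documented", {
  set.seed(7)
  pb <- model_params(lj_bonded = TRUE)
  p <- model_params()
  x <- random_valid_chain(8, p)
  expect_equal(total_energy(x, pb), oracle_energy(x, pb), tolerance = 1e-10)
  bonds <- sqrt(rowSums((x[-1, ] - x[-8, ])^2))
  expect_equal(total_energy(x, pb) - total_energy(x, p),
               sum(v_lj(bonds, p)), tolerance = 1e-10)
})

test_that("H and q are invariant under rigid motions", {
  p <- model_params(s_tau = 8)
  set.seed(11)
  x <- random_valid_chain(20, p)
  e0 <- total_energy(x, p)
  q0 <- order_q(x, p)
  for (k in 1:5) {
    y <- random_rigid_motion(x)
    expect_lt(abs(total_energy(y, p) - e0), 1e-9)
    expect_lt(abs(order_q(y, p) - q0), 1e-9)
  }
})

test_that("energy decomposition is consistent and FENE errors propagate", {
  p <- model_params(s_tau = 8)
  h <- ideal_helix(30, p)
  tt <- energy_terms(h, p)
  expect_equal(tt$energy, tt$unscaled * tt$scale)
  expect_equal(sum(tt$energy), total_energy(h, p))
  bad <- h
  bad[2, ] <- bad[1, ] + c(2, 0, 0) # bond stretched past r0 + R
  expect_error(total_energy(bad, p), "FENE domain")
  expect_error(total_energy(matrix(0, 3, 2)), "N x 3")
})

test_that("order parameter q follows its defining pair sets", {
  p <- model_params()
  # numerator needs |i - j| > 6: impossible below 8 monomers
  for (n in c(4, 6, 7)) {
    expect_identical(order_q(ideal_helix(n, p), p), 0)
  }
  # ideal single helix: all long-range pairs beyond the LJ cutoff
  h <- ideal_helix(30, p)
  q <- order_q(h, p)
  expect_lt(q, 0.02) # falls in the lowest histogram bin (center 0.01)
  expect_gte(q, 0)
  # fully extended chain: empty denominator -> 0 by convention
  straight <- cbind(0:9, 0, 0)
  expect_identical(order_q(straight, p), 0)
})

test_that("chain_geometry round-trips the internal coordinates", {
  p <- model_params()
  h <- ideal_helix(12, p)
  g <- chain_geometry(h, p)
  expect_equal(g$bond[1:11], rep(p$r0, 11), tolerance = 1e-10)
  expect_equal(g$theta[2:11], rep(p$theta0, 10), tolerance = 1e-10)
  expect_equal(g$tau[1:9], rep(p$tau0, 9), tolerance = 1e-10)
})
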