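p <- model_params(s_tau = 8)

test_that("build_chain round-trips through chain_geometry", {
  set.seed(61)
  n <- 9
  r <- runif(n - 1, 0.9, 1.1)
  th <- runif(n - 2, 0.5, 2.5)
  ta <- runif(n - 3, -3, 3)
  x <- build_chain(n, r, th, ta, p)
  g <- chain_geometry(x, p)
  expect_equal(g$bond[1:(n - 1)], r, tolerance = 1e-9)
  expect_equal(g$theta[2:(n - 1)], th, tolerance = 1e-9)
  expect_equal(g$tau[1:(n - 3)], ta, tolerance = 1e-9)
  # interior-angle convention round-trips too
  pi_ <- model_params(s_tau = 8, angle_convention = "interior")
  xi <- build_chain(n, r, th, ta, pi_)
  gi <- chain_geometry(xi, pi_)
  expect_equal(gi$theta[2:(n - 1)], th, tolerance = 1e-9)
})

test_that("the ideal helix zeroes its bend and torsion energies", {
  x <- ideal_helix(30, p)
  g <- chain_geometry(x, p)
  expect_equal(g$bond[1:29], rep(1, 29), tolerance = 1e-10)
  expect_equal(g$theta[2:29], rep(p$theta0, 28), tolerance = 1e-10)
  expect_equal(g$tau[1:27], rep(p$tau0, 27), tolerance = 1e-10)
  et <- energy_terms(x, p)
  expect_equal(et$energy[et$term == "fene"], 0, tolerance = 1e-12)
  expect_equal(et$energy[et$term == "bend"], 0, tolerance = 1e-12)
  expect_equal(et$energy[et$term == "torsion"], 0, tolerance = 1e-12)
  # a single helix has essentially no long-range contacts
  expect_lt(abs(order_q(x, p)), 0.02)
  expect_error(ideal_helix(3, p))
})

test_that("random coils have exact bonds and differ between draws", {
  set.seed(62)
  x <- random_coil(20, p)
  b <- sqrt(rowSums((x[-1, ] - x[-20, ])^2))
  expect_equal(b, rep(p$r0, 19), tolerance = 1e-12)
  y <- random_coil(20, p)
  expect_false(identical(x, y))
})

test_that("the two-helix template is a valid near-balanced bundle seed", {
  x <- two_helix_template(30, p)
  expect_identical(dim(x), c(30L, 3L))
  b <- sqrt(rowSums((x[-1, ] - x[-30, ])^2))
  # every bond inside the FENE domain
  expect_true(all(abs(b - p$r0) < p$R))
  expect_true(is.finite(total_energy(x, p)))
  # helix segments balanced to within one monomer (2 turn monomers)
  n1 <- ceiling((30 - 2) / 2)
  expect_lte(abs(n1 - (30 - 2 - n1)), 1)
  # the two segments face each other: many long-range pairs inside the
  # LJ cutoff (the raw seed is strained, so q itself is only meaningful
  # after relaxation)
  d <- as.matrix(stats::dist(x))
  long_contacts <- sum(d[abs(row(d) - col(d)) > 6] < p$rc) / 2
  expect_gt(long_contacts, 10)
  # energy invariant under rigid motion
  set.seed(63)
  xr <- random_rigid_motion(x)
  expect_equal(total_energy(xr, p), total_energy(x, p), tolerance = 1e-8)
  expect_error(two_helix_template(8, p))
})

test_that("a short relaxation keeps the template in the bundle q band", {
  s <- build_schedule(n = 30, n_temp = 1, t_range = c(0.2, 0.2), s_tau = 8,
                      sweeps = 1500, burn_in = 0, tune_steps = FALSE,
                      move_mix = c(local = 0.8, global = 0,
                                   bend = 0.1, torsion = 0.1),
                      local_step = 0.1, max_bend = 0.1, max_torsion = 0.1)
  set.seed(64)
  res <- run_thread_sweeps(two_helix_template(30, p), p, beta = 5,
                           n_sweeps = 1500, schedule = s)
  qbar <- mean(res$trace$q[1001:1500])
  expect_gt(qbar, 0.30)
  expect_lt(qbar, 0.50)
  # relaxation lowers the energy from the synthetic seed
  expect_lt(res$trace$E[1500], total_energy(two_helix_template(30, p), p))
})

test_that("the enumerable system matches its closed forms", {
  sys <- enumerable_system(c(0, 1), c(1, 2))
  expect_equal(sys$mean_energy(log(2)), 0.5)
  expect_equal(sys$log_z(0), log(3))
  b <- 0.7
  z <- 1 + 2 * exp(-b)
  expect_equal(sys$log_z(b), log(z))
  expect_equal(sys$probabilities(b), c(1, 2 * exp(-b)) / z)
  e1 <- 2 * exp(-b) / z
  expect_equal(sys$mean_energy(b), e1)
  expect_equal(sys$specific_heat(b), b^2 * (e1 - e1^2))
  set.seed(65)
  m <- 2e5
  cnt <- sys$sample_counts(b, m)
  expect_identical(sum(cnt), as.integer(m))
  expect_lt(abs(cnt[2] / m - 2 * exp(-b) / z), 0.01)
  expect_error(enumerable_system(0, 1))
})

test_that("planted entropy carries the truth and stays smooth", {
  pe <- planted_entropy(order = 2, e_t = -3)
  truth <- attr(pe, "truth")
  expect_identical(truth$order, 2)
  expect_identical(truth$energy, -3)
  expect_true(all(diff(pe$S) > 0)) # entropy increasing on the grid
  expect_true(all(diff(pe$E) - 0.1 < 1e-12))
  flat <- planted_entropy(order = 3, e_t = 0, amplitude = 0)
  expect_true(is.na(attr(flat, "truth")$order))
  # a transition-free curve is exactly the log baseline
  expect_equal(flat$S, 30 * log(flat$E - (min(flat$E) - 50)),
               tolerance = 1e-12)
  expect_error(planted_entropy(order = 5, e_t = 0))
  expect_error(planted_entropy(order = 2, e_t = 100))
})

test_that("preset grids mirror the study conditions", {
  g <- study_grids("n30_full")
  expect_identical(g$n, 30)
  expect_length(g$temperatures, 16)
  expect_equal(range(g$temperatures), c(0.2, 1.6))
  expect_length(g$s_tau, 10)
  expect_equal(range(g$s_tau), c(5, 14))
  g40 <- study_grids("n40_full")
  expect_identical(g40$n, 40)
  expect_equal(range(g40$s_tau), c(5, 25))
  sm <- study_grids("smoke", sweeps = 123)
  expect_equal(sm$sweeps, 123)
  expect_error(study_grids("nope"))
})
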