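test_that("geometric temperature ladder has constant successive ratio", {
  tt <- geometric_temperatures(0.2, 1.6, 16)
  expect_length(tt, 16)
  expect_equal(tt[1], 0.2)
  expect_equal(tt[16], 1.6)
  expect_equal(diff(log(tt)), rep(log(1.6 / 0.2) / 15, 15), tolerance = 1e-12)
  expect_identical(geometric_temperatures(0.5, 2, 1), 0.5)
})

test_that("schedule construction validates its inputs", {
  s <- build_schedule(n = 30)
  expect_s3_class(s, "helix_schedule")
  expect_length(s$temperatures, 16)
  expect_length(s$s_tau, 10)
  expect_error(build_schedule(sweeps = 100, burn_in = 100))
  expect_error(build_schedule(t_range = c(-1, 1)))
  expect_error(build_schedule(n_temp = 2, t_range = c(1, 1)), "t_max")
  expect_error(build_schedule(move_mix = c(1, 1)))
})

test_that("exchange probability reduces correctly for equal Hamiltonians", {
  # equal beta: swapping identical thermodynamic states always succeeds
  expect_identical(exchange_probability(2, 2, -5, -7, -7, -5), 1)
  # general detailed-balance form
  expect_equal(exchange_probability(1, 2, -5, -7, -7, -5),
               min(1, exp(1 * (-5 - (-7)) + 2 * (-7 - (-5)))))
  # same Hamiltonian: min(1, exp((beta_i - beta_j) (E_i - E_j)))
  bi <- 2; bj <- 1; ei <- -3; ej <- -9
  expect_equal(exchange_probability(bi, bj, ei, ej, ej, ei),
               min(1, exp((bi - bj) * (ei - ej))))
  # probability is bounded and positive
  expect_lte(exchange_probability(5, 0.5, -40, 10, 10, -40), 1)
  expect_error(exchange_probability(-1, 1, 0, 0, 0, 0))
})

test_that("single-thread sweeps conserve the energy bookkeeping", {
  p <- model_params(s_tau = 8)
  s <- build_schedule(n = 10, sweeps = 200, burn_in = 0, tune_steps = FALSE)
  set.seed(5)
  res <- run_thread_sweeps(ideal_helix(10, p), p, beta = 2, n_sweeps = 200,
                           schedule = s)
  # final cached energy equals a fresh evaluation of the final conformation
  expect_equal(res$energy, total_energy(res$coords, p), tolerance = 1e-8)
  expect_equal(nrow(res$trace), 200)
  expect_equal(res$trace$E[200], res$energy, tolerance = 1e-8)
  # the recorded minimum was actually visited and beats every sweep record
  expect_lte(res$min_energy, min(res$trace$E) + 1e-10)
  expect_equal(total_energy(res$min_coords, p), res$min_energy,
               tolerance = 1e-8)
  # one move attempt per monomer per sweep
  expect_identical(sum(res$moves$attempts), 200L * 10L)
  expect_true(all(res$moves$accepts <= res$moves$attempts))
})

test_that("the replica-exchange grid is bitwise reproducible from the seed", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 3, s_tau = c(6, 10), sweeps = 300,
                      burn_in = 100, exchange_interval = 50)
  r1 <- run_grid(s, p, seed = 42)
  r2 <- run_grid(s, p, seed = 42)
  expect_identical(r1$e_trace, r2$e_trace)
  expect_identical(r1$q_trace, r2$q_trace)
  expect_identical(r1$final, r2$final)
  r3 <- run_grid(s, p, seed = 43)
  expect_false(identical(r1$e_trace, r3$e_trace))
})

test_that("grid threads carry the right Hamiltonians and swap validly", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 4, s_tau = c(6, 10), sweeps = 400,
                      burn_in = 100, exchange_interval = 50)
  r <- run_grid(s, p, seed = 9)
  expect_equal(nrow(r$threads), 8)
  expect_setequal(unique(r$threads$s_tau), c(6, 10))
  # every final conformation re-evaluates to its thread's Hamiltonian value
  for (t in seq_len(8)) {
    pt <- model_params(s_tau = r$threads$s_tau[t])
    expect_equal(r$e_trace[400, t], total_energy(r$final[[t]], pt),
                 tolerance = 1e-8)
  }
  expect_true(all(r$exchange$accepts <= r$exchange$attempts))
  expect_gt(sum(r$exchange$attempts), 0)
  # exchanges pair grid neighbors only
  th <- r$threads
  for (k in seq_len(nrow(r$exchange))) {
    i <- r$exchange$thread_i[k]
    j <- r$exchange$thread_j[k]
    same_s <- th$i_s[i] == th$i_s[j] && abs(th$i_temp[i] - th$i_temp[j]) == 1
    same_t <- th$i_temp[i] == th$i_temp[j] && abs(th$i_s[i] - th$i_s[j]) == 1
    expect_true(same_s || same_t)
  }
})

test_that("energy histograms deposit exactly once per production sweep", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 4, s_tau = 8, sweeps = 500,
                      burn_in = 100, e_bin = 0.5)
  r <- run_grid(s, p, seed = 21)
  h <- energy_histograms(r)
  expect_equal(unname(h$m), rep(400, 4))
  expect_equal(unname(colSums(h$counts)), unname(h$m))
  # bin centers sit at half-integer multiples of the width
  expect_equal(h$e_mid %% 0.5, rep(0.25, length(h$e_mid)), tolerance = 1e-9)
  # threads are ordered coldest first
  expect_true(all(diff(h$beta) < 0))
})

test_that("the q-marginal of the joint histograms equals the 1D histograms", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 4, s_tau = 8, sweeps = 500,
                      burn_in = 100, e_bin = 0.5, q_bin = 0.02)
  r <- run_grid(s, p, seed = 22)
  h1 <- energy_histograms(r)
  h2 <- joint_histograms(r)
  expect_identical(apply(h2$counts, c(1, 3), sum),
                   unname(h1$counts))
  expect_identical(h2$e_mid, h1$e_mid)
})

test_that("multi-s_tau runs require an explicit histogram selection", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 2, s_tau = c(6, 10), sweeps = 200,
                      burn_in = 50)
  r <- run_grid(s, p, seed = 2)
  expect_error(energy_histograms(r), "several s_tau")
  h <- energy_histograms(r, s_tau = 6)
  expect_length(h$beta, 2)
  expect_error(energy_histograms(r, s_tau = 99), "no threads")
})

test_that("tidy and glance summarize runs faithfully", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 2, s_tau = 8, sweeps = 100,
                      burn_in = 20)
  r <- run_grid(s, p, seed = 3)
  td <- tidy(r)
  expect_equal(nrow(td), 200)
  expect_named(td, c("thread", "temperature", "s_tau", "sweep", "E", "q"))
  expect_equal(td$E[td$thread == 2], r$e_trace[, 2])
  gl <- glance(r)
  expect_equal(nrow(gl), 2)
  expect_true(all(gl$move_acceptance >= 0 & gl$move_acceptance <= 1))
  expect_true(all(gl$min_energy <= apply(r$e_trace, 2, min)))
})
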