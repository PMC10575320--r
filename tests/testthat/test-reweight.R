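test_that("logsumexp is exact and overflow-safe", {
  x <- c(-2, 0.5, 3)
  expect_equal(logsumexp(x), log(sum(exp(x))), tolerance = 1e-12)
  expect_equal(logsumexp(c(1000, 1000)), 1000 + log(2))
  expect_identical(logsumexp(numeric()), -Inf)
  expect_equal(logsumexp(c(-Inf, 0)), 0)
  expect_identical(logsumexp(c(-Inf, -Inf)), -Inf)
})

# Exact histograms for an enumerable system: expected counts proportional to
# g_k exp(-beta e_k), which makes the reweighting answer exact (no sampling
# noise), so recovered log-degeneracy differences are sharp.
exact_histograms <- function(sys, betas, m = 1e6) {
  counts <- vapply(betas, function(b) m * sys$probabilities(b),
                   numeric(length(sys$levels)))
  structure(list(e_mid = sys$levels, e_bin = 1, counts = counts,
                 beta = betas, temperature = 1 / betas, s_tau = NA_real_,
                 m = colSums(counts)),
            class = "helix_histograms")
}

test_that("a single histogram reweights to the exact density of states", {
  sys <- enumerable_system(c(0, 1), c(1, 2))
  h <- exact_histograms(sys, 0.7)
  dos <- single_histogram_dos(h)
  dlg <- diff(dos$table$log_g)
  expect_equal(dlg, log(2), tolerance = 1e-10)
  expect_identical(dos$table$log_g[dos$gauge], 0)
})

test_that("WHAM recovers the two-level system from exact histograms", {
  sys <- enumerable_system(c(0, 1), c(1, 2))
  dos <- wham(exact_histograms(sys, c(0.5, 1, 2)))
  expect_true(dos$converged)
  expect_equal(diff(dos$table$log_g), log(2), tolerance = 1e-8)
})

test_that("WHAM recovers a 7-level ladder from sampled histograms", {
  lv <- 0:6
  dg <- c(1, 3, 10, 40, 100, 400, 1500)
  sys <- enumerable_system(lv, dg)
  set.seed(31)
  m <- 2e5
  betas <- c(0.25, 1, 2, 4)
  counts <- vapply(betas, function(b) sys$sample_counts(b, m),
                   numeric(7))
  h <- structure(list(e_mid = lv, e_bin = 1, counts = counts, beta = betas,
                      temperature = 1 / betas, s_tau = NA_real_,
                      m = colSums(counts)), class = "helix_histograms")
  dos <- wham(h)
  expect_true(dos$converged)
  truth <- log(dg) - log(dg[dos$gauge])
  # multinomial sampling tolerance: every level holds >= 1e3 effective counts
  expect_equal(dos$table$log_g, truth, tolerance = 0.05)
})

test_that("the converged WHAM result is a fixed point of its own update", {
  sys <- enumerable_system(0:4, c(1, 4, 12, 30, 80))
  set.seed(32)
  betas <- c(0.5, 1.5, 3)
  counts <- vapply(betas, function(b) sys$sample_counts(b, 1e5), numeric(5))
  h <- structure(list(e_mid = 0:4, e_bin = 1, counts = counts, beta = betas,
                      temperature = 1 / betas, s_tau = NA_real_,
                      m = colSums(counts)), class = "helix_histograms")
  dos <- wham(h, tol = 1e-10)
  lg <- dos$table$log_g
  lz <- vapply(betas, function(b) logsumexp(lg - b * dos$table$E), numeric(1))
  lz <- lz - lz[1] + dos$log_z$log_z[1]
  # one more application of the Z update moves nothing
  expect_equal(lz, dos$log_z$log_z, tolerance = 1e-7)
})

test_that("WHAM warns when histograms do not overlap", {
  h <- structure(list(
    e_mid = c(0, 1, 10, 11), e_bin = 1,
    counts = cbind(c(50, 50, 0, 0), c(0, 0, 50, 50)),
    beta = c(2, 0.1), temperature = c(0.5, 10), s_tau = NA_real_,
    m = c(100, 100)), class = "helix_histograms")
  expect_warning(wham(h), "overlap")
})

test_that("canonical back-reweighting matches enumerable closed forms", {
  sys <- enumerable_system(c(0, 1, 3), c(2, 5, 20))
  dos <- wham(exact_histograms(sys, c(0.4, 1, 2.5)))
  # spot value from the defining closed form
  expect_equal(sys$mean_energy(log(2)),
               sum(c(0, 1, 3) * c(2, 5 / 2, 20 / 8)) /
                 sum(c(2, 5 / 2, 20 / 8)), tolerance = 1e-12)
  temps <- seq(0.3, 3, by = 0.003)
  can <- canonical_observables(dos, temps)
  expect_equal(can$e_mean, sys$mean_energy(1 / temps), tolerance = 1e-6)
  expect_equal(can$cv_fluct, sys$specific_heat(1 / temps), tolerance = 1e-6)
  # finite-difference and fluctuation forms of C_V agree on a fine grid
  mid <- 2:(length(temps) - 1)
  expect_equal(can$cv[mid], can$cv_fluct[mid], tolerance = 1e-3)
})

test_that("canonical weights normalize and favor low energy at low T", {
  sys <- enumerable_system(0:3, c(1, 2, 4, 8))
  dos <- wham(exact_histograms(sys, c(0.5, 2)))
  w <- canonical_weights(dos, beta = 10)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_equal(w$weight[1], 1, tolerance = 1e-3)
})

test_that("2D reweighting is consistent with its 1D marginal", {
  p <- model_params()
  s <- build_schedule(n = 10, n_temp = 4, s_tau = 8, sweeps = 600,
                      burn_in = 100, e_bin = 0.5)
  r <- run_grid(s, p, seed = 41)
  h1 <- energy_histograms(r)
  h2 <- joint_histograms(r)
  dos <- wham(h1)
  d2 <- wham_2d(h2, dos)
  marg <- apply(d2$log_g, 1, logsumexp)
  supp <- dos$table$support
  expect_equal(marg[supp], dos$table$log_g[supp], tolerance = 1e-8)
  # omitting the 1D solve reproduces the same answer
  d2b <- wham_2d(h2)
  expect_equal(d2b$log_g[d2b$support], d2$log_g[d2$support],
               tolerance = 1e-6)
})

test_that("dos tidiers expose the table and the solve metadata", {
  sys <- enumerable_system(c(0, 1), c(1, 4))
  dos <- wham(exact_histograms(sys, c(0.5, 2)))
  td <- tidy(dos)
  expect_named(td, c("E", "log_g", "support", "S"))
  gl <- glance(dos)
  expect_identical(gl$n_bins, 2L)
  expect_true(gl$converged)
})
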