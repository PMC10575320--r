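#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @export
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Density of states from a single histogram
#'
#' A thread at inverse temperature `beta` estimates the density of states as
#' `g(E) = h(E) * exp(beta * E)`; in log space,
#' `log g = log h(E) + beta * E` on the histogram's support. The additive
#' gauge is fixed by pinning `log g = 0` at the most populated bin.
#'
#' @param h a `helix_histograms` object with a single thread, or a list with
#'   elements `e_mid`, `counts` (vector), `beta`.
#' @param thread which thread of `h` to use (default 1).
#' @return A `helix_dos` object (see [wham()]).
#' @export
single_histogram_dos <- function(h, thread = 1) {
  counts <- if (is.matrix(h$counts)) h$counts[, thread] else h$counts
  if (sum(counts) == 0) stop("empty histogram")
  beta <- h$beta[thread]
  support <- counts > 0
  log_g <- rep(-Inf, length(counts))
  log_g[support] <- log(counts[support]) + beta * h$e_mid[support]
  gauge <- which.max(counts)
  log_g <- log_g - log_g[gauge]
  new_dos(h$e_mid, log_g, support, gauge,
          log_z = tibble::tibble(beta = beta,
                                 log_z = logsumexp(log_g - beta * h$e_mid)),
          iterations = 0L, converged = TRUE, e_bin = h$e_bin,
          s_tau = h$s_tau %||% NA_real_)
}

new_dos <- function(e_mid, log_g, support, gauge, log_z, iterations,
                    converged, e_bin, s_tau) {
  structure(list(
    table = tibble::tibble(E = e_mid, log_g = log_g, support = support),
    gauge = gauge, log_z = log_z, iterations = iterations,
    converged = converged, e_bin = e_bin, s_tau = s_tau
  ), class = "helix_dos")
}

#' @export
print.helix_dos <- function(x, ...) {
  cat(sprintf("Density of states: %d bins (%d supported), e_bin = %g, s_tau = %s\n",
              nrow(x$table), sum(x$table$support), x$e_bin,
              format(x$s_tau)))
  cat(sprintf("  WHAM: %d iterations, %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Multiple-histogram reweighting (WHAM) to the density of states
#'
#' Combines the energy histograms of all threads of one Hamiltonian into a
#' single density of states spanning every sampled energy, iterating
#' \deqn{g(E) = \frac{\sum_i h_i(E)}{\sum_i M_i Z_i^{-1} e^{-\beta_i E}},
#'   \qquad Z_i = \sum_E g(E) e^{-\beta_i E}}
#' entirely in log space (log-sum-exp) from the initial guess `Z_i = 1`,
#' until `max_i |delta log Z_i| < tol`. The converged `log g` is gauge-fixed
#' to 0 at the most populated bin; empty bins inside the envelope keep
#' `log g = -Inf` (smoothing happens later, in the microcanonical step).
#'
#' @param h a `helix_histograms` object (threads share bin edges by
#'   construction).
#' @param tol convergence tolerance on `max |delta log Z|`.
#' @param max_iter iteration cap; non-convergence returns the partial result
#'   with a warning and `converged = FALSE`.
#' @return A `helix_dos` object: `table` (tibble `E`, `log_g`, `support`),
#'   `log_z` (tibble per thread), `iterations`, `converged`.
#' @export
wham <- function(h, tol = 1e-8, max_iter = 1e5) {
  counts <- h$counts
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = 1)
  nb <- nrow(counts)
  nt <- ncol(counts)
  beta <- h$beta
  stopifnot(length(beta) == nt)
  e <- h$e_mid
  m <- colSums(counts)
  keep <- m > 0
  if (!any(keep)) stop("all histograms are empty")
  counts <- counts[, keep, drop = FALSE]
  beta <- beta[keep]
  m <- m[keep]
  nt <- length(beta)

  check_overlap(counts, beta)

  log_h_sum <- ifelse(rowSums(counts) > 0, log(rowSums(counts)), -Inf)
  support <- rowSums(counts) > 0
  log_m <- log(m)
  log_z <- rep(0, nt)
  be <- outer(beta, e) # nt x nb
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per bin: logsumexp_i(log M_i - log Z_i - beta_i E)
    a <- (log_m - log_z) - be
    amax <- apply(a, 2, max)
    log_den <- amax + log(colSums(exp(sweep(a, 2, amax))))
    log_g <- log_h_sum - log_den
    # update log Z_i = logsumexp_E(log g - beta_i E) over support
    lg_s <- log_g[support]
    ze <- sweep(-be[, support, drop = FALSE], 2, lg_s, "+")
    zmax <- apply(ze, 1, max)
    log_z_new <- zmax + log(rowSums(exp(ze - zmax)))
    delta <- max(abs(log_z_new - log_z))
    # re-anchor to keep the overall additive gauge from drifting
    log_z <- log_z_new - log_z_new[1]
    if (delta < tol || iter >= max_iter) break
  }
  converged <- iter < max_iter
  if (!converged) {
    warning("WHAM did not converge in ", max_iter,
            " iterations (last delta log Z = ", format(delta), ")")
  }
  gauge <- which.max(rowSums(counts))
  shift <- log_g[gauge]
  log_g <- log_g - shift
  log_z <- log_z - shift
  new_dos(e, log_g, support, gauge,
          log_z = tibble::tibble(beta = beta, temperature = 1 / beta,
                                 log_z = log_z),
          iterations = iter, converged = converged, e_bin = h$e_bin,
          s_tau = h$s_tau %||% NA_real_)
}

check_overlap <- function(counts, beta) {
  ord <- order(beta)
  for (k in seq_len(length(ord) - 1)) {
    a <- counts[, ord[k]] > 0
    b <- counts[, ord[k + 1]] > 0
    if (!any(a & b)) {
      warning("histograms at beta = ", format(beta[ord[k]]), " and ",
              format(beta[ord[k + 1]]),
              " do not overlap; the reweighted density of states may be ",
              "disconnected")
    }
  }
  invisible(TRUE)
}

#' Two-dimensional density of states over (E, q)
#'
#' Applies the 2D analog of the reweighting equation,
#' `g(E, q) = sum_i h_i(E, q) / sum_i M_i Z_i^{-1} exp(-beta_i E)`,
#' using the partition functions already converged by the 1D solve on the
#' marginal histograms (the weights depend on E only, which also makes the
#' q-marginal of `g(E, q)` agree with the 1D `g(E)` by construction).
#'
#' @param h2 a `helix_histograms_2d` object.
#' @param dos the converged 1D [wham()] result for the same threads. If
#'   omitted, the 1D solve is run on the q-marginal of `h2`.
#' @inheritParams wham
#' @return A `helix_dos2d` object: `e_mid`, `q_mid`, `log_g` (matrix),
#'   `support` (logical matrix), plus the underlying 1D `dos`.
#' @export
wham_2d <- function(h2, dos = NULL, tol = 1e-8, max_iter = 1e5) {
  if (is.null(dos)) {
    h1 <- list(e_mid = h2$e_mid, e_bin = h2$e_bin,
               counts = apply(h2$counts, c(1, 3), sum),
               beta = h2$beta, m = h2$m, s_tau = h2$s_tau)
    class(h1) <- "helix_histograms"
    dos <- wham(h1, tol = tol, max_iter = max_iter)
  }
  if (!isTRUE(all.equal(dos$table$E, h2$e_mid))) {
    stop("energy grids of the 2D histograms and the 1D DoS do not match")
  }
  lz <- dos$log_z$log_z
  beta <- dos$log_z$beta
  keep <- h2$m > 0
  counts <- h2$counts[, , keep, drop = FALSE]
  log_m <- log(h2$m[keep])
  stopifnot(length(beta) == sum(keep))
  a <- (log_m - lz) - outer(beta, h2$e_mid) # nt x nE
  amax <- apply(a, 2, max)
  log_den <- amax + log(colSums(exp(sweep(a, 2, amax)))) # per E bin
  h_sum <- apply(counts, c(1, 2), sum)
  log_g <- ifelse(h_sum > 0, log(h_sum), -Inf) - log_den
  # same gauge as the 1D result: subtract so the q-marginal matches log_g 1D
  # (it already does; pin using the 1D gauge bin)
  marg <- apply(log_g, 1, logsumexp)
  shift <- marg[dos$gauge] - dos$table$log_g[dos$gauge]
  log_g <- log_g - shift
  structure(list(
    e_mid = h2$e_mid, q_mid = h2$q_mid, e_bin = h2$e_bin, q_bin = h2$q_bin,
    log_g = log_g, support = h_sum > 0, dos = dos, s_tau = h2$s_tau
  ), class = "helix_dos2d")
}

#' Canonical energy distribution from the density of states
#'
#' Back-reweights the density of states to the canonical ensemble at
#' inverse temperature `beta`: weights proportional to
#' `g(E) * exp(-beta * E)`, normalized over the support (computed via
#' log-sum-exp).
#'
#' @param dos a `helix_dos` object.
#' @param beta inverse temperature (> 0).
#' @return A tibble `E`, `weight` (weights sum to 1 over the support).
#' @export
canonical_weights <- function(dos, beta) {
  stopifnot(beta > 0)
  lg <- dos$table$log_g
  lw <- lg - beta * dos$table$E
  lw <- lw - logsumexp(lw)
  tibble::tibble(E = dos$table$E, weight = exp(lw))
}

#' Canonical mean energy and specific heat across temperatures
#'
#' For each temperature, computes the canonical mean energy
#' `E_bar = sum(h(E) E) / sum(h(E))` with `h(E) = g(E) exp(-E/T)`, then the
#' specific heat both as the centered finite difference `dE_bar/dT` and via
#' the fluctuation identity `(⟨E²⟩ − ⟨E⟩²)/T²`; the two agree to the
#' differencing error on a sufficiently fine grid.
#'
#' @param dos a `helix_dos` object.
#' @param temperatures positive, increasing temperature grid (fine enough
#'   for differencing).
#' @return A tibble: `temperature`, `e_mean`, `cv` (finite difference;
#'   `NA` at the end points), `cv_fluct`.
#' @export
canonical_observables <- function(dos, temperatures) {
  stopifnot(all(temperatures > 0), !is.unsorted(temperatures))
  e <- dos$table$E
  res <- lapply(temperatures, function(tt) {
    w <- canonical_weights(dos, 1 / tt)$weight
    e1 <- sum(w * e)
    e2 <- sum(w * e^2)
    c(e1 = e1, var = e2 - e1^2)
  })
  e_mean <- vapply(res, `[[`, numeric(1), "e1")
  e_var <- vapply(res, `[[`, numeric(1), "var")
  nT <- length(temperatures)
  cv <- rep(NA_real_, nT)
  if (nT >= 3) {
    cv[2:(nT - 1)] <- (e_mean[3:nT] - e_mean[1:(nT - 2)]) /
      (temperatures[3:nT] - temperatures[1:(nT - 2)])
  }
  tibble::tibble(temperature = temperatures, e_mean = e_mean, cv = cv,
                 cv_fluct = e_var / temperatures^2)
}
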