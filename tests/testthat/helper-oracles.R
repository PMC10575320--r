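# Independent pure-R reference implementations used as oracles. These
# deliberately re-derive everything from the defining formulas (no calls into
# the package's C++ kernels) so that agreement is evidence, not tautology.

oracle_energy <- function(x, p) {
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  fene <- 0
  for (i in 1:(n - 1)) {
    r <- dmat[i, i + 1]
    stopifnot(abs(r - p$r0) < p$R)
    fene <- fene + log(1 - ((r - p$r0) / p$R)^2)
  }
  lj <- 0
  dmin <- if (isTRUE(p$lj_bonded)) 1 else 2
  for (i in 1:(n - 1)) {
    if (i + dmin > n) next
    for (j in (i + dmin):n) {
      r <- dmat[i, j]
      if (r < p$rc) {
        lj <- lj + 4 * ((p$sigma / r)^12 - (p$sigma / r)^6) - p$vc
      }
    }
  }
  bend <- 0
  if (n >= 3) {
    for (k in 2:(n - 1)) {
      u <- x[k, ] - x[k - 1, ]
      v <- x[k + 1, ] - x[k, ]
      if (isTRUE(p$interior_angle)) u <- -u
      th <- acos(max(-1, min(1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2)))))
      bend <- bend + 1 - cos(th - p$theta0)
    }
  }
  tor <- 0
  if (n >= 4) {
    for (l in 1:(n - 3)) {
      b1 <- x[l + 1, ] - x[l, ]
      b2 <- x[l + 2, ] - x[l + 1, ]
      b3 <- x[l + 3, ] - x[l + 2, ]
      cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
      n1 <- cr(b1, b2)
      n2 <- cr(b2, b3)
      ta <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
      tor <- tor + 1 - cos(ta - p$tau0)
    }
  }
  p$s_fene * fene + p$s_lj * lj + p$s_theta * bend + p$s_tau * tor
}

oracle_q <- function(x, p) {
  n <- nrow(x)
  num <- 0
  den <- 0
  for (i in 1:(n - 1)) {
    if (i + 2 > n) next
    for (j in (i + 2):n) {
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      v <- if (r < p$rc) 4 * ((p$sigma / r)^12 - (p$sigma / r)^6) - p$vc else 0
      if (j - i > 6) num <- num + v else den <- den + v
    }
  }
  if (abs(den) < p$q_eps) 0 else num / den
}

random_rigid_motion <- function(x) {
  z <- matrix(stats::rnorm(9), 3)
  qr_dec <- qr(z)
  rot <- qr.Q(qr_dec)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  sweep(x %*% rot, 2, stats::rnorm(3, sd = 5), "+")
}

# A random valid conformation: perturbed ideal helix (bonds stay inside the
# FENE domain for small perturbations).
random_valid_chain <- function(n, p, sd = 0.03) {
  x <- ideal_helix(n, p) + matrix(stats::rnorm(3 * n, sd = sd), n, 3)
  b <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  stopifnot(all(abs(b - p$r0) < p$R))
  x
}

# Quadrature oracle for the N = 2 bond-length ensemble: the relative
# coordinate has density proportional to r^2 exp(-beta * S_FENE * v_FENE(r)).
# Returns expected probabilities of the energy histogram bins `breaks`.
oracle_dimer_energy_probs <- function(beta, p, breaks) {
  r <- seq(p$r0 - p$R + 1e-9, p$r0 + p$R - 1e-9, length.out = 200001)
  e <- p$s_fene * log(1 - ((r - p$r0) / p$R)^2)
  w <- r^2 * exp(-beta * e)
  w <- w / sum(w)
  bin <- cut(e, breaks = breaks, include.lowest = TRUE)
  probs <- tapply(w, bin, sum)
  probs[is.na(probs)] <- 0
  as.numeric(probs)
}
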