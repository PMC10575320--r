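#' Build a chain from internal coordinates
#'
#' Sequential placement: each monomer is set at bond length `r` from the
#' previous one, with bending angle `theta` and dihedral `tau` relative to
#' the preceding bonds (angles interpreted under the convention carried by
#' `params`).
#'
#' @param n number of monomers (>= 2).
#' @param r,theta,tau internal coordinates (scalars or vectors recycled to
#'   the needed length: `n - 1` bonds, `n - 2` angles, `n - 3` dihedrals).
#' @inheritParams v_fene
#' @return An `n x 3` coordinate matrix.
#' @export
build_chain <- function(n, r, theta, tau, params = model_params()) {
  stopifnot(n >= 2)
  r <- rep_len(r, n - 1)
  theta <- if (n >= 3) rep_len(theta, n - 2) else numeric()
  tau <- if (n >= 4) rep_len(tau, n - 3) else numeric()
  # internal representation uses the bond-vector turn angle
  turn <- if (params$interior_angle) pi - theta else theta
  x <- matrix(0, n, 3)
  x[2, ] <- c(r[1], 0, 0)
  if (n >= 3) {
    x[3, ] <- x[2, ] + r[2] * c(cos(turn[1]), sin(turn[1]), 0)
  }
  if (n >= 4) {
    for (i in 4:n) {
      bp <- x[i - 1, ] - x[i - 2, ]
      bpp <- x[i - 2, ] - x[i - 3, ]
      u <- bp / sqrt(sum(bp^2))
      nv <- cross3(bpp, bp)
      nv <- nv / sqrt(sum(nv^2))
      m <- cross3(nv, u)
      th <- turn[i - 2]
      ta <- tau[i - 3]
      b <- r[i - 1] * (cos(th) * u + sin(th) * (cos(ta) * m + sin(ta) * nv))
      x[i, ] <- x[i - 1, ] + b
    }
  }
  x
}

#' Ideal helix conformation
#'
#' The reference geometry of the model: every bond at `r0`, every bending
#' angle at `theta0`, every dihedral at `tau0` (right-handed for positive
#' `tau0`). Bending and torsion energies are exactly zero by construction;
#' the only nonzero Hamiltonian term is the LJ sum.
#'
#' @param n number of monomers (>= 4).
#' @inheritParams v_fene
#' @return An `n x 3` coordinate matrix.
#' @export
ideal_helix <- function(n, params = model_params()) {
  stopifnot(n >= 4)
  build_chain(n, params$r0, params$theta0, params$tau0, params)
}

#' Random-coil initial conformation
#'
#' A random walk with every bond at exactly `r0` (so the FENE domain holds by
#' construction) and uniformly random bond directions. Used as an alternative
#' initializer for ergodicity cross-checks; high-energy overlaps are relaxed
#' quickly by the sampler.
#'
#' @inheritParams ideal_helix
#' @return An `n x 3` coordinate matrix.
#' @export
random_coil <- function(n, params = model_params()) {
  stopifnot(n >= 2)
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    z <- stats::rnorm(3)
    x[i, ] <- x[i - 1, ] + params$r0 * z / sqrt(sum(z^2))
  }
  x
}

helix_axis <- function(x) {
  cx <- sweep(x, 2, colMeans(x))
  v <- svd(cx, nu = 0, nv = 1)$v[, 1]
  if (sum((x[nrow(x), ] - x[1, ]) * v) < 0) v <- -v
  v
}

#' Two-helix bundle template
#'
#' A synthetic seed structure: two antiparallel ideal-helix segments joined
#' by a short turn, with the segment surfaces placed near the LJ contact
#' distance. It is an annealing seed for the two-helix-bundle phase, not a
#' ground-state claim; after low-temperature relaxation its bundling order
#' parameter q settles into the bundle band 0.30--0.50 (equilibrated
#' low-temperature bundles of this model sit near 0.42--0.45, as the soft
#' FENE bonds compress slightly to tighten the inter-segment packing).
#'
#' @param n total number of monomers (>= 12).
#' @param turn_monomers number of monomers in the connecting turn (2 or 3).
#' @inheritParams v_fene
#' @return An `n x 3` coordinate matrix (valid FENE geometry).
#' @export
two_helix_template <- function(n, params = model_params(), turn_monomers = 2) {
  stopifnot(n >= 12, turn_monomers >= 1)
  n1 <- ceiling((n - turn_monomers) / 2)
  n2 <- n - turn_monomers - n1

  axis_radius <- function(h) {
    ctr <- colMeans(h)
    a <- helix_axis(h)
    cx <- sweep(h, 2, ctr)
    perp <- cx - outer(drop(cx %*% a), a)
    list(center = ctr, axis = a, perp = perp,
         radius = mean(sqrt(rowSums(perp^2))),
         t = drop(cx %*% a))
  }
  rot_about <- function(x, origin, axis, ang) {
    cx <- sweep(x, 2, origin)
    out <- t(apply(cx, 1, function(v) {
      v * cos(ang) + cross3(axis, v) * sin(ang) +
        axis * sum(axis * v) * (1 - cos(ang))
    }))
    sweep(out, 2, origin, "+")
  }
  align_rotation <- function(from, to) {
    ax <- cross3(from, to)
    s <- sqrt(sum(ax^2))
    if (s < 1e-12) return(if (sum(from * to) > 0) diag(3) else -diag(3))
    ax <- ax / s
    ang <- atan2(s, sum(from * to))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }

  h1 <- ideal_helix(n1, params)
  g1 <- axis_radius(h1)

  # second segment: rotate 180 degrees about an axis perpendicular to its
  # helix axis (reverses direction, preserves handedness), then align its
  # axis with -a1
  h2 <- ideal_helix(n2, params)
  g2 <- axis_radius(h2)
  pax <- cross3(g2$axis, c(1, 0, 0))
  if (sqrt(sum(pax^2)) < 1e-6) pax <- cross3(g2$axis, c(0, 1, 0))
  pax <- pax / sqrt(sum(pax^2))
  h2 <- rot_about(h2, g2$center, pax, pi)
  g2 <- axis_radius(h2)
  a2 <- if (sum((h2[n2, ] - h2[1, ]) * g2$axis) > 0) g2$axis else -g2$axis
  h2 <- h2 %*% t(align_rotation(a2, -g1$axis))
  g2 <- axis_radius(h2)

  # axes parallel at LJ contact: facing monomers one LJ minimum apart
  sep <- g1$radius + g2$radius + 2^(1 / 6) * params$sigma
  off_dir <- g1$perp[n1, ] / sqrt(sum(g1$perp[n1, ]^2))
  # align the +a1 axial extremes (h1 ends there; antiparallel h2 starts there)
  ax_shift <- max(g1$t) - max(sweep(h2, 2, g2$center) %*% g1$axis)
  target_c2 <- g1$center + off_dir * sep + g1$axis * drop(ax_shift)
  h2 <- sweep(h2, 2, target_c2 - colMeans(h2), "+")

  # spin h2 about its own axis so the end-to-start gap matches the natural
  # turn length (turn_monomers + 1 bonds at r0), deterministic grid search
  gap_target <- (turn_monomers + 1) * params$r0
  best <- Inf
  best_ang <- 0
  for (ang in seq(0, 2 * pi, length.out = 73)[-73]) {
    cand <- rot_about(h2[1, , drop = FALSE], target_c2, g1$axis, ang)
    d <- abs(sqrt(sum((cand - h1[n1, ])^2)) - gap_target)
    if (d < best) { best <- d; best_ang <- ang }
  }
  h2 <- rot_about(h2, target_c2, g1$axis, best_ang)

  # turn monomers: interpolate between the segment ends with a slight
  # deterministic bow. Exactly collinear turn bonds would make the turn
  # dihedrals numerically degenerate (bend angle ~ 0), so the torsion energy
  # of the template would depend on round-off; the bow keeps every dihedral
  # well conditioned.
  chord <- h2[1, ] - h1[n1, ]
  u_ch <- chord / sqrt(sum(chord^2))
  bow_dir <- cross3(u_ch, g1$axis)
  if (sqrt(sum(bow_dir^2)) < 1e-8) bow_dir <- cross3(u_ch, off_dir)
  bow_dir <- bow_dir / sqrt(sum(bow_dir^2))
  bow <- 0.2 * params$r0
  make_turn <- function(dir) {
    tp <- matrix(0, turn_monomers, 3)
    for (k in seq_len(turn_monomers)) {
      f <- k / (turn_monomers + 1)
      tp[k, ] <- (1 - f) * h1[n1, ] + f * h2[1, ] + bow * sin(pi * f) * dir
    }
    tp
  }
  # bow away from the helices: of the two perpendicular directions, keep the
  # one whose turn monomers stay farther from every non-turn monomer
  clearance <- function(tp) {
    min(apply(tp, 1, function(pt) {
      min(sqrt(rowSums(sweep(rbind(h1, h2), 2, pt)^2)))
    }))
  }
  cand_a <- make_turn(bow_dir)
  cand_b <- make_turn(-bow_dir)
  tpts <- if (clearance(cand_a) >= clearance(cand_b)) cand_a else cand_b
  x <- rbind(h1, tpts, h2)
  bonds <- sqrt(rowSums((x[-1, ] - x[-n, ])^2))
  if (any(abs(bonds - params$r0) >= params$R)) {
    stop("two-helix template construction produced a bond outside the FENE ",
         "domain; try a different `turn_monomers`")
  }
  x
}

#' Exactly enumerable finite system
#'
#' A discrete system with known energy levels and degeneracies: the
#' independent oracle for histogram-reweighting code. Closed forms for the
#' partition function, mean energy and specific heat are evaluated by direct
#' summation; `sample_counts()` draws an exact canonical sample
#' (multinomial over levels).
#'
#' @param levels numeric vector of energy levels.
#' @param degeneracies positive degeneracies `g_k`, same length.
#' @return An object of class `enumerable_system` with elements
#'   `levels`, `degeneracies`, and functions `log_z(beta)`,
#'   `mean_energy(beta)`, `specific_heat(beta)`,
#'   `probabilities(beta)`, `sample_counts(beta, m)`.
#' @examples
#' sys <- enumerable_system(c(0, 1), c(1, 2))
#' sys$mean_energy(log(2)) # 0.5
#' @export
enumerable_system <- function(levels, degeneracies) {
  stopifnot(length(levels) >= 2, length(levels) == length(degeneracies),
            all(degeneracies > 0))
  lg <- log(degeneracies)
  log_z <- function(beta) logsumexp(lg - beta * levels)
  probabilities <- function(beta) {
    w <- lg - beta * levels
    exp(w - logsumexp(w))
  }
  mean_energy <- function(beta) {
    vapply(beta, function(b) sum(probabilities(b) * levels), numeric(1))
  }
  specific_heat <- function(beta) {
    vapply(beta, function(b) {
      p <- probabilities(b)
      e1 <- sum(p * levels)
      b^2 * (sum(p * levels^2) - e1^2) # C_V = beta^2 Var(E), kB = 1
    }, numeric(1))
  }
  sample_counts <- function(beta, m) {
    drop(stats::rmultinom(1, m, probabilities(beta)))
  }
  structure(
    list(levels = levels, degeneracies = degeneracies, log_z = log_z,
         probabilities = probabilities, mean_energy = mean_energy,
         specific_heat = specific_heat, sample_counts = sample_counts),
    class = "enumerable_system"
  )
}

#' Synthetic entropy curve with one planted transition
#'
#' Constructs a microcanonical entropy S(E) on `grid` whose derivatives are
#' smooth, monotone and sign-alternating (the transition-free baseline
#' `S0 = c * log(E - E0)`), plus one localized feature of the requested
#' order: a Gaussian bump added to the order-th derivative, pointed toward
#' zero, integrated back down to S. The planted order and energy are
#' attached as the ground truth for detector validation.
#'
#' @param order transition order, 1--4. Order 1 plants a backbending region
#'   in `dS/dE` (the bump pushes `d2S/dE2` above zero); orders 2--4 plant a
#'   least-sensitive extremum in the corresponding derivative that
#'   approaches zero without crossing.
#' @param e_t transition energy (interior to the grid).
#' @param amplitude bump height as a fraction of the local baseline
#'   magnitude (0 < amplitude < 1 for orders 2--4; for order 1 the bump is
#'   `(1 + amplitude)` times the baseline so the derivative changes sign).
#'   `amplitude = 0` gives a transition-free curve.
#' @param width Gaussian width of the feature in energy units.
#' @param grid uniform energy grid.
#' @param scale overall entropy scale `c` of the baseline.
#' @param e0_offset distance of the baseline singularity below the grid.
#' @return A tibble with columns `E`, `S`, carrying attributes
#'   `truth = list(order, energy)` and class `planted_entropy`.
#' @export
planted_entropy <- function(order, e_t, amplitude = 0.8, width = 2,
                            grid = seq(-30, 30, by = 0.1),
                            scale = 30, e0_offset = 50) {
  stopifnot(order %in% 1:4, amplitude >= 0, width > 0)
  if (amplitude > 0) stopifnot(e_t > min(grid), e_t < max(grid))
  e0 <- min(grid) - e0_offset
  u <- grid - e0
  # baseline derivatives of c*log(u): alternate sign, approach zero
  base <- list(
    function(u) scale * log(u),
    function(u) scale / u,
    function(u) -scale / u^2,
    function(u) 2 * scale / u^3,
    function(u) -6 * scale / u^4
  )
  s <- base[[1]](u)
  if (amplitude > 0) {
    bump <- exp(-(grid - e_t)^2 / (2 * width^2))
    # derivative channel the feature lives in (order n -> n-th derivative of S
    # gets a bump toward zero; order 1 -> second derivative crosses zero)
    ch <- if (order == 1) 2 else order
    b0 <- abs(base[[ch + 1]](e_t - e0))
    height <- if (order == 1) (1 + amplitude) * b0 else amplitude * b0
    sgn <- -sign(base[[ch + 1]](e_t - e0)) # point the bump toward zero
    d_add <- sgn * height * bump
    # integrate the bump `ch` times down to S (trapezoid, zero constants:
    # integration constants only tilt S by a polynomial, which adds no
    # extrema to the planted channel)
    h <- grid[2] - grid[1]
    f <- d_add
    for (k in seq_len(ch)) {
      f <- cumsum(c(0, (f[-1] + f[-length(f)]) / 2)) * h
    }
    s <- s + f
  }
  out <- tibble::tibble(E = grid, S = s)
  attr(out, "truth") <- list(order = if (amplitude > 0) order else NA_integer_,
                             energy = if (amplitude > 0) e_t else NA_real_)
  class(out) <- c("planted_entropy", class(out))
  out
}

#' Preset simulation schedules
#'
#' Named presets for the standard study conditions of this model: `n30_full`
#' (N = 30; 16 temperatures from 0.2 to 1.6, spaced geometrically; 10
#' torsion scales from 5 to 14; 160 threads) and `n40_full` (N = 40 with
#' `s_tau` from 5 to 25), plus two reduced presets for desk-scale work:
#' `n30_reduced` (one `s_tau` column, shortened run) and `smoke` (N = 10).
#'
#' @param preset one of `"n30_full"`, `"n40_full"`, `"n30_reduced"`,
#'   `"smoke"`.
#' @param ... overrides forwarded to [build_schedule()].
#' @return A `helix_schedule` object.
#' @export
study_grids <- function(preset = c("n30_full", "n40_full", "n30_reduced",
                                   "smoke"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    n30_full = list(n = 30, t_range = c(0.2, 1.6), n_temp = 16,
                    s_tau = seq(5, 14, length.out = 10),
                    sweeps = 5e5, burn_in = 5e4),
    n40_full = list(n = 40, t_range = c(0.2, 1.6), n_temp = 16,
                    s_tau = seq(5, 25, length.out = 10),
                    sweeps = 5e5, burn_in = 5e4),
    n30_reduced = list(n = 30, t_range = c(0.2, 1.6), n_temp = 16,
                       s_tau = 8, sweeps = 2e4, burn_in = 2e3),
    smoke = list(n = 10, t_range = c(0.2, 1.6), n_temp = 4,
                 s_tau = 8, sweeps = 500, burn_in = 50)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(build_schedule, args)
}
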