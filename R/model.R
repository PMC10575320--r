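#' Model parameters for the helical homopolymer
#'
#' Builds the full set of Hamiltonian constants for the coarse-grained
#' helical homopolymer: FENE bond potential, truncated-and-shifted
#' Lennard-Jones pair potential, and cosine bending/torsion potentials with
#' reference angles `theta0` and `tau0`. All quantities are in reduced units
#' (`r0 = 1`, `s_lj = 1`, `kB = 1`).
#'
#' Derived constants are always recomputed from their defining expressions:
#' `sigma = 2^(-1/6) * r0`, `rc = 2.5 * sigma`,
#' `vc = 4 * ((sigma/rc)^12 - (sigma/rc)^6)` (the shift that makes the LJ
#' potential vanish continuously at the cutoff), and
#' `s_fene = -(98/5) * r0^2 * R^2 / 2`, which equals `-1.8` at the defaults.
#'
#' @param s_tau torsion energy scale (positive; the axis along which helix
#'   stiffness is varied, typically 5--14 for chains of 30 monomers).
#' @param s_theta bending energy scale (default 200).
#' @param s_lj Lennard-Jones energy scale (default 1).
#' @param r0 equilibrium bond length (default 1, reduced units).
#' @param R maximum bond-length deviation; bonds must satisfy
#'   `|r - r0| < R` (default 3/7).
#' @param theta0 reference bending angle in radians, measured between
#'   successive bond vectors (default 1.742).
#' @param tau0 reference dihedral angle in radians; positive values select a
#'   right-handed helix (default 0.873).
#' @param lj_bonded include bonded pairs (`|i-j| = 1`) in the LJ sum?
#'   Default `FALSE`: only non-bonded monomers interact via LJ.
#' @param angle_convention `"bond"` (angle between successive bond vectors;
#'   a straight chain has `theta = 0`) or `"interior"` (interior angle at the
#'   middle monomer). The bond-vector convention is the one under which
#'   `theta0 = 1.742` produces a compact helix.
#' @param q_eps tolerance below which the denominator of the bundling order
#'   parameter q is treated as zero (q is then 0 by convention).
#' @return An object of class `helix_params`: a named list of constants.
#' @examples
#' p <- model_params(s_tau = 8)
#' p$s_fene # -1.8
#' @export
model_params <- function(s_tau = 8, s_theta = 200, s_lj = 1,
                         r0 = 1, R = 3 / 7,
                         theta0 = 1.742, tau0 = 0.873,
                         lj_bonded = FALSE,
                         angle_convention = c("bond", "interior"),
                         q_eps = 1e-9) {
  angle_convention <- match.arg(angle_convention)
  stopifnot(r0 > 0, R > 0, R < r0, s_tau > 0, s_theta >= 0, q_eps > 0)
  sigma <- 2^(-1 / 6) * r0
  rc <- 2.5 * sigma
  p <- list(
    r0 = r0, R = R, sigma = sigma, rc = rc,
    vc = 4 * ((sigma / rc)^12 - (sigma / rc)^6),
    s_fene = -(98 / 5) * r0^2 * R^2 / 2,
    s_lj = s_lj, s_theta = s_theta, s_tau = s_tau,
    theta0 = theta0, tau0 = tau0,
    lj_bonded = lj_bonded,
    interior_angle = identical(angle_convention, "interior"),
    q_eps = q_eps
  )
  class(p) <- "helix_params"
  p
}

#' @export
print.helix_params <- function(x, ...) {
  cat("Helical homopolymer model parameters (reduced units)\n")
  cat(sprintf("  bonds:   FENE  r0 = %g, R = %g, S_FENE = %g\n",
              x$r0, x$R, x$s_fene))
  cat(sprintf("  pairs:   LJ    sigma = %.6f, rc = %.6f, vc = %.6f, S_LJ = %g%s\n",
              x$sigma, x$rc, x$vc, x$s_lj,
              if (x$lj_bonded) " (bonded pairs included)" else ""))
  cat(sprintf("  bending: theta0 = %g rad (%s convention), S_theta = %g\n",
              x$theta0, if (x$interior_angle) "interior" else "bond-vector",
              x$s_theta))
  cat(sprintf("  torsion: tau0 = %g rad, S_tau = %g\n", x$tau0, x$s_tau))
  invisible(x)
}

as_params_list <- function(p) {
  if (!inherits(p, "helix_params")) stop("`params` must come from model_params()")
  unclass(p)
}

check_conformation <- function(x) {
  if (!is.matrix(x) || ncol(x) != 3 || nrow(x) < 2 || !is.numeric(x)) {
    stop("a conformation must be a numeric N x 3 matrix with N >= 2")
  }
  storage.mode(x) <- "double"
  x
}

#' FENE bond-stretch potential
#'
#' Unscaled finitely extensible nonlinear elastic bond energy
#' `log(1 - ((r - r0)/R)^2)`. Zero at `r = r0`, negative elsewhere, and
#' undefined once `|r - r0| >= R`: proposals that stretch a bond that far are
#' rejected outright by the sampler rather than evaluated.
#'
#' @param r bond length(s).
#' @param params a [model_params()] object.
#' @return Unscaled FENE energy, same length as `r`.
#' @export
v_fene <- function(r, params = model_params()) {
  x <- (r - params$r0) / params$R
  if (any(abs(x) >= 1)) {
    stop("bond length outside the FENE domain (|r - r0| >= R)")
  }
  log(1 - x^2)
}

#' Truncated and shifted Lennard-Jones pair potential
#'
#' `4 * ((sigma/r)^12 - (sigma/r)^6) - vc` for `r < rc`, exactly 0 for
#' `r >= rc`; the shift `vc` makes the potential continuous at the cutoff.
#'
#' @inheritParams v_fene
#' @param r pair distance(s), must be positive.
#' @return LJ energy, same length as `r`.
#' @export
v_lj <- function(r, params = model_params()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sr6 <- (params$sigma / r)^6
  ifelse(r >= params$rc, 0, 4 * (sr6^2 - sr6) - params$vc)
}

#' Bending and torsion potentials
#'
#' Unscaled cosine penalties `1 - cos(theta - theta0)` and
#' `1 - cos(tau - tau0)`. Both vanish only at the reference angle and range
#' over `[0, 2]`. The torsion potential is deliberately *not* symmetric under
#' `tau -> -tau`: a nonzero `tau0` selects one helical handedness.
#'
#' @inheritParams v_fene
#' @param theta bending angle(s) in radians.
#' @param tau signed dihedral angle(s) in radians.
#' @return Unscaled potential values.
#' @export
v_bend <- function(theta, params = model_params()) {
  1 - cos(theta - params$theta0)
}

#' @rdname v_bend
#' @export
v_torsion <- function(tau, params = model_params()) {
  1 - cos(tau - params$tau0)
}

#' Bending angle of two consecutive bonds
#'
#' Angle in `[0, pi]` between the bond vectors `b - a` and `c - b` (or, under
#' the `"interior"` convention, the interior angle at `b`). The cosine is
#' clamped to `[-1, 1]` before `acos` to guard against round-off.
#'
#' @param a,b,c positions of three consecutive monomers (length-3 vectors).
#' @inheritParams v_fene
#' @return Angle in radians.
#' @export
bending_angle <- function(a, b, c, params = model_params()) {
  u <- b - a
  v <- c - b
  if (params$interior_angle) u <- -u
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate geometry: zero-length bond")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Signed dihedral angle of three consecutive bonds
#'
#' Standard atan2 convention on the two plane normals; the sign comes from
#' the handedness of the three bonds, so mirror-imaging a conformation
#' negates every dihedral. Right-handed helices have positive dihedrals.
#'
#' @param a,b,c,d positions of four consecutive monomers.
#' @return Signed angle in `(-pi, pi]`.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) == 0 || sum(n2^2) == 0) {
    stop("degenerate geometry: vanishing plane normal")
  }
  atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Internal coordinates of a chain
#'
#' @param x an `N x 3` coordinate matrix.
#' @inheritParams v_fene
#' @return A tibble with one row per monomer: `bond` (length of the bond to
#'   the next monomer), `theta` (bending angle centred on the monomer) and
#'   `tau` (dihedral of the bond starting at the monomer), `NA` where
#'   undefined.
#' @export
chain_geometry <- function(x, params = model_params()) {
  x <- check_conformation(x)
  n <- nrow(x)
  bond <- c(sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2)), NA)
  theta <- rep(NA_real_, n)
  tau <- rep(NA_real_, n)
  if (n >= 3) {
    for (k in 2:(n - 1)) theta[k] <- bending_angle(x[k - 1, ], x[k, ], x[k + 1, ], params)
  }
  if (n >= 4) {
    for (l in 1:(n - 3)) tau[l] <- dihedral_angle(x[l, ], x[l + 1, ], x[l + 2, ], x[l + 3, ])
  }
  tibble::tibble(monomer = seq_len(n), bond = bond, theta = theta, tau = tau)
}

#' Total energy of a conformation
#'
#' Evaluates the Hamiltonian
#' `H(X) = S_FENE * sum v_FENE + S_LJ * sum v_LJ + S_tau * sum v_tor +
#' S_theta * sum v_bend`, with the LJ sum over non-bonded pairs
#' (`|i - j| >= 2` unless `lj_bonded` is set), bending over the `N - 2`
#' interior angles and torsion over the `N - 3` dihedrals. Invariant under
#' rigid motions of the chain.
#'
#' @param x an `N x 3` coordinate matrix.
#' @inheritParams v_fene
#' @return Total energy (scalar). Errors if any bond violates the FENE
#'   domain.
#' @export
total_energy <- function(x, params = model_params()) {
  tt <- energy_terms(x, params)
  if (!is.finite(tt$energy[tt$term == "fene"])) {
    stop("bond length outside the FENE domain (|r - r0| >= R)")
  }
  sum(tt$energy)
}

#' Energy decomposition by Hamiltonian term
#'
#' @inheritParams total_energy
#' @return A tibble with columns `term` (fene, lj, bend, torsion),
#'   `unscaled` (raw potential sum), `scale` and `energy = scale * unscaled`.
#' @export
energy_terms <- function(x, params = model_params()) {
  x <- check_conformation(x)
  raw <- energy_terms_cpp(x, as_params_list(params))
  scales <- c(fene = params$s_fene, lj = params$s_lj,
              bend = params$s_theta, torsion = params$s_tau)
  tibble::tibble(
    term = names(scales),
    unscaled = as.numeric(raw[names(scales)]),
    scale = as.numeric(scales),
    energy = .data$unscaled * .data$scale
  )
}

#' Helix-bundling order parameter q
#'
#' Ratio of the summed truncated-shifted LJ energy over long-range pairs
#' (`|i - j| > 6`) to short-range pairs (`2 <= |i - j| <= 6`). Single
#' helices have essentially no long-range LJ contact (q in the lowest bin,
#' around 0.01), while two-helix bundles, whose segments pack against each
#' other, sit in a well-separated band around 0.35--0.45 (equilibrated
#' low-temperature bundles of this model concentrate near the top of that
#' band). Returns 0 by convention when the denominator
#' magnitude falls below `q_eps` (e.g. fully extended chains).
#'
#' @inheritParams total_energy
#' @return The dimensionless bundling ratio q.
#' @export
order_q <- function(x, params = model_params()) {
  x <- check_conformation(x)
  if (nrow(x) < 3) stop("q requires at least 3 monomers")
  order_q_cpp(x, as_params_list(params), params$q_eps)
}
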