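#' Monte Carlo move proposals
#'
#' The four update types used by the sampler, exposed individually. All draw
#' from R's RNG, so `set.seed()` makes proposals reproducible, and all
#' proposal densities are symmetric (the reverse move is equally likely), as
#' Metropolis acceptance requires.
#'
#' * `propose_local_move()`: displaces one uniformly chosen monomer by a
#'   vector drawn uniformly from the cube `[-step, step]^3`.
#' * `propose_global_displacement()`: picks a pivot `k` (any monomer but the
#'   last) and shifts monomers `k+1..N` rigidly by one common random vector.
#' * `propose_bend_move()`: picks an interior pivot and rotates all
#'   subsequent monomers about the axis through the pivot perpendicular to
#'   its two neighboring bonds (normalized cross product); when the bonds
#'   are parallel the axis is resampled uniformly in the perpendicular
#'   plane. Rotation angle uniform in `[-max_angle, max_angle]`.
#' * `propose_torsion_move()`: picks an interior pivot and rotates all
#'   subsequent monomers about the previous bond; the dihedral at that bond
#'   changes by exactly the drawn angle while all bond lengths and bending
#'   angles are preserved.
#'
#' @param x an `N x 3` coordinate matrix.
#' @param step maximum per-axis displacement.
#' @param max_angle maximum rotation angle in radians.
#' @return A list with elements `coords` (the proposed conformation),
#'   `pivot` (1-based pivot index) and `draw` (the displacement vector or
#'   rotation angle).
#' @export
propose_local_move <- function(x, step = 0.3) {
  stopifnot(step > 0)
  propose_local_cpp(check_conformation(x), step)
}

#' @rdname propose_local_move
#' @export
propose_global_displacement <- function(x, step = 0.3) {
  x <- check_conformation(x)
  propose_global_cpp(x, step)
}

#' @rdname propose_local_move
#' @export
propose_bend_move <- function(x, max_angle = 0.5) {
  x <- check_conformation(x)
  if (nrow(x) < 3) stop("bend move needs at least 3 monomers")
  propose_bend_cpp(x, max_angle)
}

#' @rdname propose_local_move
#' @export
propose_torsion_move <- function(x, max_angle = 0.5) {
  x <- check_conformation(x)
  if (nrow(x) < 3) stop("torsion move needs at least 3 monomers")
  propose_torsion_cpp(x, max_angle)
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-beta * delta_e))`, using one
#' uniform draw. A proposal whose bonds leave the FENE domain
#' (`proposal_valid = FALSE`) is rejected unconditionally, before any energy
#' is consulted.
#'
#' @param delta_e energy change of the proposal.
#' @param beta inverse temperature (> 0).
#' @param proposal_valid does every bond satisfy the FENE domain?
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
metropolis_accept <- function(delta_e, beta, proposal_valid = TRUE) {
  stopifnot(beta > 0)
  if (!proposal_valid) return(FALSE)
  if (delta_e <= 0) return(TRUE)
  stats::runif(1) < exp(-beta * delta_e)
}
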