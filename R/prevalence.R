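#' Structural prevalence over energy and the bundling order parameter
#'
#' `p(E, q) = g(E, q) / g(E)`, the relative prevalence of structure types
#' within each microcanonical ensemble. The normalizer `g(E)` is taken as
#' the q-marginal of `g(E, q)`, which guarantees that every populated energy
#' column sums to exactly 1 (the independently reweighted 1D density of
#' states agrees within reweighting consistency anyway). Cells never visited
#' by the sampler are masked (`NA`), matching the white cells of a
#' prevalence heat map.
#'
#' @param dos2d a `helix_dos2d` object from [wham_2d()].
#' @return A `prevalence_field` tibble: `E`, `q`, `p` (`NA` when masked);
#'   attributes carry the grids and bin widths.
#' @export
prevalence_field <- function(dos2d) {
  stopifnot(inherits(dos2d, "helix_dos2d"))
  lg <- dos2d$log_g
  marg <- apply(lg, 1, logsumexp)
  p <- exp(sweep(lg, 1, marg))
  p[!dos2d$support] <- NA_real_
  p[!is.finite(marg), ] <- NA_real_
  out <- tidyr::expand_grid(q = dos2d$q_mid, E = dos2d$e_mid)
  out <- dplyr::arrange(out, .data$q, .data$E)
  out$p <- as.vector(p) # column-major: E fastest, grouped by q
  out <- out[, c("E", "q", "p")]
  attr(out, "e_mid") <- dos2d$e_mid
  attr(out, "q_mid") <- dos2d$q_mid
  attr(out, "e_bin") <- dos2d$e_bin
  attr(out, "q_bin") <- dos2d$q_bin
  attr(out, "s_tau") <- dos2d$s_tau
  class(out) <- c("prevalence_field", class(out))
  out
}

#' Constant-q cross-sections of the prevalence field
#'
#' Extracts p(E) at the q bins nearest the requested values — typically the
#' two-helix-bundle band (around 0.35--0.45), the single-helix bin (around
#' 0.01), and a few intermediate bins. The actual bin centers used are
#' reported.
#'
#' @param field a [prevalence_field()] result.
#' @param q_values q values to extract (each matched to the nearest bin
#'   center; an error if outside the grid by more than one bin).
#' @return A tibble `q_requested`, `q` (bin center used), `E`, `p`. Columns
#'   that are entirely masked come back with all-`NA` `p` and a warning.
#' @export
q_cross_sections <- function(field, q_values) {
  q_mid <- attr(field, "q_mid")
  q_bin <- attr(field, "q_bin")
  out <- lapply(q_values, function(qv) {
    d <- abs(q_mid - qv)
    k <- which.min(d)
    if (d[k] > q_bin) stop("requested q = ", qv, " lies outside the q grid")
    col <- field[abs(field$q - q_mid[k]) < q_bin / 2, ]
    if (all(is.na(col$p))) {
      warning("q bin at ", format(q_mid[k]), " is entirely unpopulated")
    }
    tibble::tibble(q_requested = qv, q = q_mid[k], E = col$E, p = col$p)
  })
  dplyr::bind_rows(out)
}
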