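#' Microcanonical entropy from the density of states
#'
#' `S(E) = kB log g(E)` with `kB = 1`, restricted to the longest contiguous
#' run of supported energy bins after trimming sparse edges (bins with fewer
#' than `min_counts`-backed support at the extremes would otherwise leave
#' isolated islands that the smoothing window cannot span).
#'
#' @param dos a `helix_dos` object (or any list with a `table` tibble
#'   holding `E`, `log_g`, `support`).
#' @param min_run minimum length of the contiguous support run required
#'   (must accommodate the smoothing window later).
#' @return An `entropy_curves` tibble with columns `E`, `S`; attributes
#'   record the bin width and trimming.
#' @export
entropy_from_dos <- function(dos, min_run = 5) {
  tb <- dos$table
  supp <- tb$support & is.finite(tb$log_g)
  r <- rle(supp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) stop("density of states has no supported bins")
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  if (length(idx) < min_run) {
    stop("contiguous support (", length(idx),
         " bins) too short for analysis")
  }
  out <- tibble::tibble(E = tb$E[idx], S = tb$log_g[idx])
  attr(out, "e_bin") <- dos$e_bin %||% (out$E[2] - out$E[1])
  attr(out, "trimmed") <- nrow(tb) - length(idx)
  class(out) <- c("entropy_curves", class(out))
  out
}

#' Savitzky-Golay smoothed entropy and derivatives
#'
#' Fits a local polynomial of the given order in a sliding window and
#' evaluates it and its first four derivatives, all scaled by the energy
#' bin width. One smoothing operator produces every curve, so `S`, `beta`,
#' `gamma`, `delta` and the fourth derivative are mutually consistent.
#' Polynomials of degree `<= order` are reproduced exactly in the interior;
#' near the boundaries the fit is evaluated off-center within the same
#' window.
#'
#' @param curves a tibble with columns `E` (uniform grid) and `S`, e.g. from
#'   [entropy_from_dos()] or [planted_entropy()].
#' @param window odd window length in bins (auto-shrunk to the largest odd
#'   length `<=` the series if necessary).
#' @param order polynomial order (`order < window`; `>= 4` is needed to
#'   resolve fourth-order transition signals).
#' @return An `entropy_curves` tibble with columns `E`, `S` (smoothed),
#'   `beta` = dS/dE, `gamma` = d2S/dE2, `delta` = d3S/dE3 and `d4`;
#'   attributes `window`, `order`, `e_bin`.
#' @export
smooth_derivatives <- function(curves, window = 51, order = 4) {
  e <- curves$E
  s <- curves$S
  n <- length(e)
  h <- diff(e)
  if (any(abs(h - h[1]) > 1e-8 * max(abs(h)))) {
    stop("energy grid must be uniform")
  }
  h <- h[1]
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) {
    window <- if (n %% 2 == 1) n else n - 1
  }
  if (order >= window) stop("polynomial order must be below the window length")
  sm <- lapply(0:4, function(m) {
    if (m > order) rep(0, n) else signal::sgolayfilt(s, p = order, n = window,
                                                     m = m, ts = h)
  })
  out <- tibble::tibble(E = e, S = sm[[1]], beta = sm[[2]], gamma = sm[[3]],
                        delta = sm[[4]], d4 = sm[[5]])
  attr(out, "window") <- window
  attr(out, "order") <- order
  attr(out, "e_bin") <- h
  class(out) <- c("entropy_curves", class(out))
  out
}

local_extrema <- function(v, kind = c("max", "min")) {
  kind <- match.arg(kind)
  n <- length(v)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  hit <- if (kind == "max") v[i] > v[i - 1] & v[i] >= v[i + 1]
         else v[i] < v[i - 1] & v[i] <= v[i + 1]
  i[hit]
}

#' Detect and classify phase transitions by inflection-point analysis
#'
#' Implements microcanonical inflection-point analysis on smoothed entropy
#' derivatives: an n-th order transition in a finite system shows up as a
#' region of least sensitivity in the (n-1)-th derivative of S. Candidates
#' are collected lowest order first and each energy is assigned to exactly
#' one order:
#'
#' 1. *First order*: a backbending region of `beta` (`gamma > 0`
#'    somewhere); the transition energy is the inflection of S inside it
#'    (the maximum of `gamma`).
#' 2. *Second order*: a local maximum of `gamma` that approaches zero from
#'    below without crossing (`gamma < 0` at the peak); equivalently a zero
#'    crossing of `delta` at that energy.
#' 3. *Third order*: a local minimum of `delta` dipping toward zero (the
#'    "inverted peaks" of the third derivative).
#' 4. *Fourth order*: a local extremum of the fourth derivative approaching
#'    zero from the side of its local baseline.
#'
#' "Approaching zero" is operationalized as the extremum magnitude falling
#' below `zero_fraction` of the local baseline magnitude; the baseline is
#' the median of the channel over `±5` window-lengths around the candidate
#' (excluding one window-length around it). Candidates with prominence
#' below `prominence` are discarded, as are candidates within
#' `exclusion` energy units of an already-assigned lower-order transition
#' (a low-order feature necessarily echoes in all higher derivatives).
#'
#' @param curves output of [smooth_derivatives()].
#' @param prominence minimum prominence; by default 5 times the median
#'   absolute deviation of the channel after removing its running-median
#'   trend (a window-scale noise estimate robust to localized signals).
#' @param zero_fraction fraction of the baseline magnitude below which an
#'   extremum counts as "approaching zero" (default 0.9).
#' @param exclusion dedup radius in energy units (default one smoothing
#'   window).
#' @param max_order highest transition order searched (<= 4).
#' @return A `helix_transitions` tibble: `energy`, `order`, `channel`,
#'   `value`, `baseline`, `prominence`, sorted by energy. Transition-free
#'   input yields zero rows.
#' @export
detect_transitions <- function(curves, prominence = NULL, zero_fraction = 0.9,
                               exclusion = NULL, max_order = 4) {
  stopifnot(all(c("beta", "gamma", "delta", "d4") %in% names(curves)))
  window <- attr(curves, "window") %||% 51
  h <- attr(curves, "e_bin") %||% (curves$E[2] - curves$E[1])
  n <- nrow(curves)
  margin <- (window - 1) %/% 2
  ok <- seq_len(n) > margin & seq_len(n) <= n - margin
  if (!any(ok)) stop("support too short for the smoothing window")
  if (is.null(exclusion)) exclusion <- window * h

  baseline_at <- function(v, i) {
    j <- which(ok & abs(seq_len(n) - i) <= 5 * window &
                 abs(seq_len(n) - i) > window)
    if (length(j) == 0) j <- which(ok)
    stats::median(v[j])
  }
  thr <- function(v) {
    if (!is.null(prominence)) return(prominence)
    # Noise scale of the channel after removing its smooth local trend: the
    # raw channel drifts over the full energy range, which would swamp
    # genuine localized signals if used directly.
    vv <- v[ok]
    k <- min(window, length(vv) - (1 - length(vv) %% 2))
    if (k %% 2 == 0) k <- k - 1
    res <- if (k >= 3) vv - stats::runmed(vv, k) else vv - stats::median(vv)
    max(5 * stats::mad(res), 0.02 * stats::mad(vv), 1e-12)
  }

  rec <- list()
  accepted <- numeric()
  add <- function(i, ord, channel, value, base, prom) {
    e_t <- curves$E[i]
    if (any(abs(accepted - e_t) < exclusion)) return(FALSE)
    accepted <<- c(accepted, e_t)
    rec[[length(rec) + 1]] <<- tibble::tibble(
      energy = e_t, order = ord, channel = channel, value = value,
      baseline = base, prominence = prom)
    TRUE
  }

  g <- curves$gamma
  d <- curves$delta
  f4 <- curves$d4
  interior <- which(ok)
  # Extrema are located on the centered-fit interior only: the off-center
  # boundary fits wiggle and would otherwise plant fake extrema at the seam.
  interior_extrema <- function(v, kind) {
    interior[local_extrema(v[interior], kind)]
  }

  # -- first order: backbending regions of beta (gamma > 0)
  pos <- g > 0 & ok
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      i <- idx[which.max(g[idx])]
      base <- baseline_at(g, i)
      prom <- g[i] - base
      if (prom >= thr(g)) add(i, 1L, "gamma>0", g[i], base, prom)
    }
  }

  # -- second order: sub-zero local maxima of gamma approaching zero
  if (max_order >= 2) {
    for (i in interior_extrema(g, "max")) {
      if (g[i] >= 0) next
      base <- baseline_at(g, i)
      if (base >= 0) next
      prom <- g[i] - base
      if (prom >= thr(g) && abs(g[i]) < zero_fraction * abs(base)) {
        add(i, 2L, "gamma-peak", g[i], base, prom)
      }
    }
  }

  # -- third order: local minima of delta dipping toward zero
  if (max_order >= 3) {
    for (i in interior_extrema(d, "min")) {
      base <- baseline_at(d, i)
      if (base <= 0) next
      prom <- base - d[i]
      if (prom >= thr(d) && d[i] < zero_fraction * base) {
        add(i, 3L, "delta-dip", d[i], base, prom)
      }
    }
  }

  # -- fourth order: extrema of the fourth derivative approaching zero
  if (max_order >= 4) {
    cand <- c(interior_extrema(f4, "max"), interior_extrema(f4, "min"))
    for (i in cand) {
      base <- baseline_at(f4, i)
      if (base == 0) next
      prom <- abs(f4[i] - base)
      toward_zero <- sign(f4[i] - base) == -sign(base)
      if (toward_zero && prom >= thr(f4) &&
          abs(f4[i]) < zero_fraction * abs(base)) {
        add(i, 4L, "d4-extremum", f4[i], base, prom)
      }
    }
  }

  out <- if (length(rec)) dplyr::arrange(dplyr::bind_rows(rec), .data$energy)
         else tibble::tibble(energy = numeric(), order = integer(),
                             channel = character(), value = numeric(),
                             baseline = numeric(), prominence = numeric())
  attr(out, "window") <- window
  attr(out, "zero_fraction") <- zero_fraction
  class(out) <- c("helix_transitions", class(out))
  out
}
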