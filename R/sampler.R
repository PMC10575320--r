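#' Simulation schedule for the two-dimensional replica-exchange grid
#'
#' Defines the full grid of Metropolis threads: a geometric temperature
#' ladder crossed with a ladder of torsion strengths `s_tau`, plus sweep
#' counts, the move mix, step sizes and histogram binning. Temperatures are
#' spaced exponentially so successive temperatures differ by the same
#' factor: `T_k = t_min * (t_max/t_min)^(k/(K-1))`.
#'
#' @param n chain length (number of monomers).
#' @param t_range `c(t_min, t_max)` of the temperature ladder.
#' @param n_temp number of temperatures (>= 1).
#' @param s_tau vector of torsion energy scales, one Hamiltonian per value.
#' @param sweeps production sweeps per thread (one sweep = `n` move
#'   attempts; E and q are recorded once per sweep).
#' @param burn_in sweeps discarded before histogramming (`< sweeps`).
#' @param exchange_interval sweeps between replica-exchange rounds.
#' @param move_mix probabilities of the four move kinds, in the order
#'   local, global displacement, bend rotation, torsion rotation.
#' @param local_step,global_step maximum per-axis displacements.
#' @param max_bend,max_torsion maximum rotation angles (radians).
#' @param e_bin,q_bin histogram bin widths for energy and q.
#' @param tune_steps adapt step sizes per thread toward `tune_target`
#'   acceptance during burn-in only (frozen before production sweeps, which
#'   preserves detailed balance in production)?
#' @param tune_target per-kind acceptance rate targeted by burn-in tuning.
#' @param exchange_axes which grid axes exchange replicas: both by default;
#'   `"s_tau"` restricts to Hamiltonian exchanges, `"temperature"` to
#'   temperature exchanges.
#' @param seed default RNG seed for [run_grid()].
#' @return A `helix_schedule` object.
#' @export
build_schedule <- function(n = 30, t_range = c(0.2, 1.6), n_temp = 16,
                           s_tau = seq(5, 14, length.out = 10),
                           sweeps = 20000, burn_in = 2000,
                           exchange_interval = 100,
                           move_mix = c(local = 0.7, global = 0.1,
                                        bend = 0.1, torsion = 0.1),
                           local_step = 0.3, global_step = 0.3,
                           max_bend = 0.5, max_torsion = 0.5,
                           e_bin = 0.1, q_bin = 0.02,
                           tune_steps = TRUE, tune_target = 0.4,
                           exchange_axes = c("temperature", "s_tau"),
                           seed = 1L) {
  stopifnot(n >= 2, length(t_range) == 2, t_range[1] > 0,
            t_range[2] >= t_range[1], n_temp >= 1,
            all(s_tau > 0), sweeps > burn_in, burn_in >= 0,
            exchange_interval >= 1, length(move_mix) == 4,
            all(move_mix >= 0), sum(move_mix) > 0,
            e_bin > 0, q_bin > 0)
  if (n_temp > 1 && t_range[2] <= t_range[1]) {
    stop("t_max must exceed t_min for a ladder with more than one rung")
  }
  exchange_axes <- match.arg(exchange_axes, several.ok = TRUE)
  temperatures <- geometric_temperatures(t_range[1], t_range[2], n_temp)
  structure(list(
    n = n, temperatures = temperatures, s_tau = as.numeric(s_tau),
    sweeps = as.integer(sweeps), burn_in = as.integer(burn_in),
    exchange_interval = as.integer(exchange_interval),
    move_mix = move_mix, local_step = local_step, global_step = global_step,
    max_bend = max_bend, max_torsion = max_torsion,
    e_bin = e_bin, q_bin = q_bin, exchange_axes = exchange_axes,
    tune_steps = isTRUE(tune_steps), tune_target = tune_target,
    seed = as.integer(seed)
  ), class = "helix_schedule")
}

#' Geometric temperature ladder
#'
#' @param t_min,t_max endpoints (positive, `t_min <= t_max`).
#' @param k number of rungs.
#' @return Strictly increasing temperatures with constant successive ratio.
#' @export
geometric_temperatures <- function(t_min, t_max, k) {
  stopifnot(t_min > 0, k >= 1)
  if (k == 1) return(t_min)
  t_min * (t_max / t_min)^((0:(k - 1)) / (k - 1))
}

#' @export
print.helix_schedule <- function(x, ...) {
  cat(sprintf("Replica-exchange schedule: N = %d, %d temperatures x %d s_tau = %d threads\n",
              x$n, length(x$temperatures), length(x$s_tau),
              length(x$temperatures) * length(x$s_tau)))
  cat(sprintf("  T in [%.3g, %.3g] (geometric), s_tau in [%g, %g]\n",
              min(x$temperatures), max(x$temperatures),
              min(x$s_tau), max(x$s_tau)))
  cat(sprintf("  %d sweeps (%d burn-in), exchange every %d sweeps\n",
              x$sweeps, x$burn_in, x$exchange_interval))
  invisible(x)
}

#' Replica-exchange acceptance probability
#'
#' For threads `i` and `j` with inverse temperatures `beta_i`, `beta_j` and
#' Hamiltonians `H_i`, `H_j`, a swap of configurations is accepted with
#' probability
#' `min(1, exp(beta_i H_i(X_i) + beta_j H_j(X_j) - beta_i H_i(X_j) -
#' beta_j H_j(X_i)))`. For identical Hamiltonians this reduces to
#' `min(1, exp((beta_i - beta_j) (E_i - E_j)))`.
#'
#' @param beta_i,beta_j inverse temperatures (> 0).
#' @param e_ii `H_i(X_i)`; @param e_jj `H_j(X_j)`;
#' @param e_ij `H_i(X_j)`; @param e_ji `H_j(X_i)`.
#' @return The acceptance probability.
#' @export
exchange_probability <- function(beta_i, beta_j, e_ii, e_jj, e_ij, e_ji) {
  stopifnot(beta_i > 0, beta_j > 0)
  expo <- beta_i * e_ii + beta_j * e_jj - beta_i * e_ij - beta_j * e_ji
  min(1, exp(min(expo, 0)))
}

scaled_energy <- function(terms, params) {
  params$s_fene * terms[["fene"]] + params$s_lj * terms[["lj"]] +
    params$s_theta * terms[["bend"]] + params$s_tau * terms[["torsion"]]
}

#' Run Metropolis sweeps for a single thread
#'
#' Advances one replica by `n_sweeps` sweeps of `n` move attempts each,
#' drawn from the schedule's move mix, recording energy and the bundling
#' order parameter q once per sweep. Energies are fully recomputed per
#' proposal; FENE-domain violations are rejected outright.
#'
#' @param x starting conformation (`N x 3` matrix).
#' @param params a [model_params()] object (fixes the thread's Hamiltonian).
#' @param beta inverse temperature.
#' @param n_sweeps number of sweeps.
#' @param schedule a [build_schedule()] object supplying move mix and steps.
#' @param record record per-sweep E and q traces? (default `TRUE`)
#' @return A list: `coords`, `energy`, `terms` (raw per-term sums),
#'   `trace` (tibble with `sweep`, `E`, `q`), `moves` (tibble of per-kind
#'   attempts/accepts), `min_energy`, `min_coords`.
#' @export
run_thread_sweeps <- function(x, params, beta, n_sweeps,
                              schedule = build_schedule(n = nrow(x)),
                              record = TRUE) {
  x <- check_conformation(x)
  stopifnot(beta > 0, n_sweeps >= 0)
  if (n_sweeps == 0) {
    terms <- energy_terms_cpp(x, as_params_list(params))
    return(list(coords = x, energy = scaled_energy(terms, params),
                terms = terms,
                trace = tibble::tibble(sweep = integer(), E = numeric(),
                                       q = numeric()),
                moves = move_table(integer(4), integer(4)),
                min_energy = scaled_energy(terms, params), min_coords = x))
  }
  res <- run_sweeps_cpp(x, as_params_list(params), beta, as.integer(n_sweeps),
                        as.numeric(schedule$move_mix), schedule$local_step,
                        schedule$global_step, schedule$max_bend,
                        schedule$max_torsion, params$q_eps, record)
  list(coords = res$coords, energy = res$energy, terms = res$terms,
       trace = tibble::tibble(sweep = seq_len(n_sweeps),
                              E = as.numeric(res$e_trace),
                              q = as.numeric(res$q_trace)),
       moves = move_table(res$attempts, res$accepts),
       min_energy = res$min_energy, min_coords = res$min_coords)
}

move_table <- function(attempts, accepts) {
  tibble::tibble(kind = c("local", "global", "bend", "torsion"),
                 attempts = as.integer(attempts),
                 accepts = as.integer(accepts))
}

#' Run the full two-dimensional replica-exchange grid
#'
#' Advances every thread of the temperature-by-`s_tau` grid, alternating
#' Metropolis sweep bursts with replica-exchange rounds. Exchange rounds
#' alternate between temperature-neighbor pairs (same Hamiltonian) and
#' `s_tau`-neighbor pairs (Hamiltonian exchange at equal temperature), with
#' even/odd pairing alternating each time an axis recurs. Swaps exchange
#' conformations; the cached per-term energy sums make re-evaluation under
#' the receiving Hamiltonian exact and free.
#'
#' Threads execute serially in thread order within a single RNG stream, so
#' the whole run is reproducible bitwise from `(schedule, seed)`.
#'
#' @param schedule a [build_schedule()] object.
#' @param params base [model_params()]; each thread overrides `s_tau`.
#' @param init `"helix"` (default: all replicas start from the ideal-helix
#'   fixture, a valid FENE geometry everywhere), `"coil"` for random coils,
#'   or a list of conformations, one per thread.
#' @param seed RNG seed (defaults to the schedule's).
#' @param progress print a line per exchange round?
#' @return A `helix_run` object: `schedule`, `threads` (tibble with
#'   `thread`, `temperature`, `beta`, `s_tau`), `e_trace`/`q_trace`
#'   (sweeps x threads matrices), `moves` (per-thread move statistics),
#'   `exchange` (tibble of attempted/accepted swaps per neighbor pair),
#'   `minima` (per-thread lowest-energy records with conformations), and
#'   `final` (per-thread final conformations).
#' @export
run_grid <- function(schedule, params = model_params(), init = "helix",
                     seed = schedule$seed, progress = FALSE) {
  stopifnot(inherits(schedule, "helix_schedule"))
  set.seed(seed)
  temps <- schedule$temperatures
  svals <- schedule$s_tau
  kt <- length(temps)
  ks <- length(svals)
  nthr <- kt * ks
  threads <- tibble::tibble(
    thread = seq_len(nthr),
    i_temp = rep(seq_len(kt), times = ks),
    i_s = rep(seq_len(ks), each = kt),
    temperature = temps[rep(seq_len(kt), times = ks)],
    s_tau = svals[rep(seq_len(ks), each = kt)]
  )
  threads$beta <- 1 / threads$temperature
  par_list <- lapply(threads$s_tau, function(s) {
    p <- params
    p$s_tau <- s
    p
  })

  states <- vector("list", nthr)
  for (t in seq_len(nthr)) {
    x0 <- if (is.list(init)) {
      check_conformation(init[[t]])
    } else if (identical(init, "helix")) {
      ideal_helix(schedule$n, par_list[[t]])
    } else if (identical(init, "coil")) {
      random_coil(schedule$n, par_list[[t]])
    } else {
      stop("`init` must be \"helix\", \"coil\", or a list of conformations")
    }
    terms <- energy_terms_cpp(x0, as_params_list(par_list[[t]]))
    if (!is.finite(terms[["fene"]])) {
      stop("initial conformation for thread ", t, " violates the FENE domain")
    }
    states[[t]] <- list(coords = x0, terms = terms)
  }

  sweeps <- schedule$sweeps
  interval <- schedule$exchange_interval
  e_trace <- matrix(NA_real_, sweeps, nthr)
  q_trace <- matrix(NA_real_, sweeps, nthr)
  att_mv <- matrix(0L, 4, nthr)
  acc_mv <- matrix(0L, 4, nthr)
  # per-thread step sizes (rows: local, global, bend, torsion); tuned toward
  # the target acceptance during burn-in only, then frozen
  steps <- matrix(c(schedule$local_step, schedule$global_step,
                    schedule$max_bend, schedule$max_torsion),
                  4, nthr)
  min_e <- rep(Inf, nthr)
  min_x <- vector("list", nthr)
  min_q <- rep(NA_real_, nthr)

  axes <- schedule$exchange_axes
  if (kt < 2) axes <- setdiff(axes, "temperature")
  if (ks < 2) axes <- setdiff(axes, "s_tau")
  ex_att <- list()
  ex_acc <- list()

  done <- 0L
  round_i <- 0L
  while (done < sweeps) {
    burst <- min(interval, sweeps - done)
    for (t in seq_len(nthr)) {
      res <- run_sweeps_cpp(states[[t]]$coords, as_params_list(par_list[[t]]),
                            threads$beta[t], burst,
                            as.numeric(schedule$move_mix),
                            steps[1, t], steps[2, t], steps[3, t], steps[4, t],
                            params$q_eps, TRUE)
      states[[t]] <- list(coords = res$coords, terms = res$terms)
      e_trace[(done + 1):(done + burst), t] <- res$e_trace
      q_trace[(done + 1):(done + burst), t] <- res$q_trace
      att_mv[, t] <- att_mv[, t] + res$attempts
      acc_mv[, t] <- acc_mv[, t] + res$accepts
      if (res$min_energy < min_e[t]) {
        min_e[t] <- res$min_energy
        min_x[[t]] <- res$min_coords
        min_q[t] <- order_q_cpp(res$min_coords, as_params_list(par_list[[t]]),
                                params$q_eps)
      }
      if (schedule$tune_steps && done + burst <= schedule$burn_in) {
        rate <- ifelse(res$attempts > 0, res$accepts / res$attempts, NA)
        fac <- pmin(1.5, pmax(0.6, exp(rate - schedule$tune_target)))
        fac[is.na(fac)] <- 1
        steps[1:2, t] <- pmin(1.5, pmax(0.005, steps[1:2, t] * fac[1:2]))
        steps[3:4, t] <- pmin(pi, pmax(0.005, steps[3:4, t] * fac[3:4]))
      }
    }
    done <- done + burst
    if (done >= sweeps || length(axes) == 0) break
    round_i <- round_i + 1L
    axis <- axes[((round_i - 1L) %% length(axes)) + 1L]
    parity <- ((round_i - 1L) %/% length(axes)) %% 2L
    pairs <- exchange_pairs(threads, axis, parity)
    for (pr in pairs) {
      i <- pr[1]; j <- pr[2]
      ti <- states[[i]]$terms; tj <- states[[j]]$terms
      e_ii <- scaled_energy(ti, par_list[[i]])
      e_jj <- scaled_energy(tj, par_list[[j]])
      e_ij <- scaled_energy(tj, par_list[[i]])
      e_ji <- scaled_energy(ti, par_list[[j]])
      p_acc <- exchange_probability(threads$beta[i], threads$beta[j],
                                    e_ii, e_jj, e_ij, e_ji)
      key <- paste(i, j, sep = "-")
      ex_att[[key]] <- (ex_att[[key]] %||% 0L) + 1L
      if (stats::runif(1) < p_acc) {
        ex_acc[[key]] <- (ex_acc[[key]] %||% 0L) + 1L
        tmp <- states[[i]]
        states[[i]] <- states[[j]]
        states[[j]] <- tmp
      }
    }
    if (progress) {
      message(sprintf("round %d (%s axis): %d/%d sweeps", round_i, axis,
                      done, sweeps))
    }
  }

  keys <- names(ex_att)
  exchange <- tibble::tibble(
    thread_i = as.integer(sub("-.*", "", keys)),
    thread_j = as.integer(sub(".*-", "", keys)),
    attempts = vapply(keys, function(k) as.integer(ex_att[[k]]), integer(1)),
    accepts = vapply(keys, function(k) as.integer(ex_acc[[k]] %||% 0L),
                     integer(1))
  )
  moves <- dplyr::bind_rows(lapply(seq_len(nthr), function(t) {
    dplyr::mutate(move_table(att_mv[, t], acc_mv[, t]), thread = t,
                  .before = 1)
  }))
  minima <- tibble::tibble(thread = seq_len(nthr),
                           s_tau = threads$s_tau,
                           temperature = threads$temperature,
                           min_energy = min_e, min_q = min_q)
  structure(list(
    schedule = schedule, params = params, threads = threads,
    e_trace = e_trace, q_trace = q_trace, moves = moves,
    exchange = exchange, minima = minima, min_coords = min_x,
    final = lapply(states, `[[`, "coords"), steps = steps, seed = seed
  ), class = "helix_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

exchange_pairs <- function(threads, axis, parity) {
  pairs <- list()
  if (axis == "temperature") {
    for (s in unique(threads$i_s)) {
      idx <- threads$thread[threads$i_s == s][order(threads$i_temp[threads$i_s == s])]
      if (length(idx) - 1 < 1 + parity) next
      starts <- seq(1 + parity, length(idx) - 1, by = 2)
      for (a in starts) pairs[[length(pairs) + 1]] <- c(idx[a], idx[a + 1])
    }
  } else {
    for (tt in unique(threads$i_temp)) {
      idx <- threads$thread[threads$i_temp == tt][order(threads$i_s[threads$i_temp == tt])]
      if (length(idx) - 1 < 1 + parity) next
      starts <- seq(1 + parity, length(idx) - 1, by = 2)
      for (a in starts) pairs[[length(pairs) + 1]] <- c(idx[a], idx[a + 1])
    }
  }
  pairs
}

#' @export
print.helix_run <- function(x, ...) {
  cat(sprintf("helix_run: %d threads x %d sweeps (N = %d)\n",
              nrow(x$threads), x$schedule$sweeps, x$schedule$n))
  cat(sprintf("  lowest sampled energy: %.3f (thread %d, s_tau = %g, q = %.3f)\n",
              min(x$minima$min_energy),
              x$minima$thread[which.min(x$minima$min_energy)],
              x$minima$s_tau[which.min(x$minima$min_energy)],
              x$minima$min_q[which.min(x$minima$min_energy)]))
  invisible(x)
}

bin_index <- function(v, width) as.integer(floor(v / width))

#' Per-thread energy histograms from a run
#'
#' Bins the post-burn-in per-sweep energies of every thread at one `s_tau`
#' onto a shared uniform grid (bin edges at integer multiples of `e_bin`).
#' One deposit per sweep, so each thread's total count is exactly
#' `sweeps - burn_in`.
#'
#' @param run a [run_grid()] result.
#' @param s_tau which Hamiltonian's threads to histogram (required when the
#'   run covers several; defaults to the single value present).
#' @param e_bin bin width (defaults to the schedule's).
#' @return A `helix_histograms` object: `e_mid` (bin centers), `counts`
#'   (bins x threads matrix), `beta`, `temperature`, `s_tau`, `m`
#'   (per-thread totals), `e_bin`.
#' @export
energy_histograms <- function(run, s_tau = NULL, e_bin = run$schedule$e_bin) {
  sel <- select_threads(run, s_tau)
  sweeps_keep <- (run$schedule$burn_in + 1):run$schedule$sweeps
  e <- run$e_trace[sweeps_keep, sel$thread, drop = FALSE]
  idx_range <- range(bin_index(e, e_bin))
  idx_seq <- idx_range[1]:idx_range[2]
  counts <- apply(e, 2, function(col) {
    tabulate(bin_index(col, e_bin) - idx_range[1] + 1L,
             nbins = length(idx_seq))
  })
  structure(list(
    e_mid = (idx_seq + 0.5) * e_bin, e_bin = e_bin,
    counts = counts, beta = 1 / sel$temperature,
    temperature = sel$temperature, s_tau = unique(sel$s_tau),
    m = colSums(counts)
  ), class = "helix_histograms")
}

#' Per-thread joint (E, q) histograms from a run
#'
#' @inheritParams energy_histograms
#' @param q_bin q bin width (defaults to the schedule's).
#' @return A `helix_histograms_2d` object: `e_mid`, `q_mid`, `counts`
#'   (E-bins x q-bins x threads array), `beta`, `s_tau`, `m`. The q-marginal
#'   of `counts` reproduces the 1D histograms accumulated from the same
#'   sweeps exactly.
#' @export
joint_histograms <- function(run, s_tau = NULL,
                             e_bin = run$schedule$e_bin,
                             q_bin = run$schedule$q_bin) {
  sel <- select_threads(run, s_tau)
  sweeps_keep <- (run$schedule$burn_in + 1):run$schedule$sweeps
  e <- run$e_trace[sweeps_keep, sel$thread, drop = FALSE]
  q <- run$q_trace[sweeps_keep, sel$thread, drop = FALSE]
  ei_range <- range(bin_index(e, e_bin))
  qi_range <- range(bin_index(q, q_bin))
  ne <- ei_range[2] - ei_range[1] + 1L
  nq <- qi_range[2] - qi_range[1] + 1L
  counts <- array(0L, dim = c(ne, nq, ncol(e)))
  for (t in seq_len(ncol(e))) {
    ei <- bin_index(e[, t], e_bin) - ei_range[1] + 1L
    qi <- bin_index(q[, t], q_bin) - qi_range[1] + 1L
    flat <- tabulate((qi - 1L) * ne + ei, nbins = ne * nq)
    counts[, , t] <- flat
  }
  structure(list(
    e_mid = (ei_range[1]:ei_range[2] + 0.5) * e_bin,
    q_mid = (qi_range[1]:qi_range[2] + 0.5) * q_bin,
    e_bin = e_bin, q_bin = q_bin, counts = counts,
    beta = 1 / sel$temperature, temperature = sel$temperature,
    s_tau = unique(sel$s_tau), m = apply(counts, 3, sum)
  ), class = "helix_histograms_2d")
}

select_threads <- function(run, s_tau) {
  stopifnot(inherits(run, "helix_run"))
  th <- run$threads
  if (is.null(s_tau)) {
    if (length(unique(th$s_tau)) > 1) {
      stop("run spans several s_tau values; pick one (histograms combine ",
           "threads of a single Hamiltonian)")
    }
  } else {
    th <- th[abs(th$s_tau - s_tau) < 1e-9, ]
    if (nrow(th) == 0) stop("no threads at s_tau = ", s_tau)
  }
  th[order(th$beta, decreasing = TRUE), ]
}
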